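#' Accessors for MetNetPhylo data classes
#'
#' \code{organismID} returns the organism identifier of a
#' \linkS4class{MetabolicNetwork}; \code{nodeTable} and \code{edgeTable}
#' return its node annotation table and canonical edge matrix.
#' \code{scoreTable} returns the entry table of a
#' \linkS4class{NodePairScores} (canonical orientation, one row per
#' unordered pair). \code{clusterTable}, \code{clusterEntropies} and
#' \code{nClusters} access an \linkS4class{EnzymeClusterSet}.
#'
#' @param x an object of the documented class.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
setMethod("organismID", "MetabolicNetwork", function(x) x@organism)

#' @rdname accessors
setMethod("nodeTable", "MetabolicNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("edgeTable", "MetabolicNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("scoreTable", "NodePairScores", function(x) x@entries)

#' @rdname accessors
setMethod("clusterTable", "EnzymeClusterSet", function(x) x@members)

#' @rdname accessors
setMethod("clusterEntropies", "EnzymeClusterSet", function(x) x@entropy)

#' @rdname accessors
setMethod("nClusters", "EnzymeClusterSet",
          function(x) length(x@entropy))

setMethod("show", "MetabolicNetwork", function(object) {
    n <- object@nodes
    cat("MetabolicNetwork for organism '", object@organism, "'\n", sep = "")
    cat("  nodes: ", nrow(n), " (", sum(n$kind == "enzyme"), " enzymes, ",
        sum(n$kind == "metabolite"), " metabolites)\n", sep = "")
    cat("  edges: ", nrow(object@edges), "\n", sep = "")
    ann <- sum(!is.na(n$group_id[n$kind == "enzyme"]))
    cat("  annotated enzymes (group_id): ", ann, "\n", sep = "")
})

setMethod("show", "NodePairScores", function(object) {
    e <- object@entries
    cat("NodePairScores with ", nrow(e), " entries\n", sep = "")
    if (nrow(e)) {
        orgs <- sort(unique(c(e$orgA, e$orgB)))
        cat("  organisms: ", paste(orgs, collapse = ", "), "\n", sep = "")
        cat("  score range: [", format(min(e$score)), ", ",
            format(max(e$score)), "]\n", sep = "")
    }
})

setMethod("show", "EnzymeClusterSet", function(object) {
    k <- nClusters(object)
    sz <- if (k) table(object@members$cluster_id) else integer()
    cat("EnzymeClusterSet with ", k, " clusters over ",
        nrow(object@members), " enzymes\n", sep = "")
    if (k) {
        cat("  cluster sizes: min ", min(sz), ", median ",
            stats::median(sz), ", max ", max(sz), "\n", sep = "")
        he <- object@entropy
        if (any(!is.na(he)))
            cat("  entropies computed for ", sum(!is.na(he)),
                " clusters\n", sep = "")
    }
})

setMethod("show", "AlignmentGraph", function(object) {
    cat("AlignmentGraph: ", nrow(object@members), " enzymes, ",
        nrow(object@edges), " cross-organism edges\n", sep = "")
})

# internal: "org|node" member keys for a cluster/member table
.memberKeys <- function(df)
    paste(df$organism, df$node_id, sep = "|")

# internal: list of per-cluster member-key character vectors
.clusterKeyList <- function(clusters) {
    m <- clusterTable(clusters)
    split(.memberKeys(m), m$cluster_id)
}

# internal: list of per-cluster organism sets
.clusterOrgList <- function(clusters) {
    m <- clusterTable(clusters)
    lapply(split(m$organism, m$cluster_id), unique)
}
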