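#' @import methods
NULL

.validNodeTable <- function(nodes) {
    req <- c("node_id", "kind", "group_id", "pathway_ids", "compound_id")
    if (!all(req %in% names(nodes)))
        return(paste0("nodes table must have columns: ",
                      paste(req, collapse = ", ")))
    if (anyDuplicated(nodes$node_id))
        return(paste0("duplicate node_id: ",
                      paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
                            collapse = ", ")))
    if (any(grepl("[[:space:]]", nodes$node_id)))
        return("node_id must not contain whitespace")
    if (!all(nodes$kind %in% c("enzyme", "metabolite")))
        return("kind must be 'enzyme' or 'metabolite'")
    met <- nodes$kind == "metabolite"
    if (any(!is.na(nodes$group_id[met])))
        return("metabolite nodes must not carry a group_id")
    if (any(nzchar(nodes$pathway_ids[met])))
        return("metabolite nodes must not carry pathway_ids")
    if (any(!is.na(nodes$compound_id[!met])))
        return("enzyme nodes must not carry a compound_id")
    TRUE
}

#' Metabolic network of one organism
#'
#' An undirected graph whose nodes are enzymes and metabolites and whose
#' edges are the reactions catalyzed by enzymes. Enzyme nodes may carry a
#' KEGG group ID (a KO or EC label) and a set of KEGG pathway IDs;
#' metabolite nodes may carry a compound ID. Node and edge order are
#' canonicalized on construction so that identical networks compare (and
#' serialize) identically.
#'
#' @slot organism single organism identifier (free string; KEGG three-letter
#'   codes in examples).
#' @slot nodes data.frame with columns \code{node_id}, \code{kind}
#'   ("enzyme"/"metabolite"), \code{group_id} (NA if absent),
#'   \code{pathway_ids} (semicolon-joined, "" if none), \code{compound_id}
#'   (NA if absent).
#' @slot edges two-column character matrix of node_id pairs; each row
#'   sorted, rows deduplicated and ordered.
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
    representation(organism = "character",
                   nodes = "data.frame",
                   edges = "matrix"))

setValidity("MetabolicNetwork", function(object) {
    if (length(object@organism) != 1L || !nzchar(object@organism))
        return("organism must be a single non-empty string")
    ok <- .validNodeTable(object@nodes)
    if (!isTRUE(ok)) return(ok)
    e <- object@edges
    if (ncol(e) != 2L)
        return("edges must be a two-column matrix")
    if (nrow(e)) {
        unknown <- setdiff(c(e), object@nodes$node_id)
        if (length(unknown))
            return(paste0("edge references unknown node: ",
                          paste(unknown, collapse = ", ")))
        if (any(e[, 1L] == e[, 2L]))
            return("self-loop edges are not allowed")
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        if (anyDuplicated(key))
            return("duplicate edges are not allowed")
    }
    TRUE
})

.canonicalizeEdges <- function(edges) {
    edges <- as.matrix(edges)
    if (!nrow(edges)) {
        e <- matrix(character(), ncol = 2L)
        colnames(e) <- c("from", "to")
        return(e)
    }
    storage.mode(edges) <- "character"
    e <- cbind(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L]))
    e <- unique(e)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
    colnames(e) <- c("from", "to")
    e
}

.canonicalPathways <- function(x) {
    vapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
           function(p) paste(sort(unique(p[nzchar(p)])), collapse = ";"),
           character(1))
}

#' Construct a MetabolicNetwork
#'
#' @param organism organism identifier.
#' @param nodes data.frame with columns \code{node_id}, \code{kind}, and
#'   optionally \code{group_id}, \code{pathway_ids} (semicolon-joined
#'   string), \code{compound_id}. Missing annotation columns are filled
#'   with NA / "".
#' @param edges two-column matrix or data.frame of node_id pairs
#'   (undirected; duplicates and orientation are canonicalized).
#' @return a validated \linkS4class{MetabolicNetwork}.
#' @examples
#' nodes <- data.frame(node_id = c("e1", "e2", "m1"),
#'                     kind = c("enzyme", "enzyme", "metabolite"),
#'                     group_id = c("K00001", "K00002", NA),
#'                     compound_id = c(NA, NA, "C00031"))
#' net <- MetabolicNetwork("eco", nodes,
#'                         rbind(c("e1", "m1"), c("e2", "m1")))
#' @export
MetabolicNetwork <- function(organism, nodes, edges = NULL) {
    nodes <- as.data.frame(nodes)
    if (is.null(nodes$group_id)) nodes$group_id <- NA_character_
    if (is.null(nodes$pathway_ids)) nodes$pathway_ids <- ""
    if (is.null(nodes$compound_id)) nodes$compound_id <- NA_character_
    nodes$node_id <- as.character(nodes$node_id)
    nodes$kind <- as.character(nodes$kind)
    nodes$group_id <- as.character(nodes$group_id)
    nodes$group_id[!is.na(nodes$group_id) & !nzchar(nodes$group_id)] <-
        NA_character_
    nodes$pathway_ids <- .canonicalPathways(as.character(nodes$pathway_ids))
    nodes$compound_id <- as.character(nodes$compound_id)
    nodes$compound_id[!is.na(nodes$compound_id) &
                      !nzchar(nodes$compound_id)] <- NA_character_
    nodes <- nodes[order(nodes$node_id),
                   c("node_id", "kind", "group_id", "pathway_ids",
                     "compound_id")]
    rownames(nodes) <- NULL
    if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
    new("MetabolicNetwork", organism = as.character(organism),
        nodes = nodes, edges = .canonicalizeEdges(edges))
}

#' Sparse cross-species node similarity scores
#'
#' Sparse table of non-negative similarity values between nodes of distinct
#' organisms. Used both for the input prior (standing in for sequence
#' similarity) and for converged alignment scores. Entries are stored once
#' in a canonical orientation (smaller organism ID first); the symmetric
#' closure is implicit.
#'
#' @slot entries data.frame with columns \code{orgA}, \code{nodeA},
#'   \code{orgB}, \code{nodeB}, \code{score}.
#' @exportClass NodePairScores
setClass("NodePairScores", representation(entries = "data.frame"))

setValidity("NodePairScores", function(object) {
    e <- object@entries
    req <- c("orgA", "nodeA", "orgB", "nodeB", "score")
    if (!identical(names(e), req))
        return(paste0("entries must have columns ", paste(req, collapse = ", ")))
    if (!nrow(e)) return(TRUE)
    if (any(e$orgA == e$orgB))
        return("score entries must link nodes of distinct organisms")
    if (any(!is.finite(e$score)) || any(e$score < 0))
        return("scores must be finite and non-negative")
    if (any(e$orgA > e$orgB))
        return("entries must be stored with orgA < orgB (canonical orientation)")
    key <- paste(e$orgA, e$nodeA, e$orgB, e$nodeB, sep = "\r")
    if (anyDuplicated(key))
        return("duplicate (organism, node) pairs in score table")
    TRUE
})

#' Construct a NodePairScores table
#'
#' @param entries data.frame with columns \code{orgA}, \code{nodeA},
#'   \code{orgB}, \code{nodeB}, \code{score} in any orientation; entries are
#'   flipped to canonical orientation and sorted. Listing the same pair in
#'   both orientations is allowed only with equal scores.
#' @return a validated \linkS4class{NodePairScores}.
#' @export
NodePairScores <- function(entries = NULL) {
    if (is.null(entries) || !nrow(entries)) {
        entries <- data.frame(orgA = character(), nodeA = character(),
                              orgB = character(), nodeB = character(),
                              score = numeric())
        return(new("NodePairScores", entries = entries))
    }
    entries <- as.data.frame(entries)
    for (cn in c("orgA", "nodeA", "orgB", "nodeB"))
        entries[[cn]] <- as.character(entries[[cn]])
    entries$score <- as.numeric(entries$score)
    flip <- entries$orgA > entries$orgB
    if (any(flip)) {
        tmpO <- entries$orgA[flip]; tmpN <- entries$nodeA[flip]
        entries$orgA[flip] <- entries$orgB[flip]
        entries$nodeA[flip] <- entries$nodeB[flip]
        entries$orgB[flip] <- tmpO
        entries$nodeB[flip] <- tmpN
    }
    key <- paste(entries$orgA, entries$nodeA, entries$orgB, entries$nodeB,
                 sep = "\r")
    if (anyDuplicated(key)) {
        agg <- tapply(entries$score, key, function(s) diff(range(s)))
        if (any(agg > 0)) {
            bad <- names(agg)[agg > 0][1L]
            stop("conflicting scores for pair ",
                 paste(strsplit(bad, "\r", fixed = TRUE)[[1L]],
                       collapse = " "))
        }
        entries <- entries[!duplicated(key), ]
    }
    entries <- entries[order(entries$orgA, entries$nodeA, entries$orgB,
                             entries$nodeB), ]
    rownames(entries) <- NULL
    new("NodePairScores", entries = entries)
}

#' Multi-species enzyme clusters
#'
#' A disjoint collection of enzyme clusters spanning one or more organisms —
#' the units of conserved function produced by the star alignment. Each
#' cluster may carry a Shannon entropy of its members' KEGG group IDs
#' (NA until computed; NaN marks a cluster with no annotated member).
#'
#' @slot members data.frame with columns \code{cluster_id} (integer),
#'   \code{organism}, \code{node_id}.
#' @slot entropy numeric vector, one value per cluster (NA if not yet
#'   computed).
#' @exportClass EnzymeClusterSet
setClass("EnzymeClusterSet",
    representation(members = "data.frame", entropy = "numeric"))

setValidity("EnzymeClusterSet", function(object) {
    m <- object@members
    if (!identical(names(m), c("cluster_id", "organism", "node_id")))
        return("members must have columns cluster_id, organism, node_id")
    ids <- unique(m$cluster_id)
    if (length(object@entropy) != length(ids))
        return("entropy must have one value per cluster")
    key <- paste(m$organism, m$node_id, sep = "|")
    if (anyDuplicated(key))
        return(paste0("enzyme assigned to more than one cluster: ",
                      key[duplicated(key)][1L]))
    TRUE
})

#' Construct an EnzymeClusterSet
#'
#' @param members data.frame with columns \code{cluster_id},
#'   \code{organism}, \code{node_id}; clusters are renumbered 1..k in
#'   order of first appearance and members sorted within cluster.
#' @param entropy optional numeric vector of per-cluster entropies (in
#'   cluster_id order).
#' @return a validated \linkS4class{EnzymeClusterSet}.
#' @export
EnzymeClusterSet <- function(members, entropy = NULL) {
    members <- as.data.frame(members)
    members$organism <- as.character(members$organism)
    members$node_id <- as.character(members$node_id)
    ids <- unique(members$cluster_id)
    members$cluster_id <- match(members$cluster_id, ids)
    members <- members[order(members$cluster_id, members$organism,
                             members$node_id),
                       c("cluster_id", "organism", "node_id")]
    rownames(members) <- NULL
    if (is.null(entropy)) entropy <- rep(NA_real_, length(ids))
    new("EnzymeClusterSet", members = members, entropy = as.numeric(entropy))
}

#' k-partite alignment graph over enzymes
#'
#' All enzyme nodes of all networks, with positive cross-organism edge
#' weights taken from converged pairwise similarity tables. Within-organism
#' edges never occur.
#'
#' @slot members data.frame with columns \code{organism}, \code{node_id};
#'   one row per enzyme, sorted.
#' @slot edges data.frame with integer columns \code{i}, \code{j} (row
#'   indices into members, i < j) and numeric \code{weight}.
#' @exportClass AlignmentGraph
setClass("AlignmentGraph",
    representation(members = "data.frame", edges = "data.frame"))

setValidity("AlignmentGraph", function(object) {
    m <- object@members; e <- object@edges
    if (!identical(names(m), c("organism", "node_id")))
        return("members must have columns organism, node_id")
    if (!identical(names(e), c("i", "j", "weight")))
        return("edges must have columns i, j, weight")
    if (nrow(e)) {
        if (any(e$i < 1L) || any(e$j > nrow(m)) || any(e$i >= e$j))
            return("edge indices must satisfy 1 <= i < j <= #members")
        if (any(e$weight <= 0) || any(!is.finite(e$weight)))
            return("edge weights must be positive and finite")
        if (any(m$organism[e$i] == m$organism[e$j]))
            return("within-organism edges are not allowed")
    }
    TRUE
})
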