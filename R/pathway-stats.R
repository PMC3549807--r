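# Per-pathway shared-enzyme statistics: for a pair of organisms, restrict
# to the clusters containing enzymes of both, and tally the members'
# pathway annotations. Similar networks share more enzymes, so large
# counts flag functionally similar pathways between the two organisms.

# lookup: "org|node" -> character vector of pathway ids
.pathwayLookup <- function(networks) {
    out <- list()
    for (net in networks) {
        n <- nodeTable(net)
        enz <- n$kind == "enzyme"
        keys <- paste(organismID(net), n$node_id[enz], sep = "|")
        pw <- strsplit(n$pathway_ids[enz], ";", fixed = TRUE)
        pw <- lapply(pw, function(p) p[nzchar(p)])
        out[keys] <- pw
    }
    out
}

#' Shared-cluster pathway enzyme counts for an organism pair
#'
#' Restricts to clusters containing at least one enzyme of each of
#' \code{orgA} and \code{orgB}; within those clusters, every member enzyme
#' belonging to either organism contributes one count to each KEGG pathway
#' ID it is annotated with. Enzymes of other organisms in the same cluster
#' are ignored. Symmetric in the two organisms.
#'
#' @param clusters the filtered \linkS4class{EnzymeClusterSet}.
#' @param networks list of \linkS4class{MetabolicNetwork}s.
#' @param orgA,orgB organism identifiers (must occur among the networks).
#' @param perOrganism if TRUE, return separate counts per organism instead
#'   of the pooled tally.
#' @return with \code{perOrganism = FALSE}, a named integer vector
#'   (pathway_id -> count, zero-count pathways omitted), sorted by
#'   pathway_id; otherwise a data.frame with columns \code{pathway_id},
#'   \code{countA}, \code{countB}.
#' @export
sharedPathwayCounts <- function(clusters, networks, orgA, orgB,
                                perOrganism = FALSE) {
    orgs <- vapply(networks, organismID, character(1))
    missing <- setdiff(c(orgA, orgB), orgs)
    if (length(missing))
        stop("unknown organism: ", paste(missing, collapse = ", "))
    m <- clusterTable(clusters)
    byCl <- split(m$organism, m$cluster_id)
    shared <- names(byCl)[vapply(byCl, function(o)
        orgA %in% o && orgB %in% o, logical(1))]
    sel <- m[m$cluster_id %in% as.integer(shared) &
             m$organism %in% c(orgA, orgB), ]
    lk <- .pathwayLookup(networks)
    tallyFor <- function(rows) {
        pw <- unlist(lk[.memberKeys(rows)], use.names = FALSE)
        if (!length(pw)) return(stats::setNames(integer(), character()))
        tb <- table(pw)
        stats::setNames(as.integer(tb), names(tb))
    }
    if (!perOrganism) return(tallyFor(sel))
    ca <- tallyFor(sel[sel$organism == orgA, ])
    cb <- tallyFor(sel[sel$organism == orgB, ])
    ids <- sort(union(names(ca), names(cb)))
    data.frame(pathway_id = ids,
               countA = ifelse(is.na(ca[ids]), 0L, ca[ids]),
               countB = ifelse(is.na(cb[ids]), 0L, cb[ids]),
               row.names = NULL)
}

#' Compare pathway count profiles of two organism pairs
#'
#' Outer-joins two count maps (e.g. from [sharedPathwayCounts()] for two
#' different organism pairs), zero-filling pathways absent from one side,
#' and sorts by absolute difference (descending), ties by pathway_id.
#'
#' @param counts1,counts2 named integer vectors (pathway_id -> count).
#' @return data.frame with columns \code{pathway_id}, \code{count1},
#'   \code{count2}, \code{difference} (count1 - count2).
#' @export
comparePathwayCounts <- function(counts1, counts2) {
    ids <- union(names(counts1), names(counts2))
    c1 <- ifelse(is.na(counts1[ids]), 0L, counts1[ids])
    c2 <- ifelse(is.na(counts2[ids]), 0L, counts2[ids])
    out <- data.frame(pathway_id = ids, count1 = as.integer(c1),
                      count2 = as.integer(c2),
                      difference = as.integer(c1 - c2))
    out <- out[order(-abs(out$difference), out$pathway_id), ]
    rownames(out) <- NULL
    out
}
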