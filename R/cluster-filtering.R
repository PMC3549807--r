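# Entropy-based functional-consistency filter. A cluster's entropy is the
# Shannon entropy of the distribution of KEGG group IDs among its annotated
# members:  H = -sum_i p_i log p_i,  p_i the fraction of members with group
# ID i. Low entropy = functionally uniform cluster; clusters with entropy
# no larger than the threshold are retained.

# lookup: "org|node" -> group_id for all enzymes of all networks
.groupLookup <- function(networks) {
    unlist(lapply(unname(networks), function(net) {
        n <- nodeTable(net)
        enz <- n$kind == "enzyme"
        stats::setNames(n$group_id[enz],
                        paste(organismID(net), n$node_id[enz], sep = "|"))
    }))
}

#' Shannon entropy of cluster group-ID composition
#'
#' For each cluster, computes \eqn{H = -\sum_i p_i \log p_i} where
#' \eqn{p_i} is the fraction of the cluster's annotated members carrying
#' KEGG group ID i. Members without a group_id are excluded from the
#' fractions; a cluster with no annotated member at all has undefined
#' entropy and is reported as NaN (it always fails the filter) with a
#' warning.
#'
#' @param clusters an \linkS4class{EnzymeClusterSet}.
#' @param networks list of \linkS4class{MetabolicNetwork}s resolving every
#'   member to its annotation.
#' @param logBase \code{"natural"} (default) or \code{"base2"}.
#' @return numeric vector of entropies, one per cluster (NaN for fully
#'   unannotated clusters).
#' @export
clusterEntropy <- function(clusters, networks,
                           logBase = c("natural", "base2")) {
    logBase <- match.arg(logBase)
    lk <- .groupLookup(networks)
    keyList <- .clusterKeyList(clusters)
    unresolved <- setdiff(unlist(keyList), names(lk))
    if (length(unresolved))
        stop("cluster member not found among network enzymes: ",
             unresolved[1L])
    lg <- if (logBase == "natural") log else log2
    h <- vapply(keyList, function(k) {
        gids <- lk[k]
        gids <- gids[!is.na(gids)]
        if (!length(gids)) return(NaN)
        p <- as.vector(table(gids)) / length(gids)
        -sum(p * lg(p))
    }, numeric(1))
    if (any(is.nan(h)))
        warning(sum(is.nan(h)),
                " cluster(s) have no annotated member; entropy undefined")
    unname(h)
}

#' Filter clusters by annotation entropy
#'
#' Retains exactly the clusters whose group-ID entropy is no larger than
#' \code{threshold} (boundary inclusive), preserving input order, and
#' stores the computed entropy on each retained cluster. Fully unannotated
#' clusters (entropy undefined) are always removed.
#'
#' @param clusters an \linkS4class{EnzymeClusterSet}.
#' @param networks list of \linkS4class{MetabolicNetwork}s.
#' @param threshold entropy cutoff (default 0.5, natural log).
#' @param logBase \code{"natural"} or \code{"base2"}.
#' @return the retained \linkS4class{EnzymeClusterSet} with entropies set.
#' @export
filterClusters <- function(clusters, networks, threshold = 0.5,
                           logBase = c("natural", "base2")) {
    stopifnot(threshold >= 0)
    h <- clusterEntropy(clusters, networks, logBase = logBase)
    keep <- which(!is.nan(h) & h <= threshold)
    m <- clusterTable(clusters)
    sel <- m[m$cluster_id %in% keep, ]
    EnzymeClusterSet(sel, entropy = h[keep])
}
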