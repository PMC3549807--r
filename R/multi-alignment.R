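# Star-restricted personalized spectral clustering over the k-partite
# alignment graph: pivots are picked by weighted degree among unassigned
# enzymes, each pivot's star is ranked by personalized PageRank, and the
# high-mass members are extracted as one conserved-function cluster.

#' Assemble the k-partite alignment graph
#'
#' Collects the enzyme-enzyme entries of all converged pairwise score
#' tables into one weighted graph over every enzyme of every network.
#' Edges below \code{minWeight} are dropped; organism pairs without a
#' score table simply contribute no edges.
#'
#' @param scoreTables list of \linkS4class{NodePairScores}, one per scored
#'   organism pair.
#' @param networks list of \linkS4class{MetabolicNetwork}s defining the
#'   enzyme universe (isolated enzymes matter: they become singleton
#'   clusters downstream).
#' @param minWeight edge inclusion floor applied as a plain threshold when
#'   given. The default (NULL) is adaptive: within each score table,
#'   edges must score at least twice the table's mean enzyme-pair score
#'   (in a unit-mass table the uninformative background sits below the
#'   mean) and lie within a factor 2 of both endpoints' best score into
#'   the partner organism (reciprocal best-hit band).
#' @return an \linkS4class{AlignmentGraph}.
#' @export
buildAlignmentGraph <- function(scoreTables, networks, minWeight = NULL) {
    if (inherits(scoreTables, "NodePairScores"))
        scoreTables <- list(scoreTables)
    memb <- do.call(rbind, lapply(networks, function(net) {
        n <- nodeTable(net)
        data.frame(organism = organismID(net),
                   node_id = n$node_id[n$kind == "enzyme"])
    }))
    memb <- memb[order(memb$organism, memb$node_id), ]
    rownames(memb) <- NULL
    key <- .memberKeys(memb)
    if (anyDuplicated(key)) stop("duplicate organism in networks")
    kinds <- unlist(lapply(unname(networks), function(net) {
        n <- nodeTable(net)
        stats::setNames(n$kind, paste(organismID(net), n$node_id, sep = "|"))
    }))
    kept <- lapply(scoreTables, function(tab) {
        e <- scoreTable(tab)
        if (!nrow(e)) return(e[0, ])
        kA <- paste(e$orgA, e$nodeA, sep = "|")
        kB <- paste(e$orgB, e$nodeB, sep = "|")
        enz <- kinds[kA] == "enzyme" & kinds[kB] == "enzyme"
        enz[is.na(enz)] <- FALSE
        e <- e[enz, , drop = FALSE]
        if (!nrow(e)) return(e)
        if (!is.null(minWeight))
            return(e[e$score >= minWeight, , drop = FALSE])
        # adaptive default: (1) global floor at twice the mean enzyme-pair
        # score — in a unit-mass table the uninformative background sits
        # below the mean; (2) reciprocal best-hit band — keep an edge only
        # if it is within a factor 2 of both endpoints' best score into the
        # partner organism, so merely topology-similar pairs (several-fold
        # weaker than the true match) cannot flood the stars
        e <- e[e$score >= 2 * mean(e$score), , drop = FALSE]
        if (!nrow(e)) return(e)
        keyU <- paste(e$orgA, e$nodeA, e$orgB, sep = "\r")
        keyV <- paste(e$orgB, e$nodeB, e$orgA, sep = "\r")
        bestU <- stats::ave(e$score, keyU, FUN = max)
        bestV <- stats::ave(e$score, keyV, FUN = max)
        e[e$score >= 0.5 * bestU & e$score >= 0.5 * bestV, , drop = FALSE]
    })
    all <- do.call(rbind, kept)
    if (is.null(all) || !nrow(all)) {
        edges <- data.frame(i = integer(), j = integer(), weight = numeric())
        return(new("AlignmentGraph", members = memb, edges = edges))
    }
    kA <- paste(all$orgA, all$nodeA, sep = "|")
    kB <- paste(all$orgB, all$nodeB, sep = "|")
    sel <- rep(TRUE, nrow(all))
    i <- match(kA[sel], key); j <- match(kB[sel], key)
    if (anyNA(i) || anyNA(j))
        stop("score table references an enzyme not present in networks")
    sw <- ifelse(i < j, i, j); lg <- ifelse(i < j, j, i)
    edges <- data.frame(i = sw, j = lg, weight = all$score[sel])
    ek <- paste(edges$i, edges$j)
    if (anyDuplicated(ek)) {
        agg <- tapply(edges$weight, ek, function(w) diff(range(w)))
        if (any(agg > 1e-9 * max(edges$weight)))
            stop("inconsistent duplicate edge weights in score tables")
        edges <- edges[!duplicated(ek), ]
    }
    edges <- edges[order(edges$i, edges$j), ]
    rownames(edges) <- NULL
    new("AlignmentGraph", members = memb, edges = edges)
}

# personalized PageRank on a dense weighted subgraph; restart on `pivot`
.personalPageRank <- function(W, pivot, damping, tol = 1e-12,
                              maxIter = 100000L) {
    n <- nrow(W)
    cs <- colSums(W)
    nz <- cs > 0
    Tm <- W
    Tm[, nz] <- sweep(W[, nz, drop = FALSE], 2L, cs[nz], "/")
    # dangling columns restart to the pivot
    restart <- numeric(n); restart[pivot] <- 1
    p <- restart
    for (it in seq_len(maxIter)) {
        pn <- damping * as.vector(Tm %*% p) + restart *
            ((1 - damping) + damping * sum(p[!nz]))
        delta <- sum(abs(pn - p))
        p <- pn
        if (delta <= tol) break
    }
    p
}

#' Extract multi-species enzyme clusters by star alignment
#'
#' Iteratively: pick the unassigned enzyme with the largest total weight
#' to other unassigned enzymes (ties broken lexicographically by
#' (organism, node_id)); form the star of that pivot and its unassigned
#' neighbors; rank the star by personalized PageRank on its induced
#' subgraph with the restart concentrated on the pivot; keep the pivot
#' plus every star member whose stationary mass is at least
#' \code{keepRatio} times the pivot's mass. Extraction repeats until no
#' edges remain among unassigned enzymes; the rest become singleton
#' clusters. Clusters may contain several enzymes of one organism
#' (paralog-tolerant). Fully deterministic.
#'
#' @param g an \linkS4class{AlignmentGraph}.
#' @param damping PageRank damping factor in (0,1).
#' @param keepRatio retention threshold relative to the pivot's mass,
#'   in (0,1].
#' @return an \linkS4class{EnzymeClusterSet}, clusters numbered in
#'   extraction order with singletons last.
#' @export
spectralStarClusters <- function(g, damping = 0.85, keepRatio = 0.3) {
    stopifnot(damping > 0, damping < 1, keepRatio > 0, keepRatio <= 1)
    memb <- g@members
    n <- nrow(memb)
    edges <- g@edges
    assigned <- logical(n)
    # members are pre-sorted by (organism, node_id): index order is the
    # lexicographic tie-break order
    clusters <- list()
    active <- rep(TRUE, nrow(edges))
    while (any(active)) {
        ae <- edges[active, , drop = FALSE]
        strength <- numeric(n)
        sa <- rowsum(c(ae$weight, ae$weight), c(ae$i, ae$j))
        strength[as.integer(rownames(sa))] <- sa[, 1L]
        pivot <- which.max(strength)   # first max = lexicographic tie-break
        nb <- unique(c(ae$j[ae$i == pivot], ae$i[ae$j == pivot]))
        star <- c(pivot, sort(nb))
        sub <- ae[ae$i %in% star & ae$j %in% star, , drop = FALSE]
        m <- length(star)
        W <- matrix(0, m, m)
        si <- match(sub$i, star); sj <- match(sub$j, star)
        W[cbind(si, sj)] <- sub$weight
        W[cbind(sj, si)] <- sub$weight
        p <- .personalPageRank(W, 1L, damping)
        keep <- star[p >= keepRatio * p[1L]]
        keep <- unique(c(pivot, keep))
        clusters[[length(clusters) + 1L]] <- keep
        assigned[keep] <- TRUE
        active <- active & !assigned[edges$i] & !assigned[edges$j]
    }
    for (k in which(!assigned))
        clusters[[length(clusters) + 1L]] <- k
    members <- data.frame(
        cluster_id = rep(seq_along(clusters), lengths(clusters)),
        organism = memb$organism[unlist(clusters)],
        node_id = memb$node_id[unlist(clusters)])
    EnzymeClusterSet(members)
}
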