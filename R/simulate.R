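# Synthetic benchmark generator: one ancestral enzyme-metabolite network
# evolved along a known tree by per-branch gene loss, edge rewiring and
# annotation relabeling. Every surviving lineage of an ancestral enzyme is
# a planted ortholog group, and a two-level prior (high score within
# groups, low elsewhere) stands in for sequence similarity. Everything is
# reproducible from one seed; per-branch substreams are derived
# deterministically so adding leaves does not perturb other branches.

.deriveSeed <- function(seed, k)
    as.integer((as.numeric(seed) %% 65536 * 32749 + 104729 * k) %% 2147483647)

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Simulate metabolic networks evolved along a known tree
#'
#' Generates an ancestral bipartite-style network of \code{nEnzymes}
#' enzymes wired to \code{nMetabolites} metabolites (each enzyme linked to
#' each metabolite with probability \code{meanDegree / nMetabolites}, and
#' to at least one), with unique per-enzyme KEGG-style group IDs, pathway
#' annotations drawn from a small pathway set, and shared compound IDs.
#' The network then evolves along each branch of \code{tree}
#' independently: every enzyme is deleted with probability
#' \code{nodeLossRate}, every surviving edge is rewired to a different
#' metabolite with probability \code{edgeRewireRate}, and every enzyme's
#' group label is replaced by a novel label with probability
#' \code{annotationNoise}. Leaf states become per-organism networks;
#' surviving lineages of each ancestral enzyme form the planted ortholog
#' groups; the prior scores \code{sHi} within groups and \code{sLo}
#' elsewhere (optional uniform jitter of half-width \code{jitter},
#' truncated at 0).
#'
#' @param tree a \code{phylo} tree over the organisms, or an integer
#'   taxon count for a random tree (\code{ape::rtree}) drawn under the
#'   seed.
#' @param nEnzymes,nMetabolites ancestral node counts.
#' @param meanDegree expected edges per enzyme in the ancestral network.
#' @param nodeLossRate,edgeRewireRate,annotationNoise per-branch event
#'   probabilities, each in [0,1].
#' @param sHi,sLo prior scores for within-group / background enzyme pairs.
#' @param jitter half-width of uniform noise added to prior scores (0 =
#'   none).
#' @param nPathways size of the pathway label pool.
#' @param seed integer seed fixing all randomness.
#' @return list with elements \code{networks} (named list of
#'   \linkS4class{MetabolicNetwork}, one per leaf), \code{truth}
#'   (planted ortholog groups as an \linkS4class{EnzymeClusterSet}),
#'   \code{prior} (\linkS4class{NodePairScores}), \code{tree} (the
#'   generating \code{phylo}).
#' @export
simulateNetworks <- function(tree = 6L, nEnzymes = 60L, nMetabolites = 30L,
                             meanDegree = 3, nodeLossRate = 0.05,
                             edgeRewireRate = 0.05, annotationNoise = 0.02,
                             sHi = 0.9, sLo = 0.05, jitter = 0,
                             nPathways = 5L, seed = 1L) {
    rates <- c(nodeLossRate, edgeRewireRate, annotationNoise)
    if (any(rates < 0) || any(rates > 1))
        stop("loss, rewire and annotation rates must lie in [0, 1]")
    stopifnot(nEnzymes >= 1, nMetabolites >= 1, meanDegree > 0,
              sHi >= 0, sLo >= 0, jitter >= 0)
    if (is.numeric(tree) && length(tree) == 1L) {
        nl <- as.integer(tree)
        stopifnot(nl >= 2L)
        tree <- .withSeed(.deriveSeed(seed, 1L), ape::rtree(nl))
        tree$tip.label <- sprintf("org%02d", seq_len(nl))
    }
    if (!inherits(tree, "phylo")) stop("tree must be a phylo or a count")

    # ancestral network
    anc <- .withSeed(.deriveSeed(seed, 2L), {
        p <- min(1, meanDegree / nMetabolites)
        adj <- matrix(stats::runif(nEnzymes * nMetabolites) < p,
                      nEnzymes, nMetabolites)
        for (i in which(rowSums(adj) == 0))
            adj[i, sample.int(nMetabolites, 1L)] <- TRUE
        pwPool <- sprintf("ko%05d", seq_len(nPathways) * 10L)
        pw <- lapply(seq_len(nEnzymes), function(i)
            sort(sample(pwPool, sample(1:2, 1L))))
        list(edges = which(adj, arr.ind = TRUE), pw = pw)
    })
    grp0 <- sprintf("K%05d", seq_len(nEnzymes))

    tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    nTip <- length(tree$tip.label)
    root <- nTip + 1L
    states <- vector("list", nTip + tree$Nnode)
    states[[root]] <- list(enz = seq_len(nEnzymes), grp = grp0,
                           edges = anc$edges)
    for (k in seq_len(nrow(tree$edge))) {
        par <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
        st <- states[[par]]
        bseed <- .deriveSeed(seed, 100L + k)
        states[[child]] <- .withSeed(bseed, {
            # gene loss
            keep <- stats::runif(length(st$enz)) >= nodeLossRate
            enz <- st$enz[keep]
            edges <- st$edges[st$edges[, 1L] %in% enz, , drop = FALSE]
            grp <- st$grp
            # edge rewiring: move the metabolite endpoint
            if (nrow(edges)) {
                hit <- which(stats::runif(nrow(edges)) < edgeRewireRate)
                for (r in hit) {
                    e <- edges[r, 1L]
                    cand <- setdiff(seq_len(nMetabolites),
                                    edges[edges[, 1L] == e, 2L])
                    if (length(cand))
                        edges[r, 2L] <- cand[sample.int(length(cand), 1L)]
                }
            }
            # annotation relabeling to novel, deterministic labels
            flip <- which(stats::runif(nEnzymes) < annotationNoise)
            flip <- intersect(flip, enz)
            grp[flip] <- sprintf("KX%d_%d", bseed %% 100000L, flip)
            list(enz = enz, grp = grp, edges = edges)
        })
    }

    orgs <- tree$tip.label
    eid <- sprintf("e%03d", seq_len(nEnzymes))
    mid <- sprintf("m%03d", seq_len(nMetabolites))
    networks <- stats::setNames(lapply(seq_len(nTip), function(tp) {
        st <- states[[tp]]
        nE <- length(st$enz)
        nodes <- rbind(
            data.frame(node_id = eid[st$enz],
                       kind = rep("enzyme", nE),
                       group_id = st$grp[st$enz],
                       pathway_ids = vapply(anc$pw[st$enz], paste,
                                            character(1), collapse = ";"),
                       compound_id = rep(NA_character_, nE)),
            data.frame(node_id = mid, kind = "metabolite",
                       group_id = NA_character_, pathway_ids = "",
                       compound_id = sprintf("C%05d", seq_len(nMetabolites))))
        edges <- cbind(eid[st$edges[, 1L]], mid[st$edges[, 2L]])
        MetabolicNetwork(orgs[tp], nodes, edges)
    }), orgs)

    # planted ortholog groups: surviving lineages per ancestral enzyme
    surv <- lapply(seq_len(nEnzymes), function(i)
        orgs[vapply(seq_len(nTip), function(tp)
            i %in% states[[tp]]$enz, logical(1))])
    nonEmpty <- which(lengths(surv) > 0)
    truth <- EnzymeClusterSet(data.frame(
        cluster_id = rep(seq_along(nonEmpty), lengths(surv[nonEmpty])),
        organism = unlist(surv[nonEmpty]),
        node_id = rep(eid[nonEmpty], lengths(surv[nonEmpty]))))

    # prior: two-level scores over all cross-organism enzyme pairs
    prior <- .withSeed(.deriveSeed(seed, 3L), {
        rows <- list()
        for (a in seq_len(nTip - 1L)) for (b in (a + 1L):nTip) {
            ea <- states[[a]]$enz; eb <- states[[b]]$enz
            if (!length(ea) || !length(eb)) next
            gr <- expand.grid(ia = ea, ib = eb)
            sc <- ifelse(gr$ia == gr$ib, sHi, sLo)
            if (jitter > 0)
                sc <- pmax(0, sc + stats::runif(length(sc), -jitter, jitter))
            rows[[length(rows) + 1L]] <- data.frame(
                orgA = orgs[a], nodeA = eid[gr$ia],
                orgB = orgs[b], nodeB = eid[gr$ib], score = sc)
        }
        if (length(rows)) NodePairScores(do.call(rbind, rows))
        else NodePairScores()
    })

    list(networks = networks, truth = truth, prior = prior, tree = tree)
}

# unordered co-membership pair keys of a cluster key list
.coPairs <- function(keyList) {
    out <- lapply(keyList, function(k) {
        if (length(k) < 2L) return(character())
        k <- sort(k)
        cmb <- utils::combn(k, 2L)
        paste(cmb[1L, ], cmb[2L, ], sep = "\r")
    })
    unlist(out, use.names = FALSE)
}

#' Score recovered clusters against planted ortholog groups
#'
#' Pairwise precision and recall of co-clustering (over unordered enzyme
#' pairs placed together) plus the fraction of planted groups recovered as
#' exact member sets. With no predicted pairs precision is reported as 1;
#' with no true pairs recall is 1.
#'
#' @param truth planted groups (\linkS4class{EnzymeClusterSet}).
#' @param clusters recovered clusters (\linkS4class{EnzymeClusterSet}).
#' @return named numeric vector \code{precision}, \code{recall},
#'   \code{exactGroupFraction}.
#' @export
evaluateRecovery <- function(truth, clusters) {
    tk <- .clusterKeyList(truth)
    ck <- .clusterKeyList(clusters)
    tp <- .coPairs(tk); cp <- .coPairs(ck)
    inter <- length(intersect(tp, cp))
    precision <- if (length(cp)) inter / length(cp) else 1
    recall <- if (length(tp)) inter / length(tp) else 1
    tsig <- vapply(tk, function(k) paste(sort(k), collapse = "\t"),
                   character(1))
    csig <- vapply(ck, function(k) paste(sort(k), collapse = "\t"),
                   character(1))
    c(precision = precision, recall = recall,
      exactGroupFraction = mean(tsig %in% csig))
}

#' Write a simulated fixture to a directory
#'
#' Serializes every leaf network (\code{<org>.nodes.tsv} /
#' \code{<org>.edges.tsv}), the prior (\code{scores.tsv}), the planted
#' groups (\code{truth.clusters.tsv}) and the generating tree
#' (\code{tree.nwk}).
#'
#' @param sim result of [simulateNetworks()].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeFixture <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (org in names(sim$networks))
        writeNetwork(sim$networks[[org]],
                     file.path(dir, paste0(org, ".nodes.tsv")),
                     file.path(dir, paste0(org, ".edges.tsv")))
    writeScores(sim$prior, file.path(dir, "scores.tsv"))
    writeClusters(sim$truth, file.path(dir, "truth.clusters.tsv"))
    toNewick(sim$tree, file.path(dir, "tree.nwk"))
    invisible(dir)
}

#' Read a fixture directory
#'
#' Counterpart of [writeFixture()]: loads every \code{<org>.nodes.tsv} /
#' \code{<org>.edges.tsv} pair, plus \code{scores.tsv},
#' \code{truth.clusters.tsv} and \code{tree.nwk} when present.
#'
#' @param dir fixture directory.
#' @return list with \code{networks}, \code{prior}, \code{truth},
#'   \code{tree} (the latter three NULL when absent).
#' @export
readFixture <- function(dir) {
    nodeFiles <- sort(list.files(dir, pattern = "\\.nodes\\.tsv$"))
    if (!length(nodeFiles)) stop("no <org>.nodes.tsv files in ", dir)
    orgs <- sub("\\.nodes\\.tsv$", "", nodeFiles)
    networks <- stats::setNames(lapply(orgs, function(org)
        readNetwork(file.path(dir, paste0(org, ".nodes.tsv")),
                    file.path(dir, paste0(org, ".edges.tsv")), org)), orgs)
    pf <- file.path(dir, "scores.tsv")
    tf <- file.path(dir, "truth.clusters.tsv")
    wf <- file.path(dir, "tree.nwk")
    list(networks = networks,
         prior = if (file.exists(pf)) readScores(pf) else NULL,
         truth = if (file.exists(tf)) readClusters(tf) else NULL,
         tree = if (file.exists(wf)) fromNewick(path = wf) else NULL)
}
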