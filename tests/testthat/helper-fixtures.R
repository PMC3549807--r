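# Fixture builders used across the suite. Everything is generated in code;
# seeds are always explicit.

# compact network builder: enz/met are node-id vectors, groups/compounds
# optional parallel annotation vectors, edges a 2-column matrix
mkNet <- function(org, enz, met = character(), edges = NULL,
                  groups = NULL, pathways = NULL, compounds = NULL) {
    if (is.null(groups)) groups <- rep(NA_character_, length(enz))
    if (is.null(pathways)) pathways <- rep("", length(enz))
    if (is.null(compounds)) compounds <- rep(NA_character_, length(met))
    nodes <- rbind(
        data.frame(node_id = enz, kind = "enzyme", group_id = groups,
                   pathway_ids = pathways, compound_id = NA_character_),
        if (length(met))
            data.frame(node_id = met, kind = "metabolite",
                       group_id = NA_character_, pathway_ids = "",
                       compound_id = compounds))
    MetabolicNetwork(org, nodes, edges)
}

# random connected-ish network with enzymes e1..eN and metabolites m1..mM;
# edges may pair any node kinds (the format permits it)
randNet <- function(org, nEnz, nMet, nEdges, seed) {
    set.seed(seed)
    ids <- c(paste0("e", seq_len(nEnz)),
             if (nMet) paste0("m", seq_len(nMet)))
    pool <- t(combn(ids, 2L))
    pick <- pool[sample.int(nrow(pool), min(nEdges, nrow(pool))), ,
                 drop = FALSE]
    mkNet(org, paste0("e", seq_len(nEnz)),
          if (nMet) paste0("m", seq_len(nMet)) else character(),
          edges = pick,
          compounds = if (nMet) paste0("C", seq_len(nMet)) else character())
}

# clusters with prescribed group-id composition: groupList is a list of
# character vectors (NA = unannotated member); returns the cluster set plus
# the single network resolving every member
clustersFromGroups <- function(groupList) {
    sizes <- lengths(groupList)
    ids <- paste0("e", seq_len(sum(sizes)))
    net <- mkNet("X", ids, groups = unlist(groupList))
    clusters <- EnzymeClusterSet(data.frame(
        cluster_id = rep(seq_along(groupList), sizes),
        organism = "X", node_id = ids))
    list(clusters = clusters, networks = list(net))
}

# random disjoint cluster set over organisms org1..orgK
randClusters <- function(nOrg, nClusters, maxSize, seed) {
    set.seed(seed)
    orgs <- sprintf("org%02d", seq_len(nOrg))
    counter <- 0L
    rows <- lapply(seq_len(nClusters), function(k) {
        sz <- sample.int(maxSize, 1L)
        o <- sample(orgs, sz, replace = TRUE)
        data.frame(cluster_id = k, organism = o,
                   node_id = paste0("n", counter + seq_len(sz) +
                                        k * 1000L))
    })
    EnzymeClusterSet(do.call(rbind, rows))
}

# brute-force organism distance straight from the definition: walk the
# cluster list once, counting intersection and union memberships
bruteDistance <- function(clusters, orgA, orgB) {
    m <- clusterTable(clusters)
    nInt <- 0L; nUni <- 0L
    for (cid in unique(m$cluster_id)) {
        orgs <- m$organism[m$cluster_id == cid]
        inA <- orgA %in% orgs; inB <- orgB %in% orgs
        if (inA && inB) nInt <- nInt + 1L
        if (inA || inB) nUni <- nUni + 1L
    }
    if (nUni == 0L) return(1)
    1 - nInt / nUni
}

# independent dense fixed-point solve of the similarity recursion:
# (I - alpha * M) r = (1 - alpha) * e over admissible pairs, where M is
# assembled pair-by-pair from the two adjacency structures. Returns the
# normalized dense matrix (rows = nodes of A).
denseSolveScores <- function(netA, netB, prior, alpha) {
    na <- nodeTable(netA); nb <- nodeTable(netB)
    nbrs <- function(net) {
        ids <- nodeTable(net)$node_id
        e <- edgeTable(net)
        out <- setNames(vector("list", length(ids)), ids)
        for (r in seq_len(nrow(e))) {
            out[[e[r, 1L]]] <- c(out[[e[r, 1L]]], e[r, 2L])
            out[[e[r, 2L]]] <- c(out[[e[r, 2L]]], e[r, 1L])
        }
        out
    }
    nA <- nbrs(netA); nB <- nbrs(netB)
    # admissible pair index
    pairs <- expand.grid(i = seq_len(nrow(na)), j = seq_len(nrow(nb)))
    adm <- (na$kind[pairs$i] == "enzyme") == (nb$kind[pairs$j] == "enzyme")
    pairs <- pairs[adm, ]
    key <- paste(pairs$i, pairs$j)
    np <- nrow(pairs)
    # prior vector, same conventions as the implementation
    e <- numeric(np)
    pe <- scoreTable(prior)
    oa <- organismID(netA); ob <- organismID(netB)
    sel <- pe$orgA == min(oa, ob) & pe$orgB == max(oa, ob)
    pe <- pe[sel, , drop = FALSE]
    hasEnzPrior <- nrow(pe) > 0
    for (p in seq_len(np)) {
        i <- pairs$i[p]; j <- pairs$j[p]
        if (na$kind[i] == "metabolite") {
            if (!is.na(na$compound_id[i]) && !is.na(nb$compound_id[j]) &&
                na$compound_id[i] == nb$compound_id[j]) e[p] <- 1
        } else if (hasEnzPrior) {
            if (oa <= ob)
                hit <- pe$nodeA == na$node_id[i] & pe$nodeB == nb$node_id[j]
            else
                hit <- pe$nodeB == na$node_id[i] & pe$nodeA == nb$node_id[j]
            if (any(hit)) e[p] <- pe$score[hit]
        } else if (na$kind[i] == "enzyme") {
            e[p] <- 1    # uniform enzyme prior fallback
        }
    }
    if (sum(e) == 0) e[] <- 1
    e <- e / sum(e)
    deg <- c(lengths(nA), lengths(nB))
    names(deg) <- c(paste0("A.", na$node_id), paste0("B.", nb$node_id))
    M <- matrix(0, np, np)
    for (p in seq_len(np)) {
        i <- pairs$i[p]; j <- pairs$j[p]
        for (u in nA[[na$node_id[i]]]) for (v in nB[[nb$node_id[j]]]) {
            q <- match(paste(match(u, na$node_id), match(v, nb$node_id)),
                       key)
            if (!is.na(q))
                M[p, q] <- 1 / (deg[paste0("A.", u)] * deg[paste0("B.", v)])
        }
    }
    r <- solve(diag(np) - alpha * M, (1 - alpha) * e)
    r <- r / sum(r)
    out <- matrix(0, nrow(na), nrow(nb),
                  dimnames = list(na$node_id, nb$node_id))
    out[cbind(pairs$i, pairs$j)] <- r
    out
}

# dense matrix view of a NodePairScores table for one organism pair
scoresAsMatrix <- function(scores, netA, netB) {
    out <- matrix(0, nrow(nodeTable(netA)), nrow(nodeTable(netB)),
                  dimnames = list(nodeTable(netA)$node_id,
                                  nodeTable(netB)$node_id))
    e <- scoreTable(scores)
    oa <- organismID(netA)
    for (r in seq_len(nrow(e))) {
        if (e$orgA[r] == oa) out[e$nodeA[r], e$nodeB[r]] <- e$score[r]
        else out[e$nodeB[r], e$nodeA[r]] <- e$score[r]
    }
    out
}

# run the alignment-through-clustering front end on a simulation
clusterSim <- function(sim, ...) {
    nets <- sim$networks
    n <- length(nets)
    st <- list()
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
        st[[length(st) + 1L]] <-
            pairwiseScores(nets[[a]], nets[[b]], sim$prior, ...)
    spectralStarClusters(buildAlignmentGraph(st, nets))
}

# topological (unit-branch-length) leaf-to-leaf path lengths of a tree
pathLengths <- function(tree)
    ape::cophenetic.phylo(ape::compute.brlen(tree, 1))
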