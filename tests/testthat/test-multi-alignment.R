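test_that("alignment graph respects organism pairs and the weight floor", {
    nets <- list(mkNet("X", c("e1", "e2")), mkNet("Y", c("f1", "f2")),
                 mkNet("Z", c("g1")))
    # only the (X, Y) pair scored -> bipartite between X and Y enzymes
    s <- NodePairScores(data.frame(
        orgA = "X", nodeA = c("e1", "e2"), orgB = "Y",
        nodeB = c("f1", "f2"), score = c(0.4, 0.05)))
    g <- buildAlignmentGraph(list(s), nets, minWeight = 0)
    orgsOf <- function(g) cbind(g@members$organism[g@edges$i],
                                g@members$organism[g@edges$j])
    expect_equal(nrow(g@edges), 2L)
    expect_true(all(orgsOf(g) %in% c("X", "Y")))
    expect_equal(nrow(g@members), 5L)     # Z's enzyme is a member
    # floor keeps exactly the 0.4 edge
    g2 <- buildAlignmentGraph(list(s), nets, minWeight = 0.1)
    expect_equal(nrow(g2@edges), 1L)
    expect_equal(g2@edges$weight, 0.4)
    # floor above every score -> empty edge set
    g3 <- buildAlignmentGraph(list(s), nets, minWeight = 1)
    expect_equal(nrow(g3@edges), 0L)
})

test_that("single-edge graphs and empty graphs cluster as forced", {
    nets <- list(mkNet("X", c("e1", "e2")), mkNet("Y", c("f1", "f2")))
    s <- NodePairScores(data.frame(orgA = "X", nodeA = "e1", orgB = "Y",
                                   nodeB = "f1", score = 1))
    g <- buildAlignmentGraph(list(s), nets, minWeight = 0)
    cl <- spectralStarClusters(g)
    keys <- MetNetPhylo:::.clusterKeyList(cl)
    expect_equal(nClusters(cl), 3L)   # the pair plus two singletons
    expect_true(any(vapply(keys, function(k)
        setequal(k, c("X|e1", "Y|f1")), logical(1))))
    # empty graph over 4 enzymes -> 4 singletons
    g0 <- buildAlignmentGraph(list(NodePairScores()), nets)
    cl0 <- spectralStarClusters(g0)
    expect_equal(nClusters(cl0), 4L)
    expect_true(all(lengths(MetNetPhylo:::.clusterKeyList(cl0)) == 1L))
})

test_that("planted heavy cliques are recovered and match the best partition", {
    orgs <- c("X", "Y", "Z")
    nets <- lapply(orgs, function(o) mkNet(o, c("p", "q")))
    # two 3-organism cliques (one per enzyme), heavy inside, faint across
    mkPair <- function(oa, ob) {
        grid <- expand.grid(na = c("p", "q"), nb = c("p", "q"))
        NodePairScores(data.frame(
            orgA = oa, nodeA = grid$na, orgB = ob, nodeB = grid$nb,
            score = ifelse(grid$na == grid$nb, 1.0, 0.01)))
    }
    st <- list(mkPair("X", "Y"), mkPair("X", "Z"), mkPair("Y", "Z"))
    g <- buildAlignmentGraph(st, nets, minWeight = 0)
    cl <- spectralStarClusters(g, keepRatio = 0.2)
    keys <- lapply(MetNetPhylo:::.clusterKeyList(cl), sort)
    expect_true(any(vapply(keys, function(k)
        identical(k, c("X|p", "Y|p", "Z|p")), logical(1))))
    expect_true(any(vapply(keys, function(k)
        identical(k, c("X|q", "Y|q", "Z|q")), logical(1))))

    # brute-force best-partition oracle on the 6-node instance:
    # correlation-clustering score with the midpoint weight as baseline
    memb <- MetNetPhylo:::.memberKeys(g@members)
    w <- matrix(0, 6, 6, dimnames = list(memb, memb))
    w[cbind(memb[g@edges$i], memb[g@edges$j])] <- g@edges$weight
    w <- w + t(w)
    theta <- (max(w[w > 0]) + min(w[w > 0])) / 2
    partScore <- function(assign) {
        s <- 0
        for (a in seq_len(5)) for (b in (a + 1):6)
            if (assign[a] == assign[b]) s <- s + w[a, b] - theta
        s
    }
    allParts <- function(n) {        # set partitions as assignment vectors
        out <- list(1L)
        for (k in 2:n) {
            nxt <- list()
            for (p in out) for (c in seq_len(max(p) + 1L))
                nxt[[length(nxt) + 1L]] <- c(p, c)
            out <- nxt
        }
        out
    }
    scores <- vapply(allParts(6), partScore, numeric(1))
    best <- allParts(6)[[which.max(scores)]]
    bestSets <- lapply(split(memb, best), sort)
    expect_true(any(vapply(bestSets, identical,
                           logical(1), c("X|p", "Y|p", "Z|p"))))
    expect_true(any(vapply(bestSets, identical,
                           logical(1), c("X|q", "Y|q", "Z|q"))))
})

test_that("clusters partition the enzyme universe deterministically", {
    for (seed in c(5, 9)) {
        sim <- simulateNetworks(tree = 4L, nEnzymes = 15L,
                                nMetabolites = 8L, seed = seed)
        cl1 <- clusterSim(sim)
        cl2 <- clusterSim(sim)
        expect_identical(clusterTable(cl1), clusterTable(cl2))
        nEnz <- sum(vapply(sim$networks, function(n)
            sum(nodeTable(n)$kind == "enzyme"), numeric(1)))
        expect_equal(nrow(clusterTable(cl1)), nEnz)   # disjoint cover
        expect_false(anyDuplicated(
            MetNetPhylo:::.memberKeys(clusterTable(cl1))) > 0)
    }
})
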