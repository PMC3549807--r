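test_that("networks read back from TSV with annotations intact", {
    dir <- withr::local_tempdir()
    np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
    writeLines(c("node_id\tkind\tgroup_id\tpathway_ids\tcompound_id\textra",
                 "# a comment",
                 "e1\tenzyme\tK00001\tko00010;ko00020\t\tjunk",
                 "e2\tenzyme\tK00002\t\t\tjunk",
                 "",
                 "m1\tmetabolite\t\t\tC00031\tjunk"), np)
    writeLines(c("e1\tm1", "e2\tm1"), ep)
    net <- readNetwork(np, ep, "eco")
    expect_s4_class(net, "MetabolicNetwork")
    expect_identical(organismID(net), "eco")
    n <- nodeTable(net)
    expect_equal(nrow(n), 3L)
    expect_equal(nrow(edgeTable(net)), 2L)
    expect_identical(n$group_id[n$node_id == "e1"], "K00001")
    expect_identical(n$pathway_ids[n$node_id == "e1"], "ko00010;ko00020")
    expect_identical(n$compound_id[n$node_id == "m1"], "C00031")

    # duplicated edge line collapses to one undirected edge
    writeLines(c("e1\te2", "e2\te1"), ep)
    expect_equal(nrow(edgeTable(readNetwork(np, ep, "eco"))), 1L)

    # error contracts
    writeLines("e1\tmissing_node", ep)
    expect_error(readNetwork(np, ep, "eco"), "missing_node")
    expect_error(readNetwork(file.path(dir, "absent.tsv"), ep, "eco"),
                 "not found")
    writeLines(c("node_id\tkind", "e1\tenzyme", "e1\tenzyme"), np)
    writeLines(character(), ep)
    expect_error(readNetwork(np, ep, "eco"), "duplicate")
})

test_that("network write/read round-trips and is canonical", {
    dir <- withr::local_tempdir()
    for (seed in 1:5) {
        net <- randNet("org", nEnz = 6, nMet = 4, nEdges = 12, seed = seed)
        np <- file.path(dir, "n.tsv"); ep <- file.path(dir, "e.tsv")
        writeNetwork(net, np, ep)
        back <- readNetwork(np, ep, "org")
        expect_equal(nodeTable(back), nodeTable(net))
        expect_equal(edgeTable(back), edgeTable(net))
    }
    # same network with permuted node/edge input order -> identical bytes
    nodes <- data.frame(node_id = c("e1", "e2", "m1"),
                        kind = c("enzyme", "enzyme", "metabolite"),
                        compound_id = c(NA, NA, "C1"))
    n1 <- MetabolicNetwork("x", nodes, rbind(c("e1", "m1"), c("m1", "e2")))
    n2 <- MetabolicNetwork("x", nodes[c(3, 1, 2), ],
                           rbind(c("e2", "m1"), c("e1", "m1")))
    f1 <- file.path(dir, "a"); f2 <- file.path(dir, "b")
    writeNetwork(n1, paste0(f1, ".n"), paste0(f1, ".e"))
    writeNetwork(n2, paste0(f2, ".n"), paste0(f2, ".e"))
    expect_identical(readLines(paste0(f1, ".n")), readLines(paste0(f2, ".n")))
    expect_identical(readLines(paste0(f1, ".e")), readLines(paste0(f2, ".e")))
    # empty pathway set survives the round trip as empty
    expect_identical(nodeTable(n1)$pathway_ids[1], "")
})

test_that("score tables apply symmetric closure and reject conflicts", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "scores.tsv")
    writeLines("X\te1\tY\tf1\t0.5", p)
    s <- readScores(p)
    e <- scoreTable(s)
    expect_equal(nrow(e), 1L)            # canonical single entry
    expect_identical(e$orgA, "X")
    expect_equal(e$score, 0.5)
    # the flipped orientation denotes the same entry
    writeLines(c("X\te1\tY\tf1\t0.5", "Y\tf1\tX\te1\t0.5"), p)
    expect_equal(nrow(scoreTable(readScores(p))), 1L)
    # conflicting duplicate
    writeLines(c("X\te1\tY\tf1\t0.5", "Y\tf1\tX\te1\t0.7"), p)
    expect_error(readScores(p), "conflict")
    # negative / non-numeric scores carry a line number
    writeLines(c("X\te1\tY\tf1\t0.5", "X\te2\tY\tf1\t-1"), p)
    expect_error(readScores(p), "line 2")
    writeLines("X\te1\tY\tf1\tabc", p)
    expect_error(readScores(p), "line 1")
    # empty file -> empty table
    writeLines(character(), p)
    expect_equal(nrow(scoreTable(readScores(p))), 0L)
    # round trip
    s <- NodePairScores(data.frame(orgA = "Y", nodeA = "f1", orgB = "X",
                                   nodeB = "e1", score = 1 / 3))
    writeScores(s, p)
    expect_equal(scoreTable(readScores(p)), scoreTable(s))
})

test_that("cluster files round-trip with canonical member order", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "clusters.tsv")
    writeLines("X|e1\tY|f1", p)
    cl <- readClusters(p)
    expect_equal(nClusters(cl), 1L)
    expect_equal(nrow(clusterTable(cl)), 2L)

    cl3 <- EnzymeClusterSet(data.frame(
        cluster_id = c(1, 1, 2, 3, 3, 3),
        organism = c("Y", "X", "X", "Z", "X", "Y"),
        node_id = c("f1", "e1", "e2", "g9", "e3", "f2")))
    writeClusters(cl3, p)
    first <- readLines(p)
    writeClusters(readClusters(p), p)
    expect_identical(readLines(p), first)    # canonical, byte-stable

    writeLines("Xe1\tY|f1", p)
    expect_error(readClusters(p), "line 1")

    # entropy column: numeric final token without '|'
    h <- c(0, log(2), 0.25)
    writeClusters(EnzymeClusterSet(clusterTable(cl3), entropy = h), p,
                  withEntropy = TRUE)
    back <- readClusters(p)
    expect_equal(clusterEntropies(back), h)
    expect_equal(clusterTable(back), clusterTable(cl3))
})
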