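test_that("three-taxon trees carry the closed-form branch lengths", {
    d <- matrix(c(0, 0.3, 0.5,
                  0.3, 0, 0.4,
                  0.5, 0.4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- neighborJoining(d)
    expect_equal(ape::Ntip(tr), 3L)
    ed <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
    expect_equal(ed[["A"]], (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-12)
    expect_equal(ed[["B"]], (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-12)
    expect_equal(ed[["C"]], (0.5 + 0.4 - 0.3) / 2, tolerance = 1e-12)
})

test_that("the additive quartet is recovered with exact branch lengths", {
    taxa <- c("A", "B", "C", "D")
    d <- matrix(c(0, 3, 5, 6,
                  3, 0, 6, 7,
                  5, 6, 0, 7,
                  6, 7, 7, 0), 4, 4, dimnames = list(taxa, taxa))
    # four-point condition: two of the three pair sums are equal and maximal
    sums <- c(d["A","B"] + d["C","D"], d["A","C"] + d["B","D"],
              d["A","D"] + d["B","C"])
    expect_equal(sort(sums)[2], sort(sums)[3])
    expect_equal(which.min(sums), 1L)       # AB|CD is the additive split
    tr <- neighborJoining(d)
    truth <- fromNewick("((A:1,B:2):1,(C:3,D:4));")
    expect_equal(robinsonFoulds(tr, truth), 0L)
    expect_equal(ape::cophenetic.phylo(tr)[taxa, taxa], d,
                 tolerance = 1e-9)
})

test_that("random additive matrices are reconstructed exactly", {
    for (seed in 1:10) {
        set.seed(seed)
        n <- sample(4:10, 1)
        gen <- ape::rtree(n)
        d <- ape::cophenetic.phylo(gen)
        d <- d[order(rownames(d)), order(colnames(d))]
        tr <- neighborJoining(d)
        expect_equal(robinsonFoulds(tr, gen), 0L)
        expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)],
                     d, tolerance = 1e-9)
    }
})

test_that("degenerate taxon counts and invalid matrices are handled", {
    d1 <- matrix(0, 1, 1, dimnames = list("eco", "eco"))
    expect_equal(toNewick(neighborJoining(d1)), "eco;")
    d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    t2 <- neighborJoining(d2)
    expect_equal(sum(t2$edge.length), 0.4)
    bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
    expect_error(neighborJoining(bad), "symmetric")
    bad2 <- matrix(c(1, 0.5, 0.5, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
    expect_error(neighborJoining(bad2), "diagonal")
    # non-additive input may imply negative branch lengths: clamped, noted
    d3 <- matrix(c(0,      0.9633, 0.3236, 0.8236,
                   0.9633, 0,      0.5189, 0.2330,
                   0.3236, 0.5189, 0,      0.4322,
                   0.8236, 0.2330, 0.4322, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
    expect_message(t3 <- neighborJoining(d3), "clamping")
    expect_true(all(t3$edge.length >= 0))
})

test_that("Newick serialization round-trips trees", {
    expect_equal(fromNewick("((A,B),(C,D));")$tip.label[1], "A")
    expect_equal(ape::Ntip(fromNewick("((A,B),(C,D));")), 4L)
    expect_error(fromNewick("((A,B),(C,D);"), "parentheses")
    set.seed(5)
    tr <- ape::rtree(8)
    txt <- toNewick(tr)
    expect_match(txt, ";$")
    back <- fromNewick(txt)
    expect_equal(robinsonFoulds(tr, back), 0L)
    expect_equal(sort(back$edge.length), sort(round(tr$edge.length, 6)),
                 tolerance = 1e-9)
    # file round trip
    f <- withr::local_tempfile()
    toNewick(tr, f)
    expect_equal(robinsonFoulds(fromNewick(path = f), tr), 0L)
})

test_that("Robinson-Foulds counts single-tree bipartitions", {
    t1 <- fromNewick("((A,B),(C,D));")
    t2 <- fromNewick("((A,C),(B,D));")
    expect_equal(robinsonFoulds(t1, t1), 0L)
    expect_equal(robinsonFoulds(t1, t2), 2L)
    expect_error(robinsonFoulds(t1, fromNewick("((A,B),(C,E));")), "E")
    set.seed(9)
    for (rep in 1:5) {
        n <- sample(4:9, 1)
        a <- ape::rtree(n); b <- ape::rtree(n)
        b$tip.label <- a$tip.label
        expect_lte(robinsonFoulds(a, b), 2 * (n - 3))
    }
})

test_that("UPGMA returns a rooted ultrametric alternative", {
    set.seed(2)
    cl <- randClusters(nOrg = 4, nClusters = 20, maxSize = 5, seed = 2)
    d <- suppressWarnings(
        organismDistanceMatrix(cl, sprintf("org%02d", 1:4)))
    tr <- upgmaTree(d)
    expect_true(ape::is.rooted(tr))
    expect_true(ape::is.ultrametric(tr))
})
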