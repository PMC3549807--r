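test_that("alpha = 0 returns the normalized prior, independent of topology", {
    a <- randNet("A", 4, 2, 8, seed = 1)
    b <- randNet("B", 4, 2, 8, seed = 2)
    prior <- NodePairScores(data.frame(
        orgA = "A", nodeA = c("e1", "e2", "e3"),
        orgB = "B", nodeB = c("e1", "e3", "e2"),
        score = c(2, 1, 1)))
    r <- pairwiseScores(a, b, prior, alpha = 0)
    m <- scoresAsMatrix(r, a, b)
    # prior mass: enzyme entries 2 + 1 + 1 plus the two compound-identity
    # metabolite pairs (m1, m1) and (m2, m2) at 1 each -> total 6
    expect_equal(m["e1", "e1"], 2 / 6)
    expect_equal(m["e2", "e3"], 1 / 6)
    expect_equal(m["m1", "m1"], 1 / 6)
    expect_equal(m["m1", "m2"], 0)
    expect_equal(sum(m), 1, tolerance = 1e-9)
    # permuting edges leaves the alpha = 0 result unchanged
    b2 <- randNet("B", 4, 2, 8, seed = 99)
    r2 <- pairwiseScores(a, b2, prior, alpha = 0)
    expect_equal(scoreTable(r2), scoreTable(r))
})

test_that("symmetric single-edge networks give the uniform fixed point", {
    a <- mkNet("A", c("a1", "a2"), edges = rbind(c("a1", "a2")))
    b <- mkNet("B", c("b1", "b2"), edges = rbind(c("b1", "b2")))
    r <- suppressMessages(
        pairwiseScores(a, b, NodePairScores(), alpha = 1))
    m <- scoresAsMatrix(r, a, b)
    expect_equal(as.vector(m), rep(0.25, 4), tolerance = 1e-9)
})

test_that("power iteration matches the dense linear-system solve", {
    for (seed in 1:4) {
        a <- randNet("A", 3, 2, 6, seed = seed)
        b <- randNet("B", 3, 2, 6, seed = seed + 50)
        set.seed(seed + 100)
        pr <- expand.grid(nodeA = paste0("e", 1:3),
                          nodeB = paste0("e", 1:3))
        prior <- NodePairScores(data.frame(
            orgA = "A", nodeA = pr$nodeA, orgB = "B", nodeB = pr$nodeB,
            score = runif(nrow(pr))))
        for (alpha in c(0.3, 0.6)) {
            got <- scoresAsMatrix(
                pairwiseScores(a, b, prior, alpha = alpha, tol = 1e-14),
                a, b)
            want <- denseSolveScores(a, b, prior, alpha)
            expect_lt(sum(abs(got - want)), 1e-8)
        }
    }
})

test_that("converged scores are a unit-mass non-negative distribution", {
    a <- randNet("A", 5, 3, 14, seed = 3)
    b <- randNet("B", 6, 3, 16, seed = 4)
    prior <- NodePairScores(data.frame(orgA = "A", nodeA = "e1",
                                       orgB = "B", nodeB = "e2",
                                       score = 1))
    for (alpha in c(0.2, 0.9)) {
        e <- scoreTable(pairwiseScores(a, b, prior, alpha = alpha))
        expect_true(all(e$score >= 0))
        expect_equal(sum(e$score), 1, tolerance = 1e-9)
    }
    expect_error(pairwiseScores(a, a, prior), "distinct")
    bad <- NodePairScores(data.frame(orgA = "A", nodeA = "nope",
                                     orgB = "B", nodeB = "e1", score = 1))
    expect_error(pairwiseScores(a, b, bad), "unknown node")
})

test_that("enzyme-metabolite pairs never receive similarity mass", {
    a <- randNet("A", 3, 3, 9, seed = 11)
    b <- randNet("B", 3, 3, 9, seed = 12)
    r <- suppressMessages(pairwiseScores(a, b, NodePairScores(),
                                         alpha = 0.7))
    e <- scoreTable(r)
    kindA <- ifelse(grepl("^e", e$nodeA), "enzyme", "metabolite")
    kindB <- ifelse(grepl("^e", e$nodeB), "enzyme", "metabolite")
    expect_true(all(kindA == kindB))
})

test_that("greedy one-to-one extraction follows score order and tie rules", {
    s <- NodePairScores(data.frame(
        orgA = "X", nodeA = c("a", "a", "b"),
        orgB = "Y", nodeB = c("x", "y", "y"),
        score = c(0.9, 0.8, 0.7)))
    m <- greedyOneToOne(s)
    expect_identical(m$nodeA, c("a", "b"))
    expect_identical(m$nodeB, c("x", "y"))
    # exact tie -> lexicographically smaller nodeB
    s2 <- NodePairScores(data.frame(orgA = "X", nodeA = c("a", "a"),
                                    orgB = "Y", nodeB = c("y", "x"),
                                    score = 0.5))
    expect_identical(greedyOneToOne(s2)$nodeB, "x")
})

test_that("greedy mapping recovers a planted isomorphism between paths", {
    a <- mkNet("A", paste0("a", 1:4),
               edges = cbind(paste0("a", 1:3), paste0("a", 2:4)))
    b <- mkNet("B", paste0("b", 1:4),
               edges = cbind(paste0("b", 1:3), paste0("b", 2:4)))
    pr <- expand.grid(i = 1:4, j = 1:4)
    prior <- NodePairScores(data.frame(
        orgA = "A", nodeA = paste0("a", pr$i),
        orgB = "B", nodeB = paste0("b", pr$j),
        score = ifelse(pr$i == pr$j, 0.9, 0.05)))
    r <- pairwiseScores(a, b, prior, alpha = 0.6)
    got <- greedyOneToOne(r)
    expect_identical(got$nodeB, sub("a", "b", got$nodeA))
    # brute force over all 4! bijections maximizing total score agrees
    m <- scoresAsMatrix(r, a, b)
    perms <- rbind(1:4)
    perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
    tot <- apply(perms, 1, function(p)
        sum(m[cbind(1:4, p)]))
    best <- perms[which.max(tot), ]
    expect_equal(best, 1:4, ignore_attr = TRUE)
})
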