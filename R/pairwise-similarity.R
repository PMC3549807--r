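# Cross-species node similarity by topology/prior blending.
#
# The converged score matrix R over node pairs (i in A, j in B) satisfies
#   R[i,j] = alpha * sum_{u in N(i)} sum_{v in N(j)} R[u,v] / (|N(u)| |N(v)|)
#          + (1 - alpha) * E[i,j]
# where E is the prior normalized to unit mass over admissible pairs.
# Similarity is defined over enzyme-enzyme and metabolite-metabolite pairs
# only; enzyme-metabolite pairs are held at zero but metabolite pairs
# conduct topological signal between enzyme pairs.

# column-normalized adjacency: W[i,u] = 1/deg(u) if u ~ i else 0.
.normAdjacency <- function(net) {
    ids <- nodeTable(net)$node_id
    n <- length(ids)
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    e <- edgeTable(net)
    if (nrow(e)) {
        A[cbind(match(e[, 1L], ids), match(e[, 2L], ids))] <- 1
        A[cbind(match(e[, 2L], ids), match(e[, 1L], ids))] <- 1
    }
    deg <- colSums(A)
    W <- A
    nz <- deg > 0
    W[, nz] <- sweep(A[, nz, drop = FALSE], 2L, deg[nz], "/")
    W
}

# prior matrix E over nodes of A x nodes of B, plus admissibility mask
.buildPrior <- function(netA, netB, prior) {
    na <- nodeTable(netA); nb <- nodeTable(netB)
    enzA <- na$kind == "enzyme"; enzB <- nb$kind == "enzyme"
    mask <- outer(enzA, enzB, "==")   # enzyme-enzyme or metabolite-metabolite
    E <- matrix(0, nrow(na), nrow(nb),
                dimnames = list(na$node_id, nb$node_id))
    # metabolite prior: compound identity
    metA <- which(!enzA & !is.na(na$compound_id))
    metB <- which(!enzB & !is.na(nb$compound_id))
    if (length(metA) && length(metB)) {
        hit <- outer(na$compound_id[metA], nb$compound_id[metB], "==")
        E[metA, metB][hit] <- 1
    }
    # enzyme prior from the score table (symmetric closure already applied)
    e <- scoreTable(prior)
    oa <- organismID(netA); ob <- organismID(netB)
    sel <- (e$orgA == min(oa, ob)) & (e$orgB == max(oa, ob))
    e <- e[sel, , drop = FALSE]
    if (nrow(e)) {
        if (oa <= ob) {
            ia <- match(e$nodeA, na$node_id); ib <- match(e$nodeB, nb$node_id)
        } else {
            ia <- match(e$nodeB, na$node_id); ib <- match(e$nodeA, nb$node_id)
        }
        if (anyNA(ia) || anyNA(ib)) {
            bad <- c(e$nodeA[is.na(ia)], e$nodeB[is.na(ib)])[1L]
            stop("prior references unknown node: ", bad)
        }
        if (any(!mask[cbind(ia, ib)]))
            stop("prior entries must link nodes of the same kind")
        E[cbind(ia, ib)] <- e$score
    } else {
        # no sequence prior for this organism pair: uniform over enzyme pairs
        if (any(enzA) && any(enzB)) {
            message("no prior entries for pair (", oa, ", ", ob,
                    "); using uniform enzyme prior")
            E[enzA, enzB] <- 1
        }
    }
    E[!mask] <- 0
    list(E = E, mask = mask)
}

#' Converged cross-species node similarity scores
#'
#' Runs the power iteration for the functional-similarity recursion that
#' blends a cross-species prior (weight \code{1 - alpha}) with neighborhood
#' topology (weight \code{alpha}): at the fixed point a node pair scores
#' highly when its prior score is high and its neighbors pair up with
#' high-scoring pairs. Similarity is computed over enzyme-enzyme and
#' metabolite-metabolite pairs; enzyme-metabolite pairs are fixed at zero.
#' The metabolite prior is the compound-identity indicator; the enzyme
#' prior comes from \code{prior} (uniform, with a message, when the table
#' has no entries for this organism pair). The returned table is
#' normalized to total mass 1 and sparsified by dropping entries below
#' 1e-12 of the total.
#'
#' @param netA,netB \linkS4class{MetabolicNetwork}s of distinct organisms.
#' @param prior a \linkS4class{NodePairScores} prior (may be empty).
#' @param alpha topology weight in [0,1]; 0 reduces to the normalized
#'   prior, 1 uses topology only.
#' @param tol L1 convergence tolerance of the iteration.
#' @param maxIter iteration cap.
#' @param sparsify drop pairs below 1e-12 of total mass from the result?
#' @return a \linkS4class{NodePairScores} with the converged scores.
#' @examples
#' a <- MetabolicNetwork("X",
#'     data.frame(node_id = c("a1", "a2"), kind = "enzyme"),
#'     rbind(c("a1", "a2")))
#' b <- MetabolicNetwork("Y",
#'     data.frame(node_id = c("b1", "b2"), kind = "enzyme"),
#'     rbind(c("b1", "b2")))
#' pairwiseScores(a, b, NodePairScores(), alpha = 1)
#' @export
pairwiseScores <- function(netA, netB, prior = NodePairScores(),
                           alpha = 0.6, tol = 1e-10, maxIter = 1000L,
                           sparsify = TRUE) {
    stopifnot(alpha >= 0, alpha <= 1, tol > 0, maxIter >= 1)
    if (organismID(netA) == organismID(netB))
        stop("networks must belong to distinct organisms")
    pr <- .buildPrior(netA, netB, prior)
    E <- pr$E
    if (sum(E) == 0) {
        warning("all-zero prior; falling back to uniform over admissible pairs")
        E[pr$mask] <- 1
    }
    E <- E / sum(E)
    WA <- .normAdjacency(netA)
    WB <- .normAdjacency(netB)
    R <- E
    for (it in seq_len(maxIter)) {
        Rnew <- WA %*% R %*% t(WB)
        Rnew[!pr$mask] <- 0
        Rnew <- alpha * Rnew + (1 - alpha) * E
        delta <- sum(abs(Rnew - R))
        R <- Rnew
        if (delta <= tol) break
    }
    tot <- sum(R)
    if (tot <= 0) stop("similarity iteration produced zero mass")
    R <- R / tot
    idx <- which(R > if (sparsify) 1e-12 else 0, arr.ind = TRUE)
    oa <- organismID(netA); ob <- organismID(netB)
    NodePairScores(data.frame(
        orgA = oa, nodeA = rownames(R)[idx[, 1L]],
        orgB = ob, nodeB = colnames(R)[idx[, 2L]],
        score = R[idx]))
}

#' Greedy one-to-one node mapping from a score table
#'
#' Diagnostic utility projecting a converged score table onto a one-to-one
#' global alignment: repeatedly extract the highest-scoring pair whose two
#' nodes are both still unassigned, ties broken lexicographically by
#' (nodeA, nodeB).
#'
#' @param scores a non-empty \linkS4class{NodePairScores} between exactly
#'   two organisms.
#' @return data.frame with columns \code{nodeA}, \code{nodeB},
#'   \code{score}, one row per matched pair.
#' @export
greedyOneToOne <- function(scores) {
    e <- scoreTable(scores)
    if (!nrow(e)) stop("score table is empty")
    if (length(unique(e$orgA)) > 1L || length(unique(e$orgB)) > 1L)
        stop("greedyOneToOne expects scores for a single organism pair")
    e <- e[order(-e$score, e$nodeA, e$nodeB), ]
    usedA <- character(); usedB <- character()
    keep <- logical(nrow(e))
    for (k in seq_len(nrow(e))) {
        if (!(e$nodeA[k] %in% usedA) && !(e$nodeB[k] %in% usedB)) {
            keep[k] <- TRUE
            usedA <- c(usedA, e$nodeA[k])
            usedB <- c(usedB, e$nodeB[k])
        }
    }
    out <- e[keep, c("nodeA", "nodeB", "score")]
    rownames(out) <- NULL
    out
}
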