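# Tree reconstruction from the organism distance matrix. Trees are ape
# "phylo" objects throughout; neighbor joining is the default (PHYLIP's
# neighbor is the conventional companion of a distance matrix of this
# kind), with UPGMA available since published displays of such trees are
# often rooted.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining on a validated symmetric
#' zero-diagonal matrix. Consistent on additive matrices: the generating
#' topology and branch lengths are recovered exactly. Negative branch
#' lengths (possible on non-additive input) are clamped to 0 with a
#' message. n = 2 yields the single-edge tree splitting the distance
#' evenly; n = 1 a single-leaf tree.
#'
#' @param d symmetric distance matrix with organism dimnames.
#' @return an unrooted \code{phylo} tree.
#' @export
# minimal valid phylo for one taxon (root with a single zero-length edge)
.singleLeafTree <- function(name)
    structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = name,
                   edge.length = 0, Nnode = 1L), class = "phylo")

neighborJoining <- function(d) {
    .checkDistanceMatrix(d)
    n <- nrow(d)
    if (n == 1L)
        return(.singleLeafTree(rownames(d)[1L]))
    if (n == 2L)
        return(ape::read.tree(text = sprintf(
            "(%s:%.10g,%s:%.10g);", rownames(d)[1L], d[1, 2] / 2,
            rownames(d)[2L], d[1, 2] / 2)))
    tr <- ape::nj(stats::as.dist(d))
    if (any(tr$edge.length < 0)) {
        message("clamping ", sum(tr$edge.length < 0),
                " negative branch length(s) to 0")
        tr$edge.length[tr$edge.length < 0] <- 0
    }
    ape::unroot(tr)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering, returned as a rooted
#' ultrametric \code{phylo} tree.
#'
#' @param d symmetric distance matrix with organism dimnames.
#' @return a rooted \code{phylo} tree.
#' @export
upgmaTree <- function(d) {
    .checkDistanceMatrix(d)
    if (nrow(d) < 2L) stop("UPGMA needs at least two taxa")
    ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
}

#' Serialize a tree to Newick
#'
#' Branch lengths written at 6 decimal places; the string ends with ';'.
#'
#' @param tree a \code{phylo} tree.
#' @param path optional output file; when NULL the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
toNewick <- function(tree, path = NULL) {
    txt <- if (length(tree$tip.label) == 1L)
        paste0(tree$tip.label, ";")
    else ape::write.tree(tree, digits = 6)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Parse a Newick tree
#'
#' @param text Newick string, or NULL to read from \code{path}.
#' @param path optional file to read.
#' @return a \code{phylo} tree.
#' @export
fromNewick <- function(text = NULL, path = NULL) {
    if (is.null(text)) {
        if (is.null(path)) stop("provide text or path")
        text <- paste(readLines(path), collapse = "")
    }
    open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
    close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
    if (open != close)
        stop("unbalanced parentheses in Newick string (", open,
             " open, ", close, " close)")
    bare <- sub(";\\s*$", "", trimws(text))
    if (!grepl("[(),:]", bare) && nzchar(bare))
        return(.singleLeafTree(bare))
    tr <- ape::read.tree(text = text)
    if (is.null(tr)) stop("failed to parse Newick string")
    tr
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two (unrooted)
#' trees; 0 means identical topology. The trees must carry identical leaf
#' sets.
#'
#' @param t1,t2 \code{phylo} trees over the same leaves.
#' @return non-negative integer.
#' @export
robinsonFoulds <- function(t1, t2) {
    l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
    if (!identical(l1, l2))
        stop("leaf sets differ; only in tree 1: ",
             paste(setdiff(l1, l2), collapse = ", "),
             "; only in tree 2: ",
             paste(setdiff(l2, l1), collapse = ", "))
    if (length(l1) <= 3L) return(0L)
    as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
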