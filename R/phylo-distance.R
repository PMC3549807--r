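# Organism distances from cluster co-membership. For organisms A and B,
# |S_AnB| is the number of clusters containing enzymes of both organisms
# and |S_AuB| the number containing enzymes of either; the Jaccard ratio
# |S_AnB| / |S_AuB| is 1 for identical membership, so the distance is
# d = 1 - |S_AnB| / |S_AuB| (the raw ratio is available for exact-text
# replication of the printed formula).

#' Cluster co-membership distance between two organisms
#'
#' @param clusters the entropy-filtered \linkS4class{EnzymeClusterSet}.
#' @param orgA,orgB organism identifiers.
#' @param form \code{"one-minus-jaccard"} (default; 0 = identical cluster
#'   membership) or \code{"raw-ratio"} (the plain ratio
#'   \eqn{|S_{A\cap B}|/|S_{A\cup B}|}).
#' @return a value in [0,1]. If neither organism appears in any cluster
#'   the ratio is undefined; the distance is reported as 1 (ratio 0) with
#'   a warning.
#' @export
organismDistance <- function(clusters, orgA, orgB,
                             form = c("one-minus-jaccard", "raw-ratio")) {
    form <- match.arg(form)
    orgSets <- .clusterOrgList(clusters)
    hasA <- vapply(orgSets, function(o) orgA %in% o, logical(1))
    hasB <- vapply(orgSets, function(o) orgB %in% o, logical(1))
    nUnion <- sum(hasA | hasB)
    if (nUnion == 0L) {
        warning("organisms ", orgA, " and ", orgB,
                " appear in no cluster; distance undefined, reporting 1")
        ratio <- 0
    } else {
        ratio <- sum(hasA & hasB) / nUnion
    }
    if (form == "raw-ratio") ratio else 1 - ratio
}

#' Pairwise organism distance matrix
#'
#' Applies [organismDistance()] to every organism pair.
#'
#' @param clusters the filtered \linkS4class{EnzymeClusterSet}.
#' @param organismIDs ordered, unique organism identifiers (rows/columns
#'   of the result).
#' @param form passed to [organismDistance()].
#' @return symmetric numeric matrix with zero diagonal and dimnames
#'   \code{organismIDs}.
#' @export
organismDistanceMatrix <- function(clusters, organismIDs,
                                   form = c("one-minus-jaccard",
                                            "raw-ratio")) {
    form <- match.arg(form)
    if (anyDuplicated(organismIDs))
        stop("duplicate organism ids: ",
             organismIDs[duplicated(organismIDs)][1L])
    n <- length(organismIDs)
    if (!n) stop("organismIDs must be non-empty")
    d <- matrix(0, n, n, dimnames = list(organismIDs, organismIDs))
    if (n > 1L) {
        orgSets <- .clusterOrgList(clusters)
        has <- vapply(organismIDs, function(org)
            vapply(orgSets, function(o) org %in% o, logical(1)),
            logical(length(orgSets)))
        has <- matrix(has, ncol = n)   # clusters x organisms
        for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
            nUnion <- sum(has[, a] | has[, b])
            ratio <- if (nUnion == 0L) {
                warning("organisms ", organismIDs[a], " and ",
                        organismIDs[b], " appear in no cluster")
                0
            } else sum(has[, a] & has[, b]) / nUnion
            d[a, b] <- d[b, a] <- if (form == "raw-ratio") ratio
                                  else 1 - ratio
        }
        if (form == "raw-ratio") diag(d) <- 1
    } else if (form == "raw-ratio") diag(d) <- 1
    d
}

# invariant checks shared by PHYLIP output and tree building
.checkDistanceMatrix <- function(d) {
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("distance matrix must be square")
    if (is.null(rownames(d)))
        stop("distance matrix must carry organism names as dimnames")
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                          check.attributes = FALSE)))
        stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12))
        stop("distance matrix must have a zero diagonal")
    if (any(!is.finite(d)))
        stop("distance matrix entries must be finite")
    invisible(d)
}

# 10-character PHYLIP names, numeric-suffix mangling for collisions
.phylipNames <- function(names) {
    out <- formatC(substr(names, 1L, 10L), width = -10L)
    dup <- duplicated(out) | duplicated(out, fromLast = TRUE)
    if (any(dup)) {
        used <- out[!dup]
        for (grp in unique(out[dup])) {
            idx <- which(out == grp)
            suffix <- 0L
            for (i in idx) {
                repeat {
                    suffix <- suffix + 1L
                    stem <- substr(trimws(grp, "right"), 1L,
                                   10L - nchar(as.character(suffix)))
                    cand <- formatC(paste0(stem, suffix), width = -10L)
                    if (!(cand %in% used)) break
                }
                out[i] <- cand
                used <- c(used, cand)
            }
        }
    }
    out
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each following row is a name padded or
#' truncated to 10 characters followed by the distances at 6 decimal
#' places. Names that collide after truncation are disambiguated with a
#' numeric suffix; the mangled-to-original mapping is written to the
#' sidecar file \code{<path>.names} (TSV).
#'
#' @param d symmetric distance matrix with organism dimnames.
#' @param path output path.
#' @return invisibly, the character vector of mangled names used.
#' @export
writePhylip <- function(d, path) {
    .checkDistanceMatrix(d)
    nm <- .phylipNames(rownames(d))
    rows <- vapply(seq_len(nrow(d)), function(i)
        paste0(nm[i], paste(sprintf("%.6f", d[i, ]), collapse = " ")),
        character(1))
    writeLines(c(as.character(nrow(d)), rows), path)
    writeLines(paste(trimws(nm, "right"), rownames(d), sep = "\t"),
               paste0(path, ".names"))
    invisible(nm)
}

#' Read a PHYLIP square distance matrix
#'
#' Counterpart of [writePhylip()]; restores original organism names from
#' the \code{<path>.names} sidecar when present.
#'
#' @param path path to the PHYLIP file.
#' @return symmetric numeric matrix with dimnames.
#' @export
readPhylip <- function(path) {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1L]))
    if (is.na(n) || length(lines) < n + 1L)
        stop("malformed PHYLIP file: ", path)
    nm <- character(n)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
        ln <- lines[i + 1L]
        nm[i] <- trimws(substr(ln, 1L, 10L), "right")
        vals <- as.numeric(strsplit(trimws(substr(ln, 11L, nchar(ln))),
                                    "\\s+")[[1L]])
        if (length(vals) != n)
            stop("row ", i, " of ", path, " has ", length(vals),
                 " values, expected ", n)
        d[i, ] <- vals
    }
    sidecar <- paste0(path, ".names")
    if (file.exists(sidecar)) {
        map <- utils::read.table(sidecar, sep = "\t", header = FALSE,
                                 colClasses = "character")
        nm <- map$V2[match(nm, map$V1)]
    }
    dimnames(d) <- list(nm, nm)
    d
}

#' Write a full-precision distance matrix TSV
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output path.
#' @return invisibly, \code{d}.
#' @export
writeDistTsv <- function(d, path) {
    .checkDistanceMatrix(d)
    header <- paste(c("organism", colnames(d)), collapse = "\t")
    rows <- vapply(seq_len(nrow(d)), function(i)
        paste(c(rownames(d)[i],
                formatC(d[i, ], format = "g", digits = 17)),
              collapse = "\t"), character(1))
    writeLines(c(header, rows), path)
    invisible(d)
}
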