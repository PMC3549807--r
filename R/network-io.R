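.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    lines[keep]
}

.splitFields <- function(lines)
    strsplit(lines, "\t", fixed = TRUE)

#' Read a metabolic network from node and edge tables
#'
#' Nodes are read from a tab-separated file with a header naming at least
#' \code{node_id} and \code{kind}; the optional annotation columns
#' \code{group_id}, \code{pathway_ids} (semicolon-joined) and
#' \code{compound_id} are picked up when present and unknown columns are
#' ignored. Edges are read from a headerless two-column tab-separated file
#' of node_id pairs. Blank lines and lines starting with '#' are skipped
#' in both files.
#'
#' @param nodesPath path to the nodes TSV.
#' @param edgesPath path to the edges TSV.
#' @param organism organism identifier to attach to the network.
#' @return a validated \linkS4class{MetabolicNetwork}.
#' @seealso [writeNetwork()]
#' @export
readNetwork <- function(nodesPath, edgesPath, organism) {
    lines <- .readTsv(nodesPath)
    if (!length(lines)) stop("empty nodes file: ", nodesPath)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!all(c("node_id", "kind") %in% header))
        stop("nodes file must have header columns node_id and kind: ",
             nodesPath)
    rows <- .splitFields(lines[-1L])
    get <- function(col) {
        idx <- match(col, header)
        if (is.na(idx)) return(rep(NA_character_, length(rows)))
        vapply(rows, function(r) if (length(r) >= idx) r[idx]
                                 else NA_character_, character(1))
    }
    nodes <- data.frame(node_id = get("node_id"), kind = get("kind"),
                        group_id = get("group_id"),
                        pathway_ids = get("pathway_ids"),
                        compound_id = get("compound_id"))
    nodes$pathway_ids[is.na(nodes$pathway_ids)] <- ""
    if (anyDuplicated(nodes$node_id))
        stop("duplicate node_id in ", nodesPath, ": ",
             nodes$node_id[duplicated(nodes$node_id)][1L])

    elines <- .readTsv(edgesPath)
    edges <- if (length(elines)) {
        parts <- .splitFields(elines)
        if (any(lengths(parts) < 2L))
            stop("edges file rows must have two tab-separated node ids: ",
                 edgesPath)
        cbind(vapply(parts, `[`, character(1), 1L),
              vapply(parts, `[`, character(1), 2L))
    } else matrix(character(), ncol = 2L)
    unknown <- setdiff(c(edges), nodes$node_id)
    if (length(unknown))
        stop("edge references unknown node: ",
             paste(unknown, collapse = ", "))
    if (!any(nodes$kind == "enzyme"))
        stop("network must contain at least one enzyme node: ", nodesPath)
    MetabolicNetwork(organism, nodes, edges)
}

#' Write a metabolic network to node and edge tables
#'
#' Serialization is canonical: nodes sorted by \code{node_id}, edges with
#' sorted endpoints in sorted order, so the same in-memory network always
#' yields byte-identical files. \code{readNetwork()} on the output
#' reproduces the network exactly.
#'
#' @param net a \linkS4class{MetabolicNetwork}.
#' @param nodesPath,edgesPath output paths.
#' @return invisibly, \code{net}.
#' @export
writeNetwork <- function(net, nodesPath, edgesPath) {
    n <- nodeTable(net)
    out <- c(paste(c("node_id", "kind", "group_id", "pathway_ids",
                     "compound_id"), collapse = "\t"),
             paste(n$node_id, n$kind,
                   ifelse(is.na(n$group_id), "", n$group_id),
                   n$pathway_ids,
                   ifelse(is.na(n$compound_id), "", n$compound_id),
                   sep = "\t"))
    writeLines(out, nodesPath)
    e <- edgeTable(net)
    writeLines(if (nrow(e)) paste(e[, 1L], e[, 2L], sep = "\t")
               else character(), edgesPath)
    invisible(net)
}

#' Read a cross-species node score table
#'
#' Expects five tab-separated columns per line: orgA, nodeA, orgB, nodeB,
#' score (no header; '#' comments and blank lines skipped). The symmetric
#' closure is applied on read — an entry in either orientation denotes the
#' same unordered pair — and listing a pair twice with different scores is
#' an error.
#'
#' @param path path to the scores TSV.
#' @return a \linkS4class{NodePairScores}; empty file yields an empty table
#'   (downstream code then falls back to a uniform prior).
#' @export
readScores <- function(path) {
    lines <- .readTsv(path)
    if (!length(lines)) return(NodePairScores())
    parts <- .splitFields(lines)
    if (any(lengths(parts) < 5L))
        stop("malformed score line (need 5 columns) at line ",
             which(lengths(parts) < 5L)[1L], " of ", path)
    sc <- suppressWarnings(
        as.numeric(vapply(parts, `[`, character(1), 5L)))
    bad <- which(is.na(sc) | sc < 0)
    if (length(bad))
        stop("negative or non-numeric score at line ", bad[1L],
             " of ", path)
    NodePairScores(data.frame(
        orgA = vapply(parts, `[`, character(1), 1L),
        nodeA = vapply(parts, `[`, character(1), 2L),
        orgB = vapply(parts, `[`, character(1), 3L),
        nodeB = vapply(parts, `[`, character(1), 4L),
        score = sc))
}

#' Write a cross-species node score table
#'
#' One canonical-orientation entry per line; full precision. Reading the
#' file back reproduces the object.
#'
#' @param scores a \linkS4class{NodePairScores}.
#' @param path output path.
#' @return invisibly, \code{scores}.
#' @export
writeScores <- function(scores, path) {
    e <- scoreTable(scores)
    writeLines(paste(e$orgA, e$nodeA, e$orgB, e$nodeB,
                     formatC(e$score, format = "g", digits = 17),
                     sep = "\t"), path)
    invisible(scores)
}

#' Read enzyme clusters
#'
#' One cluster per line; members are \code{organism|node_id} tokens
#' separated by tabs. A final token that contains no '|' but parses as a
#' number is taken as the cluster's entropy (the annotated dialect written
#' by [filterClusters()] output paths); any other token without '|' is a
#' format error.
#'
#' @param path path to the clusters file.
#' @return an \linkS4class{EnzymeClusterSet} (entropies attached when the
#'   file carries the entropy column).
#' @export
readClusters <- function(path) {
    lines <- .readTsv(path)
    if (!length(lines))
        return(EnzymeClusterSet(data.frame(cluster_id = integer(),
                                           organism = character(),
                                           node_id = character()),
                                entropy = numeric()))
    parts <- .splitFields(lines)
    members <- vector("list", length(parts))
    entropy <- rep(NA_real_, length(parts))
    for (k in seq_along(parts)) {
        toks <- parts[[k]]
        last <- toks[length(toks)]
        if (!grepl("|", last, fixed = TRUE)) {
            val <- suppressWarnings(as.numeric(last))
            if (is.na(val) && !(last %in% c("NA", "NaN")))
                stop("malformed member token '", last, "' at line ", k,
                     " of ", path)
            entropy[k] <- val
            toks <- toks[-length(toks)]
        }
        if (!length(toks))
            stop("cluster with no members at line ", k, " of ", path)
        bad <- which(!grepl("|", toks, fixed = TRUE))
        if (length(bad))
            stop("malformed member token '", toks[bad[1L]], "' at line ",
                 k, " of ", path)
        org <- sub("\\|.*$", "", toks)
        node <- sub("^[^|]*\\|", "", toks)
        members[[k]] <- data.frame(cluster_id = k, organism = org,
                                   node_id = node)
    }
    EnzymeClusterSet(do.call(rbind, members), entropy = entropy)
}

#' Write enzyme clusters
#'
#' One cluster per line, members canonicalized (sorted) within the line and
#' lines in cluster order. With \code{withEntropy = TRUE} each line gains a
#' final tab-separated numeric entropy token (see [readClusters()]).
#'
#' @param clusters an \linkS4class{EnzymeClusterSet}.
#' @param path output path.
#' @param withEntropy append the per-cluster entropy column?
#' @return invisibly, \code{clusters}.
#' @export
writeClusters <- function(clusters, path, withEntropy = FALSE) {
    keyList <- .clusterKeyList(clusters)
    lines <- vapply(keyList, function(k) paste(sort(k), collapse = "\t"),
                    character(1))
    if (withEntropy) {
        h <- clusterEntropies(clusters)
        lines <- paste(lines, formatC(h, format = "g", digits = 17),
                       sep = "\t")
    }
    writeLines(unname(lines), path)
    invisible(clusters)
}
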