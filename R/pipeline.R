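# End-to-end orchestration: align -> cluster -> filter -> dist -> tree.
# Every intermediate is written to the output directory along with a
# manifest recording parameters and versions; stages with existing output
# can be skipped with resume = TRUE.

.stageMsg <- function(stage, skipped = FALSE, t0 = NULL) {
    if (skipped) message("[", stage, "] skipped (output exists)")
    else message("[", stage, "] done in ",
                 sprintf("%.2f", as.numeric(Sys.time()) - t0), " s")
}

#' Run the full phyletic-tree reconstruction pipeline
#'
#' Stages, in order: (1) \emph{align} — converged pairwise similarity
#' scores for every organism pair (\code{scores.tsv}); (2) \emph{cluster}
#' — alignment graph plus star clustering (\code{clusters.tsv}); (3)
#' \emph{filter} — entropy filter (\code{clusters_filtered.tsv}, with the
#' entropy column); (4) \emph{dist} — organism distance matrix
#' (\code{dist.tsv}, \code{dist.phylip} + names sidecar); (5) \emph{tree}
#' — Newick tree (\code{tree.nwk}). A \code{manifest.json} records
#' parameters and versions. The run is fully deterministic for fixed
#' inputs and parameters.
#'
#' @param networks named list of \linkS4class{MetabolicNetwork}s, or NULL
#'   to read a fixture directory.
#' @param prior a \linkS4class{NodePairScores} prior (may be NULL/empty).
#' @param inputDir fixture directory (see [readFixture()]) used when
#'   \code{networks} is NULL.
#' @param outDir output directory, created if needed.
#' @param alpha,tol,maxIter similarity-iteration parameters
#'   (see [pairwiseScores()]).
#' @param damping,keepRatio star-clustering parameters
#'   (see [spectralStarClusters()]).
#' @param minWeight alignment-graph edge floor (NULL = 1e-4 x max score).
#' @param entropyThreshold,logBase filter parameters
#'   (see [filterClusters()]).
#' @param distanceForm passed to [organismDistanceMatrix()].
#' @param treeMethod \code{"nj"} (default) or \code{"upgma"}.
#' @param resume skip stages whose outputs already exist?
#' @return invisibly, a list with the in-memory results: \code{scores},
#'   \code{clusters}, \code{filtered}, \code{dist}, \code{tree}, and the
#'   output \code{dir}.
#' @export
runPipeline <- function(networks = NULL, prior = NULL, inputDir = NULL,
                        outDir, alpha = 0.6, tol = 1e-10, maxIter = 1000L,
                        damping = 0.85, keepRatio = 0.3, minWeight = NULL,
                        entropyThreshold = 0.5,
                        logBase = c("natural", "base2"),
                        distanceForm = c("one-minus-jaccard", "raw-ratio"),
                        treeMethod = c("nj", "upgma"), resume = FALSE) {
    logBase <- match.arg(logBase)
    distanceForm <- match.arg(distanceForm)
    treeMethod <- match.arg(treeMethod)
    if (is.null(networks)) {
        if (is.null(inputDir)) stop("provide networks or inputDir")
        fx <- readFixture(inputDir)
        networks <- fx$networks
        if (is.null(prior)) prior <- fx$prior
    }
    if (length(networks) < 2L) stop("need at least two organisms")
    if (is.null(prior)) prior <- NodePairScores()
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    orgs <- vapply(networks, organismID, character(1))
    if (anyDuplicated(orgs)) stop("duplicate organism ids among networks")
    paths <- list(scores = file.path(outDir, "scores.tsv"),
                  clusters = file.path(outDir, "clusters.tsv"),
                  filtered = file.path(outDir, "clusters_filtered.tsv"),
                  dist = file.path(outDir, "dist.tsv"),
                  phylip = file.path(outDir, "dist.phylip"),
                  tree = file.path(outDir, "tree.nwk"))

    # align
    if (resume && file.exists(paths$scores)) {
        .stageMsg("align", skipped = TRUE)
        scores <- readScores(paths$scores)
        scoreTables <- list(scores)
    } else {
        t0 <- as.numeric(Sys.time())
        n <- length(networks)
        scoreTables <- list()
        for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
            scoreTables[[length(scoreTables) + 1L]] <-
                pairwiseScores(networks[[a]], networks[[b]], prior,
                               alpha = alpha, tol = tol, maxIter = maxIter)
        scores <- NodePairScores(do.call(rbind,
                                         lapply(scoreTables, scoreTable)))
        writeScores(scores, paths$scores)
        .stageMsg("align", t0 = t0)
    }

    # cluster
    if (resume && file.exists(paths$clusters)) {
        .stageMsg("cluster", skipped = TRUE)
        clusters <- readClusters(paths$clusters)
    } else {
        t0 <- as.numeric(Sys.time())
        g <- buildAlignmentGraph(scoreTables, networks,
                                 minWeight = minWeight)
        clusters <- spectralStarClusters(g, damping = damping,
                                         keepRatio = keepRatio)
        writeClusters(clusters, paths$clusters)
        .stageMsg("cluster", t0 = t0)
    }

    # filter
    if (resume && file.exists(paths$filtered)) {
        .stageMsg("filter", skipped = TRUE)
        filtered <- readClusters(paths$filtered)
    } else {
        t0 <- as.numeric(Sys.time())
        filtered <- filterClusters(clusters, networks,
                                   threshold = entropyThreshold,
                                   logBase = logBase)
        writeClusters(filtered, paths$filtered, withEntropy = TRUE)
        .stageMsg("filter", t0 = t0)
    }

    # dist
    if (resume && file.exists(paths$dist)) {
        .stageMsg("dist", skipped = TRUE)
        d <- readPhylip(paths$phylip)
    } else {
        t0 <- as.numeric(Sys.time())
        d <- organismDistanceMatrix(filtered, sort(unname(orgs)),
                                    form = distanceForm)
        if (distanceForm == "one-minus-jaccard") {
            writeDistTsv(d, paths$dist)
            writePhylip(d, paths$phylip)
        } else {
            # similarity form: TSV only (PHYLIP expects distances)
            header <- paste(c("organism", colnames(d)), collapse = "\t")
            rows <- vapply(seq_len(nrow(d)), function(i)
                paste(c(rownames(d)[i],
                        formatC(d[i, ], format = "g", digits = 17)),
                      collapse = "\t"), character(1))
            writeLines(c(header, rows), paths$dist)
        }
        .stageMsg("dist", t0 = t0)
    }

    # tree
    if (resume && file.exists(paths$tree)) {
        .stageMsg("tree", skipped = TRUE)
        tree <- fromNewick(path = paths$tree)
    } else {
        t0 <- as.numeric(Sys.time())
        if (distanceForm == "raw-ratio")
            stop("tree building requires distanceForm = 'one-minus-jaccard'")
        tree <- if (treeMethod == "nj") neighborJoining(d) else upgmaTree(d)
        toNewick(tree, paths$tree)
        .stageMsg("tree", t0 = t0)
    }

    manifest <- list(
        package = "MetNetPhylo",
        version = as.character(utils::packageVersion("MetNetPhylo")),
        r_version = R.version.string,
        organisms = sort(unname(orgs)),
        parameters = list(alpha = alpha, tol = tol, maxIter = maxIter,
                          damping = damping, keepRatio = keepRatio,
                          minWeight = minWeight,
                          entropyThreshold = entropyThreshold,
                          logBase = logBase, distanceForm = distanceForm,
                          treeMethod = treeMethod))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(list(scores = scores, clusters = clusters,
                   filtered = filtered, dist = d, tree = tree,
                   dir = outDir))
}
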