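#' @describeIn correlationMatrix Pearson correlations across subjects between
#'   every pair of region residual vectors. The diagonal is stored as 0
#'   (self-loops removed). Errors when fewer than 3 subjects are available or
#'   a region has zero residual variance.
#' @export
setMethod("correlationMatrix", "matrix", function(x) {
    if (nrow(x) < 3L)
        stop("at least 3 subjects are required for Pearson correlation")
    v <- apply(x, 2L, stats::var)
    if (any(v <= 0))
        stop("zero-variance region(s): ",
            paste(colnames(x)[v <= 0], collapse = ", "))
    R <- cor(x)
    R <- (R + t(R)) / 2
    diag(R) <- 0
    new("RegionCorrelation", mat = R, nSubjects = nrow(x))
})

#' @describeIn correlationMatrix residualize (per-group is not meaningful for
#'   a whole experiment; this convenience computes one matrix from all
#'   subjects after pooled residualization)
#' @export
setMethod("correlationMatrix", "ThicknessExperiment", function(x) {
    correlationMatrix(residualize(x, scope = "pooled"))
})

# Upper-triangle edge candidates ordered by decreasing r, ties broken by
# lexicographic region-pair order so thresholding is deterministic.
.edgeOrder <- function(R) {
    n <- nrow(R)
    ut <- which(upper.tri(R), arr.ind = TRUE)
    r <- R[ut]
    o <- order(-r, ut[, 1L], ut[, 2L])
    list(i = ut[o, 1L], j = ut[o, 2L], r = r[o], n = n)
}

#' Number of edges at a given density
#'
#' \code{round(density * N * (N - 1) / 2)} for an N-node undirected graph.
#'
#' @param density edge density in (0, 1)
#' @param n number of nodes
#' @export
edgeCount <- function(density, n) as.integer(round(density * n * (n - 1) / 2))

#' Binarize a correlation matrix at a fixed edge density
#'
#' The \code{E = round(density * N(N-1)/2)} strongest positive correlations
#' become edges; everything else (including every negative correlation) is 0.
#' Ties at the cut rank are broken by larger r then lexicographic region-pair
#' order. Errors when fewer than E positive correlations exist, reporting the
#' maximum achievable density.
#'
#' @param R a \linkS4class{RegionCorrelation}
#' @param density target edge density in (0, 1)
#' @return a \linkS4class{BinaryNetwork}
#' @examples
#' te <- generateCohort(syntheticSpec(groupSizes = c(30, 30)))
#' R <- correlationMatrix(residualize(te)[1:30, ])
#' net <- thresholdAtDensity(R, 0.15)
#' @export
thresholdAtDensity <- function(R, density) {
    stopifnot(is(R, "RegionCorrelation"), density > 0, density < 1)
    eo <- .edgeOrder(R@mat)
    n <- eo$n
    E <- edgeCount(density, n)
    nPos <- sum(eo$r > 0)
    if (nPos < E)
        stop(sprintf(
            "only %d positive correlations available; maximum achievable density is %.4f (requested %.4f)",
            nPos, nPos / (n * (n - 1) / 2), density))
    A <- matrix(0, n, n, dimnames = dimnames(R@mat))
    if (E > 0L) {
        sel <- seq_len(E)
        A[cbind(eo$i[sel], eo$j[sel])] <- 1
        A[cbind(eo$j[sel], eo$i[sel])] <- 1
    }
    new("BinaryNetwork", adjacency = A, density = density)
}

# igraph view of a BinaryNetwork (or plain adjacency matrix).
.asIgraph <- function(net) {
    a <- if (is(net, "BinaryNetwork")) net@adjacency else net
    igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
}

# Build igraph directly from the top-E entries of an ordered edge list;
# avoids materializing adjacency matrices in hot loops.
.graphAtDensity <- function(eo, E) {
    igraph::make_undirected_graph(rbind(eo$i[seq_len(E)], eo$j[seq_len(E)]),
        n = eo$n)
}

#' Select the analysed density range from two group correlation matrices
#'
#' Probes a density grid and returns the range whose lower limit is the
#' smallest probed density at which both groups' networks are connected
#' (a single component spanning all regions) and whose upper limit is the
#' largest probed density at which both groups' small-world index sigma
#' exceeds \code{sigmaRule} (default 1.2). Sigma is computed against seeded
#' degree-matched rewired ensembles so the selection is reproducible.
#'
#' @param R1,R2 \linkS4class{RegionCorrelation} for the two groups
#' @param sigmaRule small-world threshold for the upper limit (default 1.2)
#' @param probeStep probing grid step (default 0.01)
#' @param probeMax largest density probed (default 0.5)
#' @param nRandom ensemble size per network for sigma (default 20)
#' @param rewiresPerEdge edge-swap budget per edge (default 10)
#' @param seed RNG seed for the ensembles
#' @return a \linkS4class{DensityRange} with \code{step = probeStep}
#' @export
selectDensityRange <- function(R1, R2, sigmaRule = 1.2, probeStep = 0.01,
        probeMax = 0.5, nRandom = 20L, rewiresPerEdge = 10L, seed = 1L) {
    stopifnot(identical(regions(R1), regions(R2)))
    grid <- seq(probeStep, probeMax, by = probeStep)
    connected <- vapply(grid, function(d) {
        all(vapply(list(R1, R2), function(R) {
            tryCatch(igraph::is_connected(.asIgraph(thresholdAtDensity(R, d))),
                error = function(e) FALSE)
        }, logical(1)))
    }, logical(1))
    smallWorldOK <- vapply(grid, function(d) {
        all(vapply(list(R1, R2), function(R) {
            tryCatch({
                net <- thresholdAtDensity(R, d)
                ens <- matchRandomEnsemble(net, nRandom = nRandom,
                    rewiresPerEdge = rewiresPerEdge, seed = seed)
                smallWorld(net, ens)["sigma"] > sigmaRule
            }, error = function(e) FALSE)
        }, logical(1)))
    }, logical(1))
    if (!any(connected) || !any(smallWorldOK) ||
        min(grid[connected]) > max(grid[smallWorldOK]))
        stop(sprintf(
            "no density satisfies both rules: connected for both groups on [%s]; sigma > %.2f on [%s]",
            if (any(connected)) sprintf("%.2f, %.2f", min(grid[connected]), max(grid[connected])) else "empty",
            sigmaRule,
            if (any(smallWorldOK)) sprintf("%.2f, %.2f", min(grid[smallWorldOK]), max(grid[smallWorldOK])) else "empty"))
    densityRange(min(grid[connected]), max(grid[smallWorldOK]), probeStep)
}

#' Construct a DensityRange
#'
#' @param dMin,dMax endpoints in (0, 1)
#' @param step analysis grid step (default 0.01)
#' @export
densityRange <- function(dMin, dMax, step = 0.01) {
    new("DensityRange", dMin = dMin, dMax = dMax, step = step)
}

#' Density grid of a DensityRange
#' @param range a \linkS4class{DensityRange}
#' @export
densityGrid <- function(range) {
    seq(range@dMin, range@dMax, by = range@step)
}

#' Write a binary network as an edge list (region_a, region_b, r)
#'
#' @param net a \linkS4class{BinaryNetwork}
#' @param R the \linkS4class{RegionCorrelation} it was thresholded from
#' @param path output CSV path
#' @export
writeEdgeList <- function(net, R, path) {
    a <- net@adjacency
    idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    df <- data.frame(region_a = rownames(a)[idx[, 1]],
        region_b = rownames(a)[idx[, 2]],
        r = R@mat[idx])
    write.csv(df[order(-df$r), ], path, row.names = FALSE, quote = FALSE)
    invisible(df)
}
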