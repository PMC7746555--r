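#' @import methods
#' @importFrom stats cor quantile rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' ThicknessExperiment: subjects-by-regions cortical thickness container
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay
#' \code{"thickness"} holds regional mean cortical thickness in millimetres
#' with regions as rows and subjects as columns; \code{colData} carries the
#' per-subject phenotype used throughout the pipeline: \code{group} (factor),
#' \code{age} (years) and \code{sex} (0/1).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("ThicknessExperiment", contains = "SummarizedExperiment")

setValidity("ThicknessExperiment", function(object) {
    msg <- character()
    if (!"thickness" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'thickness' is required")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("group", "age", "sex"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("thickness" %in% SummarizedExperiment::assayNames(object)) {
        th <- SummarizedExperiment::assay(object, "thickness")
        if (anyNA(th))
            msg <- c(msg, "thickness values must not contain NA")
        if (is.null(rownames(object)))
            msg <- c(msg, "region (row) names are required")
    }
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% c(0, 1)))
        msg <- c(msg, "sex must be coded 0/1")
    if (length(msg)) msg else TRUE
})

#' RegionCorrelation: symmetric interregional Pearson correlation matrix
#'
#' Group-level Pearson correlations of corrected (residualized) cortical
#' thickness between every pair of regions, computed across subjects. The
#' diagonal is stored as 0: self-correlations never participate in edge
#' selection.
#'
#' @slot mat symmetric numeric matrix, zero diagonal, off-diagonal in [-1, 1]
#' @slot nSubjects number of subjects the correlations were estimated from
#' @export
setClass("RegionCorrelation",
    representation(mat = "matrix", nSubjects = "integer"))

setValidity("RegionCorrelation", function(object) {
    m <- object@mat
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    else {
        if (max(abs(m - t(m))) > 1e-12) msg <- c(msg, "matrix must be symmetric within 1e-12")
        if (any(abs(diag(m)) > 0)) msg <- c(msg, "diagonal must be 0")
        off <- m[upper.tri(m)]
        if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
            msg <- c(msg, "off-diagonal values must lie in [-1, 1]")
        if (is.null(rownames(m))) msg <- c(msg, "region names are required")
    }
    if (length(msg)) msg else TRUE
})

#' BinaryNetwork: undirected, unweighted graph at a fixed density
#'
#' Binary adjacency matrix obtained by retaining the strongest positive
#' correlations as edges until the requested edge density is reached. The
#' diagonal is zero (no self-loops) and the edge count is exactly
#' \code{round(density * N * (N - 1) / 2)}.
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal
#' @slot density fraction of possible edges present
#' @export
setClass("BinaryNetwork",
    representation(adjacency = "matrix", density = "numeric"))

setValidity("BinaryNetwork", function(object) {
    a <- object@adjacency
    msg <- character()
    if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
    else {
        if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
        if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be 0 (no self-loops)")
        if (max(abs(a - t(a))) > 0) msg <- c(msg, "adjacency must be symmetric")
        n <- nrow(a)
        e <- sum(a[upper.tri(a)])
        if (e != round(object@density * n * (n - 1) / 2))
            msg <- c(msg, "edge count must equal round(density * N(N-1)/2)")
    }
    if (length(msg)) msg else TRUE
})

#' DensityRange: analysed interval of network densities
#'
#' @slot dMin,dMax range endpoints in (0, 1)
#' @slot step grid step used to probe/analyse densities
#' @export
setClass("DensityRange",
    representation(dMin = "numeric", dMax = "numeric", step = "numeric"))

setValidity("DensityRange", function(object) {
    msg <- character()
    if (object@dMin <= 0 || object@dMax >= 1)
        msg <- c(msg, "densities must lie within (0, 1)")
    if (object@dMin > object@dMax)
        msg <- c(msg, "dMin must not exceed dMax")
    if (object@step <= 0) msg <- c(msg, "step must be positive")
    if (length(msg)) msg else TRUE
})

#' RandomEnsemble: degree-matched rewired random networks
#'
#' Summaries of \code{nRandom} degree-preserving edge-swap randomizations of a
#' source network, used to normalize the clustering coefficient and
#' characteristic path length (gamma, lambda, sigma).
#'
#' @slot nRandom ensemble size
#' @slot rewiresPerEdge number of attempted swaps per edge
#' @slot seed RNG seed used
#' @slot cpRand,lpRand per-member clustering coefficient and path length
#' @export
setClass("RandomEnsemble",
    representation(nRandom = "integer", rewiresPerEdge = "integer",
        seed = "integer", cpRand = "numeric", lpRand = "numeric"))

#' HubSet: regions whose betweenness exceeds mean + 1.5 SD
#'
#' @slot hubs region names flagged as hubs (possibly empty)
#' @slot betweenness the nodal betweenness values used
#' @slot mean,sd network mean and population SD of betweenness
#' @slot threshold the applied cutoff (mean + k * sd)
#' @export
setClass("HubSet",
    representation(hubs = "character", betweenness = "numeric",
        mean = "numeric", sd = "numeric", threshold = "numeric"))

#' MetricCurves: metric values per group across the density grid, plus AUC
#'
#' @slot curves long data.frame: metric, density, group, value
#' @slot auc data.frame: metric, group, auc (trapezoidal over the grid)
#' @slot densities the density grid
#' @slot groups the two group labels (group 1 minus group 2 is the contrast)
#' @export
setClass("MetricCurves",
    representation(curves = "data.frame", auc = "data.frame",
        densities = "numeric", groups = "character"))

#' PermutationResult: permutation inference for one metric
#'
#' Observed group differences (group 1 minus group 2) per density and for the
#' across-density AUC, together with their label-permutation null
#' distributions, two-sided add-one p-values and 95% null bands.
#'
#' @slot metric metric name
#' @slot densities density grid
#' @slot observed observed difference per density
#' @slot observedAUC observed AUC difference
#' @slot nullDensity nPerm-by-density matrix of permuted differences
#' @slot nullAUC permuted AUC differences
#' @slot pDensity,pAUC two-sided p-values, add-one rule
#' @slot bands 2-by-density matrix of 2.5/97.5 null percentiles
#' @slot nPerm requested repetitions; @slot nEffective non-missing per column
#' @slot seed RNG seed
#' @export
setClass("PermutationResult",
    representation(metric = "character", densities = "numeric",
        observed = "numeric", observedAUC = "numeric",
        nullDensity = "matrix", nullAUC = "numeric",
        pDensity = "numeric", pAUC = "numeric", bands = "matrix",
        nPerm = "integer", nEffective = "integer", seed = "integer"))

#' SyntheticSpec: parameters of the synthetic two-group cohort generator
#'
#' Describes a two-group cohort of regional thickness values with a
#' block-structured (planted-partition) interregional correlation matrix per
#' group, linear age/sex effects shared by both groups, and i.i.d. residual
#' scale \code{noiseSD}. Optionally a designated bridge region is given its
#' own correlation to every other region, per group, to plant high-betweenness
#' connector nodes.
#'
#' @slot nRegions number of regions (68 for the Desikan-Killiany atlas)
#' @slot groupSizes two group sizes
#' @slot blockPartition integer block assignment per region
#' @slot withinBlockR,betweenBlockR per-group correlations in [0, 1)
#' @slot covariateEffects per-region age and sex coefficients
#' @slot noiseSD residual standard deviation (mm)
#' @slot baseline per-region mean thickness (mm)
#' @slot ageRange uniform sampling interval for age (years)
#' @slot bridgeRegion optional region index (0 = none)
#' @slot bridgeR per-group correlation of the bridge region to the regions
#'   of the targeted blocks
#' @slot bridgeBlocks blocks the bridge correlates with (empty = all)
#' @slot seed RNG seed
#' @export
setClass("SyntheticSpec",
    representation(nRegions = "integer", groupSizes = "integer",
        blockPartition = "integer", withinBlockR = "numeric",
        betweenBlockR = "numeric", covariateEffects = "matrix",
        noiseSD = "numeric", baseline = "numeric", ageRange = "numeric",
        bridgeRegion = "integer", bridgeR = "numeric",
        bridgeBlocks = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (length(object@groupSizes) != 2 || any(object@groupSizes < 3))
        msg <- c(msg, "two group sizes >= 3 are required (Pearson correlation degenerates below)")
    if (length(object@blockPartition) != object@nRegions)
        msg <- c(msg, "blockPartition must assign every region to a block")
    if (any(object@withinBlockR < 0) || any(object@withinBlockR >= 1) ||
        any(object@betweenBlockR < 0) || any(object@betweenBlockR >= 1))
        msg <- c(msg, "block correlations must lie in [0, 1)")
    if (any(object@betweenBlockR > object@withinBlockR))
        msg <- c(msg, "betweenBlockR must not exceed withinBlockR")
    if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be positive")
    if (length(msg)) msg else TRUE
})
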