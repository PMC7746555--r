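#' Describe a synthetic two-group cortical-thickness cohort
#'
#' Constructs a \linkS4class{SyntheticSpec}. Defaults emulate the study
#' conditions of a two-group cortical-thickness comparison on the 68-region
#' Desikan-Killiany parcellation: group sizes 67 and 88, four equal blocks of
#' correlated regions, moderate within-block correlation, linear age and sex
#' effects and a residual scale typical of regional mean thickness.
#'
#' Interregional dependence is a planted-partition correlation matrix: regions
#' in the same block correlate at \code{withinBlockR}, regions in different
#' blocks at \code{betweenBlockR}; both may differ between the two groups to
#' plant group-level covariance differences. An optional bridge region is
#' instead correlated at \code{bridgeR} with every other region, which plants
#' a high-betweenness connector node at thresholding time.
#'
#' @param nRegions number of regions (default 68)
#' @param groupSizes the two group sizes (default c(67, 88))
#' @param nBlocks number of equally sized correlation blocks (default 4);
#'   ignored when \code{blockPartition} is given
#' @param blockPartition explicit integer block label per region
#' @param withinBlockR within-block correlation, length 1 or 2 (per group)
#' @param betweenBlockR between-block correlation, length 1 or 2
#' @param ageEffect,sexEffect per-region linear coefficients (recycled);
#'   defaults -0.005 mm/year and 0.02 mm reflect mild cortical thinning with
#'   age and a small sex offset
#' @param noiseSD residual standard deviation in mm (default 0.12)
#' @param baseline per-region mean thickness in mm (default 2.5, recycled)
#' @param ageRange uniform sampling interval for age (default c(40, 70) years)
#' @param bridgeRegion optional region index to turn into a bridge
#' @param bridgeR bridge correlation, length 1 or 2 (per group)
#' @param bridgeBlocks blocks whose regions the bridge correlates with
#'   (default: all). Targeting a subset keeps the bridge distinguishable
#'   from the cohort's global mean signal
#' @param seed RNG seed (default 1)
#' @return a \linkS4class{SyntheticSpec}
#' @seealso \code{\link{generateCohort}}
#' @examples
#' sp <- syntheticSpec(groupSizes = c(20, 20), seed = 7)
#' te <- generateCohort(sp)
#' @export
syntheticSpec <- function(nRegions = 68L, groupSizes = c(67L, 88L),
        nBlocks = 4L, blockPartition = NULL,
        withinBlockR = 0.5, betweenBlockR = 0.2,
        ageEffect = -0.005, sexEffect = 0.02,
        noiseSD = 0.12, baseline = 2.5, ageRange = c(40, 70),
        bridgeRegion = NULL, bridgeR = 0, bridgeBlocks = NULL, seed = 1L) {
    nRegions <- as.integer(nRegions)
    if (is.null(blockPartition))
        blockPartition <- sort(rep_len(seq_len(nBlocks), nRegions))
    eff <- cbind(age = rep_len(ageEffect, nRegions),
                 sex = rep_len(sexEffect, nRegions))
    new("SyntheticSpec",
        nRegions = nRegions,
        groupSizes = as.integer(groupSizes),
        blockPartition = as.integer(blockPartition),
        withinBlockR = rep_len(withinBlockR, 2L),
        betweenBlockR = rep_len(betweenBlockR, 2L),
        covariateEffects = eff,
        noiseSD = as.numeric(noiseSD),
        baseline = rep_len(as.numeric(baseline), nRegions),
        ageRange = as.numeric(ageRange),
        bridgeRegion = if (is.null(bridgeRegion)) 0L else as.integer(bridgeRegion),
        bridgeR = rep_len(as.numeric(bridgeR), 2L),
        bridgeBlocks = if (is.null(bridgeBlocks)) integer() else
            as.integer(bridgeBlocks),
        seed = as.integer(seed))
}

# Planted-partition correlation matrix for one group, with optional bridge row.
.blockCorrelation <- function(spec, group) {
    part <- spec@blockPartition
    n <- spec@nRegions
    same <- outer(part, part, "==")
    C <- ifelse(same, spec@withinBlockR[group], spec@betweenBlockR[group])
    if (spec@bridgeRegion > 0L) {
        b <- spec@bridgeRegion
        target <- if (length(spec@bridgeBlocks))
            part %in% spec@bridgeBlocks else rep(TRUE, n)
        C[b, ] <- C[, b] <- 0
        C[b, target] <- C[target, b] <- spec@bridgeR[group]
    }
    diag(C) <- 1
    C
}

# PSD repair by eigenvalue clipping; warns when clipping changes the matrix.
.ensurePSD <- function(C, label) {
    ev <- eigen(C, symmetric = TRUE)
    if (min(ev$values) < -1e-10) {
        warning(sprintf(
            "implied correlation matrix for %s is not positive semi-definite (min eigenvalue %.3g); clipping negative eigenvalues",
            label, min(ev$values)))
        v <- pmax(ev$values, 0)
        C <- ev$vectors %*% (v * t(ev$vectors))
        s <- sqrt(diag(C))
        C <- C / outer(s, s)
        diag(C) <- 1
    }
    C
}

#' Generate a synthetic two-group cortical-thickness cohort
#'
#' Samples a \linkS4class{ThicknessExperiment} from a
#' \linkS4class{SyntheticSpec}: ages uniform on the spec's interval, sex
#' Bernoulli(0.5), and regional thickness = baseline + age and sex effects +
#' a multivariate normal draw with the spec's block-structured correlation
#' (scaled by \code{noiseSD}). The implied correlation matrix is checked for
#' positive semi-definiteness before sampling and repaired by eigenvalue
#' clipping with a warning if needed. Identical spec and seed give
#' bit-identical cohorts.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param regionNames region names; defaults to the packaged Desikan-Killiany
#'   list when \code{nRegions} is 68, else \code{region_1 ...}
#' @return a \linkS4class{ThicknessExperiment} with colData columns
#'   \code{group} (factor "group1"/"group2"), \code{age}, \code{sex}
#' @examples
#' te <- generateCohort(syntheticSpec(groupSizes = c(10, 12), seed = 3))
#' dim(te)
#' @export
generateCohort <- function(spec, regionNames = NULL) {
    validObject(spec)
    n <- spec@nRegions
    if (is.null(regionNames))
        regionNames <- if (n == 68L) dkRegions() else sprintf("region_%02d", seq_len(n))
    stopifnot(length(regionNames) == n)
    set.seed(spec@seed)
    groups <- rep(c("group1", "group2"), spec@groupSizes)
    nTot <- sum(spec@groupSizes)
    age <- runif(nTot, spec@ageRange[1], spec@ageRange[2])
    sex <- rbinom(nTot, 1L, 0.5)
    thick <- matrix(NA_real_, nTot, n)
    for (g in 1:2) {
        C <- .blockCorrelation(spec, g)
        C <- .ensurePSD(C, sprintf("group %d (within=%.2f, between=%.2f)",
            g, spec@withinBlockR[g], spec@betweenBlockR[g]))
        idx <- which(groups == paste0("group", g))
        e <- MASS::mvrnorm(length(idx), mu = rep(0, n),
            Sigma = spec@noiseSD^2 * C)
        thick[idx, ] <- e
    }
    thick <- thick +
        rep(spec@baseline, each = nTot) +
        outer(age, spec@covariateEffects[, "age"]) +
        outer(sex, spec@covariateEffects[, "sex"])
    colnames(thick) <- regionNames
    rownames(thick) <- sprintf("sub_%03d", seq_len(nTot))
    ThicknessExperiment(thick, group = groups, age = age, sex = sex)
}
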