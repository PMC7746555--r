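#' Settings for the network-comparison pipeline
#'
#' Bundles every tunable of the per-group network pipeline so that observed
#' curves and permutation repetitions are guaranteed to run under identical
#' settings.
#'
#' @param scope residualization scope, \code{"per-group"} (refitted inside
#'   each permuted pseudo-group) or \code{"pooled"}
#' @param metrics global metrics to compute; any of \code{"Cp"}, \code{"Lp"},
#'   \code{"Eglob"}, \code{"Eloc"}, \code{"transitivity"}, \code{"Q"},
#'   \code{"gamma"}, \code{"lambda"}, \code{"sigma"} (the last three require
#'   a random ensemble per network and are costly under permutation)
#' @param nodal also compute normalized nodal degree/clustering/betweenness
#' @param nRandom,rewiresPerEdge ensemble settings for gamma/lambda/sigma
#' @param modularityRestarts Louvain restarts inside the curve engine
#'   (default 1; the standalone \code{\link{modularityQ}} defaults to 5)
#' @return a list of class \code{scnSettings}
#' @export
scnSettings <- function(scope = c("per-group", "pooled"),
        metrics = c("Cp", "Lp", "Eglob", "Eloc", "transitivity", "Q"),
        nodal = FALSE, nRandom = 100L, rewiresPerEdge = 10L,
        modularityRestarts = 1L) {
    scope <- match.arg(scope)
    known <- c("Cp", "Lp", "Eglob", "Eloc", "transitivity", "Q",
        "gamma", "lambda", "sigma")
    bad <- setdiff(metrics, known)
    if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
    structure(list(scope = scope, metrics = metrics, nodal = isTRUE(nodal),
        nRandom = as.integer(nRandom),
        rewiresPerEdge = as.integer(rewiresPerEdge),
        modularityRestarts = as.integer(modularityRestarts)),
        class = "scnSettings")
}

.NODAL <- c("degree", "clustering", "betweenness")

# Pearson correlation via one BLAS crossprod; zero-variance columns yield
# NaN, which the engine treats as a degenerate repetition. Diagonal set to 0.
.fastCor <- function(x) {
    n <- nrow(x)
    cm <- colMeans(x)
    S <- crossprod(x) / n - outer(cm, cm)
    d <- diag(S)
    R <- S / sqrt(outer(d, d))
    diag(R) <- 0
    R
}

# Permutation-invariant context shared by every repetition: the covariate
# design (global mean thickness is a per-subject quantity, independent of the
# grouping), upper-triangle indices and per-density edge counts.
.makeEngineCtx <- function(Y, age, sex, densities) {
    n <- ncol(Y)
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    list(X = cbind(1, age, sex, rowMeans(Y)),
        i = ut[, 1L], j = ut[, 2L],
        lin = ut[, 1L] + n * (ut[, 2L] - 1L),
        n = n, densities = densities,
        Es = vapply(densities, edgeCount, integer(1), n = n))
}

# OLS residuals without rank diagnostics, for the permutation hot path (the
# observed design is validated once through residualize()).
.residFast <- function(Y, X) {
    Y - X %*% solve(crossprod(X), crossprod(X, Y))
}

# One group's metrics at every density, from its residual matrix.
# Returns list(global = metric x density matrix, nodal = region x density x 3).
# Infeasible densities (too few positive correlations) or degenerate
# correlation matrices yield NA columns. Assumes the RNG state is managed by
# the caller.
.groupMetricsAtDensities <- function(res, ctx, settings) {
    nMet <- length(settings$metrics)
    nD <- length(ctx$densities)
    glob <- matrix(NA_real_, nMet, nD,
        dimnames = list(settings$metrics, NULL))
    nod <- if (settings$nodal)
        array(NA_real_, c(ncol(res), nD, 3L),
            dimnames = list(colnames(res), NULL, .NODAL)) else NULL
    R <- .fastCor(res)
    if (anyNA(R)) return(list(global = glob, nodal = nod))
    r <- R[ctx$lin]
    o <- order(-r, ctx$i, ctx$j)
    eo <- list(i = ctx$i[o], j = ctx$j[o], r = r[o], n = ctx$n)
    nPos <- sum(eo$r > 0)
    needSW <- any(c("gamma", "lambda", "sigma") %in% settings$metrics)
    for (k in seq_len(nD)) {
        E <- ctx$Es[k]
        if (E < 1L || E > nPos) next
        g <- .graphAtDensity(eo, E)
        m <- settings$metrics
        cc <- NULL
        if (any(c("Cp", "gamma", "sigma") %in% m) ||
            (settings$nodal)) {
            cc <- igraph::transitivity(g, type = "localundirected",
                isolates = "zero")
        }
        lp <- if (any(c("Lp", "lambda", "sigma") %in% m))
            igraph::mean_distance(g, unconnected = TRUE) else NULL
        if ("Cp" %in% m) glob["Cp", k] <- mean(cc)
        if ("Lp" %in% m) glob["Lp", k] <- lp
        if ("Eglob" %in% m) {
            d <- igraph::distances(g)
            inv <- 1 / d[upper.tri(d)]
            glob["Eglob", k] <- mean(ifelse(is.finite(inv), inv, 0))
        }
        if ("Eloc" %in% m)
            glob["Eloc", k] <- localEfficiency(igraph::as_adjacency_matrix(
                g, sparse = FALSE))$network
        if ("transitivity" %in% m) {
            t <- igraph::transitivity(g, type = "global")
            glob["transitivity", k] <- if (is.nan(t)) 0 else t
        }
        if ("Q" %in% m) {
            q <- -Inf
            for (i in seq_len(settings$modularityRestarts))
                q <- max(q, igraph::modularity(igraph::cluster_louvain(g)))
            glob["Q", k] <- q
        }
        if (needSW) {
            ens <- .ensembleSummaries(g, settings$nRandom,
                settings$rewiresPerEdge)
            gamma <- mean(cc) / mean(ens$cp)
            lambda <- lp / mean(ens$lp)
            if ("gamma" %in% m) glob["gamma", k] <- gamma
            if ("lambda" %in% m) glob["lambda", k] <- lambda
            if ("sigma" %in% m) glob["sigma", k] <- gamma / lambda
        }
        if (settings$nodal) {
            deg <- igraph::degree(g)
            btw <- igraph::betweenness(g, directed = FALSE)
            normBy <- function(x) if (mean(x) == 0) x * 0 else x / mean(x)
            nod[, k, "degree"] <- normBy(deg)
            nod[, k, "clustering"] <- normBy(cc)
            nod[, k, "betweenness"] <- normBy(btw)
        }
    }
    list(global = glob, nodal = nod)
}

# Both groups' curves for an arbitrary grouping vector (observed or permuted).
.curvesEngine <- function(Y, group, ctx, settings, groupLevels) {
    if (settings$scope == "per-group") {
        lapply(groupLevels, function(g) {
            idx <- group == g
            res <- .residFast(Y[idx, , drop = FALSE],
                ctx$X[idx, , drop = FALSE])
            .groupMetricsAtDensities(res, ctx, settings)
        })
    } else {
        res <- .residFast(Y, ctx$X)
        lapply(groupLevels, function(g)
            .groupMetricsAtDensities(res[group == g, , drop = FALSE],
                ctx, settings))
    }
}

#' Trapezoidal area under a curve
#'
#' @param x strictly increasing grid (densities)
#' @param y metric values on the grid; returns NA if any value is NA
#' @export
aucTrapezoid <- function(x, y) {
    if (anyNA(y)) return(NA_real_)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

.twoGroupLevels <- function(group) {
    lev <- if (is.factor(group)) levels(group) else unique(group)
    if (length(lev) != 2L)
        stop("exactly two groups are required; found: ",
            paste(lev, collapse = ", "))
    as.character(lev)
}

#' Global metric curves across the density range for two groups
#'
#' For each group: residualize, correlate, threshold at every grid density
#' and compute the requested global metrics; summarize each metric per group
#' by the trapezoidal AUC over the grid. Errors when any grid density is
#' infeasible for a group (too few positive correlations), naming the group
#' and density.
#'
#' @param x a \linkS4class{ThicknessExperiment} with exactly two groups
#' @param range a \linkS4class{DensityRange}
#' @param settings an \code{\link{scnSettings}} list
#' @param seed RNG seed (matters for Q and gamma/lambda/sigma)
#' @return a \linkS4class{MetricCurves}
#' @export
metricCurves <- function(x, range, settings = scnSettings(), seed = 1L) {
    cd <- SummarizedExperiment::colData(x)
    lev <- .twoGroupLevels(cd$group)
    dens <- densityGrid(range)
    Y <- t(SummarizedExperiment::assay(x, "thickness"))
    residualize(x, scope = settings$scope)  # surfaces design-rank errors
    ctx <- .makeEngineCtx(Y, cd$age, cd$sex, dens)
    set.seed(seed)
    eng <- .curvesEngine(Y, as.character(cd$group), ctx, settings, lev)
    for (gi in 1:2) {
        bad <- which(colSums(is.na(eng[[gi]]$global)) > 0)
        if (length(bad))
            stop(sprintf("density %.3f is infeasible for group '%s'",
                dens[bad[1]], lev[gi]))
    }
    curves <- do.call(rbind, lapply(1:2, function(gi) {
        g <- eng[[gi]]$global
        data.frame(metric = rep(rownames(g), ncol(g)),
            density = rep(dens, each = nrow(g)),
            group = lev[gi], value = as.vector(g))
    }))
    auc <- do.call(rbind, lapply(1:2, function(gi) {
        g <- eng[[gi]]$global
        data.frame(metric = rownames(g), group = lev[gi],
            auc = apply(g, 1L, function(y) aucTrapezoid(dens, y)))
    }))
    rownames(auc) <- NULL
    new("MetricCurves", curves = curves, auc = auc, densities = dens,
        groups = lev)
}

# Deterministic per-repetition sub-seeds from one global seed, so
# repetitions are order-independent.
.deriveSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}

#' Label-permutation test of group differences in global network metrics
#'
#' Each repetition reassigns subjects at random to two pseudo-groups of the
#' original sizes, reruns the full per-group pipeline (residualization is
#' refitted within pseudo-groups when \code{scope = "per-group"}) and records
#' the pseudo-difference (group 1 minus group 2) per density and for the
#' AUC. Two-sided p-values use the add-one rule
#' \code{(b + 1) / (m + 1)}; 95% null bands are the 2.5/97.5 percentiles of
#' the per-density null. A repetition whose network is infeasible at some
#' density contributes NA there (logged); p-values are computed over
#' non-missing repetitions and the effective count is reported.
#'
#' @inheritParams metricCurves
#' @param nPerm number of permutation repetitions (the study design uses
#'   1000; calibration experiments use fewer)
#' @param seed global RNG seed; per-repetition sub-seeds are derived from it
#' @return named list of \linkS4class{PermutationResult}, one per metric
#' @export
permuteGroups <- function(x, range, settings = scnSettings(), nPerm = 1000L,
        seed = 1L) {
    if (nPerm < 1L) stop("nPerm must be at least 1")
    cd <- SummarizedExperiment::colData(x)
    lev <- .twoGroupLevels(cd$group)
    group <- as.character(cd$group)
    dens <- densityGrid(range)
    Y <- t(SummarizedExperiment::assay(x, "thickness"))
    residualize(x, scope = settings$scope)  # surfaces design-rank errors
    ctx <- .makeEngineCtx(Y, cd$age, cd$sex, dens)
    set.seed(seed)
    obs <- .curvesEngine(Y, group, ctx, settings, lev)
    obsDiff <- obs[[1]]$global - obs[[2]]$global
    if (anyNA(obsDiff))
        stop("observed networks are infeasible at some grid density")
    subSeeds <- .deriveSeeds(seed, nPerm)
    nMet <- length(settings$metrics)
    nullD <- array(NA_real_, c(nPerm, length(dens), nMet),
        dimnames = list(NULL, NULL, settings$metrics))
    for (p in seq_len(nPerm)) {
        set.seed(subSeeds[p])
        pg <- sample(group)
        eng <- .curvesEngine(Y, pg, ctx, settings, lev)
        nullD[p, , ] <- t(eng[[1]]$global - eng[[2]]$global)
    }
    nMissing <- sum(is.na(nullD))
    if (nMissing > 0)
        message(sprintf("%d permuted metric value(s) missing (infeasible densities); p-values use non-missing repetitions", nMissing))
    out <- lapply(seq_len(nMet), function(mi) {
        m <- settings$metrics[mi]
        nd <- nullD[, , mi, drop = FALSE]
        dim(nd) <- c(nPerm, length(dens))
        nullAUC <- apply(nd, 1L, function(y) aucTrapezoid(dens, y))
        obsAUC <- aucTrapezoid(dens, obsDiff[m, ])
        pD <- vapply(seq_along(dens), function(k) {
            v <- nd[, k]; v <- v[!is.na(v)]
            (sum(abs(v) >= abs(obsDiff[m, k])) + 1) / (length(v) + 1)
        }, numeric(1))
        vA <- nullAUC[!is.na(nullAUC)]
        pA <- (sum(abs(vA) >= abs(obsAUC)) + 1) / (length(vA) + 1)
        bands <- apply(nd, 2L, quantile, probs = c(0.025, 0.975),
            na.rm = TRUE)
        new("PermutationResult", metric = m, densities = dens,
            observed = obsDiff[m, ], observedAUC = obsAUC,
            nullDensity = nd, nullAUC = nullAUC,
            pDensity = pD, pAUC = pA, bands = bands,
            nPerm = as.integer(nPerm),
            nEffective = as.integer(colSums(!is.na(nd))),
            seed = as.integer(seed))
    })
    names(out) <- settings$metrics
    out
}

#' Label-permutation test of regional (nodal) network metrics
#'
#' Applies the permutation machinery of \code{\link{permuteGroups}} to the
#' mean-normalized nodal degree, clustering coefficient and betweenness
#' centrality of every region, summarized by AUC across densities. P-values
#' are reported uncorrected and with Benjamini-Hochberg adjustment across
#' regions (the primary report is uncorrected; the adjusted column labels
#' the multiplicity).
#'
#' @inheritParams permuteGroups
#' @return data.frame: metric, region, observed AUC difference (group 1 -
#'   group 2), p_auc, p_auc_bh
#' @export
compareNodal <- function(x, range, settings = scnSettings(), nPerm = 1000L,
        seed = 1L) {
    if (nPerm < 1L) stop("nPerm must be at least 1")
    settings$nodal <- TRUE
    settings$metrics <- character(0)  # only the nodal arrays are needed
    cd <- SummarizedExperiment::colData(x)
    lev <- .twoGroupLevels(cd$group)
    group <- as.character(cd$group)
    dens <- densityGrid(range)
    Y <- t(SummarizedExperiment::assay(x, "thickness"))
    residualize(x, scope = settings$scope)  # surfaces design-rank errors
    ctx <- .makeEngineCtx(Y, cd$age, cd$sex, dens)
    set.seed(seed)
    obs <- .curvesEngine(Y, group, ctx, settings, lev)
    obsAUC <- .nodalAUC(obs, dens)   # region x metric
    subSeeds <- .deriveSeeds(seed, nPerm)
    cnt <- eff <- array(0L, dim(obsAUC), dimnames = dimnames(obsAUC))
    for (p in seq_len(nPerm)) {
        set.seed(subSeeds[p])
        pg <- sample(group)
        eng <- .curvesEngine(Y, pg, ctx, settings, lev)
        nullAUC <- .nodalAUC(eng, dens)
        ok <- !is.na(nullAUC)
        cnt[ok] <- cnt[ok] + (abs(nullAUC[ok]) >= abs(obsAUC[ok]))
        eff[ok] <- eff[ok] + 1L
    }
    pAUC <- (cnt + 1) / (eff + 1)
    out <- do.call(rbind, lapply(colnames(obsAUC), function(m)
        data.frame(metric = m, region = rownames(obsAUC),
            auc_diff = obsAUC[, m], p_auc = pAUC[, m],
            p_auc_bh = stats::p.adjust(pAUC[, m], method = "BH"),
            row.names = NULL)))
    out
}

# region x nodal-metric AUC differences (group1 - group2) from engine output.
.nodalAUC <- function(eng, dens) {
    d <- eng[[1]]$nodal - eng[[2]]$nodal
    apply(d, c(1L, 3L), function(y) aucTrapezoid(dens, y))
}

#' Compare hub sets between the two groups
#'
#' Detects hubs (betweenness at least 1.5 SD above the network mean) in each
#' group's network, either at a single density (default: the lower end of the
#' range) or by majority vote across the whole density grid, and reports the
#' shared/group-specific partition.
#'
#' @inheritParams metricCurves
#' @param hubDensity density at which to detect hubs (default
#'   \code{range@dMin})
#' @param aggregate \code{"single"} (one density) or \code{"majority"} (a
#'   region is a hub if flagged at more than half of the grid densities)
#' @param k SD multiplier for the hub rule (default 1.5)
#' @return list with per-group \linkS4class{HubSet}s (single-density mode)
#'   or hub name vectors (majority mode), plus \code{shared},
#'   \code{group1_only}, \code{group2_only}
#' @export
compareHubs <- function(x, range, settings = scnSettings(),
        hubDensity = NULL, aggregate = c("single", "majority"), k = 1.5) {
    aggregate <- match.arg(aggregate)
    cd <- SummarizedExperiment::colData(x)
    lev <- .twoGroupLevels(cd$group)
    res <- residualize(x, scope = settings$scope)
    group <- as.character(cd$group)
    Rs <- lapply(lev, function(g)
        correlationMatrix(res[group == g, , drop = FALSE]))
    if (aggregate == "single") {
        d <- if (is.null(hubDensity)) range@dMin else hubDensity
        hubsets <- lapply(Rs, function(R)
            detectHubs(thresholdAtDensity(R, d), k = k))
        hubs <- lapply(hubsets, hubRegions)
    } else {
        dens <- densityGrid(range)
        hubs <- lapply(Rs, function(R) {
            counts <- table(unlist(lapply(dens, function(d)
                hubRegions(detectHubs(thresholdAtDensity(R, d), k = k)))))
            names(counts)[counts > length(dens) / 2]
        })
        hubsets <- hubs
    }
    names(hubsets) <- lev
    c(hubsets,
      list(shared = intersect(hubs[[1]], hubs[[2]]),
           group1_only = setdiff(hubs[[1]], hubs[[2]]),
           group2_only = setdiff(hubs[[2]], hubs[[1]])))
}
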