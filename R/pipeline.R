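#' Run the full structural covariance network pipeline from a config
#'
#' Reproducible orchestration of simulate/load -> residualize -> correlate ->
#' density range -> metric curves -> permutation inference -> hubs, writing
#' tidy CSV artifacts plus a JSON manifest (settings, seeds, input checksum)
#' to an output directory. A persisted config re-executes to byte-identical
#' outputs given identical inputs.
#'
#' Config fields (YAML file or list): \code{input} (thickness CSV; omit when
#' \code{simulate} is given), \code{simulate} (arguments for
#' \code{\link{syntheticSpec}}), \code{parcellation} (path; default packaged
#' Desikan-Killiany), \code{density} (\code{min}, \code{max}, \code{step};
#' omit min/max to auto-select via \code{\link{selectDensityRange}}),
#' \code{sigma_rule}, \code{scope}, \code{metrics}, \code{nodal},
#' \code{ensemble} (\code{n_random}, \code{rewires_per_edge}),
#' \code{permutations}, \code{hub} (\code{density}, \code{aggregate}),
#' \code{seed}, \code{output_dir}.
#'
#' @param config path to a YAML file or an equivalent named list
#' @return invisibly, a list with the in-memory results (experiment, range,
#'   curves, permutation, nodal, hubs, manifest)
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- config
    dir.create(cfg$output_dir %||% "scnet_out", showWarnings = FALSE,
        recursive = TRUE)
    outDir <- cfg$output_dir %||% "scnet_out"
    seed <- as.integer(cfg$seed %||% 1L)

    # validate before any computation
    dn <- cfg$density %||% list()
    if (!is.null(dn$min) && !is.null(dn$max) && dn$min > dn$max)
        stop("config error: density min exceeds density max")
    step <- dn$step %||% 0.01

    parc <- if (!is.null(cfg$parcellation))
        readParcellation(cfg$parcellation) else dkRegions()

    if (!is.null(cfg$simulate)) {
        spec <- do.call(syntheticSpec,
            c(cfg$simulate, list(seed = seed)))
        te <- generateCohort(spec)
        writeThickness(te, file.path(outDir, "thickness.csv"))
        inputPath <- file.path(outDir, "thickness.csv")
    } else {
        if (is.null(cfg$input)) stop("config error: either 'input' or 'simulate' is required")
        te <- loadThickness(cfg$input, parcellation = parc)
        inputPath <- cfg$input
    }

    settings <- scnSettings(
        scope = cfg$scope %||% "per-group",
        metrics = cfg$metrics %||% c("Cp", "Lp", "Eglob", "Eloc",
            "transitivity", "Q"),
        nodal = isTRUE(cfg$nodal),
        nRandom = cfg$ensemble$n_random %||% 100L,
        rewiresPerEdge = cfg$ensemble$rewires_per_edge %||% 10L,
        modularityRestarts = cfg$modularity_restarts %||% 1L)

    res <- residualize(te, scope = settings$scope)
    write.csv(data.frame(subject_id = rownames(res), res,
        check.names = FALSE), file.path(outDir, "residuals.csv"),
        row.names = FALSE, quote = FALSE)

    cd <- SummarizedExperiment::colData(te)
    lev <- .twoGroupLevels(cd$group)
    group <- as.character(cd$group)
    Rs <- lapply(lev, function(g)
        correlationMatrix(res[group == g, , drop = FALSE]))
    for (i in 1:2)
        write.csv(Rs[[i]]@mat, file.path(outDir,
            sprintf("correlation_%s.csv", lev[i])), quote = FALSE)

    if (is.null(dn$min) || is.null(dn$max)) {
        range <- selectDensityRange(Rs[[1]], Rs[[2]],
            sigmaRule = cfg$sigma_rule %||% 1.2, probeStep = step,
            nRandom = min(settings$nRandom, 20L),
            rewiresPerEdge = settings$rewiresPerEdge, seed = seed)
    } else {
        range <- densityRange(dn$min, dn$max, step)
    }

    curves <- metricCurves(te, range, settings, seed = seed)
    write.csv(curves$curves, file.path(outDir, "metric_curves.csv"),
        row.names = FALSE, quote = FALSE)
    write.csv(curves$auc, file.path(outDir, "metric_auc.csv"),
        row.names = FALSE, quote = FALSE)

    nPerm <- as.integer(cfg$permutations %||% 1000L)
    perm <- permuteGroups(te, range, settings, nPerm = nPerm, seed = seed)
    permTab <- do.call(rbind, lapply(perm, function(pr) rbind(
        data.frame(metric = pr@metric, density = pr@densities,
            observed_diff = pr@observed, band_lo = pr@bands[1, ],
            band_hi = pr@bands[2, ], p = pr@pDensity),
        data.frame(metric = pr@metric, density = NA_real_,
            observed_diff = pr@observedAUC, band_lo = NA_real_,
            band_hi = NA_real_, p = pr@pAUC))))
    rownames(permTab) <- NULL
    write.csv(permTab, file.path(outDir, "permutation_global.csv"),
        row.names = FALSE, quote = FALSE)

    nodalTab <- NULL
    if (isTRUE(cfg$nodal)) {
        nodalTab <- compareNodal(te, range, settings, nPerm = nPerm,
            seed = seed)
        write.csv(nodalTab, file.path(outDir, "nodal_permutation.csv"),
            row.names = FALSE, quote = FALSE)
    }

    hubs <- compareHubs(te, range, settings,
        hubDensity = cfg$hub$density %||% NULL,
        aggregate = cfg$hub$aggregate %||% "single")
    hubTab <- data.frame(
        group = rep(lev, vapply(hubs[lev], function(h)
            length(if (is(h, "HubSet")) hubRegions(h) else h), integer(1))),
        region = unlist(lapply(hubs[lev], function(h)
            if (is(h, "HubSet")) hubRegions(h) else h)))
    write.csv(hubTab, file.path(outDir, "hubs.csv"), row.names = FALSE,
        quote = FALSE)

    manifest <- list(
        package = "scnet",
        version = as.character(utils::packageVersion("scnet")),
        seed = seed, settings = unclass(settings),
        density = list(min = range@dMin, max = range@dMax,
            step = range@step),
        permutations = nPerm,
        groups = as.list(setNames(as.integer(table(group)[lev]), lev)),
        input = list(path = inputPath,
            md5 = unname(tools::md5sum(inputPath))),
        complete = TRUE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(experiment = te, range = range, curves = curves,
        permutation = perm, nodal = nodalTab, hubs = hubs,
        manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
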