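#' Construct a ThicknessExperiment from a subjects-by-regions matrix
#'
#' @param thickness numeric matrix, subjects in rows, regions in columns
#' @param group group label per subject (coerced to factor)
#' @param age age in years per subject
#' @param sex per-subject sex; any two-level coding is mapped to 0/1
#'   (first level after sorting = 0) and the mapping logged
#' @return a \linkS4class{ThicknessExperiment}
#' @export
ThicknessExperiment <- function(thickness, group, age, sex) {
    stopifnot(is.matrix(thickness), nrow(thickness) == length(group),
        length(age) == length(group), length(sex) == length(group))
    if (!all(sex %in% c(0, 1))) {
        lev <- sort(unique(as.character(sex)))
        if (length(lev) > 2)
            stop("sex must have at most two levels; found: ",
                paste(lev, collapse = ", "))
        message(sprintf("sex recoded: '%s' -> 0, '%s' -> 1",
            lev[1], lev[length(lev)]))
        sex <- as.integer(as.character(sex) == lev[length(lev)])
    }
    subj <- rownames(thickness)
    if (is.null(subj)) subj <- sprintf("sub_%03d", seq_len(nrow(thickness)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(thickness = t(thickness)),
        colData = S4Vectors::DataFrame(
            subject_id = subj, group = factor(group),
            age = as.numeric(age), sex = as.integer(sex),
            row.names = subj))
    new("ThicknessExperiment", se)
}

#' The 68-region Desikan-Killiany parcellation shipped with the package
#'
#' @return character vector of 68 region names (lh_/rh_ prefixed)
#' @export
dkRegions <- function() {
    readParcellation(system.file("extdata", "desikan_killiany_regions.txt",
        package = "scnet", mustWork = TRUE))
}

#' Read a parcellation file (one region name per line)
#'
#' @param path plain-text file, one region name per line; blank lines and
#'   lines starting with '#' are ignored
#' @return character vector of region names
#' @export
readParcellation <- function(path) {
    x <- trimws(readLines(path))
    x <- x[nzchar(x) & !startsWith(x, "#")]
    if (anyDuplicated(x)) stop("duplicated region names in parcellation file")
    x
}

#' Load a cortical-thickness table from a delimited text file
#'
#' Expects a header with columns \code{subject_id}, \code{group}, \code{age},
#' \code{sex} and one column per region of the declared parcellation. Region
#' columns are reordered to the parcellation internally; unknown extra
#' columns are ignored with a log message; rows with missing thickness are
#' dropped with a log message.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line)
#' @param parcellation character vector of expected region names
#'   (default: the packaged Desikan-Killiany list)
#' @return a \linkS4class{ThicknessExperiment}
#' @export
loadThickness <- function(path, parcellation = dkRegions()) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
    df <- read.delim(path, sep = sep, check.names = FALSE,
        stringsAsFactors = FALSE)
    required <- c("subject_id", "group", "age", "sex")
    missMeta <- setdiff(required, colnames(df))
    if (length(missMeta))
        stop("missing required columns: ", paste(missMeta, collapse = ", "))
    missRegions <- setdiff(parcellation, colnames(df))
    if (length(missRegions))
        stop("missing region columns: ", paste(missRegions, collapse = ", "))
    extra <- setdiff(colnames(df), c(required, parcellation))
    if (length(extra))
        message("ignoring unexpected columns: ", paste(extra, collapse = ", "))
    th <- df[, parcellation, drop = FALSE]
    bad <- !vapply(th, is.numeric, logical(1))
    if (any(bad)) {
        col <- parcellation[which(bad)[1]]
        row <- which(is.na(suppressWarnings(as.numeric(th[[col]]))))[1]
        stop(sprintf("non-numeric thickness in column '%s' (e.g. row %d)",
            col, row))
    }
    th <- as.matrix(th)
    rownames(th) <- as.character(df$subject_id)
    keep <- stats::complete.cases(th)
    if (!all(keep)) {
        message(sprintf("dropping %d row(s) with missing thickness: %s",
            sum(!keep), paste(rownames(th)[!keep], collapse = ", ")))
        th <- th[keep, , drop = FALSE]
        df <- df[keep, , drop = FALSE]
    }
    message(sprintf("loaded %d subjects x %d regions from %s",
        nrow(th), ncol(th), path))
    ThicknessExperiment(th, group = df$group, age = df$age, sex = df$sex)
}

#' Write a ThicknessExperiment as CSV
#'
#' Columns: subject_id, group, age, sex, then one column per region.
#'
#' @param x a \linkS4class{ThicknessExperiment}
#' @param path output CSV path
#' @return invisibly, the written data.frame
#' @export
writeThickness <- function(x, path) {
    cd <- SummarizedExperiment::colData(x)
    df <- data.frame(subject_id = cd$subject_id,
        group = as.character(cd$group), age = cd$age, sex = cd$sex,
        t(SummarizedExperiment::assay(x, "thickness")),
        check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(df)
}

#' @describeIn regions region names of a ThicknessExperiment
#' @export
setMethod("regions", "ThicknessExperiment", function(x) rownames(x))

#' @describeIn regions region names of a RegionCorrelation
#' @export
setMethod("regions", "RegionCorrelation", function(x) rownames(x@mat))

#' @describeIn regions region names of a BinaryNetwork
#' @export
setMethod("regions", "BinaryNetwork", function(x) rownames(x@adjacency))

#' @describeIn adjacency 0/1 adjacency matrix
#' @export
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)

#' @describeIn networkDensity edge density of the network
#' @export
setMethod("networkDensity", "BinaryNetwork", function(x) x@density)

#' @describeIn hubRegions hub region names
#' @export
setMethod("hubRegions", "HubSet", function(x) x@hubs)

setMethod("show", "BinaryNetwork", function(object) {
    n <- nrow(object@adjacency)
    cat(sprintf("BinaryNetwork: %d regions, %d edges (density %.3f)\n",
        n, sum(object@adjacency) / 2, object@density))
})

setMethod("show", "RegionCorrelation", function(object) {
    cat(sprintf("RegionCorrelation: %d regions, estimated from %d subjects\n",
        nrow(object@mat), object@nSubjects))
})

setMethod("show", "HubSet", function(object) {
    cat(sprintf("HubSet: %d hub(s) [betweenness >= %.3f = mean %.3f + 1.5 x SD %.3f]\n",
        length(object@hubs), object@threshold, object@mean, object@sd))
    if (length(object@hubs)) cat("  ", paste(object@hubs, collapse = ", "), "\n")
})

setMethod("show", "MetricCurves", function(object) {
    cat(sprintf("MetricCurves: %s over %d densities [%.2f, %.2f], groups %s vs %s\n",
        paste(unique(object$curves$metric), collapse = ", "),
        length(object@densities), min(object@densities), max(object@densities),
        object@groups[1], object@groups[2]))
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf("PermutationResult: %s, %d permutations (seed %d)\n",
        object@metric, object@nPerm, object@seed))
    cat(sprintf("  AUC difference (group1 - group2): %.4g, p = %.4g\n",
        object@observedAUC, object@pAUC))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf("SyntheticSpec: %d regions, groups %d/%d, %d blocks, within r %.2f/%.2f, between r %.2f/%.2f, seed %d\n",
        object@nRegions, object@groupSizes[1], object@groupSizes[2],
        length(unique(object@blockPartition)),
        object@withinBlockR[1], object@withinBlockR[2],
        object@betweenBlockR[1], object@betweenBlockR[2], object@seed))
})

#' @describeIn MetricCurves extract slots by name with \code{$}
#' @param x,name slot access
#' @export
setMethod("$", "MetricCurves", function(x, name) slot(x, name))

#' @describeIn PermutationResult extract slots by name with \code{$}
#' @param x,name slot access
#' @export
setMethod("$", "PermutationResult", function(x, name) slot(x, name))
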