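# Fast OLS residualization of a subjects-by-regions block against
# [1, age, sex, global mean thickness]. Errors on rank-deficient designs,
# naming the offending column.
.residualizeMatrix <- function(Y, age, sex) {
    gmt <- rowMeans(Y)
    # an (effectively) constant global mean carries no information and would
    # otherwise be pure numerical noise in the design, e.g. when the input is
    # already residualized
    if (sd(gmt) <= 1e-8 * mean(abs(Y)))
        X <- cbind(intercept = 1, age = age, sex = sex)
    else
        X <- cbind(intercept = 1, age = age, sex = sex, global_mean = gmt)
    if (nrow(X) < ncol(X) + 1L)
        stop(sprintf("at least %d subjects are required to fit %d regression parameters",
            ncol(X) + 1L, ncol(X)))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        # global mean thickness is derived from the outcomes; when it carries
        # no information beyond the other covariates (e.g. thickness exactly
        # linear in them, or already-residualized input) it is simply dropped.
        # Degenerate age/sex are a data error.
        if (!all(aliased == "global_mean"))
            stop("rank-deficient design; collinear column(s): ",
                paste(setdiff(aliased, "global_mean"), collapse = ", "))
        qrX <- qr(X[, colnames(X) != "global_mean", drop = FALSE])
        if (qrX$rank < 3L)
            stop("rank-deficient design; collinear column(s): age, sex")
    }
    res <- qr.resid(qrX, Y)
    dimnames(res) <- dimnames(Y)
    res
}

#' @describeIn residualize OLS residuals of regional thickness against age,
#'   sex and the subject's global mean thickness (the unweighted mean over
#'   regions), fitted per region. With \code{scope = "per-group"} (default)
#'   the regression is fitted within each group separately, matching the
#'   group-wise network construction; \code{"pooled"} fits one model over all
#'   subjects. Residuals ("corrected cortical thickness") are what enter the
#'   correlation matrix.
#' @param scope \code{"per-group"} or \code{"pooled"}
#' @return numeric matrix, subjects by regions, of regression residuals;
#'   attribute \code{scope} records the scope used
#' @export
setMethod("residualize", "ThicknessExperiment",
    function(x, scope = c("per-group", "pooled")) {
        scope <- match.arg(scope)
        Y <- t(SummarizedExperiment::assay(x, "thickness"))
        cd <- SummarizedExperiment::colData(x)
        res <- .residualizeGroups(Y, as.character(cd$group), cd$age, cd$sex,
            perGroup = scope == "per-group")
        attr(res, "scope") <- scope
        res
    })

# Shared by residualize() and the permutation engine, where pseudo-group
# labels replace the observed ones.
.residualizeGroups <- function(Y, group, age, sex, perGroup = TRUE) {
    if (!perGroup)
        return(.residualizeMatrix(Y, age, sex))
    res <- Y
    for (g in unique(group)) {
        i <- which(group == g)
        res[i, ] <- .residualizeMatrix(Y[i, , drop = FALSE], age[i], sex[i])
    }
    res
}
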