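smallCohort <- function(seed = 31, n = c(25, 25), ...) {
    generateCohort(syntheticSpec(groupSizes = n, seed = seed, ...))
}

test_that("AUC of constant and linear curves is exact", {
    d <- seq(0.15, 0.40, by = 0.05)
    expect_equal(aucTrapezoid(d, rep(3, length(d))), 3 * 0.25)
    # trapezoid is exact for linear curves
    y <- 2 + 4 * d
    expect_equal(aucTrapezoid(d, y), 2 * 0.25 + 2 * (0.4^2 - 0.15^2),
        tolerance = 1e-12)
    expect_true(is.na(aucTrapezoid(d, c(1, NA, 1, 1, 1, 1))))
})

test_that("trapezoid AUC agrees with fine-grid integration within its error bound", {
    f <- function(d) sin(8 * d) + d^2
    coarse <- seq(0.15, 0.40, by = 0.01)
    fine <- seq(0.15, 0.40, by = 0.001)
    aucC <- aucTrapezoid(coarse, f(coarse))
    aucF <- aucTrapezoid(fine, f(fine))
    # trapezoid error is O(h^2 (b-a) max|f''| / 12); bound for h = 0.01,
    # max|f''| = 64
    expect_lt(abs(aucC - aucF), 0.01^2 * 0.25 * 64 / 12)
})

test_that("metric curves reproduce per-density recomputation and AUC", {
    te <- smallCohort()
    rng <- densityRange(0.15, 0.40, 0.05)
    st <- scnSettings(metrics = c("Cp", "Lp", "Q"))
    mc <- metricCurves(te, rng, st, seed = 3)
    # Cp curve for group1 equals direct recomputation through the public ops
    res <- residualize(te)
    grp <- SummarizedExperiment::colData(te)$group
    R1 <- correlationMatrix(res[grp == "group1", ])
    for (d in c(0.15, 0.30)) {
        net <- thresholdAtDensity(R1, d)
        v <- subset(mc$curves, metric == "Cp" & group == "group1" &
            abs(density - d) < 1e-9)$value
        expect_equal(v, clusteringCoefficient(net)$network, tolerance = 1e-12)
    }
    a <- subset(mc$auc, metric == "Cp" & group == "group1")$auc
    y <- subset(mc$curves, metric == "Cp" & group == "group1")$value
    expect_equal(a, aucTrapezoid(mc$densities, y), tolerance = 1e-12)
})

test_that("permutation results are deterministic under a fixed seed", {
    te <- smallCohort(seed = 32)
    rng <- densityRange(0.2, 0.4, 0.1)
    st <- scnSettings(metrics = c("Cp", "Lp"))
    p1 <- permuteGroups(te, rng, st, nPerm = 30, seed = 5)
    p2 <- permuteGroups(te, rng, st, nPerm = 30, seed = 5)
    expect_identical(p1$Cp@pAUC, p2$Cp@pAUC)
    expect_identical(p1$Lp@nullDensity, p2$Lp@nullDensity)
    p3 <- permuteGroups(te, rng, st, nPerm = 30, seed = 6)
    expect_false(identical(p1$Cp@nullAUC, p3$Cp@nullAUC))
})

test_that("observed differences reproduce the metric-curves values", {
    te <- smallCohort(seed = 33)
    rng <- densityRange(0.2, 0.4, 0.1)
    st <- scnSettings(metrics = c("Cp", "Q"))
    mc <- metricCurves(te, rng, st, seed = 4)
    pr <- permuteGroups(te, rng, st, nPerm = 10, seed = 4)
    for (m in c("Cp", "Q")) {
        v1 <- subset(mc$curves, metric == m & group == "group1")$value
        v2 <- subset(mc$curves, metric == m & group == "group2")$value
        expect_equal(unname(pr[[m]]@observed), v1 - v2, tolerance = 1e-12)
        a <- subset(mc$auc, metric == m)
        expect_equal(pr[[m]]@observedAUC,
            a$auc[a$group == "group1"] - a$auc[a$group == "group2"],
            tolerance = 1e-12)
    }
})

test_that("p-values use the add-one rule and lie in (0, 1]", {
    te <- smallCohort(seed = 34)
    rng <- densityRange(0.2, 0.3, 0.1)
    st <- scnSettings(metrics = "Cp")
    pr <- permuteGroups(te, rng, st, nPerm = 19, seed = 7)
    b <- sum(abs(pr$Cp@nullAUC) >= abs(pr$Cp@observedAUC))
    expect_equal(pr$Cp@pAUC, (b + 1) / 20)
    expect_true(pr$Cp@pAUC > 0 && pr$Cp@pAUC <= 1)
})

test_that("p-values are invariant to swapping the group labels", {
    te <- smallCohort(seed = 35, n = c(15, 20))
    cd <- SummarizedExperiment::colData(te)
    sw <- ThicknessExperiment(t(SummarizedExperiment::assay(te, "thickness")),
        group = factor(ifelse(cd$group == "group1", "group2", "group1"),
            levels = c("group1", "group2")),
        age = cd$age, sex = cd$sex)
    rng <- densityRange(0.2, 0.4, 0.1)
    st <- scnSettings(metrics = "Cp")
    p1 <- permuteGroups(te, rng, st, nPerm = 50, seed = 8)
    p2 <- permuteGroups(sw, rng, st, nPerm = 50, seed = 8)
    expect_equal(p1$Cp@observedAUC, -p2$Cp@observedAUC, tolerance = 1e-12)
    expect_identical(p1$Cp@pAUC, p2$Cp@pAUC)
})

test_that("the null distribution of AUC differences is symmetric about 0", {
    te <- smallCohort(seed = 36)
    rng <- densityRange(0.2, 0.4, 0.1)
    pr <- permuteGroups(te, rng, scnSettings(metrics = "Cp"), nPerm = 200,
        seed = 9)
    nullAUC <- pr$Cp@nullAUC
    skew <- mean((nullAUC - mean(nullAUC))^3) / sd(nullAUC)^3
    expect_lt(abs(skew), 0.6)
    expect_lt(abs(mean(nullAUC)) / sd(nullAUC), 0.3)
})

test_that("zero permutations are rejected", {
    te <- smallCohort(seed = 37)
    rng <- densityRange(0.2, 0.3, 0.1)
    expect_error(permuteGroups(te, rng, nPerm = 0), "at least 1")
    expect_error(compareNodal(te, rng, nPerm = 0), "at least 1")
})

test_that("nodal comparison returns calibrated-looking uncorrected p-values", {
    te <- smallCohort(seed = 38, n = c(20, 20))
    rng <- densityRange(0.2, 0.4, 0.1)
    nod <- compareNodal(te, rng, scnSettings(metrics = "Cp"), nPerm = 60,
        seed = 10)
    expect_setequal(unique(nod$metric), c("degree", "clustering", "betweenness"))
    expect_identical(nrow(nod), 3L * 68L)
    expect_true(all(nod$p_auc > 0 & nod$p_auc <= 1))
    expect_true(all(nod$p_auc_bh >= nod$p_auc - 1e-12))
})

test_that("identical groups give identical hub sets", {
    # same covariance spec and deterministic pipeline: duplicate the
    # group-1 subjects into both groups
    te <- smallCohort(seed = 39, n = c(30, 30))
    th <- t(SummarizedExperiment::assay(te, "thickness"))
    cd <- SummarizedExperiment::colData(te)
    i1 <- which(cd$group == "group1")
    thDup <- rbind(th[i1, ], th[i1, ])
    rownames(thDup) <- NULL
    dup <- ThicknessExperiment(thDup,
        group = rep(c("group1", "group2"), each = length(i1)),
        age = rep(cd$age[i1], 2), sex = rep(cd$sex[i1], 2))
    rng <- densityRange(0.2, 0.4, 0.1)
    hubs <- compareHubs(dup, rng)
    expect_identical(hubRegions(hubs$group1), hubRegions(hubs$group2))
    expect_identical(hubs$group1_only, character(0))
    expect_identical(hubs$group2_only, character(0))
})

test_that("a zero-SD betweenness group yields an empty hub set, not an error", {
    hs <- detectHubs(setNames(rep(2, 5), paste0("r", 1:5)))
    expect_identical(hubRegions(hs), character(0))
})
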