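test_that("closed-form values on canonical small graphs", {
    K3 <- netFromAdj(k3()); P3 <- netFromAdj(p3())
    S4g <- netFromAdj(starGraph(4)); K4 <- netFromAdj(k4())
    # triangle: everything saturates
    expect_equal(clusteringCoefficient(K3)$network, 1)
    expect_equal(characteristicPathLength(K3), 1)
    expect_equal(globalEfficiency(K3), 1)
    expect_equal(networkTransitivity(K3), 1)
    # path P3
    expect_equal(clusteringCoefficient(P3)$network, 0)
    expect_equal(characteristicPathLength(P3), 4 / 3)
    expect_equal(globalEfficiency(P3), 5 / 6)
    expect_equal(unname(betweennessCentrality(P3)), c(0, 1, 0))
    # star S4: 4 leaves
    b <- betweennessCentrality(S4g)
    expect_equal(unname(b[1]), choose(4, 2))
    expect_equal(unname(b[-1]), rep(0, 4))
    expect_equal(localEfficiency(S4g)$network, 0)
    expect_equal(networkTransitivity(S4g), 0)
    # complete graphs
    expect_equal(localEfficiency(K4)$network, 1)
    expect_warning(networkTransitivity(netFromAdj(adjFromEdges(3,
        list(c(1, 2))))), "no connected triples")
})

test_that("two disconnected edges give Eglob = 2/6", {
    net <- netFromAdj(adjFromEdges(4, list(c(1, 2), c(3, 4))))
    expect_equal(globalEfficiency(net), 2 / 6)
})

test_that("metrics match brute-force oracles on random small graphs", {
    set.seed(101)
    for (i in 1:30) {
        n <- sample(4:10, 1)
        A <- randomAdj(n, runif(1, 0.2, 0.7))
        net <- netFromAdj(A)
        expect_equal(clusteringCoefficient(net)$node,
            setNames(oracleClustering(A)$node, rownames(A)), tolerance = 1e-12)
        expect_equal(globalEfficiency(net), oracleGlobalEfficiency(A),
            tolerance = 1e-12)
        if (n <= 8)
            expect_equal(localEfficiency(net)$network,
                oracleLocalEfficiency(A)$network, tolerance = 1e-12)
        expect_equal(unname(betweennessCentrality(net)), oracleBetweenness(A),
            tolerance = 1e-10)
        if (sum(A) > 0)
            expect_equal(characteristicPathLength(net), oraclePathLength(A),
                tolerance = 1e-12)
        tr <- suppressWarnings(networkTransitivity(net))
        expect_equal(tr, oracleTransitivity(A), tolerance = 1e-12)
    }
})

test_that("metrics are invariant under node relabeling", {
    set.seed(7)
    A <- randomAdj(9, 0.4)
    perm <- sample(9)
    B <- A[perm, perm]
    n1 <- netFromAdj(A); n2 <- netFromAdj(B)
    expect_equal(clusteringCoefficient(n1)$network,
        clusteringCoefficient(n2)$network)
    expect_equal(characteristicPathLength(n1), characteristicPathLength(n2))
    expect_equal(globalEfficiency(n1), globalEfficiency(n2))
    expect_equal(sort(unname(betweennessCentrality(n1))),
        sort(unname(betweennessCentrality(n2))))
})

test_that("Eglob >= 1/Lp on connected graphs (harmonic-arithmetic inequality)", {
    set.seed(33)
    done <- 0
    while (done < 10) {
        A <- randomAdj(10, 0.5)
        if (!all(is.finite(oracleDistances(A)))) next
        net <- netFromAdj(A)
        expect_gte(globalEfficiency(net), 1 / characteristicPathLength(net))
        done <- done + 1
    }
})

test_that("modularity: exhaustive search agrees on 6-node graphs", {
    two <- netFromAdj(twoTriangles())
    res <- modularityQ(two, seed = 4)
    expect_equal(res$Q, 0.5)
    expect_equal(oracleBestQ(twoTriangles()), 0.5)
    expect_identical(length(unique(res$membership)), 2L)
    expect_identical(unname(res$membership[1:3]),
        rep(unname(res$membership[1]), 3))
    # complete graph: no partition beats one module
    K5 <- netFromAdj(completeGraph(5))
    expect_equal(modularityQ(K5, seed = 4)$Q, 0)
    expect_equal(oracleBestQ(completeGraph(5)), 0)
    # determinism
    set.seed(77); r1 <- modularityQ(two, seed = 9)
    set.seed(123); r2 <- modularityQ(two, seed = 9)
    expect_identical(r1, r2)
    expect_error(modularityQ(netFromAdj(matrix(0, 3, 3))), "at least one edge")
})

test_that("nodal metrics normalize to mean 1 and degrees sum to 2E", {
    set.seed(10)
    A <- randomAdj(12, 0.4)
    nm <- nodalMetrics(netFromAdj(A))
    expect_equal(sum(nm$degree), sum(A))
    expect_equal(mean(nm$degree_norm), 1)
    expect_equal(mean(nm$clustering_norm), 1)
    expect_equal(mean(nm$betweenness_norm), 1)
    expect_equal(nm$degree, unname(oracleDegree(A)))
    # all-zero betweenness stays defined
    nm2 <- nodalMetrics(netFromAdj(adjFromEdges(4, list(c(1, 2), c(3, 4)))))
    expect_identical(nm2$betweenness_norm, rep(0, 4))
})

test_that("rewired ensembles preserve the degree sequence", {
    set.seed(11)
    A <- randomAdj(15, 0.3)
    net <- netFromAdj(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    set.seed(12)
    for (i in 1:10) {
        gr <- igraph::rewire(g,
            igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
        expect_identical(igraph::degree(gr), igraph::degree(g))
    }
    ens <- matchRandomEnsemble(net, nRandom = 10, seed = 13)
    expect_length(ens@cpRand, 10)
    expect_true(all(is.finite(ens@cpRand)))
})

test_that("a triangle is rigid under rewiring: ensemble equals the source", {
    net <- netFromAdj(k3())
    ens <- matchRandomEnsemble(net, nRandom = 5, seed = 14)
    expect_identical(ens@cpRand, rep(1, 5))
    expect_identical(ens@lpRand, rep(1, 5))
    sw <- smallWorld(net, ens)
    expect_equal(unname(sw), c(1, 1, 1))
})

test_that("ring lattices are more clustered than degree-matched random graphs", {
    net <- netFromAdj(ringLattice(20, 4))
    ens <- matchRandomEnsemble(net, nRandom = 20, seed = 15)
    sw <- smallWorld(net, ens)
    expect_gt(sw["gamma"], 1)
    expect_gte(sw["lambda"], 1)
    expect_equal(unname(sw["sigma"]), unname(sw["gamma"] / sw["lambda"]),
        tolerance = 1e-12)
})

test_that("hub detection follows the mean + 1.5 SD betweenness rule", {
    # star S10: the centre concentrates all shortest paths
    hs <- detectHubs(netFromAdj(starGraph(10)))
    expect_identical(hubRegions(hs), "v1")
    b <- hs@betweenness
    m <- mean(b); s <- sqrt(mean((b - m)^2))
    expect_equal(hs@threshold, m + 1.5 * s)
    expect_gte(b["v1"], hs@threshold)
    # regular graph: SD = 0, no hubs rather than all hubs
    expect_identical(hubRegions(detectHubs(netFromAdj(completeGraph(6)))),
        character(0))
    # P3 by hand: betweenness {0, 1, 0}; threshold = 1/3 + 1.5 * 0.4714 > 1
    hsP3 <- detectHubs(netFromAdj(p3()))
    expect_equal(hsP3@threshold, 1 / 3 + 1.5 * sqrt(2 / 9))
    expect_identical(hubRegions(hsP3), character(0))
})

test_that("globalMetrics bundles all parameters and sigma = gamma/lambda", {
    set.seed(16)
    A <- randomAdj(20, 0.3)
    net <- netFromAdj(A)
    ens <- matchRandomEnsemble(net, nRandom = 10, seed = 17)
    gm <- globalMetrics(net, ensemble = ens, seed = 18)
    expect_named(gm, c("Cp", "Lp", "Eglob", "Eloc", "transitivity", "Q",
        "gamma", "lambda", "sigma"))
    expect_true(all(gm[c("Cp", "Eglob", "Eloc", "transitivity")] >= 0 &
        gm[c("Cp", "Eglob", "Eloc", "transitivity")] <= 1))
    expect_gte(gm["Lp"], 1)
    expect_equal(unname(gm["sigma"]), unname(gm["gamma"] / gm["lambda"]),
        tolerance = 1e-12)
})
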