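#' Nodal and network clustering coefficient
#'
#' Node value: existing edges among the node's neighbors divided by
#' \code{k(k-1)/2}; nodes with degree < 2 score 0. Network value: unweighted
#' mean over all nodes (a segregation measure).
#'
#' @param net a \linkS4class{BinaryNetwork} (or 0/1 adjacency matrix)
#' @return list with \code{node} (named vector) and \code{network} (scalar)
#' @export
clusteringCoefficient <- function(net) {
    g <- .asIgraph(net)
    node <- igraph::transitivity(g, type = "localundirected",
        isolates = "zero")
    names(node) <- igraph::V(g)$name
    list(node = node, network = mean(node))
}

#' Characteristic path length
#'
#' Mean shortest-path edge count over connected, distinct node pairs;
#' disconnected pairs are excluded from the average (an integration measure).
#'
#' @inheritParams clusteringCoefficient
#' @return scalar path length (>= 1 on nonempty graphs)
#' @export
characteristicPathLength <- function(net) {
    g <- .asIgraph(net)
    if (igraph::ecount(g) == 0L)
        stop("characteristic path length is undefined on a graph with no edges")
    igraph::mean_distance(g, unconnected = TRUE)
}

#' Global efficiency
#'
#' Mean over distinct node pairs of the inverse shortest path length, with
#' disconnected pairs contributing 0 (inverse of the harmonic mean of
#' shortest path lengths).
#'
#' @inheritParams clusteringCoefficient
#' @export
globalEfficiency <- function(net) {
    g <- .asIgraph(net)
    if (igraph::vcount(g) < 2L) return(0)
    d <- igraph::distances(g)
    inv <- 1 / d[upper.tri(d)]
    mean(ifelse(is.finite(inv), inv, 0))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its direct
#' neighbors (the node itself excluded); nodes with degree < 2 score 0.
#' Network value: mean over nodes.
#'
#' @inheritParams clusteringCoefficient
#' @return list with \code{node} and \code{network}
#' @export
localEfficiency <- function(net) {
    g <- .asIgraph(net)
    n <- igraph::vcount(g)
    node <- vapply(seq_len(n), function(v) {
        nb <- as.integer(igraph::neighbors(g, v))
        if (length(nb) < 2L) return(0)
        globalEfficiency(igraph::as_adjacency_matrix(
            igraph::induced_subgraph(g, nb), sparse = FALSE))
    }, numeric(1))
    names(node) <- igraph::V(g)$name
    list(node = node, network = mean(node))
}

#' Transitivity (whole-network triangle density)
#'
#' 3 x triangles / connected triples. Unlike the clustering coefficient this
#' is normalized at the network level and is insensitive to low-degree nodes.
#' A graph with no connected triples yields 0 with a warning.
#'
#' @inheritParams clusteringCoefficient
#' @export
networkTransitivity <- function(net) {
    g <- .asIgraph(net)
    t <- igraph::transitivity(g, type = "global")
    if (is.nan(t)) {
        warning("no connected triples; transitivity reported as 0")
        t <- 0
    }
    t
}

#' Newman modularity via seeded multi-restart Louvain
#'
#' Runs the Louvain community-detection heuristic \code{restarts} times under
#' a seeded RNG and reports the maximum modularity Q together with the
#' corresponding partition. Fixed graph + fixed seed gives identical results
#' across runs.
#'
#' @inheritParams clusteringCoefficient
#' @param seed RNG seed
#' @param restarts number of Louvain restarts (default 5)
#' @return list with \code{Q} and \code{membership} (named integer vector)
#' @export
modularityQ <- function(net, seed = 1L, restarts = 5L) {
    g <- .asIgraph(net)
    if (igraph::ecount(g) == 0L)
        stop("modularity requires at least one edge")
    set.seed(seed)
    best <- NULL
    for (i in seq_len(restarts)) {
        cl <- igraph::cluster_louvain(g)
        q <- igraph::modularity(cl)
        if (is.null(best) || q > best$Q)
            best <- list(Q = q, membership = igraph::membership(cl))
    }
    names(best$membership) <- igraph::V(g)$name
    best
}

#' Nodal betweenness centrality
#'
#' Number of shortest paths between all other node pairs passing through each
#' node, with fractional credit split among equal-length shortest paths.
#'
#' @inheritParams clusteringCoefficient
#' @return named numeric vector
#' @export
betweennessCentrality <- function(net) {
    g <- .asIgraph(net)
    b <- igraph::betweenness(g, directed = FALSE)
    names(b) <- igraph::V(g)$name
    b
}

#' Nodal metrics table
#'
#' Degree, clustering coefficient and betweenness centrality per region, each
#' also divided by its network-wide mean ("normalized"; zeros when the
#' network mean is zero so the values stay defined).
#'
#' @inheritParams clusteringCoefficient
#' @return data.frame: region, degree, clustering, betweenness and their
#'   \code{*_norm} counterparts
#' @export
nodalMetrics <- function(net) {
    g <- .asIgraph(net)
    deg <- igraph::degree(g)
    cc <- clusteringCoefficient(net)$node
    btw <- betweennessCentrality(net)
    normBy <- function(x) if (mean(x) == 0) x * 0 else x / mean(x)
    data.frame(region = regions(net), degree = as.numeric(deg),
        clustering = as.numeric(cc), betweenness = as.numeric(btw),
        degree_norm = normBy(as.numeric(deg)),
        clustering_norm = normBy(as.numeric(cc)),
        betweenness_norm = normBy(as.numeric(btw)),
        row.names = NULL)
}

#' Degree-matched random network ensemble
#'
#' Generates \code{nRandom} degree-preserving randomizations of the source
#' network by edge swapping (each member attempts
#' \code{rewiresPerEdge * E} swaps) and stores each member's clustering
#' coefficient and characteristic path length for small-world normalization.
#' Rigid graphs with no admissible swaps (e.g. a triangle) yield members
#' equal to the source.
#'
#' @inheritParams clusteringCoefficient
#' @param nRandom ensemble size (default 100)
#' @param rewiresPerEdge attempted swaps per edge (default 10)
#' @param seed RNG seed
#' @return a \linkS4class{RandomEnsemble}
#' @export
matchRandomEnsemble <- function(net, nRandom = 100L, rewiresPerEdge = 10L,
        seed = 1L) {
    g <- .asIgraph(net)
    set.seed(seed)
    sums <- .ensembleSummaries(g, nRandom, rewiresPerEdge)
    new("RandomEnsemble", nRandom = as.integer(nRandom),
        rewiresPerEdge = as.integer(rewiresPerEdge), seed = as.integer(seed),
        cpRand = sums$cp, lpRand = sums$lp)
}

# Hot-path ensemble: assumes RNG already seeded by the caller.
.ensembleSummaries <- function(g, nRandom, rewiresPerEdge) {
    niter <- max(1L, rewiresPerEdge * igraph::ecount(g))
    cp <- lp <- numeric(nRandom)
    for (i in seq_len(nRandom)) {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
        cp[i] <- mean(igraph::transitivity(gr, type = "localundirected",
            isolates = "zero"))
        lp[i] <- igraph::mean_distance(gr, unconnected = TRUE)
    }
    list(cp = cp, lp = lp)
}

#' Small-world indices against a matched random ensemble
#'
#' gamma = Cp / mean(Cp_rand), lambda = Lp / mean(Lp_rand),
#' sigma = gamma / lambda. sigma > 1 indicates small-world organisation
#' (more clustered than random at comparable path length).
#'
#' @inheritParams clusteringCoefficient
#' @param ensemble a \linkS4class{RandomEnsemble} from
#'   \code{\link{matchRandomEnsemble}}
#' @return named numeric vector: gamma, lambda, sigma
#' @export
smallWorld <- function(net, ensemble) {
    cpR <- mean(ensemble@cpRand)
    lpR <- mean(ensemble@lpRand)
    if (cpR <= 0 || lpR <= 0)
        stop("ensemble mean clustering/path length must be positive")
    gamma <- clusteringCoefficient(net)$network / cpR
    lambda <- characteristicPathLength(net) / lpR
    c(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Detect network hubs by betweenness centrality
#'
#' A region is a hub when its betweenness centrality is at least 1.5
#' population standard deviations above the network mean (inclusive cutoff).
#' When the SD is zero no region stands out and the hub set is empty.
#'
#' @param x a \linkS4class{BinaryNetwork} or a named betweenness vector
#' @param k SD multiplier (default 1.5)
#' @return a \linkS4class{HubSet}
#' @export
detectHubs <- function(x, k = 1.5) {
    b <- if (is(x, "BinaryNetwork")) betweennessCentrality(x) else x
    if (length(b) < 2L) stop("at least 2 nodes are required")
    m <- mean(b)
    s <- sqrt(mean((b - m)^2))
    thr <- m + k * s
    hubs <- if (s > 0) names(b)[b >= thr] else character()
    new("HubSet", hubs = hubs, betweenness = b, mean = m, sd = s,
        threshold = thr)
}

#' All global network parameters at one density
#'
#' @inheritParams clusteringCoefficient
#' @param ensemble optional \linkS4class{RandomEnsemble}; when supplied,
#'   gamma, lambda and sigma are included
#' @param seed,restarts passed to \code{\link{modularityQ}}
#' @return named numeric vector: Cp, Lp, Eglob, Eloc, transitivity, Q and
#'   optionally gamma, lambda, sigma
#' @export
globalMetrics <- function(net, ensemble = NULL, seed = 1L, restarts = 5L) {
    out <- c(Cp = clusteringCoefficient(net)$network,
        Lp = characteristicPathLength(net),
        Eglob = globalEfficiency(net),
        Eloc = localEfficiency(net)$network,
        transitivity = networkTransitivity(net),
        Q = modularityQ(net, seed = seed, restarts = restarts)$Q)
    if (!is.null(ensemble)) out <- c(out, smallWorld(net, ensemble))
    out
}
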