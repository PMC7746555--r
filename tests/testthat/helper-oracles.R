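# Brute-force graph-metric oracles, written from first principles on the
# adjacency matrix. Independent of the package's igraph-backed path; only
# usable on small graphs.

oracleDegree <- function(A) rowSums(A)

# Floyd-Warshall all-pairs shortest path lengths.
oracleDistances <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n)
    D[A == 1] <- 1
    diag(D) <- 0
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (D[i, k] + D[k, j] < D[i, j])
                    D[i, j] <- D[i, k] + D[k, j]
    D
}

oracleClustering <- function(A) {
    n <- nrow(A)
    node <- numeric(n)
    for (v in seq_len(n)) {
        nb <- which(A[v, ] == 1)
        k <- length(nb)
        if (k < 2) next
        e <- 0
        for (a in seq_along(nb))
            for (b in seq_along(nb))
                if (a < b && A[nb[a], nb[b]] == 1) e <- e + 1
        node[v] <- e / (k * (k - 1) / 2)
    }
    list(node = node, network = mean(node))
}

oraclePathLength <- function(A) {
    D <- oracleDistances(A)
    d <- D[upper.tri(D)]
    mean(d[is.finite(d)])
}

oracleGlobalEfficiency <- function(A) {
    D <- oracleDistances(A)
    inv <- 1 / D[upper.tri(D)]
    mean(ifelse(is.finite(inv), inv, 0))
}

oracleLocalEfficiency <- function(A) {
    n <- nrow(A)
    node <- numeric(n)
    for (v in seq_len(n)) {
        nb <- which(A[v, ] == 1)
        if (length(nb) < 2) next
        node[v] <- oracleGlobalEfficiency(A[nb, nb, drop = FALSE])
    }
    list(node = node, network = mean(node))
}

oracleTransitivity <- function(A) {
    n <- nrow(A)
    tri <- 0
    triples <- 0
    for (v in seq_len(n)) {
        nb <- which(A[v, ] == 1)
        k <- length(nb)
        if (k < 2) next
        triples <- triples + k * (k - 1) / 2
        for (a in seq_along(nb))
            for (b in seq_along(nb))
                if (a < b && A[nb[a], nb[b]] == 1) tri <- tri + 1
    }
    if (triples == 0) return(0)
    # each triangle counted once per corner vertex = 3 corner-pairs total
    tri / triples
}

# Number of shortest s->t paths for every pair, by DP over BFS layers.
oracleBetweenness <- function(A) {
    n <- nrow(A)
    D <- oracleDistances(A)
    npaths <- function(s) {
        cnt <- numeric(n)
        cnt[s] <- 1
        for (dist in seq_len(n)) {
            layer <- which(D[s, ] == dist)
            for (t in layer)
                cnt[t] <- sum(cnt[which(A[, t] == 1 & D[s, ] == dist - 1)])
        }
        cnt
    }
    cnt <- t(vapply(seq_len(n), npaths, numeric(n)))  # cnt[s, t]
    btw <- numeric(n)
    for (v in seq_len(n))
        for (s in seq_len(n))
            for (t in seq_len(n))
                if (s < t && s != v && t != v && is.finite(D[s, t]) &&
                    D[s, v] + D[v, t] == D[s, t])
                    btw[v] <- btw[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
    btw
}

# All set partitions of 1..n (for exhaustive modularity search).
allPartitions <- function(n) {
    if (n == 1) return(list(list(1L)))
    out <- list()
    for (p in allPartitions(n - 1)) {
        for (b in seq_along(p)) {
            q <- p
            q[[b]] <- c(q[[b]], n)
            out[[length(out) + 1L]] <- q
        }
        out[[length(out) + 1L]] <- c(p, list(n))
    }
    out
}

oracleNewmanQ <- function(A, membership) {
    m <- sum(A) / 2
    deg <- rowSums(A)
    q <- 0
    n <- nrow(A)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (membership[i] == membership[j])
                q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
    q / (2 * m)
}

oracleBestQ <- function(A) {
    n <- nrow(A)
    best <- -Inf
    for (p in allPartitions(n)) {
        mem <- integer(n)
        for (b in seq_along(p)) mem[p[[b]]] <- b
        best <- max(best, oracleNewmanQ(A, mem))
    }
    best
}

# Named small graphs as adjacency matrices.
adjFromEdges <- function(n, edges) {
    A <- matrix(0, n, n)
    for (e in edges) {
        A[e[1], e[2]] <- 1
        A[e[2], e[1]] <- 1
    }
    dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
    A
}

k3 <- function() adjFromEdges(3, list(c(1,2), c(1,3), c(2,3)))
p3 <- function() adjFromEdges(3, list(c(1,2), c(2,3)))
starGraph <- function(nLeaves) adjFromEdges(nLeaves + 1,
    lapply(seq_len(nLeaves) + 1, function(l) c(1, l)))
k4 <- function() adjFromEdges(4,
    list(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4)))
completeGraph <- function(n) {
    A <- matrix(1, n, n); diag(A) <- 0
    dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
    A
}
twoTriangles <- function() adjFromEdges(6,
    list(c(1,2), c(1,3), c(2,3), c(4,5), c(4,6), c(5,6)))
ringLattice <- function(n, k) {
    A <- matrix(0, n, n)
    for (i in seq_len(n))
        for (s in seq_len(k / 2)) {
            j <- ((i - 1 + s) %% n) + 1
            A[i, j] <- A[j, i] <- 1
        }
    dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
    A
}

randomAdj <- function(n, p = 0.4) {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
    A <- A + t(A)
    dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
    A
}

# BinaryNetwork from a raw adjacency matrix (bypasses thresholding).
netFromAdj <- function(A) {
    n <- nrow(A)
    methods::new("BinaryNetwork", adjacency = A,
        density = sum(A) / 2 / (n * (n - 1) / 2))
}
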