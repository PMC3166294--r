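# Fixtures built in code and independent oracles used across test files.

# barbell graph: two triangles {a1,a2,a3}, {b1,b2,b3} joined by edge a1-b1
barbellNetwork <- function() {
    GeneNetwork(data.frame(
        a = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
        b = c("a2", "a3", "a3", "b2", "b3", "b3", "b1")))
}

# random propagation instance built directly from matrices
randomInstance <- function(nd, ng, seed, pEdge = 0.1, pSim = 0.3,
                           pAssoc = 0.15, theta = 0.5) {
    set.seed(seed)
    gn <- sprintf("g%02d", seq_len(ng))
    dn <- sprintf("d%02d", seq_len(nd))
    A <- matrix(0, ng, ng, dimnames = list(gn, gn))
    A[upper.tri(A)] <- stats::rbinom(sum(upper.tri(A)), 1, pEdge)
    A <- A + t(A)
    diag(A) <- 1
    net <- new("GeneNetwork", genes = gn,
               adjacency = Matrix::Matrix(A, sparse = TRUE),
               selfLoopsAdded = TRUE)
    S <- matrix(0, nd, nd, dimnames = list(dn, dn))
    vals <- stats::runif(sum(upper.tri(S)), theta, 1) *
        stats::rbinom(sum(upper.tri(S)), 1, pSim)
    S[upper.tri(S)] <- vals
    S <- S + t(S)
    diag(S) <- 1
    sim <- new("DiseaseSimilarityNetwork", diseases = dn, similarity = S,
               theta = theta)
    pairs <- expand.grid(disease = dn, gene = gn, stringsAsFactors = FALSE)
    assoc <- pairs[stats::runif(nrow(pairs)) < pAssoc, , drop = FALSE]
    if (nrow(assoc) == 0L) assoc <- pairs[1, , drop = FALSE]
    prior <- buildPriorMatrix(assoc, sim, net, theta = theta)
    list(net = net, sim = sim, assoc = assoc, prior = prior)
}

# oracle: one propagation step by the explicit double summation over
# similar diseases and gene neighbours
oracleStep <- function(F, Snorm, Anorm, F0, w) {
    Snorm <- as.matrix(Snorm); Anorm <- as.matrix(Anorm)
    out <- F0 * 0
    for (p in seq_len(nrow(F))) for (g in seq_len(ncol(F))) {
        acc <- 0
        for (q in seq_len(nrow(F))) for (h in seq_len(ncol(F)))
            acc <- acc + Snorm[p, q] * F[q, h] * Anorm[h, g]
        out[p, g] <- (1 - w) * acc + w * F0[p, g]
    }
    out
}

# oracle: fixed point by direct solve of the vectorized linear system
oracleFixedPoint <- function(prior, sim, net, w) {
    Snorm <- as.matrix(normalizeSymmetric(sim@similarity))
    Anorm <- as.matrix(normalizeSymmetric(net@adjacency))
    F0 <- scores(prior)
    n <- length(F0)
    M <- diag(n) - (1 - w) * kronecker(t(Anorm), Snorm)
    matrix(solve(M, w * as.vector(F0)), nrow = nrow(F0), dimnames = dimnames(F0))
}

# oracle: exact personalized PageRank of the lazy walk by power iteration
oracleExactPPR <- function(net, seed, teleport, tol = 1e-14) {
    A <- as.matrix(adjacency(net))
    deg <- rowSums(A)
    W <- (diag(nrow(A)) + A / deg) / 2
    e <- as.numeric(genes(net) == seed)
    p <- e
    repeat {
        pn <- teleport * e + (1 - teleport) * as.vector(p %*% W)
        if (max(abs(pn - p)) < tol) break
        p <- pn
    }
    stats::setNames(pn, genes(net))
}

# oracle: conductance of a vertex set, computed straight from the adjacency
oracleConductance <- function(net, set) {
    A <- as.matrix(adjacency(net))
    deg <- rowSums(A)
    inS <- genes(net) %in% set
    cut <- sum(A[inS, !inS])
    vol <- sum(deg[inS])
    cut / min(vol, sum(deg) - vol)
}

# oracle: exhaustive minimum-conductance prefix along the sweep order
oracleSweepMinimum <- function(ppr, net) {
    A <- as.matrix(adjacency(net))
    deg <- rowSums(A)
    sup <- names(ppr@values)
    ord <- order(-(ppr@values / deg[match(sup, genes(net))]), sup)
    sup <- sup[ord]
    best <- Inf; bestSet <- NULL
    for (t in seq_len(min(length(sup), length(genes(net)) - 1L))) {
        phi <- oracleConductance(net, sup[seq_len(t)])
        if (is.finite(phi) && phi < best - 1e-12) {
            best <- phi; bestSet <- sup[seq_len(t)]
        }
    }
    list(conductance = best, set = sort(bestSet))
}
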