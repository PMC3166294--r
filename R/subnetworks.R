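#' Approximate personalized PageRank by the push algorithm
#'
#' Local, push-style approximation of the personalized PageRank vector of
#' the lazy random walk seeded at one gene. While some node `u` holds
#' residual mass `r(u) >= epsilon * degree(u)`, a push moves
#' `teleport * r(u)` into the value at `u`, keeps half of the remainder as
#' residual at `u` and spreads the other half over `u`'s neighbours in
#' proportion to edge weight. Work is proportional to the mass moved, so
#' the running time scales with the size of the discovered neighbourhood,
#' not with the graph.
#'
#' @param net a [GeneNetwork-class]; degrees are adjacency row sums.
#' @param seed seed gene identifier.
#' @param teleport restart probability in (0,1) (default 0.15).
#' @param epsilon approximation tolerance (default 1e-4); on return every
#'   residual satisfies `r(u) < epsilon * degree(u)`.
#' @return a [PPRVector-class].
#' @export
approximatePageRank <- function(net, seed, teleport = 0.15, epsilon = 1e-4) {
    stopifnot(is(net, "GeneNetwork"))
    if (!seed %in% net@genes) stop("seed gene not in network: ", seed)
    if (teleport <= 0 || teleport >= 1) stop("teleport must lie in (0,1)")
    if (epsilon <= 0) stop("epsilon must be positive")
    A <- net@adjacency
    deg <- Matrix::rowSums(A)
    s <- match(seed, net@genes)
    if (deg[s] == 0)
        stop("seed gene ", seed, " is isolated (no interactions, no self-loop)")
    n <- length(net@genes)
    p <- numeric(n)
    r <- numeric(n)
    r[s] <- 1
    # adjacency in column-compressed form for fast neighbour lookup
    Ac <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
    queue <- s
    inQueue <- logical(n)
    inQueue[s] <- TRUE
    while (length(queue)) {
        u <- queue[[1]]
        queue <- queue[-1]
        inQueue[u] <- FALSE
        if (deg[u] == 0 || r[u] < epsilon * deg[u]) next
        ru <- r[u]
        p[u] <- p[u] + teleport * ru
        rest <- (1 - teleport) * ru
        r[u] <- rest / 2
        nb <- (Ac@p[u] + 1L):Ac@p[u + 1L]
        vi <- Ac@i[nb] + 1L
        wv <- Ac@x[nb]
        r[vi] <- r[vi] + (rest / 2) * wv / deg[u]
        touched <- c(u, vi)
        hot <- touched[r[touched] >= epsilon * deg[touched] & !inQueue[touched]]
        if (length(hot)) { queue <- c(queue, hot); inQueue[hot] <- TRUE }
    }
    keepP <- which(p > 0); keepR <- which(r > 0)
    new("PPRVector", seed = seed, teleport = teleport, epsilon = epsilon,
        values = stats::setNames(p[keepP], net@genes[keepP]),
        residual = stats::setNames(r[keepR], net@genes[keepR]))
}

#' Minimum-conductance sweep cut
#'
#' Orders the support of an approximate PageRank vector by degree-normalized
#' mass (`value/degree`, descending; ties broken alphabetically by gene
#' identifier) and returns the prefix set with minimum conductance,
#' `cut(S) / min(vol(S), vol(V \ S))`. The full vertex set is never a
#' candidate (its complement has zero volume).
#'
#' @param ppr a [PPRVector-class] with nonempty support.
#' @param net the [GeneNetwork-class] the vector was computed on.
#' @return a [Subnetwork-class] (member ranks unset).
#' @export
sweepCut <- function(ppr, net) {
    if (!length(ppr@values)) stop("empty PageRank vector: nothing to sweep")
    A <- as.matrix(net@adjacency)
    deg <- rowSums(A)
    totalVol <- sum(deg)
    sup <- names(ppr@values)
    idx <- match(sup, net@genes)
    ord <- order(-(ppr@values / deg[idx]), sup)
    sup <- sup[ord]; idx <- idx[ord]
    vol <- 0; cut <- 0
    inS <- logical(length(net@genes))
    best <- Inf; bestLen <- 0L
    maxLen <- min(length(sup), length(net@genes) - 1L)
    for (t in seq_len(maxLen)) {
        u <- idx[t]
        internal <- sum(A[u, inS]) # edges back into the prefix
        cut <- cut + deg[u] - A[u, u] - 2 * internal
        vol <- vol + deg[u]
        inS[u] <- TRUE
        denom <- min(vol, totalVol - vol)
        if (denom <= 0) next
        phi <- unname(cut / denom)
        if (phi < best - 1e-12) { best <- phi; bestLen <- t }
    }
    if (!is.finite(best)) stop("sweep found no valid prefix")
    membersIdx <- idx[seq_len(bestLen)]
    new("Subnetwork", members = net@genes[sort(membersIdx)],
        conductance = best, seed = ppr@seed,
        memberRanks = stats::setNames(rep(NA_real_, bestLen),
                                      net@genes[sort(membersIdx)]))
}

#' Discover candidate disease subnetworks around known disease genes
#'
#' Runs PageRankNibble (approximate personalized PageRank plus sweep cut)
#' from each known disease gene, keeps subnetworks within a size range,
#' annotates members with their genome-wide prioritization ranks for the
#' queried disease, and keeps subnetworks in which a minimum fraction of
#' members ranks at or under `rankCutoff`.
#'
#' @param net a [GeneNetwork-class].
#' @param F a propagated [AssociationMatrix-class] (or `NULL` to skip rank
#'   annotation and filtering).
#' @param disease disease identifier whose ranking annotates the members.
#' @param seedGenes character vector of seed genes (known disease genes).
#' @param sizeRange numeric length-2 vector, inclusive member-count bounds
#'   (default c(5, 50)).
#' @param rankCutoff genome-wide rank defining a "well-ranked" member
#'   (default 200).
#' @param minRankedFraction minimum fraction of members ranked at or under
#'   `rankCutoff` (default 0.5).
#' @param teleport,epsilon PageRankNibble parameters.
#' @return list of [Subnetwork-class] objects (possibly empty).
#' @export
discoverDiseaseSubnetworks <- function(net, F = NULL, disease = NULL,
                                       seedGenes, sizeRange = c(5, 50),
                                       rankCutoff = 200L,
                                       minRankedFraction = 0.5,
                                       teleport = 0.15, epsilon = 1e-4) {
    bad <- setdiff(seedGenes, net@genes)
    if (length(bad)) stop("seed gene(s) not in network: ", paste(bad, collapse = ", "))
    ranking <- NULL
    if (!is.null(F)) {
        if (is.null(disease)) stop("a disease must be named to annotate ranks")
        ranking <- rankGenes(F, disease)
    }
    out <- list()
    for (sg in seedGenes) {
        sub <- sweepCut(approximatePageRank(net, sg, teleport, epsilon), net)
        sz <- length(sub@members)
        if (sz < sizeRange[1] || sz > sizeRange[2]) next
        if (!is.null(ranking)) {
            rk <- ranking$rank[match(sub@members, ranking$gene)]
            sub@memberRanks <- stats::setNames(as.numeric(rk), sub@members)
            if (mean(rk <= rankCutoff, na.rm = TRUE) < minRankedFraction) next
        }
        out[[length(out) + 1L]] <- sub
    }
    out
}
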