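#' Mean square deviation between two matrices
#'
#' The stopping statistic of the iterative propagation: the mean over all
#' entries of the squared elementwise differences.
#'
#' @param A,B numeric matrices of identical shape.
#' @return nonnegative scalar.
#' @examples
#' msd(matrix(0, 2, 2), matrix(1, 2, 2))  # 1
#' @export
msd <- function(A, B) {
    if (!all(dim(A) == dim(B))) stop("msd: shape mismatch")
    mean((A - B)^2)
}

#' One bilinear propagation step
#'
#' Computes `(1 - w) * Snorm %*% F %*% Anorm + w * F0`: the score of a
#' disease-gene pair is the weighted sum of current scores between the
#' diseases similar to it and the network neighbours of the gene (both
#' including themselves, via the unit similarity diagonal and the self-loop
#' extension), mixed with the prior.
#'
#' @param F current score matrix (diseases x genes).
#' @param Snorm normalized disease similarity matrix.
#' @param Anorm normalized extended adjacency matrix.
#' @param F0 prior score matrix.
#' @param priorWeight mixing weight of the prior term.
#' @return updated score matrix.
#' @export
propagationStep <- function(F, Snorm, Anorm, F0, priorWeight) {
    out <- (1 - priorWeight) * as.matrix(Snorm %*% F %*% Anorm) +
        priorWeight * F0
    dimnames(out) <- dimnames(F0)
    out
}

#' Propagate disease-gene association scores to convergence
#'
#' Iterates the bilinear update `F(t) = (1 - w) S F(t-1) A + w F0` from
#' `F(0) = F0`, where `S` and `A` are the degree-normalized similarity and
#' self-loop-extended adjacency matrices, until the mean square deviation
#' between successive iterates drops to `tol` or `maxIter` is hit. With
#' symmetric normalization both factors have spectral radius at most 1, so
#' the contraction factor is at most `1 - w` and convergence is guaranteed
#' for any prior weight w > 0.
#'
#' @param prior an [AssociationMatrix-class] with role `"prior"`.
#' @param sim a [DiseaseSimilarityNetwork-class].
#' @param net a self-loop-extended [GeneNetwork-class].
#' @param config a [PropagationConfig-class].
#' @return list with elements `scores` (an [AssociationMatrix-class], role
#'   `"propagated"`) and `report` (a [ConvergenceReport-class]).
#' @examples
#' net <- extendSelfLoops(GeneNetwork(data.frame(a = "g1", b = "g2")))
#' sim <- DiseaseSimilarityNetwork(matrix(1, 1, 1, dimnames = list("d1", "d1")))
#' prior <- buildPriorMatrix(data.frame(disease = "d1", gene = "g1"), sim, net)
#' propagate(prior, sim, net)$scores  # fixed point c(0.8, 0.2)
#' @export
propagate <- function(prior, sim, net, config = PropagationConfig()) {
    stopifnot(is(prior, "AssociationMatrix"), is(sim, "DiseaseSimilarityNetwork"),
              is(net, "GeneNetwork"), is(config, "PropagationConfig"))
    if (prior@role != "prior") stop("propagate needs a prior-role matrix")
    if (!net@selfLoopsAdded)
        stop("gene network must be self-loop extended before propagation")
    if (!identical(prior@diseases, sim@diseases) ||
        !identical(prior@genes, net@genes))
        stop("prior matrix is not aligned with the networks")
    norm <- switch(config@normalization,
                   symmetric = normalizeSymmetric,
                   row_stochastic = normalizeRowStochastic)
    Snorm <- norm(sim@similarity)
    Anorm <- norm(net@adjacency)
    w <- config@priorWeight
    F0 <- prior@scores
    Fc <- F0
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < config@maxIter) {
        iter <- iter + 1L
        Fn <- propagationStep(Fc, Snorm, Anorm, F0, w)
        dev <- msd(Fn, Fc)
        trace <- c(trace, dev)
        Fc <- Fn
        if (dev <= config@tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning(sprintf("propagation did not converge in %d iterations (MSD %.3g > tol %.3g)",
                        config@maxIter, utils::tail(trace, 1), config@tol))
    # scores can exceed 1 by rounding only; clamp within numerical noise
    Fc[Fc > 1 & Fc < 1 + 1e-9] <- 1
    list(scores = new("AssociationMatrix", diseases = prior@diseases,
                      genes = prior@genes, scores = Fc, role = "propagated"),
         report = new("ConvergenceReport", iterations = iter,
                      msdTrace = trace, converged = converged))
}

#' Exact fixed point of the propagation by direct linear solve
#'
#' Solves `vec(F) = (1-w) (A' %x% S) vec(F) + w vec(F0)` exactly. Only
#' feasible for small instances (the system is `nd*ng` square); intended for
#' verification and teaching, not production runs.
#'
#' @inheritParams propagate
#' @return an [AssociationMatrix-class] with role `"propagated"`.
#' @export
propagateExact <- function(prior, sim, net, config = PropagationConfig()) {
    norm <- switch(config@normalization,
                   symmetric = normalizeSymmetric,
                   row_stochastic = normalizeRowStochastic)
    Snorm <- as.matrix(norm(sim@similarity))
    Anorm <- as.matrix(norm(net@adjacency))
    w <- config@priorWeight
    F0 <- prior@scores
    n <- length(F0)
    M <- diag(n) - (1 - w) * (t(Anorm) %x% Snorm)
    Fv <- solve(M, w * as.vector(F0))
    Fm <- matrix(Fv, nrow = nrow(F0), dimnames = dimnames(F0))
    Fm[Fm > 1 & Fm < 1 + 1e-9] <- 1
    Fm[Fm < 0 & Fm > -1e-9] <- 0
    new("AssociationMatrix", diseases = prior@diseases, genes = prior@genes,
        scores = Fm, role = "propagated")
}

#' Rank candidate genes for a disease
#'
#' Orders candidates by descending propagated score with competition ranking
#' (tied scores share the minimal rank); among ties the output order is
#' alphabetical by gene identifier for stability.
#'
#' @param F an [AssociationMatrix-class] (normally role `"propagated"`).
#' @param disease disease identifier to query.
#' @param candidates gene identifiers to rank; defaults to every gene.
#' @param exclude genes removed from the candidate list before ranking
#'   (e.g. the disease's still-known training genes during cross-validation,
#'   so they cannot displace a hidden gene).
#' @return data.frame with columns `gene`, `score`, `rank`, in rank order.
#' @export
rankGenes <- function(F, disease, candidates = F@genes, exclude = character(0)) {
    stopifnot(is(F, "AssociationMatrix"))
    if (!disease %in% F@diseases) stop("unknown disease: ", disease)
    candidates <- setdiff(candidates, exclude)
    bad <- setdiff(candidates, F@genes)
    if (length(bad)) stop("unknown candidate gene(s): ", paste(bad, collapse = ", "))
    s <- F@scores[match(disease, F@diseases), match(candidates, F@genes)]
    ord <- order(-s, candidates)
    s <- s[ord]; candidates <- candidates[ord]
    # competition ranks: ties share the minimal rank
    rk <- rank(-s, ties.method = "min")
    data.frame(gene = candidates, score = unname(s), rank = as.integer(rk),
               stringsAsFactors = FALSE)
}
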