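.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Partition associations into cross-validation folds
#'
#' Uniform random partition into `k` folds whose sizes differ by at most
#' one, reproducible under `seed`.
#'
#' @param assocs data.frame of associations (columns `disease`, `gene`).
#' @param k fold count (default 10).
#' @param seed RNG seed.
#' @return a [FoldPlan-class].
#' @export
makeFolds <- function(assocs, k = 10L, seed = 1L) {
    n <- nrow(assocs)
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2")
    if (k > n) stop("more folds than associations")
    assignments <- .withSeed(seed, sample(rep(seq_len(k), length.out = n)))
    new("FoldPlan", k = k, assignments = as.integer(assignments),
        seed = as.integer(seed))
}

.associatedGenes <- function(assocs) unique(as.character(assocs$gene))

#' Random control set of unassociated genes
#'
#' Samples `n` genes without replacement from the pool of "unassociated
#' genes" — network genes with no known association to any disease. During
#' evaluation each fold disease is paired with all `n` genes to form
#' artificial irrelevant associations.
#'
#' @param assocs known association table (defines the associated genes).
#' @param genes character vector of all network genes.
#' @param n number of control genes to draw.
#' @param seed RNG seed.
#' @return a [ControlSet-class] with mode `"random"`.
#' @export
buildRandomControl <- function(assocs, genes, n, seed = 1L) {
    pool <- setdiff(genes, .associatedGenes(assocs))
    if (n > length(pool))
        stop(sprintf("requested %d control genes but only %d unassociated genes exist",
                     n, length(pool)))
    picked <- .withSeed(seed, sample(pool, n))
    new("ControlSet", mode = "random", pool = sort(picked), perGene = list(),
        params = list(n = n, seed = as.integer(seed)))
}

#' Genome-wide control set
#'
#' Uses every unassociated gene in the network as the irrelevant pool.
#'
#' @inheritParams buildRandomControl
#' @return a [ControlSet-class] with mode `"genome_wide"`.
#' @export
buildGenomeWideControl <- function(assocs, genes) {
    pool <- setdiff(genes, .associatedGenes(assocs))
    if (!length(pool))
        warning("every network gene has a known association; genome-wide control pool is empty")
    new("ControlSet", mode = "genome_wide", pool = sort(pool), perGene = list(),
        params = list())
}

#' Artificial linkage interval around a disease gene
#'
#' Returns up to `halfWidth` genes upstream and `halfWidth` genes downstream
#' of `gene` on its chromosome, ordered by start position, restricted to
#' genes present in the interaction network. Genes absent from the network
#' are skipped without counting toward the per-side quota, so the interval
#' holds up to `2 * halfWidth` network genes (fewer near a chromosome end).
#' The anchor gene itself is excluded.
#'
#' @param gene anchor gene identifier (the hidden disease gene).
#' @param coords coordinate table from [loadGeneCoordinates()].
#' @param net a [GeneNetwork-class] defining network membership.
#' @param halfWidth genes to take on each side (default 50).
#' @return character vector of interval genes.
#' @export
linkageInterval <- function(gene, coords, net, halfWidth = 50L) {
    row <- coords[coords$gene == gene, , drop = FALSE]
    if (nrow(row) == 0L) stop("no coordinates for gene ", gene)
    chr <- coords[coords$chrom == row$chrom[1], , drop = FALSE]
    chr <- chr[order(chr$start), , drop = FALSE]
    inNet <- chr$gene %in% net@genes
    pos <- which(chr$gene == gene)
    up <- chr$gene[seq_len(pos - 1L)][inNet[seq_len(pos - 1L)]]
    if (length(up) > halfWidth) up <- utils::tail(up, halfWidth)
    dnIdx <- if (pos < nrow(chr)) seq(pos + 1L, nrow(chr)) else integer(0)
    dn <- chr$gene[dnIdx][inNet[dnIdx]]
    if (length(dn) > halfWidth) dn <- utils::head(dn, halfWidth)
    c(up, dn)
}

#' Precision/recall over rank cutoffs
#'
#' At cutoff k an item (relevant or irrelevant) is retrieved when its
#' genome-wide rank is at most k. Precision is the fraction of retrieved
#' items that are relevant; recall the fraction of relevant items retrieved.
#' When nothing is retrieved precision is reported as 1 by convention (and
#' noted), keeping averaged curves free of NaN.
#'
#' @param relevantRanks integer ranks of the relevant (true) items.
#' @param irrelevantRanks integer ranks of the irrelevant (control) items.
#' @param thresholds rank cutoffs to evaluate.
#' @return data.frame with columns `threshold`, `precision`, `recall`,
#'   `nRetrieved`.
#' @export
precisionRecallCurve <- function(relevantRanks, irrelevantRanks,
                                 thresholds = c(1, 5, 10, 50, 100, 300)) {
    if (!length(relevantRanks)) stop("empty relevant set")
    res <- lapply(thresholds, function(k) {
        relRet <- sum(relevantRanks <= k)
        irrRet <- sum(irrelevantRanks <= k)
        ret <- relRet + irrRet
        prec <- if (ret == 0L) 1 else relRet / ret
        data.frame(threshold = k, precision = prec,
                   recall = relRet / length(relevantRanks), nRetrieved = ret)
    })
    curve <- do.call(rbind, res)
    if (any(curve$nRetrieved == 0))
        message("no items retrieved at some cutoffs; precision reported as 1 there")
    curve
}

#' k-fold cross-validation of the prioritization
#'
#' For each fold the fold's associations are hidden, the prior matrix is
#' rebuilt from the remaining associations only (so a hidden pair can regain
#' prior signal solely through a similar disease known for its gene, never
#' through itself), scores are propagated, and every hidden gene is ranked
#' genome-wide for its disease. The queried disease's still-known training
#' genes are removed from the candidate list so they cannot displace the
#' hidden gene. Irrelevant control items are ranked in the same per-disease
#' rankings, and precision/recall is averaged over folds, unweighted.
#'
#' @param net a [GeneNetwork-class] (extended automatically if needed).
#' @param sim a [DiseaseSimilarityNetwork-class].
#' @param assocs known association table (columns `disease`, `gene`).
#' @param config a [PropagationConfig-class].
#' @param k fold count (default 10).
#' @param control a [ControlSet-class], or one of `"random"`,
#'   `"genome_wide"`, `"linkage_interval"` to build one internally.
#' @param nControl size of the random control set (default 2000).
#' @param halfWidth per-side size of linkage intervals (default 50).
#' @param coords coordinate table (required for interval control).
#' @param thresholds rank cutoffs for the curves.
#' @param seed RNG seed driving folds and control sampling.
#' @return list of class `prioNetCV` with elements `ranks` (one row per
#'   hidden association: fold, disease, gene, rank, nCandidates,
#'   priorAtHidden, normalizedRank), `curve` (fold-averaged PR curve),
#'   `perFold` (list of per-fold curves), `folds` (the [FoldPlan-class]),
#'   `control`.
#' @export
crossValidate <- function(net, sim, assocs, config = PropagationConfig(),
                          k = 10L, control = "random", nControl = 2000L,
                          halfWidth = 50L, coords = NULL,
                          thresholds = c(1, 5, 10, 50, 100, 300), seed = 1L) {
    assocs <- unique(as.data.frame(assocs))
    netExt <- if (net@selfLoopsAdded) net else extendSelfLoops(net)
    if (is.character(control)) {
        control <- match.arg(control,
                             c("random", "genome_wide", "linkage_interval"))
        control <- switch(control,
            random = buildRandomControl(assocs, netExt@genes,
                                        n = min(nControl,
                                                length(setdiff(netExt@genes,
                                                               .associatedGenes(assocs)))),
                                        seed = seed + 7L),
            genome_wide = buildGenomeWideControl(assocs, netExt@genes),
            linkage_interval = new("ControlSet", mode = "linkage_interval",
                                   pool = character(0), perGene = list(),
                                   params = list(halfWidth = as.integer(halfWidth))))
    }
    if (control@mode == "linkage_interval" && is.null(coords))
        stop("linkage-interval control needs a gene coordinate table")
    folds <- makeFolds(assocs, k = k, seed = seed)
    ranksOut <- list()
    perFold <- vector("list", folds@k)
    noSignal <- 0L
    for (f in seq_len(folds@k)) {
        hidden <- assocs[folds@assignments == f, , drop = FALSE]
        train <- assocs[folds@assignments != f, , drop = FALSE]
        prior <- buildPriorMatrix(train, sim, netExt, theta = config@theta)
        noSignal <- noSignal + sum(rowSums(prior@scores[unique(hidden$disease), ,
                                                        drop = FALSE]) == 0)
        Fmat <- propagate(prior, sim, netExt, config)$scores
        relRanks <- integer(0)
        irrRanks <- integer(0)
        rows <- list()
        rankCache <- list()
        for (i in seq_len(nrow(hidden))) {
            d <- hidden$disease[i]; g <- hidden$gene[i]
            if (is.null(rankCache[[d]])) {
                excl <- train$gene[train$disease == d]
                rankCache[[d]] <- rankGenes(Fmat, d, exclude = excl)
            }
            rk <- rankCache[[d]]
            r <- rk$rank[match(g, rk$gene)]
            relRanks <- c(relRanks, r)
            irrGenes <- if (control@mode == "linkage_interval")
                linkageInterval(g, coords, netExt,
                                halfWidth = control@params$halfWidth)
            else character(0)
            if (length(irrGenes))
                irrRanks <- c(irrRanks,
                              rk$rank[match(intersect(irrGenes, rk$gene), rk$gene)])
            rows[[i]] <- data.frame(fold = f, disease = d, gene = g,
                rank = r, nCandidates = nrow(rk),
                priorAtHidden = prior@scores[match(d, prior@diseases),
                                             match(g, prior@genes)],
                normalizedRank = r / nrow(rk), stringsAsFactors = FALSE)
        }
        if (control@mode != "linkage_interval") {
            for (d in unique(hidden$disease)) {
                rk <- rankCache[[d]]
                irrRanks <- c(irrRanks,
                              rk$rank[match(intersect(control@pool, rk$gene),
                                            rk$gene)])
            }
        }
        perFold[[f]] <- precisionRecallCurve(relRanks, irrRanks, thresholds)
        ranksOut[[f]] <- do.call(rbind, rows)
    }
    if (noSignal > 0L)
        message(sprintf("%d fold-disease combinations had an all-zero prior row (no similarity signal); scores fall back to network smoothing only", noSignal))
    avg <- perFold[[1]]
    foldMean <- function(col) rowMeans(matrix(
        unlist(lapply(perFold, function(x) as.numeric(x[[col]]))),
        nrow = nrow(avg)))
    avg$precision <- foldMean("precision")
    avg$recall <- foldMean("recall")
    avg$nRetrieved <- foldMean("nRetrieved")
    structure(list(ranks = do.call(rbind, ranksOut), curve = avg,
                   perFold = perFold, folds = folds, control = control),
              class = "prioNetCV")
}

#' @export
print.prioNetCV <- function(x, ...) {
    cat(sprintf("prioNet cross-validation: %d hidden associations, %d folds, control = %s\n",
                nrow(x$ranks), x$folds@k, x$control@mode))
    cat(sprintf("  hidden gene in top 10: %.1f%%; median genome-wide rank: %g\n",
                100 * mean(x$ranks$rank <= 10), stats::median(x$ranks$rank)))
    invisible(x)
}

#' Fraction of hidden genes recovered within a rank cutoff
#' @param cv result of [crossValidate()].
#' @param k rank cutoff (default 10).
#' @return scalar in \[0,1\].
#' @export
recoveryRate <- function(cv, k = 10L) mean(cv$ranks$rank <= k)

#' Gaussian-noise perturbation of the input networks
#'
#' Adds zero-mean white Gaussian noise to a random fraction of off-diagonal
#' disease-similarity entries and to the interactions among a random subset
#' of genes, mirroring the perturbation used to probe the method's
#' robustness. Perturbation acts on the upper triangle and is mirrored so
#' symmetry is preserved; values are clipped to \[0,1\]; diagonals are never
#' touched. The perturbed similarities pass through the network's theta
#' filter again (the pipeline always consumes filtered similarities), and
#' the perturbed adjacency becomes weighted.
#'
#' @param sim a [DiseaseSimilarityNetwork-class].
#' @param net a [GeneNetwork-class].
#' @param simFraction fraction of off-diagonal similarity entries to perturb
#'   (default 1/5).
#' @param nGenes number of genes whose mutual interactions are perturbed.
#' @param noiseSd standard deviation of the Gaussian noise (default 0.1).
#' @param seed RNG seed.
#' @return list with perturbed `sim` and `net`.
#' @export
perturbNetworks <- function(sim, net, simFraction = 0.2,
                            nGenes = min(1000L, length(net@genes)),
                            noiseSd = 0.1, seed = 1L) {
    if (noiseSd <= 0) stop("noiseSd must be positive")
    if (simFraction <= 0 || simFraction > 1)
        stop("simFraction must lie in (0,1]")
    .withSeed(seed, {
        S <- sim@similarity
        ut <- which(upper.tri(S))
        pick <- sample(ut, ceiling(simFraction * length(ut)))
        S[pick] <- pmin(1, pmax(0, S[pick] + stats::rnorm(length(pick), 0, noiseSd)))
        S[lower.tri(S)] <- t(S)[lower.tri(S)]
        simP <- DiseaseSimilarityNetwork(S, theta = sim@theta)

        A <- as.matrix(net@adjacency)
        gsub <- sample(length(net@genes), nGenes)
        sub <- A[gsub, gsub, drop = FALSE]
        utA <- which(upper.tri(sub))
        sub[utA] <- pmin(1, pmax(0, sub[utA] + stats::rnorm(length(utA), 0, noiseSd)))
        sub[lower.tri(sub)] <- t(sub)[lower.tri(sub)]
        A[gsub, gsub] <- sub
        netP <- new("GeneNetwork", genes = net@genes,
                    adjacency = Matrix::Matrix(A, sparse = TRUE),
                    selfLoopsAdded = net@selfLoopsAdded)
        list(sim = simP, net = netP)
    })
}
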