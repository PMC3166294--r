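#' Generate a modular synthetic benchmark instance
#'
#' Emulates the structure the propagation method assumes: disease genes for
#' similar diseases cluster in the interaction network. Gene modules are
#' Erdos-Renyi blocks (`pIn` within a module, `pOut` between), disease
#' clusters have similarity `simIn` within and `simOut` between (plus small
#' uniform jitter so rank ties are rare, clipped to \[0,1\]), and each
#' disease cluster is matched to one gene module. Known associations link
#' cluster diseases to a set of distinct "causal" genes of the matched
#' module, with each causal gene associated to at least two diseases of the
#' cluster whenever the counts allow it — an association hidden during
#' cross-validation then remains recoverable through a similar disease known
#' for the same gene, which is exactly the signal the method propagates.
#'
#' Synthetic gene coordinates are laid out sequentially along `nChrom`
#' chromosomes (genes shuffled across chromosomes, 0-based half-open
#' intervals) to exercise linkage-interval controls.
#'
#' @param nModules number of gene modules = disease clusters (default 5).
#' @param genesPerModule genes in each module (default 30).
#' @param diseasesPerCluster diseases in each cluster (default 10).
#' @param pIn,pOut within/between-module edge probabilities (defaults 0.3,
#'   0.01); `pIn > pOut` required.
#' @param simIn,simOut within/between-cluster similarity levels (defaults
#'   0.8, 0.1); `simIn >= theta > simOut` required.
#' @param assocPerCluster known associations per cluster (default 20, i.e.
#'   10 causal genes x 2 diseases with the default cluster size).
#' @param theta similarity filter threshold (default 0.5).
#' @param jitter half-width of the uniform similarity jitter (default 0.05).
#' @param nChrom chromosomes for the synthetic coordinate table (default 3).
#' @param seed RNG seed; the same seed reproduces the instance exactly.
#' @return a [SyntheticInstance-class].
#' @export
generateModularInstance <- function(nModules = 5L, genesPerModule = 30L,
                                    diseasesPerCluster = 10L,
                                    pIn = 0.3, pOut = 0.01,
                                    simIn = 0.8, simOut = 0.1,
                                    assocPerCluster = 20L, theta = 0.5,
                                    jitter = 0.05, nChrom = 3L, seed = 1L) {
    if (pIn < pOut) stop("pIn must be at least pOut")
    if (simIn < simOut) stop("simIn must be at least simOut")
    if (!(simOut < theta)) stop("simOut must be below theta")
    if (simIn < theta)
        message("simIn below theta: within-cluster similarity is filtered out (no-signal instance)")
    if (min(nModules, genesPerModule, diseasesPerCluster, assocPerCluster) < 1)
        stop("all counts must be at least 1")
    if (assocPerCluster > genesPerModule * diseasesPerCluster)
        stop("assocPerCluster exceeds the number of distinct cluster pairs")
    .withSeed(seed, {
        nG <- nModules * genesPerModule
        nD <- nModules * diseasesPerCluster
        gn <- sprintf("g%03d", seq_len(nG))
        dn <- sprintf("d%03d", seq_len(nD))
        gMod <- stats::setNames(rep(seq_len(nModules), each = genesPerModule), gn)
        dClu <- stats::setNames(rep(seq_len(nModules), each = diseasesPerCluster), dn)

        # gene modules as Erdos-Renyi blocks
        P <- matrix(pOut, nG, nG)
        same <- outer(gMod, gMod, "==")
        P[same] <- pIn
        U <- matrix(stats::runif(nG * nG), nG, nG)
        A <- matrix(0, nG, nG, dimnames = list(gn, gn))
        A[upper.tri(A)] <- as.numeric(U[upper.tri(U)] < P[upper.tri(P)])
        A <- A + t(A)
        net <- new("GeneNetwork", genes = gn,
                   adjacency = Matrix::Matrix(A, sparse = TRUE),
                   selfLoopsAdded = FALSE)

        # disease clusters: block similarity plus jitter, clipped to [0,1]
        S <- matrix(simOut, nD, nD, dimnames = list(dn, dn))
        S[outer(dClu, dClu, "==")] <- simIn
        J <- matrix(0, nD, nD)
        J[upper.tri(J)] <- stats::runif(sum(upper.tri(J)), -jitter, jitter)
        S <- pmin(pmax(S + J + t(J), 0), 1)
        diag(S) <- 1
        sim <- DiseaseSimilarityNetwork(S, theta = theta)

        # associations: distinct causal genes, each tied to >= 2 cluster
        # diseases when assocPerCluster permits
        assoc <- list()
        for (m in seq_len(nModules)) {
            modGenes <- sample(gn[gMod == m])
            cluDis <- sample(dn[dClu == m])
            nCausal <- max(1L, min(genesPerModule,
                                   ceiling(assocPerCluster / 2)))
            causal <- modGenes[seq_len(nCausal)]
            di <- ((seq_len(assocPerCluster) - 1L) %% diseasesPerCluster) + 1L
            pass <- ((seq_len(assocPerCluster) - 1L) %/% diseasesPerCluster)
            gi <- ((di - 1L + pass) %% nCausal) + 1L
            assoc[[m]] <- data.frame(disease = cluDis[di], gene = causal[gi],
                                     stringsAsFactors = FALSE)
        }
        assoc <- unique(do.call(rbind, assoc))
        rownames(assoc) <- NULL

        # sequential synthetic coordinates on nChrom chromosomes
        shuffled <- sample(gn)
        coords <- do.call(rbind, lapply(seq_len(nChrom), function(ch) {
            g <- shuffled[seq(ch, nG, by = nChrom)]
            if (!length(g)) return(NULL)
            start <- (seq_along(g) - 1L) * 10000L
            data.frame(chrom = sprintf("chr%d", ch), start = start,
                       end = start + 5000L, gene = g, stringsAsFactors = FALSE)
        }))
        coords <- coords[order(coords$chrom, coords$start), ]
        rownames(coords) <- NULL

        new("SyntheticInstance", network = net, similarity = sim,
            associations = assoc, geneModules = gMod, diseaseClusters = dClu,
            coordinates = coords,
            params = list(nModules = nModules, genesPerModule = genesPerModule,
                          diseasesPerCluster = diseasesPerCluster, pIn = pIn,
                          pOut = pOut, simIn = simIn, simOut = simOut,
                          assocPerCluster = assocPerCluster, theta = theta,
                          jitter = jitter, nChrom = nChrom, seed = seed))
    })
}

#' Split planted associations into training and hidden sets
#'
#' Uniformly hides a fraction of the planted associations. When possible,
#' every hidden pair's disease keeps at least one training association in
#' its cluster; pairs for which this cannot hold are flagged in the result.
#'
#' @param instance a [SyntheticInstance-class].
#' @param fraction fraction of associations to hide, in (0,1).
#' @param seed RNG seed.
#' @return list with data.frames `training` and `hidden`; `hidden` carries a
#'   logical column `diseaseRetainsTraining`.
#' @export
plantHiddenSet <- function(instance, fraction = 0.1, seed = 1L) {
    if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0,1)")
    assoc <- instance@associations
    n <- nrow(assoc)
    nH <- max(1L, round(fraction * n))
    hiddenIdx <- .withSeed(seed, sample(n, nH))
    hidden <- assoc[hiddenIdx, , drop = FALSE]
    training <- assoc[-hiddenIdx, , drop = FALSE]
    hidden$diseaseRetainsTraining <- hidden$disease %in% training$disease
    if (!all(hidden$diseaseRetainsTraining))
        message(sprintf("%d hidden pair(s) leave their disease with no training association",
                        sum(!hidden$diseaseRetainsTraining)))
    rownames(training) <- rownames(hidden) <- NULL
    list(training = training, hidden = hidden)
}

#' Write a synthetic instance in the package's on-disk formats
#'
#' Emits `ppi.tsv`, `sim.tsv`, `assoc.tsv` and `coords.tsv` in exactly the
#' formats the loaders read, so generated fixtures double as format tests.
#'
#' @param instance a [SyntheticInstance-class].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeInstance <- function(instance, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writePPIEdgelist(instance@network, file.path(dir, "ppi.tsv"))
    writeDiseaseSimilarity(instance@similarity, file.path(dir, "sim.tsv"))
    writeAssociations(instance@associations, file.path(dir, "assoc.tsv"))
    writeGeneCoordinates(instance@coordinates, file.path(dir, "coords.tsv"))
    invisible(dir)
}
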