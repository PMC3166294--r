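#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t diag isSymmetric
NULL

.checkSquareSymmetric <- function(M, ids, what, tol = 1e-8) {
    msg <- character(0)
    if (nrow(M) != ncol(M))
        msg <- c(msg, sprintf("%s matrix must be square", what))
    if (nrow(M) != length(ids))
        msg <- c(msg, sprintf("%s matrix dimension does not match identifier list", what))
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate %s identifiers", what))
    if (nrow(M) == ncol(M) && max(abs(M - Matrix::t(M))) > tol)
        msg <- c(msg, sprintf("%s matrix must be symmetric", what))
    msg
}

#' Gene network with binary protein-protein interactions
#'
#' Holds an ordered gene list and a symmetric adjacency matrix. Entries are
#' 0/1 interaction indicators (a perturbed network may carry weights in
#' \[0,1\]). Propagation requires the self-loop-extended form, in which every
#' gene additionally interacts with itself so that each gene counts as a
#' pseudo-neighbour of itself; see [extendSelfLoops()].
#'
#' @slot genes ordered character vector of gene identifiers; the canonical
#'   gene index shared by all downstream matrices.
#' @slot adjacency symmetric sparse `Matrix` with entries in \[0,1\].
#' @slot selfLoopsAdded logical; `TRUE` once the diagonal has been set to 1.
#' @export
setClass("GeneNetwork",
    representation(genes = "character", adjacency = "Matrix",
                   selfLoopsAdded = "logical"),
    validity = function(object) {
        msg <- .checkSquareSymmetric(object@adjacency, object@genes, "gene")
        v <- object@adjacency@x
        if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
            msg <- c(msg, "adjacency entries must lie in [0,1]")
        if (isTRUE(object@selfLoopsAdded) &&
            any(abs(Matrix::diag(object@adjacency) - 1) > 1e-12))
            msg <- c(msg, "self-loop-extended network must have unit diagonal")
        if (length(msg)) msg else TRUE
    })

#' Filtered disease phenotype-similarity network
#'
#' An ordered disease list with a symmetric similarity matrix in \[0,1\].
#' Off-diagonal similarities below the threshold `theta` are zeroed (weak
#' text-mining similarities are uninformative) and the diagonal is 1: every
#' disease is maximally similar to itself.
#'
#' @slot diseases ordered character vector of disease identifiers.
#' @slot similarity symmetric numeric matrix, entries in \[0,1\], unit diagonal;
#'   off-diagonal entries are 0 or at least `theta`.
#' @slot theta filter threshold in \[0,1\].
#' @export
setClass("DiseaseSimilarityNetwork",
    representation(diseases = "character", similarity = "matrix",
                   theta = "numeric"),
    validity = function(object) {
        S <- object@similarity
        msg <- .checkSquareSymmetric(S, object@diseases, "disease")
        if (length(object@theta) != 1L || object@theta < 0 || object@theta > 1)
            msg <- c(msg, "theta must be a single value in [0,1]")
        if (length(S)) {
            if (min(S) < -1e-12 || max(S) > 1 + 1e-12)
                msg <- c(msg, "similarity entries must lie in [0,1]")
            if (any(abs(diag(S) - 1) > 1e-12))
                msg <- c(msg, "similarity diagonal must be 1")
            off <- S[row(S) != col(S)]
            if (length(off) && any(off > 1e-12 & off < object@theta - 1e-12))
                msg <- c(msg, "off-diagonal similarities must be 0 or >= theta")
        }
        if (length(msg)) msg else TRUE
    })

#' Disease-by-gene association score matrix
#'
#' Rows are diseases, columns genes, on the same orderings as the two
#' networks. With role `"prior"` the matrix seeds propagation: known pairs
#' score exactly 1, unknown pairs carry the theta-filtered similarity to the
#' most similar disease known for that gene. With role `"propagated"` it holds
#' converged association scores.
#'
#' @slot diseases,genes ordered identifier vectors matching the networks.
#' @slot scores numeric matrix, diseases x genes; nonnegative, and in \[0,1\]
#'   for a prior (propagated scores stay within the prior's maximum on
#'   near-regular networks but are not hard-bounded by 1).
#' @slot role `"prior"` or `"propagated"`.
#' @export
setClass("AssociationMatrix",
    representation(diseases = "character", genes = "character",
                   scores = "matrix", role = "character"),
    validity = function(object) {
        msg <- character(0)
        if (nrow(object@scores) != length(object@diseases) ||
            ncol(object@scores) != length(object@genes))
            msg <- c(msg, "score matrix shape does not match identifier lists")
        if (anyDuplicated(object@diseases) || anyDuplicated(object@genes))
            msg <- c(msg, "duplicate identifiers")
        if (!object@role %in% c("prior", "propagated"))
            msg <- c(msg, "role must be 'prior' or 'propagated'")
        if (length(object@scores) && min(object@scores) < -1e-9)
            msg <- c(msg, "association scores must be nonnegative")
        if (identical(object@role, "prior") && length(object@scores) &&
            max(object@scores) > 1 + 1e-9)
            msg <- c(msg, "prior scores must lie in [0,1]")
        if (length(msg)) msg else TRUE
    })

#' Propagation settings
#'
#' Defaults follow the published calibration of the method: similarity/prior
#' threshold `theta = 0.5`, prior weight 0.6, mean-square-deviation stopping
#' tolerance 1e-5. `maxIter` is a safety cap so non-convergent configurations
#' fail loudly rather than loop. `normalization` selects symmetric degree
#' normalization (default; guarantees convergence for any prior weight > 0)
#' or row-stochastic.
#'
#' @slot priorWeight mixing weight of the prior term, in (0,1\].
#' @slot theta filter threshold in \[0,1\].
#' @slot tol stopping threshold on the MSD between successive score matrices.
#' @slot maxIter positive iteration cap.
#' @slot normalization `"symmetric"` or `"row_stochastic"`.
#' @export
setClass("PropagationConfig",
    representation(priorWeight = "numeric", theta = "numeric", tol = "numeric",
                   maxIter = "integer", normalization = "character"),
    prototype(priorWeight = 0.6, theta = 0.5, tol = 1e-5, maxIter = 1000L,
              normalization = "symmetric"),
    validity = function(object) {
        msg <- character(0)
        if (!(object@priorWeight > 0 && object@priorWeight <= 1))
            msg <- c(msg, "priorWeight must lie in (0,1]")
        if (object@theta < 0 || object@theta > 1)
            msg <- c(msg, "theta must lie in [0,1]")
        if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
        if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
        if (!object@normalization %in% c("symmetric", "row_stochastic"))
            msg <- c(msg, "normalization must be 'symmetric' or 'row_stochastic'")
        if (length(msg)) msg else TRUE
    })

#' Constructor for [PropagationConfig-class]
#' @param priorWeight,theta,tol,maxIter,normalization see the class slots.
#' @return a validated `PropagationConfig`.
#' @examples
#' PropagationConfig(priorWeight = 0.6)
#' @export
PropagationConfig <- function(priorWeight = 0.6, theta = 0.5, tol = 1e-5,
                              maxIter = 1000L, normalization = "symmetric") {
    new("PropagationConfig", priorWeight = priorWeight, theta = theta,
        tol = tol, maxIter = as.integer(maxIter), normalization = normalization)
}

#' Convergence diagnostics of one propagation run
#' @slot iterations number of update steps performed.
#' @slot msdTrace per-iteration mean square deviation between successive
#'   score matrices.
#' @slot converged `TRUE` when the final MSD is at or below the tolerance.
#' @export
setClass("ConvergenceReport",
    representation(iterations = "integer", msdTrace = "numeric",
                   converged = "logical"))

#' Cross-validation fold assignment
#' @slot k fold count.
#' @slot assignments integer fold index per association (parallel to the
#'   association table rows); fold sizes differ by at most one.
#' @slot seed RNG seed used to draw the partition.
#' @export
setClass("FoldPlan",
    representation(k = "integer", assignments = "integer", seed = "integer"),
    validity = function(object) {
        msg <- character(0)
        sz <- tabulate(object@assignments, nbins = object@k)
        if (any(object@assignments < 1L | object@assignments > object@k))
            msg <- c(msg, "fold indices out of range")
        if (length(sz) && diff(range(sz)) > 1L)
            msg <- c(msg, "fold sizes must differ by at most 1")
        if (length(msg)) msg else TRUE
    })

#' Irrelevant control set for precision/recall evaluation
#'
#' Artificially constructed disease-gene pairs treated as irrelevant items.
#' Modes: `"random"` (n genes sampled from the unassociated pool),
#' `"genome_wide"` (every unassociated network gene), `"linkage_interval"`
#' (positional neighbours of a hidden disease gene).
#'
#' @slot mode control-set flavour.
#' @slot pool character vector of irrelevant genes shared by all diseases
#'   (random / genome-wide modes); empty for interval mode.
#' @slot perGene named list mapping a hidden gene to its interval gene list
#'   (interval mode only).
#' @slot params list of construction parameters (`n`, `halfWidth`, seed).
#' @export
setClass("ControlSet",
    representation(mode = "character", pool = "character", perGene = "list",
                   params = "list"),
    validity = function(object) {
        if (!object@mode %in% c("random", "genome_wide", "linkage_interval"))
            "mode must be random, genome_wide or linkage_interval" else TRUE
    })

#' Approximate personalized PageRank vector
#'
#' Result of the push-style approximation with the lazy-walk convention:
#' each push moves `teleport * r(u)` into the value at `u`, spreads half of
#' the remainder over the neighbours of `u` and retains half at `u`.
#'
#' @slot seed seed gene identifier.
#' @slot teleport restart probability in (0,1).
#' @slot epsilon approximation tolerance; on completion every residual
#'   satisfies `r(u) < epsilon * degree(u)`.
#' @slot values named nonnegative mass vector (support only); sums to <= 1.
#' @slot residual named residual mass vector.
#' @export
setClass("PPRVector",
    representation(seed = "character", teleport = "numeric",
                   epsilon = "numeric", values = "numeric",
                   residual = "numeric"),
    validity = function(object) {
        msg <- character(0)
        if (length(object@values) && min(object@values) < -1e-12)
            msg <- c(msg, "PPR values must be nonnegative")
        if (sum(object@values) > 1 + 1e-9)
            msg <- c(msg, "PPR values must sum to at most 1")
        if (length(msg)) msg else TRUE
    })

#' Candidate disease subnetwork from a conductance sweep
#' @slot members gene identifiers in the subnetwork (contains the seed).
#' @slot conductance cut size divided by the smaller side's volume, in \[0,1\]
#'   (0 only when the sweep captures a whole connected component).
#' @slot seed the seed gene the local cluster was grown from.
#' @slot memberRanks named numeric vector of genome-wide prioritization ranks
#'   for the members (NA when no score matrix was supplied).
#' @export
setClass("Subnetwork",
    representation(members = "character", conductance = "numeric",
                   seed = "character", memberRanks = "numeric"),
    validity = function(object) {
        msg <- character(0)
        if (!object@seed %in% object@members)
            msg <- c(msg, "subnetwork must contain its seed gene")
        if (!is.finite(object@conductance) ||
            object@conductance < 0 || object@conductance > 1)
            msg <- c(msg, "conductance must lie in [0,1]")
        if (length(msg)) msg else TRUE
    })

#' Synthetic modular benchmark instance
#'
#' A planted-structure instance: gene modules drawn as Erdos-Renyi blocks,
#' disease clusters with high within / low between similarity, and known
#' associations concentrated between matched cluster-module pairs.
#'
#' @slot network raw (not yet self-loop-extended) [GeneNetwork-class].
#' @slot similarity [DiseaseSimilarityNetwork-class] (theta-filtered).
#' @slot associations data.frame with columns `disease`, `gene`.
#' @slot geneModules,diseaseClusters named integer vectors of planted labels.
#' @slot coordinates data.frame of synthetic gene coordinates
#'   (`chrom`, `start`, `end`, `gene`), 0-based half-open.
#' @slot params generator parameters including the seed.
#' @export
setClass("SyntheticInstance",
    representation(network = "GeneNetwork",
                   similarity = "DiseaseSimilarityNetwork",
                   associations = "data.frame",
                   geneModules = "integer", diseaseClusters = "integer",
                   coordinates = "data.frame", params = "list"))

setMethod("show", "GeneNetwork", function(object) {
    cat(sprintf("GeneNetwork: %d genes, %d undirected interactions%s\n",
        length(object@genes),
        (sum(object@adjacency != 0) + sum(Matrix::diag(object@adjacency) != 0)) / 2,
        if (object@selfLoopsAdded) " (self-loop extended)" else ""))
})

setMethod("show", "DiseaseSimilarityNetwork", function(object) {
    S <- object@similarity
    cat(sprintf("DiseaseSimilarityNetwork: %d diseases, %d similarity edges (theta = %g)\n",
        length(object@diseases), sum(S[upper.tri(S)] > 0), object@theta))
})

setMethod("show", "AssociationMatrix", function(object) {
    cat(sprintf("AssociationMatrix [%s]: %d diseases x %d genes, %d nonzero scores\n",
        object@role, length(object@diseases), length(object@genes),
        sum(object@scores > 0)))
})

setMethod("show", "ConvergenceReport", function(object) {
    cat(sprintf("ConvergenceReport: %d iterations, final MSD %.3g, %s\n",
        object@iterations, utils::tail(object@msdTrace, 1),
        if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "Subnetwork", function(object) {
    cat(sprintf("Subnetwork (seed %s): %d genes, conductance %.4g\n",
        object@seed, length(object@members), object@conductance))
})

setMethod("show", "PPRVector", function(object) {
    cat(sprintf("PPRVector (seed %s): support %d, mass %.4f, teleport %g, epsilon %g\n",
        object@seed, length(object@values), sum(object@values),
        object@teleport, object@epsilon))
})

setMethod("show", "SyntheticInstance", function(object) {
    cat(sprintf("SyntheticInstance: %d genes in %d modules, %d diseases in %d clusters, %d associations\n",
        length(object@network@genes), length(unique(object@geneModules)),
        length(object@similarity@diseases),
        length(unique(object@diseaseClusters)), nrow(object@associations)))
})
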