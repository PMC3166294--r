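#' Build a gene network from an edge list
#'
#' @param edges two-column data.frame or matrix of unordered gene pairs.
#' @param nodes optional character vector of additional gene identifiers to
#'   keep as isolated nodes (real interactomes contain isolated proteins
#'   that appear in the node list but in no interaction).
#' @return a [GeneNetwork-class] without self-loops extension.
#' @export
GeneNetwork <- function(edges, nodes = character(0)) {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L) stop("edge table needs at least two columns")
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    gn <- sort(unique(c(a, b, as.character(nodes))))
    if (length(gn) == 0L) stop("empty gene network")
    self <- a == b
    if (any(self))
        message(sprintf("%d self-interaction(s) recorded once (e.g. %s)",
                        sum(self), a[self][1]))
    i <- match(a, gn); j <- match(b, gn)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(length(gn), length(gn)),
                              dimnames = list(gn, gn))
    A@x[] <- 1   # collapse duplicate edges
    A <- methods::as(A, "generalMatrix")
    new("GeneNetwork", genes = gn, adjacency = A, selfLoopsAdded = FALSE)
}

#' Read a protein-protein interaction edge list
#'
#' Expects a TSV with two gene-identifier columns; lines starting with `#`
#' are treated as comments/header. Duplicate edges and reversed duplicates
#' collapse to one undirected interaction.
#'
#' @param path TSV file path.
#' @param nodes optional identifiers of isolated genes to keep.
#' @return a [GeneNetwork-class].
#' @export
loadPPIEdgelist <- function(path, nodes = character(0)) {
    lines <- readLines(path)
    keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
    lines <- lines[keep]
    if (length(lines) == 0L) stop("empty PPI edge list: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad))
        stop(sprintf("malformed PPI row at line %d of %s",
                     which(keep)[bad[1]], path))
    GeneNetwork(data.frame(a = vapply(parts, `[`, "", 1L),
                           b = vapply(parts, `[`, "", 2L)),
                nodes = nodes)
}

#' Extend a gene network with self-interactions
#'
#' Adds a self-interaction to every gene so that each gene is a
#' pseudo-neighbour of itself during propagation; the off-diagonal is
#' untouched. Calling it twice is an error.
#'
#' @param net a [GeneNetwork-class] with `selfLoopsAdded = FALSE`.
#' @return the extended [GeneNetwork-class].
#' @export
extendSelfLoops <- function(net) {
    stopifnot(is(net, "GeneNetwork"))
    if (net@selfLoopsAdded) stop("network is already self-loop extended")
    A <- net@adjacency
    Matrix::diag(A) <- 1
    new("GeneNetwork", genes = net@genes, adjacency = A, selfLoopsAdded = TRUE)
}

#' Construct a disease similarity network from a matrix
#'
#' Applies the threshold filter (off-diagonal entries below `theta` are set
#' to 0) and forces the unit diagonal.
#'
#' @param S symmetric numeric matrix with row/column names, entries in \[0,1\].
#' @param theta filter threshold in \[0,1\].
#' @return a [DiseaseSimilarityNetwork-class].
#' @export
DiseaseSimilarityNetwork <- function(S, theta = 0.5) {
    S <- as.matrix(S)
    if (is.null(rownames(S))) stop("similarity matrix must carry disease names")
    if (min(S) < 0 || max(S) > 1) stop("similarity values must lie in [0,1]")
    if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
    S[S < theta] <- 0
    diag(S) <- 1
    new("DiseaseSimilarityNetwork", diseases = rownames(S), similarity = S,
        theta = theta)
}

#' Read a disease-disease similarity file
#'
#' Accepts either triplets (`disease_a  disease_b  similarity`) or a dense
#' labeled matrix (first column = row labels, header = column labels).
#' Values below `theta` are filtered to 0, the diagonal is forced to 1.
#' If both orientations of a pair are present with different values this is
#' an error rather than an average: silent averaging hides data corruption.
#'
#' @param path TSV file path.
#' @param theta filter threshold in \[0,1\].
#' @return a [DiseaseSimilarityNetwork-class].
#' @export
loadDiseaseSimilarity <- function(path, theta = 0.5) {
    lines <- readLines(path)
    dataLines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
    if (!length(dataLines)) stop("empty similarity file: ", path)
    probe <- strsplit(dataLines[1], "\t", fixed = TRUE)[[1]]
    isTriplet <- length(probe) == 3L &&
        !suppressWarnings(is.na(as.numeric(probe[3])))
    if (!isTriplet) {
        # dense labeled matrix: header = column labels, first column = row labels
        M <- utils::read.delim(textConnection(dataLines), header = TRUE,
                               row.names = 1, check.names = FALSE)
        return(DiseaseSimilarityNetwork(as.matrix(M), theta = theta))
    }
    tab <- utils::read.delim(textConnection(dataLines), header = FALSE,
                             stringsAsFactors = FALSE)
    a <- as.character(tab[[1]]); b <- as.character(tab[[2]])
    v <- as.numeric(tab[[3]])
    if (anyNA(v)) stop("non-numeric similarity value in ", path)
    if (any(v < 0 | v > 1)) stop("similarity values must lie in [0,1]")
    dn <- sort(unique(c(a, b)))
    S <- matrix(0, length(dn), length(dn), dimnames = list(dn, dn))
    seen <- matrix(FALSE, length(dn), length(dn))
    for (r in seq_along(a)) {
        i <- match(a[r], dn); j <- match(b[r], dn)
        if (seen[i, j] && abs(S[i, j] - v[r]) > 1e-12)
            stop(sprintf("conflicting similarity entries for (%s, %s)",
                         a[r], b[r]))
        S[i, j] <- v[r]; S[j, i] <- v[r]
        seen[i, j] <- TRUE; seen[j, i] <- TRUE
    }
    DiseaseSimilarityNetwork(S, theta = theta)
}

#' Build the prior disease-gene association matrix
#'
#' Known pairs score exactly 1. For an unknown pair (p, g) the score is the
#' similarity between p and the most similar disease q that is known to be
#' associated with g; scores below `theta` are filtered to 0, so the prior
#' carries only confident similarity signal.
#'
#' @param assocs data.frame with columns `disease`, `gene` (known pairs).
#' @param sim a [DiseaseSimilarityNetwork-class].
#' @param net a [GeneNetwork-class] providing the gene universe.
#' @param theta filter threshold applied to the derived (non-known) scores;
#'   defaults to the similarity network's own theta.
#' @return an [AssociationMatrix-class] with role `"prior"`.
#' @export
buildPriorMatrix <- function(assocs, sim, net, theta = sim@theta) {
    assocs <- as.data.frame(assocs)
    d <- as.character(assocs[[1]]); g <- as.character(assocs[[2]])
    unknownD <- setdiff(d, sim@diseases)
    if (length(unknownD)) stop("unknown disease identifier(s): ",
                               paste(unknownD, collapse = ", "))
    unknownG <- setdiff(g, net@genes)
    if (length(unknownG)) stop("unknown gene identifier(s): ",
                               paste(unknownG, collapse = ", "))
    S <- sim@similarity
    nd <- length(sim@diseases); ng <- length(net@genes)
    K <- matrix(0, nd, ng, dimnames = list(sim@diseases, net@genes))
    K[cbind(match(d, sim@diseases), match(g, net@genes))] <- 1
    # for each gene, score(p) = max over q with K[q,g]=1 of S[p,q]
    F0 <- matrix(0, nd, ng, dimnames = dimnames(K))
    for (j in which(colSums(K) > 0)) {
        q <- which(K[, j] == 1)
        v <- if (length(q) == 1L) S[, q] else apply(S[, q, drop = FALSE], 1, max)
        v[v < theta] <- 0
        F0[, j] <- v
    }
    F0[K == 1] <- 1
    new("AssociationMatrix", diseases = sim@diseases, genes = net@genes,
        scores = F0, role = "prior")
}

#' Symmetric degree normalization
#'
#' Returns `D^(-1/2) M D^(-1/2)` where `D` is the diagonal of row sums. For a
#' symmetric nonnegative input the result is symmetric with spectral radius
#' at most 1, which guarantees convergence of the propagation whenever the
#' prior weight is positive.
#'
#' @param M square symmetric nonnegative matrix (base or `Matrix`) with every
#'   row sum positive (the unit diagonal of the extended network / similarity
#'   network guarantees this).
#' @return normalized matrix of the same class family.
#' @export
normalizeSymmetric <- function(M) {
    rs <- Matrix::rowSums(M)
    if (any(rs <= 0)) {
        nm <- rownames(M)[which(rs <= 0)[1]]
        stop("zero row sum at node ", if (is.null(nm)) which(rs <= 0)[1] else nm)
    }
    d <- 1 / sqrt(rs)
    if (is(M, "Matrix")) {
        D <- Matrix::Diagonal(x = d)
        out <- D %*% M %*% D
        dimnames(out) <- dimnames(M)
        out
    } else {
        M * outer(d, d)
    }
}

#' Row-stochastic normalization
#'
#' Divides every row by its sum; rows then sum to 1. Alternative to
#' [normalizeSymmetric()] selectable through
#' `PropagationConfig(normalization = "row_stochastic")`.
#'
#' @inheritParams normalizeSymmetric
#' @return row-normalized matrix.
#' @export
normalizeRowStochastic <- function(M) {
    rs <- Matrix::rowSums(M)
    if (any(rs <= 0)) {
        nm <- rownames(M)[which(rs <= 0)[1]]
        stop("zero row sum at node ", if (is.null(nm)) which(rs <= 0)[1] else nm)
    }
    if (is(M, "Matrix")) {
        out <- Matrix::Diagonal(x = 1 / rs) %*% M
        dimnames(out) <- dimnames(M)
        out
    } else {
        M / rs
    }
}

#' Read a BED-like gene coordinate table
#'
#' Columns `chrom  start  end  gene_id`, 0-based half-open intervals, one
#' record per gene. Strand is ignored: linkage-interval controls order genes
#' purely by chromosomal position.
#'
#' @param path TSV file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`, sorted by
#'   (chrom, start).
#' @export
loadGeneCoordinates <- function(path) {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("coordinate table needs 4 columns (chrom, start, end, gene)")
    tab <- data.frame(chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]),
                      end = as.integer(tab[[3]]),
                      gene = as.character(tab[[4]]),
                      stringsAsFactors = FALSE)
    if (any(tab$start >= tab$end))
        stop("degenerate interval (start >= end) for gene ",
             tab$gene[which(tab$start >= tab$end)[1]])
    if (anyDuplicated(tab$gene))
        stop("duplicate gene_id in coordinate table: ",
             tab$gene[duplicated(tab$gene)][1])
    tab[order(tab$chrom, tab$start), , drop = FALSE]
}

#' Read a disease-gene association table
#' @param path TSV with columns `disease_id`, `gene_id`.
#' @return data.frame with columns `disease`, `gene`.
#' @export
loadAssociations <- function(path) {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("association table needs 2 columns")
    unique(data.frame(disease = as.character(tab[[1]]),
                      gene = as.character(tab[[2]]),
                      stringsAsFactors = FALSE))
}

#' Write networks and tables in the package's on-disk formats
#'
#' These emit exactly the TSV formats the loaders read, so a write/read
#' round trip reproduces identical matrices.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePPIEdgelist <- function(net, path) {
    A <- as.matrix(net@adjacency)
    idx <- which(A != 0 & upper.tri(A, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(a = net@genes[idx[, 1]], b = net@genes[idx[, 2]])
    df <- df[order(df$a, df$b), ]
    writeLines(c("# gene_a\tgene_b", paste(df$a, df$b, sep = "\t")), path)
    invisible(path)
}

#' @rdname writePPIEdgelist
#' @param sim a [DiseaseSimilarityNetwork-class]; written as upper-triangle
#'   triplets of nonzero off-diagonal similarities.
#' @export
writeDiseaseSimilarity <- function(sim, path) {
    S <- sim@similarity
    idx <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
    df <- data.frame(a = sim@diseases[idx[, 1]], b = sim@diseases[idx[, 2]],
                     s = S[idx])
    df <- df[order(df$a, df$b), ]
    writeLines(c("# disease_a\tdisease_b\tsimilarity",
                 sprintf("%s\t%s\t%.10g", df$a, df$b, df$s)), path)
    invisible(path)
}

#' @rdname writePPIEdgelist
#' @param assocs data.frame with columns `disease`, `gene`.
#' @export
writeAssociations <- function(assocs, path) {
    assocs <- assocs[order(assocs$disease, assocs$gene), ]
    writeLines(c("# disease_id\tgene_id",
                 paste(assocs$disease, assocs$gene, sep = "\t")), path)
    invisible(path)
}

#' @rdname writePPIEdgelist
#' @param coords data.frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
writeGeneCoordinates <- function(coords, path) {
    writeLines(c("# chrom\tstart\tend\tgene_id",
                 sprintf("%s\t%d\t%d\t%s", coords$chrom, coords$start,
                         coords$end, coords$gene)), path)
    invisible(path)
}
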