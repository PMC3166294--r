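test_that("edge list loading collapses duplicates and keeps isolated nodes", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("# gene_a\tgene_b", "a\tb", "b\ta", "b\tc"), path)
    net <- loadPPIEdgelist(path)
    expect_setequal(genes(net), c("a", "b", "c"))
    A <- as.matrix(adjacency(net))
    expect_equal(sum(A) / 2, 2)          # two undirected edges
    expect_equal(A, t(A))

    withIso <- loadPPIEdgelist(path, nodes = "zz")
    expect_true("zz" %in% genes(withIso))
    expect_equal(sum(as.matrix(adjacency(withIso))["zz", ]), 0)
})

test_that("self-pairs are recorded once and flagged", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("a\ta", "a\tb"), path)
    expect_message(net <- loadPPIEdgelist(path), "self-interaction")
    expect_equal(as.matrix(adjacency(net))["a", "a"], 1)
})

test_that("malformed and empty edge files raise errors naming the problem", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("a\tb", "lonely"), path)
    expect_error(loadPPIEdgelist(path), "line 2")
    writeLines("# only a header", path)
    expect_error(loadPPIEdgelist(path), "empty")
})

test_that("a 5-edge toy file reproduces the hand-built adjacency", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("g1\tg2", "g2\tg3", "g3\tg4", "g4\tg1", "g1\tg3"), path)
    net <- loadPPIEdgelist(path)
    expected <- matrix(c(0, 1, 1, 1,
                         1, 0, 1, 0,
                         1, 1, 0, 1,
                         1, 0, 1, 0), 4, 4, byrow = TRUE,
                       dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
    expect_equal(as.matrix(adjacency(net)), expected)
})

test_that("self-loop extension sets the diagonal and guards idempotence", {
    net <- GeneNetwork(data.frame(a = "x", b = "y"))
    ext <- extendSelfLoops(net)
    expect_equal(as.matrix(adjacency(ext)),
                 matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
    expect_true(ext@selfLoopsAdded)
    expect_error(extendSelfLoops(ext), "already")

    # path graph: diagonal added, off-diagonal untouched
    p4 <- extendSelfLoops(GeneNetwork(data.frame(a = c("a", "b", "c"),
                                                 b = c("b", "c", "d"))))
    A <- as.matrix(adjacency(p4))
    expect_equal(diag(A), setNames(rep(1, 4), letters[1:4]))
    expect_equal(sum(A) - 4, 2 * 3)      # the 3 path edges survive

    # edgeless network extends to the identity
    iso <- extendSelfLoops(GeneNetwork(data.frame(a = character(0),
                                                  b = character(0)),
                                       nodes = c("u", "v", "w")))
    expect_equal(as.matrix(adjacency(iso)), diag(3), ignore_attr = TRUE)
})

test_that("similarity filtering applies theta, symmetrizes, forces the diagonal", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("d1\td2\t0.7", "d1\td3\t0.4"), path)
    sim <- loadDiseaseSimilarity(path, theta = 0.5)
    S <- similarity(sim)
    expect_equal(S["d1", "d2"], 0.7)
    expect_equal(S["d2", "d1"], 0.7)
    expect_equal(S["d1", "d3"], 0)
    expect_equal(unname(diag(S)), rep(1, 3))

    sim0 <- loadDiseaseSimilarity(path, theta = 0)
    expect_equal(similarity(sim0)["d1", "d3"], 0.4)
    sim1 <- loadDiseaseSimilarity(path, theta = 1)
    expect_equal(sum(similarity(sim1)) , 3)  # only the diagonal survives
})

test_that("similarity loader rejects bad values and conflicting duplicates", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines("d1\td2\t1.4", path)
    expect_error(loadDiseaseSimilarity(path), "\\[0,1\\]")
    writeLines(c("d1\td2\t0.7", "d2\td1\t0.6"), path)
    expect_error(loadDiseaseSimilarity(path), "conflicting")
    writeLines(c("d1\td2\t0.7", "d2\td1\t0.7"), path)
    expect_silent(loadDiseaseSimilarity(path))
})

test_that("dense labeled similarity matrices load equivalently to triplets", {
    dn <- c("d1", "d2")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste(c("", dn), collapse = "\t"),
                 "d1\t1\t0.8", "d2\t0.8\t1"), path)
    sim <- loadDiseaseSimilarity(path, theta = 0.5)
    expect_equal(similarity(sim)["d1", "d2"], 0.8)
})

test_that("prior matrix follows the known / most-similar-disease rule", {
    gn <- extendSelfLoops(GeneNetwork(data.frame(a = "g1", b = "g2")))
    S <- matrix(c(1, 0.7, 0.7, 1), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
    sim <- DiseaseSimilarityNetwork(S, theta = 0.5)
    prior <- buildPriorMatrix(data.frame(disease = "q", gene = "g1"), sim, gn)
    expect_equal(scores(prior)["q", "g1"], 1)           # known pair
    expect_equal(scores(prior)["p", "g1"], 0.7)         # via similar disease
    expect_equal(scores(prior)["p", "g2"], 0)           # gene unknown anywhere

    # below-theta similarity is filtered out of the derived prior
    S2 <- DiseaseSimilarityNetwork(matrix(c(1, 0.4, 0.4, 1), 2, 2,
            dimnames = dimnames(S)), theta = 0)
    prior2 <- buildPriorMatrix(data.frame(disease = "q", gene = "g1"), S2, gn,
                               theta = 0.5)
    expect_equal(scores(prior2)["p", "g1"], 0)
    expect_error(buildPriorMatrix(data.frame(disease = "q", gene = "nope"),
                                  sim, gn), "nope")
})

test_that("an identity similarity yields exactly the 0/1 known matrix", {
    inst <- randomInstance(4, 6, seed = 11)
    idS <- diag(4)
    dimnames(idS) <- list(diseases(inst$sim), diseases(inst$sim))
    idSim <- DiseaseSimilarityNetwork(idS, theta = 0.5)
    prior <- buildPriorMatrix(inst$assoc, idSim, inst$net)
    K <- matrix(0, 4, 6, dimnames = dimnames(scores(prior)))
    K[cbind(inst$assoc$disease, inst$assoc$gene)] <- 1
    expect_equal(scores(prior), K)
})

test_that("raising theta never increases filtered similarities or derived priors", {
    inst <- randomInstance(5, 8, seed = 3, theta = 0)
    Sraw <- similarity(inst$sim)
    prev <- NULL
    prevPrior <- NULL
    known <- matrix(FALSE, 5, 8)
    for (th in c(0, 0.3, 0.6, 0.9)) {
        sim <- DiseaseSimilarityNetwork(Sraw, theta = th)
        prior <- buildPriorMatrix(inst$assoc, sim, inst$net, theta = th)
        if (!is.null(prev)) {
            off <- row(similarity(sim)) != col(similarity(sim))
            expect_true(all(similarity(sim)[off] <= prev[off] + 1e-12))
            expect_true(all(scores(prior) <= prevPrior + 1e-12))
        }
        prev <- similarity(sim)
        prevPrior <- scores(prior)
    }
})

test_that("symmetric normalization matches hand computation and spectral bound", {
    expect_equal(normalizeSymmetric(diag(3)), diag(3))
    M <- matrix(1, 2, 2)
    expect_equal(normalizeSymmetric(M), matrix(0.5, 2, 2))
    for (s in 1:10) {
        set.seed(s)
        R <- matrix(runif(36), 6, 6)
        R <- (R + t(R)) / 2
        ev <- eigen(as.matrix(normalizeSymmetric(R)), symmetric = TRUE,
                    only.values = TRUE)$values
        expect_lt(max(abs(ev)), 1 + 1e-12)
    }
    Z <- diag(2); Z[1, 1] <- 0
    rownames(Z) <- colnames(Z) <- c("n1", "n2")
    expect_error(normalizeSymmetric(Z), "n1")
})

test_that("row-stochastic normalization gives unit row sums", {
    set.seed(4)
    R <- matrix(runif(25), 5, 5); R <- R + t(R)
    expect_equal(unname(rowSums(normalizeRowStochastic(R))), rep(1, 5))
})

test_that("gene coordinate tables are validated and sorted", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chr2\t100\t200\tgB", "chr1\t500\t600\tgC", "chr1\t0\t50\tgA"),
               path)
    tab <- loadGeneCoordinates(path)
    expect_equal(tab$gene, c("gA", "gC", "gB"))
    writeLines("chr1\t100\t100\tgX", path)
    expect_error(loadGeneCoordinates(path), "gX")
    writeLines(c("chr1\t0\t10\tgA", "chr1\t20\t30\tgA"), path)
    expect_error(loadGeneCoordinates(path), "duplicate")
})

test_that("write/read round trips reproduce identical matrices", {
    inst <- generateModularInstance(nModules = 2, genesPerModule = 8,
                                    diseasesPerCluster = 3,
                                    assocPerCluster = 6, seed = 9)
    dir <- withr::local_tempdir()
    writeInstance(inst, dir)
    net2 <- loadPPIEdgelist(file.path(dir, "ppi.tsv"),
                            nodes = genes(inst@network))
    expect_equal(as.matrix(adjacency(net2)),
                 as.matrix(adjacency(inst@network)))
    sim2 <- loadDiseaseSimilarity(file.path(dir, "sim.tsv"), theta = 0.5)
    expect_equal(similarity(sim2), similarity(inst@similarity),
                 tolerance = 1e-9)
    assoc2 <- loadAssociations(file.path(dir, "assoc.tsv"))
    expect_setequal(paste(assoc2$disease, assoc2$gene),
                    paste(inst@associations$disease, inst@associations$gene))
    coords2 <- loadGeneCoordinates(file.path(dir, "coords.tsv"))
    expect_setequal(coords2$gene, genes(inst@network))
})
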