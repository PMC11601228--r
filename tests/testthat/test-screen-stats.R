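toyLib <- GuideLibrary(
    guide_id = c("GA_1", "GA_2", "NTC_1", "NTC_2", "NTC_3"),
    gene = c("GA", "GA", "NTC", "NTC", "NTC"),
    protospacer = c("GGATCGCGTCTAGTGCAGAT", "GGGGTGAGGGTCCAATTCGG",
                    "GGTGGGAGAGGCGGCTTCAC", "GCGTCGAGCGGTGCAGACAA",
                    "GCCGACCGCGGCAAGCAAGC"))

test_that("RPM normalisation: symmetry, scale invariance, pseudocount arithmetic", {
    m <- matrix(c(50, 50), ncol = 1, dimnames = list(c("a", "b"), "s1"))
    expect_equal(unname(normalizeCounts(m, 0)[, 1]), c(5e5, 5e5))

    m2 <- matrix(c(10, 30, 60, 20, 60, 120), ncol = 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    rpm <- normalizeCounts(m2, 0)
    expect_equal(rpm[, "s1"], rpm[, "s2"])

    # 3-guide toy with a zero count and pseudocount 0.5
    m3 <- matrix(c(0, 33, 66), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
    rpm3 <- normalizeCounts(m3, 0.5)
    expect_equal(unname(rpm3[, 1]),
                 c(0.5, 33.5, 66.5) / 100.5 * 1e6)

    expect_error(normalizeCounts(matrix(0, 2, 1,
                                        dimnames = list(c("a", "b"), "s"))),
                 "all-zero")
})

test_that("guide LFC and robust z match hand arithmetic on a toy screen", {
    counts <- matrix(c(100, 100, 200, 100, 50,     # rep1 low
                       400, 100, 200, 100, 50),    # rep1 high
                     ncol = 2,
                     dimnames = list(guideIds(toyLib),
                                     c("rep1_low", "rep1_high")))
    rpm <- normalizeCounts(counts, 0)
    gs <- guideLfc(rpm, data.frame(replicate = 1L, low = "rep1_low",
                                   high = "rep1_high"), toyLib)
    # per-sample totals: low 550, high 850; hand LFC for GA_1:
    # log2((400/850)/(100/550))
    expect_equal(gs$lfc_mean[gs$guide_id == "GA_1"],
                 log2((400 / 850) / (100 / 550)))
    # all other guides share the same depth-ratio LFC
    shared <- log2((100 / 850) / (100 / 550))
    expect_equal(gs$lfc_mean[gs$guide_id == "NTC_1"], shared)
    # NTC guides are identical, so their median is shared and a guide at the
    # median has z = 0; spread collapses, so z is NA here
    expect_true(is.na(gs$z[1]) || gs$z[gs$guide_id == "NTC_1"] == 0)

    # identical high/low columns give all-zero LFC
    same <- cbind(rep1_low = counts[, 1], rep1_high = counts[, 1])
    gs0 <- guideLfc(normalizeCounts(same, 0),
                    data.frame(replicate = 1L, low = "rep1_low",
                               high = "rep1_high"), toyLib)
    expect_equal(gs0$lfc_mean, rep(0, 5))

    expect_error(guideLfc(rpm, data.frame(replicate = 1, low = "rep1_low",
                                          high = "nope"), toyLib),
                 "missing")
})

test_that("z-scores centre on the NTC median and scale by 1.4826 MAD", {
    rpm <- matrix(2^c(0, 3, 0, 0, 0,
                      1, 3, 1.2, 0.8, 2), ncol = 2,
                  dimnames = list(guideIds(toyLib),
                                  c("rep1_low", "rep1_high")))
    gs <- guideLfc(rpm, data.frame(replicate = 1L, low = "rep1_low",
                                   high = "rep1_high"), toyLib)
    ntc <- gs$lfc_mean[gs$is_ntc]
    expect_equal(gs$z[gs$is_ntc],
                 (ntc - median(ntc)) / mad(ntc))
})

test_that("Mann-Whitney gene test matches exact enumeration", {
    # 2 guides above all 28 NTCs: p = 2 / C(30, 2)
    ntc <- seq(-1, 1, length.out = 28)
    p <- geneTest(c(2, 3), ntc)
    expect_equal(p, 2 / choose(30, 2))
    expect_equal(p, mwuEnumerationOracle(c(2, 3), ntc))

    # central U gives p = 1
    expect_equal(geneTest(c(0.5), c(0, 1)), 1)

    # exact and approximate p agree on random no-tie instances to within the
    # enumerated worst case: over all U at n1 = 2, n2 = 28 the largest
    # |exact - approx| is 0.0334 (at U = 16)
    set.seed(12)
    diffs <- replicate(100, {
        g <- rnorm(2)
        n <- rnorm(28)
        exact <- mwuEnumerationOracle(g, n)
        approx <- suppressWarnings(
            wilcox.test(g, n, exact = FALSE, correct = TRUE)$p.value)
        abs(exact - approx)
    })
    expect_lt(max(diffs), 0.034)
    expect_lt(median(diffs), 0.02)

    expect_error(geneTest(numeric(0), ntc), "empty")
})

test_that("gene phenotype is a weighted geometric mean of guide fold changes", {
    expect_equal(genePhenotype(c(1, 1))$phenotype_fc, 2)
    expect_equal(genePhenotype(c(2, 0), weight_mode = "equal")$phenotype_fc, 2)
    # weights 0.75/0.25 arise from |z| = c(3, 1)
    ph <- genePhenotype(c(3, 1), z = c(3, 1), weight_mode = "zscore")
    expect_equal(ph$weights, c(0.75, 0.25))
    expect_equal(ph$phenotype_fc, 2^2.5)
    # |z| floor 0.25 keeps a null guide contributing
    ph2 <- genePhenotype(c(4, 0), z = c(1, 0), weight_mode = "zscore")
    expect_equal(ph2$weights, c(0.8, 0.2))
    # equal weights equal the unweighted geometric mean of fold changes
    lfcs <- c(0.3, -1.2, 2.1)
    expect_equal(genePhenotype(lfcs, weight_mode = "equal")$phenotype_fc,
                 prod(2^lfcs)^(1 / 3))
})

test_that("pseudogene construction enumerates or samples as sized", {
    ids28 <- sprintf("NTC_%02d", 1:28)
    pg <- makePseudogenes(ids28, 2)
    expect_length(pg, choose(28, 2))
    expect_true(all(vapply(pg, function(g) length(unique(g)) == 2, logical(1))))

    expect_length(makePseudogenes(c("a", "b", "c"), 2), 3)

    ids200 <- sprintf("NTC_%03d", 1:200)
    s1 <- makePseudogenes(ids200, 2, seed = 5)
    s2 <- makePseudogenes(ids200, 2, seed = 5)
    expect_identical(s1, s2)
    expect_length(s1, 1000)

    expect_error(makePseudogenes(c("a", "b"), 3), "exceeds")
})

test_that("empirical FDR reproduces the threshold-enumeration example", {
    q <- empiricalFdr(c(5, 4, 3), c(4.5, 1, 0.5, 0.2), "positive")
    expect_equal(q, c(0, 0.25, 0.25))

    # all pseudo scores below all gene scores: every q is 0
    expect_equal(empiricalFdr(c(3, 2), c(1, 0.5), "positive"), c(0, 0))

    # negative tail mirrors
    qn <- empiricalFdr(-c(5, 4, 3), -c(4.5, 1, 0.5, 0.2), "negative")
    expect_equal(qn, c(0, 0.25, 0.25))

    # q monotone non-increasing in score within a tail
    set.seed(3)
    g <- rnorm(50)
    p <- rnorm(200)
    q <- empiricalFdr(g, p, "positive")
    ord <- order(g, decreasing = TRUE)
    expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("gene scores drawn from the pseudo distribution have q near 1", {
    med_q <- sapply(1:20, function(s) {
        set.seed(s)
        median(empiricalFdr(rnorm(100), rnorm(1000), "positive"))
    })
    expect_gt(mean(med_q), 0.8)
})

test_that("hit calling partitions by sign and respects alpha boundaries", {
    res <- data.frame(gene = c("a", "b", "c"),
                      phenotype_lfc = c(1, -1, 0.2),
                      q_pos = c(0.001, 0.9, 0.5),
                      q_neg = c(0.9, 0.001, 0.5))
    out <- callHits(res, 0.01)
    expect_equal(out$hit_class, c("increase", "decrease", "none"))
    # alpha = 1: everything with finite q is a hit
    out1 <- callHits(res, 1)
    expect_true(all(out1$hit_class != "none"))
})

test_that("depth rescaling of one sample leaves all LFCs unchanged", {
    lib <- simulateGuideLibrary(6, 2, 4, 20, seed = 2)
    sim <- simulateScreen(screenConfig(lib, cells_per_guide = 100,
                                       reads_per_bin = 1e4, seed = 4,
                                       n_replicates = 2L))
    m <- screenCountsMatrix(sim$counts)
    pairs <- replicatePairs(sim$counts)
    gs1 <- guideLfc(normalizeCounts(m, 0), pairs, lib)
    m2 <- m
    m2[, 1] <- m2[, 1] * 7L
    gs2 <- guideLfc(normalizeCounts(m2, 0), pairs, lib)
    expect_equal(gs1$lfc_mean, gs2$lfc_mean)
})

test_that("scoreScreen output is internally consistent", {
    lib <- simulateGuideLibrary(10, 2, 28, 20, seed = 6)
    sim <- simulateScreen(screenConfig(lib, cells_per_guide = 200,
                                       effects = c(G0001 = 2, G0002 = -2),
                                       reads_per_bin = 1e5, seed = 8))
    res <- scoreScreen(sim$counts)
    g <- res$genes
    expect_setequal(g$gene, sprintf("G%04d", 1:10))
    expect_equal(g$phenotype_fc, 2^g$phenotype_lfc)
    expect_true(all(g$bh_q >= g$p_value - 1e-12))
    expect_true(all(g$p_value > 0 & g$p_value <= 1))
    expect_equal(g$hit_class[g$gene == "G0001"], "increase")
    expect_equal(g$hit_class[g$gene == "G0002"], "decrease")
    expect_equal(nrow(res$pseudogenes), choose(28, 2))
})

test_that("cross-screen comparison keeps genes hit anywhere, with flags", {
    mk <- function(lfc, hit) {
        data.frame(gene = c("g1", "g2", "g3"), phenotype_lfc = lfc,
                   hit_class = hit)
    }
    a <- mk(c(0.8, 0, 0), c("increase", "none", "none"))
    b <- mk(c(0.1, 0, -0.4), c("none", "none", "decrease"))
    cmp <- compareScreens(list(synapse = a, beads = b))
    expect_equal(rownames(cmp$lfc), c("g1", "g3"))
    expect_equal(cmp$significant["g1", ], c(synapse = TRUE, beads = FALSE))

    none <- mk(c(0, 0, 0), rep("none", 3))
    empty <- compareScreens(list(x = none, y = none))
    expect_equal(nrow(empty$lfc), 0)

    bad <- mk(c(0, 0, 0), rep("none", 3))
    bad$gene[1] <- "other"
    expect_error(compareScreens(list(x = a, y = bad)), "differ")
})

test_that("three simulated screens recover each screen's true effect signs", {
    lib <- simulateGuideLibrary(8, 2, 28, 20, seed = 31)
    effs <- list(beads = c(G0001 = 2), synaptosomes = c(G0002 = -2),
                 pruning = c(G0001 = 2, G0002 = -2))
    results <- lapply(seq_along(effs), function(i) {
        sim <- simulateScreen(screenConfig(lib, effects = effs[[i]],
                                           cells_per_guide = 300,
                                           reads_per_bin = 1e5,
                                           seed = 40 + i))
        scoreScreen(sim$counts)$genes
    })
    names(results) <- names(effs)
    cmp <- compareScreens(results)
    expect_true(all(c("G0001", "G0002") %in% rownames(cmp$lfc)))
    expect_gt(cmp$lfc["G0001", "beads"], 0)
    expect_lt(cmp$lfc["G0002", "synaptosomes"], 0)
    expect_true(cmp$significant["G0001", "pruning"])
    expect_true(cmp$significant["G0002", "pruning"])
})
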