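recFixture <- function() {
    data.frame(
        sample_id = c("t1", "t1", "t1", "t2", "t2"),
        gene_symbol = c("APC", "APC", "KRAS", "TP53", "APC"),
        ensembl_gene_id = c("ENSG_APC", "ENSG_APC", "ENSG_KRAS",
                            "ENSG_TP53", "ENSG_APC"),
        raw_effect = c("stop_gained", "frameshift_variant",
                       "missense_variant", "synonymous_variant",
                       "upstream_gene_variant"),
        stringsAsFactors = FALSE) |>
        transform(effect_class = classifyEffect(raw_effect))
}

test_that("effect classification follows the LoF definition", {
    expect_equal(classifyEffect(c("frameshift_variant", "STOP_GAINED",
                                  "stop_lost")),
                 rep("lof", 3))
    expect_equal(classifyEffect("missense_variant"), "missense")
    expect_equal(classifyEffect("synonymous_variant"), "synonymous")
    expect_equal(classifyEffect("upstream_gene_variant"), "other")
    ## compound annotations take the most severe matching term
    expect_equal(classifyEffect("stop_gained&splice_region_variant"), "lof")
})

test_that("binary matrices respect scope and are binarization-invariant", {
    rec <- recFixture()
    samples <- c("t1", "t2", "t3")
    m_lof <- buildMutationMatrix(rec, samples, "lof")
    expect_equal(mutationCalls(m_lof)["APC", ], c(t1 = 1, t2 = 0, t3 = 0))
    expect_true(all(mutationCalls(m_lof) %in% 0:1))
    m_mis <- buildMutationMatrix(rec, samples, "missense")
    expect_equal(unname(mutationCalls(m_mis)["APC", "t1"]), 0)
    expect_equal(unname(mutationCalls(m_mis)["KRAS", "t1"]), 1)
    ## duplicating records changes nothing (5 records in one cell still 1)
    rec_dup <- rbind(rec, rec, rec, rec, rec)
    expect_identical(mutationCalls(buildMutationMatrix(rec_dup, samples, "lof")),
                     mutationCalls(m_lof))
    expect_warning(
        empty <- buildMutationMatrix(rec[0, ], samples, "lof"),
        "all-zero")
    expect_true(all(mutationCalls(empty) == 0))
})

test_that("pathway collapse ORs member genes and is monotone", {
    rec <- recFixture()
    m <- buildMutationMatrix(rec, c("t1", "t2", "t3"), "lof")
    map <- list(WntA = c("ENSG_APC", "ENSG_CTNNB1"),
                Other = c("ENSG_APC", "ENSG_KRAS"),
                Absent = "ENSG_NOPE")
    pw <- collapseToPathways(m, map, "PID")
    expect_equal(unname(mutationCalls(pw)["WntA", ]), c(1, 0, 0))
    ## gene in two pathways mutated -> both pathways called
    expect_equal(unname(mutationCalls(pw)["Other", "t1"]), 1)
    ## pathway with no member present dropped
    expect_false("Absent" %in% featureIds(pw))
    expect_equal(featureKind(pw), "pid_pathway")
    ## sample with no LoF gene: all pathways 0
    expect_true(all(mutationCalls(pw)[, "t3"] == 0))

    ## monotonicity: adding a mutation can only flip 0 -> 1
    rec2 <- rbind(rec, data.frame(sample_id = "t3", gene_symbol = "KRAS",
                                  ensembl_gene_id = "ENSG_KRAS",
                                  raw_effect = "stop_gained",
                                  effect_class = "lof"))
    pw2 <- collapseToPathways(
        buildMutationMatrix(rec2, c("t1", "t2", "t3"), "lof"), map, "PID")
    common <- intersect(featureIds(pw), featureIds(pw2))
    expect_true(all(mutationCalls(pw2)[common, ] >=
                    mutationCalls(pw)[common, ]))
})

test_that("prevalence filter keeps features at the boundary", {
    set.seed(1)
    calls <- rbind(at10 = c(rep(1, 10), rep(0, 34)),
                   at9 = c(rep(1, 9), rep(0, 35)),
                   at1 = c(1, rep(0, 43)),
                   at0 = rep(0, 44))
    colnames(calls) <- sprintf("t%02d", 1:44)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls))
    m <- new("MutationMatrix", se, featureKind = "gene", effectScope = "lof")
    f10 <- prevalenceFilter(m, 10)
    expect_equal(featureIds(f10), "at10")
    rep10 <- metadata(f10)$prevalenceReport
    expect_equal(rep10$kept, 1L)
    expect_equal(rep10$dropped, 3L)
    ## minPatients = 1 keeps exactly the features with >= 1 mutated sample
    expect_setequal(featureIds(prevalenceFilter(m, 1)),
                    c("at10", "at9", "at1"))
})

test_that("stage groups split 1-2 vs 3-4 with explicit missingness", {
    md <- data.frame(sample_id = paste0("t", 1:5),
                     stage = c(1L, 2L, 3L, 4L, NA))
    g <- stageGroups(md)
    expect_equal(as.character(g), c("low", "low", "high", "high", NA))
    expect_equal(names(g), md$sample_id)
})

test_that("confounding test matches the exact hypergeometric", {
    ## 5 mutated samples all low stage, 5 unmutated all high stage:
    ## two-sided Fisher p = 2/252
    calls <- matrix(c(rep(1, 5), rep(0, 5)), 1,
                    dimnames = list("APC", paste0("t", 1:10)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls))
    m <- new("MutationMatrix", se, featureKind = "gene", effectScope = "lof")
    g <- setNames(factor(c(rep("low", 5), rep("high", 5)),
                         levels = c("low", "high")), paste0("t", 1:10))
    res <- confoundingTest(m, g)
    expect_equal(res$p, 2 / 252, tolerance = 1e-12)

    ## independent margins [[3,3],[3,3]] give p = 1
    calls2 <- matrix(rep(c(1, 1, 1, 0, 0, 0), 2), 1,
                     dimnames = list("X", paste0("t", 1:12)))
    se2 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls2))
    m2 <- new("MutationMatrix", se2, featureKind = "gene",
              effectScope = "lof")
    g2 <- setNames(factor(rep(c("low", "high"), each = 6),
                          levels = c("low", "high")), paste0("t", 1:12))
    expect_equal(confoundingTest(m2, g2)$p, 1)

    ## all-missing stage errors
    gna <- setNames(factor(rep(NA_character_, 10),
                           levels = c("low", "high")), paste0("t", 1:10))
    expect_error(confoundingTest(m, gna), "missing stage")
})

test_that("confounding q-values are calibrated on permuted labels", {
    ## 20 random features against random stage groups: the minimum
    ## BH q should rarely dip under 0.05
    set.seed(42)
    hits <- vapply(1:40, function(i) {
        calls <- matrix(rbinom(20 * 24, 1, 0.4), 20,
                        dimnames = list(paste0("g", 1:20), paste0("t", 1:24)))
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(calls = calls))
        m <- new("MutationMatrix", se, featureKind = "gene",
                 effectScope = "lof")
        g <- setNames(factor(sample(rep(c("low", "high"), 12)),
                             levels = c("low", "high")),
                      paste0("t", 1:24))
        min(confoundingTest(m, g)$q) < 0.05
    }, logical(1))
    expect_lt(mean(hits), 0.2)
})
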