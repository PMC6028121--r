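test_that("arcsine-root transform is exact and clips only at tolerance", {
    expect_identical(arcsineSqrt(0), 0)
    expect_equal(arcsineSqrt(1), pi / 2)
    expect_equal(arcsineSqrt(0.25), pi / 6)
    expect_equal(arcsineSqrt(1 + 1e-13), pi / 2)
    expect_error(arcsineSqrt(1.001), "0, 1")
    expect_error(arcsineSqrt(-0.1), "0, 1")
})

test_that("risk index closed forms and model validity", {
    m <- riskModel("g__A", "g__B")
    ri <- riskIndex(c(g__A = 0.04, g__B = 0.01), m)
    expect_equal(as.numeric(ri), asin(0.2) - asin(0.1), tolerance = 1e-12)
    expect_equal(as.numeric(ri), 0.101190, tolerance = 1e-5)
    ## symmetry: equal abundances cancel in a one-vs-one model
    expect_equal(as.numeric(riskIndex(c(g__A = 0.03, g__B = 0.03), m)), 0)
    ## empty negative set: plain sum of transformed positives
    m2 <- riskModel(c("g__A", "g__B"))
    expect_equal(as.numeric(riskIndex(c(g__A = 0.01, g__B = 0.01), m2)),
                 2 * asin(0.1), tolerance = 1e-12)
    ## absent taxa contribute zero and are reported
    ri3 <- riskIndex(c(g__A = 0.04), m)
    expect_equal(as.numeric(ri3), asin(0.2))
    expect_equal(attr(ri3, "missingTaxa"), "g__B")
    expect_error(riskModel(character(0)), "at least one")
    expect_error(riskModel("g__A", "g__A"), "disjoint")
})

test_that("swapping positive and negative taxa negates indices exactly", {
    at <- relativeAbundance(makeCountTable(nTaxa = 12, n = 8, seed = 4))
    taxa <- taxonIds(at)
    m1 <- riskModel(taxa[1:3], taxa[4:6])
    m2 <- riskModel(taxa[4:6], taxa[1:3])
    r1 <- applyModel(m1, at)
    r2 <- applyModel(m2, at)
    expect_identical(unname(r1), unname(-r2))
    ## boundedness
    expect_true(all(abs(r1) <= (pi / 2) * 6))
})

test_that("BH adjustment matches hand-computed step-up values", {
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(fdrAdjust(0.2), 0.2)
    expect_equal(fdrAdjust(c(0.001, 0.5)), c(0.002, 0.5))
    expect_identical(fdrAdjust(numeric(0)), numeric(0))
    expect_error(fdrAdjust(c(0, 0.5)), "\\(0, 1\\]")
    p <- c(0.04, 0.001, 0.9, 0.3)
    q <- fdrAdjust(p)
    expect_true(all(q >= p))
    expect_true(!is.unsorted(q[order(p)]))
})

test_that("MWU p on {1,2,3} vs {4,5,6} is the exact 0.1", {
    expect_equal(wilcox.test(1:3, 4:6)$p.value, 2 / choose(6, 3))
    expect_equal(wilcox.test(1:3, 4:6)$p.value, 0.1)
})

test_that("leave-one-out separates a perfectly predictive taxon", {
    at <- relativeAbundance(makeCountTable(nTaxa = 30, n = 20, planted = 1,
                                           fold = 40, seed = 9))
    lab <- twoClassLabels(20)
    names(lab) <- sampleIds(at)
    loo <- looRiskIndices(at, lab, targetClass = "mutated", seed = 2)
    ri <- riskIndices(loo)
    expect_gt(min(ri[lab == "mutated"]), max(ri[lab == "wildtype"]))
    expect_lte(mwuP(loo), wilcox.test(1:10, 11:20)$p.value * 1.0000001)
    expect_equal(loo@nTaxaUsed,
                 vapply(loo@folds, function(f)
                     length(f$positiveTaxa) + length(f$negativeTaxa),
                     integer(1)))
})

test_that("label swap negates held-out risk indices bit-exactly", {
    at <- relativeAbundance(makeCountTable(nTaxa = 30, n = 16, planted = 1,
                                           seed = 10))
    lab <- twoClassLabels(16)
    loo1 <- looRiskIndices(at, lab, targetClass = "mutated", seed = 5)
    loo2 <- looRiskIndices(at, lab, targetClass = "wildtype", seed = 5)
    expect_identical(unname(riskIndices(loo1)),
                     unname(-riskIndices(loo2)))
})

test_that("permutation p has the add-one floor and catches planted effects", {
    at <- relativeAbundance(makeCountTable(nTaxa = 30, n = 20, planted = 1:2,
                                           fold = 30, seed = 11))
    lab <- twoClassLabels(20)
    res <- permutationTest(at, lab, B = 19, targetClass = "mutated",
                           seed = 3)
    expect_equal(permP(res), 1 / 20)      # minimum attainable at B = 19
    expect_gte(permP(res), 1 / (19 + 1))
    expect_length(res@permDiffs, 19)
    expect_error(permutationTest(at, lab, B = 0), "B must be")
})

test_that("fast permutation mode agrees with faithful mode on strong effects", {
    at <- relativeAbundance(makeCountTable(nTaxa = 25, n = 16, planted = 1,
                                           fold = 40, seed = 12))
    lab <- twoClassLabels(16)
    fast <- permutationTest(at, lab, B = 19, targetClass = "mutated",
                            seed = 4, fastMode = TRUE)
    expect_equal(permP(fast), 1 / 20)
})

test_that("a fixed model transfers across lineage dialects", {
    at <- relativeAbundance(makeCountTable(nTaxa = 10, n = 6, seed = 13))
    taxa <- taxonIds(at)
    model <- riskModel(taxa[1:2], taxa[3])
    base <- applyModel(model, at)
    ## identical table: identical indices
    expect_identical(base, applyModel(model, at))
    ## spaced lineage dialect still matches
    spaced <- abundances(at)
    rownames(spaced) <- gsub(";", "; ", rownames(spaced))
    at_sp <- AbundanceTable(spaced, normalized = TRUE)
    expect_equal(unname(applyModel(model, at_sp)), unname(base))
    ## table missing all negative taxa: indices equal the positive sums
    at_pos <- at[c(1:2, 4:10), ]
    ri_pos <- applyModel(model, at_pos)
    expect_equal(unname(ri_pos),
                 unname(colSums(arcsineSqrt(abundances(at)[1:2, ]))),
                 ignore_attr = TRUE)
    expect_equal(attr(ri_pos, "missingTaxa"), taxa[3])
    expect_error(applyModel(riskModel("g__Nope"), at), "no model taxa")
})
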