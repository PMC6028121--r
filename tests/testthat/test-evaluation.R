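test_that("rank AUC equals pair counting and respects the ties convention", {
    expect_equal(auc(c(1, 2, 0), c("pos", "pos", "neg"), target = "pos"), 1)
    expect_equal(auc(rep(3, 6), twoClassLabels(6), target = "mutated"), 0.5)
    set.seed(17)
    for (rep in 1:5) {
        s <- sample(c(rnorm(6), round(rnorm(6), 1)))  # some ties likely
        lab <- sample(twoClassLabels(12))
        expect_equal(auc(s, lab, target = "mutated"),
                     aucPairOracle(s, lab == "mutated"), tolerance = 1e-9)
        ## complement identity, exact
        expect_equal(auc(s, lab, target = "mutated") +
                     auc(-s, lab, target = "mutated"), 1)
    }
})

test_that("k-fold ROC harness matches the pooled AUC for a fixed model", {
    ## one overwhelming taxon: every fold selects the same model, so the
    ## cross-validated scores are the fixed-model scores
    at <- relativeAbundance(makeCountTable(nTaxa = 20, n = 40, planted = 1,
                                           fold = 50, seed = 19))
    lab <- twoClassLabels(40)
    roc <- kfoldRoc(at, lab, k = 10, targetClass = "mutated", seed = 23)
    fixed <- applyModel(riskModel(taxonIds(at)[1],
                                  targetClass = "mutated"), at)
    expect_equal(roc@pooledAuc, auc(fixed, lab, target = "mutated"))
    expect_equal(roc@pooledAuc, 1)
    expect_gt(roc@auc, 0.99)
    ## mean curve lies within the pointwise envelope of fold curves
    grid <- roc@meanCurve$fpr
    env <- vapply(roc@folds, function(cv)
        stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max,
                      rule = 2)$y, numeric(length(grid)))
    expect_true(all(roc@meanCurve$tpr <= apply(env, 1, max) + 1e-12))
    expect_true(all(roc@meanCurve$tpr >= apply(env, 1, min) - 1e-12))
    ## fold curves are monotone non-decreasing
    for (cv in roc@folds) {
        expect_true(!is.unsorted(cv$tpr))
        expect_true(!is.unsorted(cv$fpr))
    }
})

test_that("k-fold ROC on label noise sits near chance", {
    ## the pooled held-out AUC is the unbiased summary; the vertically
    ## averaged mean curve from 4-sample fold-local curves carries the known
    ## small-fold interpolation bias, so it only gets a loose band
    pooled <- vapply(1:5, function(s) {
        at <- relativeAbundance(makeCountTable(nTaxa = 100, n = 40,
                                               seed = s))
        set.seed(s + 100)
        lab <- sample(twoClassLabels(40))
        roc <- suppressWarnings(kfoldRoc(at, lab, k = 10,
                                         targetClass = "mutated",
                                         seed = s))
        expect_gt(roc@auc, 0.25)
        expect_lt(roc@auc, 0.9)
        roc@pooledAuc
    }, numeric(1))
    expect_lt(abs(mean(pooled) - 0.5), 0.15)
    at <- relativeAbundance(makeCountTable(nTaxa = 30, n = 40, seed = 20))
    expect_error(kfoldRoc(at, c(rep("a", 3), rep("b", 37)), k = 10),
                 "k/2")
})

test_that("fixed-specificity operating point matches the exhaustive grid", {
    set.seed(37)
    for (rep in 1:5) {
        pos <- rep(c(FALSE, TRUE), each = 15)
        s <- rnorm(30) + pos * 1.5
        lab <- factor(ifelse(pos, "mutated", "wildtype"),
                      levels = c("wildtype", "mutated"))
        res <- accuracyAtSpecificity(s, lab, spec = 0.8,
                                     target = "mutated")
        oracle <- cutoffGridOracle(s, pos, 0.8)
        expect_equal(res@cutoff, oracle$cutoff, tolerance = 1e-9)
        expect_equal(res@accuracy, oracle$acc, tolerance = 1e-9)
        expect_equal(res@sensitivity, oracle$sens, tolerance = 1e-9)
        expect_gte(res@specificity, 0.8)
    }
    ## perfect separation: accuracy 1 at any specificity
    sep <- accuracyAtSpecificity(c(1, 2, 3, 11, 12, 13),
                                 twoClassLabels(6), spec = 0.8,
                                 target = "mutated")
    expect_equal(sep@accuracy, 1)
    ## degenerate scores are flagged
    deg <- accuracyAtSpecificity(rep(1, 6), twoClassLabels(6), spec = 0.8,
                                 target = "mutated")
    expect_true(deg@degenerate)
})

test_that("tied best cutoffs resolve to the interval midpoint", {
    ## alternating labels make cutoffs 1.5 and 3.5 equally good (acc 3/4):
    ## the midpoint of the tied interval, 2.5, must be returned
    cut <- micromut:::.bestCutoff(c(1, 2, 3, 4),
                                  c(FALSE, TRUE, FALSE, TRUE))
    expect_equal(cut, 2.5)
    ## a unique optimum is returned as-is (any cutoff in (2, 10] is perfect,
    ## represented by the midpoint 6)
    expect_equal(micromut:::.bestCutoff(c(1, 2, 10, 11),
                                        c(FALSE, FALSE, TRUE, TRUE)), 6)
})

test_that("LOO-refined cutoff is perfect on separable data, honest on noise", {
    at <- relativeAbundance(makeCountTable(nTaxa = 30, n = 20, planted = 1,
                                           fold = 40, seed = 21))
    lab <- twoClassLabels(20)
    res <- looOptimalCutoff(at, lab, targetClass = "mutated", seed = 31)
    expect_equal(res@accuracy, 1)
    expect_equal(res@sensitivity, 1)
    expect_equal(res@specificity, 1)

    ## null labels: held-out accuracy near the majority-class rate
    at0 <- relativeAbundance(makeCountTable(nTaxa = 60, n = 24, seed = 22))
    set.seed(41)
    lab0 <- sample(twoClassLabels(24))
    res0 <- looOptimalCutoff(at0, lab0, targetClass = "mutated", seed = 41)
    expect_lt(res0@accuracy, 0.75)
})
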