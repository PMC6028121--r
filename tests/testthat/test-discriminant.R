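test_that("KW screen matches kruskal.test and handles constants", {
    at <- relativeAbundance(makeCountTable(nTaxa = 30, n = 16, seed = 2))
    lab <- twoClassLabels(16)
    p_ours <- attr(kruskalWallisScreen(at, lab, alpha = 1), "p")
    p_ref <- apply(abundances(at), 1, function(x)
        kruskal.test(x, lab)$p.value)
    expect_equal(unname(p_ours), unname(p_ref), tolerance = 1e-12)

    ## constant taxon: p = 1, never selected
    m <- abundances(makeCountTable(nTaxa = 3, n = 10, seed = 3))
    m[1, ] <- 5
    at2 <- AbundanceTable(m)
    sel <- kruskalWallisScreen(relativeAbundance(at2), twoClassLabels(10),
                               alpha = 0.99)
    ## normalization keeps row 1 non-constant, so force one directly
    m2 <- abundances(relativeAbundance(at2))
    m2[1, ] <- 0.2
    m2[2, ] <- m2[2, ] + (1 - colSums(m2))
    at3 <- AbundanceTable(m2, normalized = TRUE)
    p3 <- attr(kruskalWallisScreen(at3, twoClassLabels(10), 0.99), "p")
    expect_equal(unname(p3[rownames(m2)[1]]), 1)
    expect_false(rownames(m2)[1] %in%
                 kruskalWallisScreen(at3, twoClassLabels(10), 0.99))
})

test_that("KW chi-square p agrees with an exact rank-sum fixture", {
    ## {1,2,3} vs {4,5,6}: H = 3.857, p ~ 0.0495 under chi-square(1)
    m <- rbind(x = (1:6) / 21, rest = 1 - (1:6) / 21)
    rownames(m) <- c("g__x", "g__rest")
    colnames(m) <- paste0("s", 1:6)
    at <- AbundanceTable(m, normalized = TRUE)
    p <- attr(kruskalWallisScreen(at, rep(c("a", "b"), each = 3), 1), "p")
    H <- qchisq(p[["g__x"]], df = 1, lower.tail = FALSE)
    expect_equal(unname(H), 3.857143, tolerance = 1e-6)
    expect_equal(unname(p[["g__x"]]), 0.04953461, tolerance = 1e-6)
})

test_that("chi-square approximation tracks the exact permutation null", {
    ## n = 4+4 fixtures in the rejection region, where the screen's
    ## decisions actually happen (mid-range p at this n is known to be
    ## approximated more coarsely by chi-square(1))
    fixtures <- list(c(1, 2, 3, 4, 10, 11, 12, 13),
                     c(1, 2, 3, 5, 4, 10, 11, 12),
                     c(2, 4, 6, 8, 7, 9, 11, 13))
    for (x in fixtures) {
        p_exact <- kwExactPermOracle(x, 4)
        p_approx <- kruskal.test(x, factor(rep(1:2, each = 4)))$p.value
        expect_lt(abs(p_approx - p_exact), 0.02)
    }
})

test_that("planted shifts are selected with the right enrichment sign", {
    ## two taxa up in the mutated half, one up in wildtype
    at <- makeCountTable(nTaxa = 60, n = 44, planted = c(1, 2), fold = 8,
                         seed = 5)
    m <- abundances(at)
    m[3, 1:22] <- round(m[3, 1:22] * 8)   # up in wildtype half
    at <- relativeAbundance(AbundanceTable(m))
    lab <- twoClassLabels(44)
    disc <- discriminantTaxa(at, lab, seed = 11)
    planted_up <- rownames(m)[1:2]
    planted_dn <- rownames(m)[3]
    expect_true(all(planted_up %in% disc$taxon))
    expect_true(planted_dn %in% disc$taxon)
    expect_equal(disc$enrichedClass[match(planted_up, disc$taxon)],
                 rep("mutated", 2))
    expect_equal(disc$enrichedClass[match(planted_dn, disc$taxon)],
                 "wildtype")
    expect_true(all(disc$ldaLog10 >= 2))
    expect_true(all(disc$kwP < 0.05))
})

test_that("taxa failing the screen are never scored", {
    at <- relativeAbundance(makeCountTable(nTaxa = 20, n = 20, seed = 6))
    lab <- twoClassLabels(20)
    sel <- kruskalWallisScreen(at, lab, alpha = 0.05)
    disc <- discriminantTaxa(at, lab, seed = 1)
    expect_true(all(disc$taxon %in% sel))
})

test_that("degenerate label configurations error early", {
    at <- relativeAbundance(makeCountTable(nTaxa = 10, n = 6, seed = 7))
    expect_error(discriminantTaxa(at, c("a", rep("b", 5))), "at least 2")
    expect_error(discriminantTaxa(at, rep("a", 6)), "two classes")
})

test_that("label swap preserves the selection bit-identically", {
    at <- relativeAbundance(makeCountTable(nTaxa = 40, n = 24,
                                           planted = 1, seed = 8))
    lab <- twoClassLabels(24)
    swapped <- factor(ifelse(lab == "mutated", "wildtype", "mutated"),
                      levels = c("wildtype", "mutated"))
    d1 <- discriminantTaxa(at, lab, seed = 21)
    d2 <- discriminantTaxa(at, swapped, seed = 21)
    expect_setequal(d1$taxon, d2$taxon)
    i <- match(d1$taxon, d2$taxon)
    expect_identical(d1$ldaLog10, d2$ldaLog10[i])
    expect_true(all(d1$enrichedClass != d2$enrichedClass[i]))
})

test_that("scaling one taxon leaves its ranks, H and p unchanged", {
    set.seed(13)
    X <- matrix(rlnorm(20 * 12), 20, 12)
    grp <- rep(0:1, each = 6)
    p1 <- micromut:::.cppFitDiscriminant(X, as.integer(grp), 2, Inf, 1L,
                                         2 / 3, 1e6, 1e-6)$kw_p
    X2 <- X
    X2[7, ] <- X2[7, ] * 1234.5
    p2 <- micromut:::.cppFitDiscriminant(X2, as.integer(grp), 2, Inf, 1L,
                                         2 / 3, 1e6, 1e-6)$kw_p
    expect_identical(p1[7], p2[7])
})

test_that("screen pass rate matches alpha under the null", {
    set.seed(31)
    frac <- replicate(50, {
        m <- matrix(rlnorm(200 * 20), 200, 20,
                    dimnames = list(lineages(200), paste0("s", 1:20)))
        at <- relativeAbundance(AbundanceTable(m))
        length(kruskalWallisScreen(at, sample(twoClassLabels(20)),
                                   alpha = 0.05)) / 200
    })
    ## binomial error around alpha = 0.05
    expect_lt(abs(mean(frac) - 0.05), 0.01)
})
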