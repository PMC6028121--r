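# Shared fixture builders and independent oracles. Everything is generated
# in code; no fixture files.

lineages <- function(n, prefix = "g__Taxon") {
    sprintf("k__Bacteria;p__P%02d;c__C;o__O;f__F%02d;%s%03d",
            (seq_len(n) - 1L) %% 5L + 1L, (seq_len(n) - 1L) %% 10L + 1L,
            prefix, seq_len(n))
}

# Poisson count table with optional multiplicative planted shifts in the
# second half of the samples.
makeCountTable <- function(nTaxa = 50, n = 24, lambda = 40,
                           planted = integer(0), fold = 8, seed = 1) {
    set.seed(seed)
    m <- matrix(rpois(nTaxa * n, lambda) + 1, nTaxa, n,
                dimnames = list(lineages(nTaxa),
                                sprintf("s%03d", seq_len(n))))
    pos <- seq_len(n) > n / 2
    for (t in planted) m[t, pos] <- round(m[t, pos] * fold)
    AbundanceTable(m)
}

twoClassLabels <- function(n, levels = c("wildtype", "mutated")) {
    factor(rep(levels, each = n / 2), levels = levels)
}

# Count table whose log-scale basis has correlation rho between taxa 1 and 2.
sparccFixture <- function(n = 200, T = 10, rho = 0, depth = 2000, seed = 1) {
    set.seed(seed)
    S <- diag(T)
    if (rho != 0) S[1, 2] <- S[2, 1] <- rho
    Z <- t(chol(S)) %*% matrix(rnorm(T * n), T, n)
    base <- exp(Z + rnorm(T, 2, 1))
    fr <- sweep(base, 2, colSums(base), "/")
    cnt <- vapply(seq_len(n), function(j) rmultinom(1, depth, fr[, j])[, 1],
                  numeric(T))
    rownames(cnt) <- lineages(T)
    colnames(cnt) <- paste0("s", seq_len(n))
    cnt
}

# O(n^2) pair-counting AUC oracle (ties count 1/2).
aucPairOracle <- function(scores, positive) {
    sp <- scores[positive]
    sn <- scores[!positive]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
}

# Exact two-group Kruskal-Wallis permutation p by full enumeration.
kwExactPermOracle <- function(x, g1size) {
    n <- length(x)
    stat <- function(idx) {
        g <- rep(2L, n); g[idx] <- 1L
        kruskal.test(x, factor(g))$statistic
    }
    obs <- stat(seq_len(g1size))
    combos <- utils::combn(n, g1size)
    perms <- apply(combos, 2, stat)
    mean(perms >= obs - 1e-12)
}

# Exhaustive-search oracle for the fixed-specificity operating point.
cutoffGridOracle <- function(scores, positive, spec) {
    cand <- c(sort(unique(scores)), Inf)
    best <- NULL
    for (cc in cand) {
        sp <- mean(scores[!positive] < cc)
        if (sp >= spec) {
            best <- list(cutoff = cc, spec = sp,
                         sens = mean(scores[positive] >= cc),
                         acc = (sum(scores[positive] >= cc) +
                                sum(scores[!positive] < cc)) / length(scores))
            break
        }
    }
    best
}
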