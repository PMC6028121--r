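# Robustness analogue of the multivariate-association check: per-taxon
# covariate-adjusted ordinary least squares on arcsine-square-root
# abundances, with the prevalence/abundance filters applied beforehand.
# This is deliberately a plain linear model, not a clone of any
# boosting-based feature-selection tool.

#' Prevalence and abundance filter for the robustness models
#'
#' Keeps taxa observed (abundance > 0) in at least `minSamples` samples and
#' with mean relative abundance of at least `minAbundance`. Idempotent.
#'
#' @param table a normalized [AbundanceTable-class].
#' @param minSamples minimum number of samples with non-zero abundance
#'   (default 5).
#' @param minAbundance minimum mean relative abundance (default 0.001).
#' @return The filtered [AbundanceTable-class].
#' @export
maaslinFilter <- function(table, minSamples = 5, minAbundance = 0.001) {
    stopifnot(is(table, "AbundanceTable"))
    if (!isNormalized(table)) table <- relativeAbundance(table)
    m <- abundances(table)
    keep <- rowSums(m > 0) >= minSamples & rowMeans(m) >= minAbundance
    table[keep, ]
}

#' Per-taxon covariate-adjusted linear models
#'
#' For each taxon, ordinary least squares of the arcsine-square-root
#' relative abundance on the binary feature status plus the covariates
#' (age, sex); the feature coefficient is tested two-sided (t-test) and
#' q-values are Benjamini-Hochberg over the tested taxa. Samples with
#' missing covariates are dropped per taxon and the used sample count
#' reported. Constant-abundance taxa get coefficient 0 and p = 1 by
#' convention; rank-deficient designs are skipped with a diagnostic.
#'
#' @param table normalized [AbundanceTable-class], normally after
#'   [maaslinFilter()].
#' @param featureLabels binary vector (1 = mutated), named by sample id or
#'   aligned with samples.
#' @param covariates data.frame of per-sample covariates (e.g. `age`,
#'   `sex`), row names or a `sample_id` column matching sample ids; `NULL`
#'   for an unadjusted model.
#' @param transform transform applied to abundances before the fit:
#'   `"arcsine_sqrt"` (default) or `"none"`.
#' @return data.frame with columns `taxon`, `coefficient`, `p`, `q`,
#'   `n_samples_used`.
#' @export
fitPerTaxonLm <- function(table, featureLabels, covariates = NULL,
                          transform = c("arcsine_sqrt", "none")) {
    stopifnot(is(table, "AbundanceTable"))
    transform <- match.arg(transform)
    if (!isNormalized(table)) table <- relativeAbundance(table)
    m <- abundances(table)
    if (!is.null(names(featureLabels)))
        featureLabels <- featureLabels[colnames(m)]
    stopifnot(length(featureLabels) == ncol(m))
    cov_df <- NULL
    if (!is.null(covariates)) {
        cov_df <- as.data.frame(covariates)
        if ("sample_id" %in% names(cov_df)) {
            rownames(cov_df) <- cov_df$sample_id
            cov_df$sample_id <- NULL
        }
        cov_df <- cov_df[colnames(m), , drop = FALSE]
    }
    res <- lapply(rownames(m), function(tx) {
        y <- m[tx, ]
        if (transform == "arcsine_sqrt") y <- arcsineSqrt(y)
        df <- data.frame(y = y, feature = featureLabels)
        if (!is.null(cov_df)) df <- cbind(df, cov_df)
        df <- df[complete.cases(df), , drop = FALSE]
        n_used <- nrow(df)
        if (sd(df$y) == 0)
            return(data.frame(taxon = tx, coefficient = 0, p = 1,
                              n_samples_used = n_used))
        fit <- lm(y ~ ., data = df)
        cf <- summary(fit)$coefficients
        if (!"feature" %in% rownames(cf) || anyNA(coef(fit))) {
            warning("rank-deficient design for taxon ", tx, "; skipped")
            return(NULL)
        }
        data.frame(taxon = tx, coefficient = cf["feature", "Estimate"],
                   p = cf["feature", "Pr(>|t|)"], n_samples_used = n_used)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) stop("no taxon could be fitted")
    out$q <- fdrAdjust(out$p)
    out[, c("taxon", "coefficient", "p", "q", "n_samples_used")]
}

#' Concordance between risk-index and linear-model calls
#'
#' Fraction of features called significant by both the permutation-tested
#' risk-index pipeline and the linear-model robustness check at the same
#' q-value threshold.
#'
#' @param riSummary data.frame with columns `feature` and `q` (risk-index
#'   permutation q-values).
#' @param lmSummary data.frame with columns `feature` and `q` (linear-model
#'   q-values) over the same features.
#' @param alpha significance threshold on q (default 0.05).
#' @return List with `k` (significant in both), `n` (significant by the
#'   risk index), and `fraction` (`k/n`, `NaN` when `n` is 0).
#' @export
concordance <- function(riSummary, lmSummary, alpha = 0.05) {
    if (!setequal(riSummary$feature, lmSummary$feature))
        stop("feature lists differ between the two summaries")
    lm_q <- lmSummary$q[match(riSummary$feature, lmSummary$feature)]
    sig_ri <- !is.na(riSummary$q) & riSummary$q < alpha
    sig_lm <- !is.na(lm_q) & lm_q < alpha
    k <- sum(sig_ri & sig_lm)
    n <- sum(sig_ri)
    list(k = k, n = n, fraction = if (n > 0) k / n else NaN)
}
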