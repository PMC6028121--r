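# Two-stage discriminant-taxon screen: per-taxon Kruskal-Wallis test, then
# bootstrapped one-dimensional Fisher LDA effect sizes on the screened taxa
# (the LEfSe scheme for two classes, no subclasses).

# Align a label vector with the table's samples and validate two classes.
.checkLabels <- function(labels, samples, minPerClass = 2L) {
    if (!is.null(names(labels))) {
        miss <- setdiff(samples, names(labels))
        if (length(miss))
            stop("labels missing for sample(s): ",
                 paste(miss, collapse = ", "))
        labels <- labels[samples]
    } else if (length(labels) != length(samples)) {
        stop("labels length does not match number of samples")
    }
    if (anyNA(labels)) stop("labels contain missing values")
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L)
        stop("exactly two classes required, got ", nlevels(labels))
    if (any(table(labels) < minPerClass))
        stop("each class needs at least ", minPerClass, " samples")
    labels
}

.normalizedMatrix <- function(table) {
    stopifnot(is(table, "AbundanceTable"))
    if (!isNormalized(table)) table <- relativeAbundance(table)
    abundances(table)
}

#' Kruskal-Wallis screen for discriminant taxa
#'
#' Per-taxon tie-corrected Kruskal-Wallis test (chi-square approximation)
#' between the two classes; taxa with p below `alpha` pass the screen.
#' Constant taxa get p = 1 and are never selected.
#'
#' @param table a normalized [AbundanceTable-class] (counts are normalized
#'   on the fly).
#' @param labels two-class factor, either named by sample id or aligned to
#'   the table's samples; each class needs >= 2 samples.
#' @param alpha screening level (default 0.05).
#' @return Character vector of passing taxon ids; the full named p-value
#'   vector is attached as attribute `"p"`.
#' @export
kruskalWallisScreen <- function(table, labels, alpha = 0.05) {
    m <- .normalizedMatrix(table)
    labels <- .checkLabels(labels, colnames(m))
    grp <- as.integer(labels) - 1L
    fit <- .cppFitDiscriminant(m, grp, kw_alpha = alpha, lda_threshold = Inf,
                               n_boot = 1L, boot_frac = 2 / 3,
                               scaling = 1e6, ridge = 1e-6)
    p <- setNames(fit$kw_p, rownames(m))
    out <- names(p)[p < alpha]
    attr(out, "p") <- p
    out
}

.fitDiscriminant <- function(m, labels, config, screenAlpha) {
    grp <- as.integer(labels) - 1L
    .cppFitDiscriminant(m, grp, kw_alpha = screenAlpha,
                        lda_threshold = config@ldaThreshold,
                        n_boot = config@nBootstrap,
                        boot_frac = config@bootstrapFraction,
                        scaling = config@scaling, ridge = config@ridge)
}

.discriminantFrame <- function(fit, taxa, labels) {
    sc <- fit$screened + 1L
    lev <- levels(labels)
    df <- S4Vectors::DataFrame(
        taxon = taxa[sc],
        enrichedClass = lev[fit$enriched + 1L],
        kwP = fit$kw_p[sc],
        ldaLog10 = fit$lda_log10)
    df
}

#' Bootstrapped LDA effect sizes for screened taxa
#'
#' For each taxon that passed the screen, fits a one-dimensional Fisher LDA
#' on the screened feature set in `nBootstrap` subsamples (a
#' `bootstrapFraction` of each class, without replacement) with a
#' ridge-regularised pooled covariance; the per-taxon effect is the bootstrap
#' mean of the average of (a) the absolute between-class difference of the
#' taxon's contribution to the LDA projection and (b) the absolute raw
#' class-mean difference, reported as `log10(1 + scaling * effect)`. Taxa
#' with score `>= ldaThreshold` are returned, signed by the class with the
#' larger raw mean.
#'
#' @param table a normalized [AbundanceTable-class].
#' @param labels two-class factor (see [kruskalWallisScreen()]).
#' @param taxa taxa to score (normally the output of the screen).
#' @param config a [DiscriminationConfig-class].
#' @param seed optional integer seed for the bootstrap subsampling.
#' @return [S4Vectors::DataFrame] with columns `taxon`, `enrichedClass`,
#'   `kwP`, `ldaLog10`, one row per selected taxon, ordered by decreasing
#'   score.
#' @export
ldaEffectSize <- function(table, labels, taxa,
                          config = discriminationConfig(), seed = NULL) {
    m <- .normalizedMatrix(table)
    labels <- .checkLabels(labels, colnames(m))
    miss <- setdiff(taxa, rownames(m))
    if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
    if (!is.null(seed)) set.seed(seed)
    sub <- m[taxa, , drop = FALSE]
    fit <- .fitDiscriminant(sub, labels, config, screenAlpha = 2) # keep all
    df <- .discriminantFrame(fit, rownames(sub), labels)
    df <- df[df$ldaLog10 >= config@ldaThreshold, , drop = FALSE]
    df[order(-df$ldaLog10), , drop = FALSE]
}

#' Discriminant taxa between two classes
#'
#' Composition of [kruskalWallisScreen()] and [ldaEffectSize()]:
#' taxa passing the Kruskal-Wallis screen at `kwAlpha` are scored by
#' bootstrapped LDA effect size and returned when the log10 score reaches
#' `ldaThreshold`. Deterministic given `seed`.
#'
#' @inheritParams ldaEffectSize
#' @return [S4Vectors::DataFrame] as in [ldaEffectSize()]; zero rows when no
#'   taxon qualifies.
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(50 * 20, 40), 50, 20,
#'             dimnames = list(sprintf("g__t%02d", 1:50), sprintf("s%d", 1:20)))
#' m[1, 11:20] <- m[1, 11:20] * 8
#' at <- relativeAbundance(AbundanceTable(m))
#' discriminantTaxa(at, rep(c("wt", "mut"), each = 10), seed = 1)
#' @export
discriminantTaxa <- function(table, labels,
                             config = discriminationConfig(), seed = NULL) {
    m <- .normalizedMatrix(table)
    labels <- .checkLabels(labels, colnames(m))
    if (!is.null(seed)) set.seed(seed)
    fit <- .fitDiscriminant(m, labels, config, screenAlpha = config@kwAlpha)
    df <- .discriminantFrame(fit, rownames(m), labels)
    df <- df[df$ldaLog10 >= config@ldaThreshold, , drop = FALSE]
    df[order(-df$ldaLog10), , drop = FALSE]
}
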