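# The arcsine-square-root risk index classifier: model construction from
# discriminant taxa, leave-one-out scoring, Mann-Whitney U and
# label-permutation significance, FDR correction and application of a fixed
# model to external cohorts.

#' Arcsine-square-root transform
#'
#' The variance-stabilising transform applied to relative abundances before
#' summation into the risk index: `asin(sqrt(p))`, mapping \[0, 1\] onto
#' \[0, pi/2\].
#'
#' @param p proportions in \[0, 1\]; values outside by no more than 1e-12
#'   are clipped, anything further is an error.
#' @return Numeric vector of transformed values.
#' @examples
#' arcsineSqrt(c(0, 0.25, 1)) # 0, pi/6, pi/2
#' @export
arcsineSqrt <- function(p) {
    if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
        stop("proportions must lie in [0, 1]")
    asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' @rdname RiskModel
#' @param positiveTaxa,negativeTaxa,targetClass,referenceClass,taxRank see
#'   the class slots.
#' @return A [RiskModel-class].
#' @export
riskModel <- function(positiveTaxa, negativeTaxa = character(0),
                      targetClass = "mutated", referenceClass = "wildtype",
                      taxRank = "genus") {
    new("RiskModel", positiveTaxa = as.character(positiveTaxa),
        negativeTaxa = as.character(negativeTaxa),
        targetClass = targetClass, referenceClass = referenceClass,
        taxRank = taxRank)
}

#' Build a risk model from discriminant taxa
#'
#' Taxa enriched in the target class become the positive set, taxa enriched
#' in the reference class the negative set.
#'
#' @param discriminants [S4Vectors::DataFrame] from [discriminantTaxa()].
#' @param targetClass label of the class the index should be high for.
#' @param taxRank taxonomic rank of the taxa.
#' @return A [RiskModel-class].
#' @export
riskModelFromDiscriminants <- function(discriminants, targetClass,
                                       taxRank = "genus") {
    cls <- unique(discriminants$enrichedClass)
    ref <- setdiff(cls, targetClass)
    if (length(ref) > 1) stop("more than two classes in discriminant set")
    pos <- discriminants$taxon[discriminants$enrichedClass == targetClass]
    neg <- discriminants$taxon[discriminants$enrichedClass != targetClass]
    riskModel(pos, neg, targetClass = targetClass,
              referenceClass = if (length(ref)) ref else "reference",
              taxRank = taxRank)
}

#' @rdname RiskModel
#' @export
setMethod("positiveTaxa", "RiskModel", function(x) x@positiveTaxa)

#' @rdname RiskModel
#' @export
setMethod("negativeTaxa", "RiskModel", function(x) x@negativeTaxa)

#' @rdname RiskModel
#' @export
setMethod("targetClass", "RiskModel", function(x) x@targetClass)

setMethod("show", "RiskModel", function(object) {
    cat(sprintf(
        "RiskModel (%s vs %s): %d positive, %d negative taxa [rank %s]\n",
        object@targetClass, object@referenceClass,
        length(object@positiveTaxa), length(object@negativeTaxa),
        object@taxRank))
})

#' Risk index of one sample
#'
#' The unweighted risk index: the sum of arcsine-square-root transformed
#' relative abundances over the model's positive taxa minus the same sum
#' over its negative taxa. Model taxa absent from the abundance vector
#' contribute zero and are reported in attribute `"missingTaxa"`.
#'
#' @param abundances named numeric vector of relative abundances for one
#'   sample (names are lineage strings).
#' @param model a [RiskModel-class].
#' @return The risk index (numeric scalar).
#' @examples
#' m <- riskModel("g__A", "g__B")
#' riskIndex(c(g__A = 0.04, g__B = 0.01), m) # asin(0.2) - asin(0.1)
#' @export
riskIndex <- function(abundances, model) {
    stopifnot(is(model, "RiskModel"))
    key <- .lineageKey(names(abundances))
    lookup <- function(taxa) {
        idx <- match(.lineageKey(taxa), key)
        vals <- ifelse(is.na(idx), 0, abundances[idx])
        list(sum = sum(arcsineSqrt(vals)), missing = taxa[is.na(idx)])
    }
    pos <- lookup(model@positiveTaxa)
    neg <- lookup(model@negativeTaxa)
    out <- pos$sum - neg$sum
    attr(out, "missingTaxa") <- c(pos$missing, neg$missing)
    out
}

#' @rdname RiskIndexResult
#' @export
setMethod("riskIndices", "RiskIndexResult", function(x) x@riskIndex)

#' @rdname RiskIndexResult
#' @export
setMethod("observedDiff", "RiskIndexResult", function(x) x@observedDiff)

#' @rdname RiskIndexResult
#' @export
setMethod("mwuP", "RiskIndexResult", function(x) x@mwuP)

#' @rdname RiskIndexResult
#' @export
setMethod("permP", "RiskIndexResult", function(x) x@permP)

#' @rdname RiskIndexResult
#' @export
setMethod("targetClass", "RiskIndexResult", function(x) x@targetClass)

setMethod("show", "RiskIndexResult", function(object) {
    cat(sprintf(
        "RiskIndexResult: %d samples (target '%s')\n  diff = %.4g, MWU p = %.4g, perm p = %s\n",
        length(object@riskIndex), object@targetClass, object@observedDiff,
        object@mwuP,
        if (is.na(object@permP)) "not computed"
        else format(object@permP, digits = 4)))
})

# Internal driver shared by looRiskIndices / permutationTest / cutoff ops.
.looEngine <- function(m, grp, config, returnTrain = FALSE) {
    .cppLooRisk(m, grp, kw_alpha = config@kwAlpha,
                lda_threshold = config@ldaThreshold,
                n_boot = config@nBootstrap,
                boot_frac = config@bootstrapFraction,
                scaling = config@scaling, ridge = config@ridge,
                return_train = returnTrain)
}

.groupDiff <- function(ri, grp) {
    ok <- !is.na(ri)
    mean(ri[ok & grp == 1L]) - mean(ri[ok & grp == 0L])
}

#' Leave-one-out risk indices
#'
#' For each sample, re-runs the full discriminant-taxon selection on the
#' other n - 1 samples, builds the risk model from the selected taxa and
#' scores the held-out sample, so no sample contributes to its own model.
#' The separation of held-out indices by class is tested with a two-sided
#' Mann-Whitney U test; run [permutationTest()] for the empirical
#' label-permutation p-value.
#'
#' @param table an [AbundanceTable-class] (normalized on the fly).
#' @param labels two-class factor; each class needs >= 3 samples so both
#'   survive any single removal.
#' @param config a [DiscriminationConfig-class].
#' @param targetClass label the index should be high for (default: the last
#'   factor level).
#' @param seed integer seed for the LDA bootstraps.
#' @param returnTrain keep per-fold training-sample risk indices (needed by
#'   [looOptimalCutoff()]).
#' @return A [RiskIndexResult-class]. Folds whose model is empty give `NA`
#'   indices; more than 20% empty folds aborts with a diagnostic.
#' @export
looRiskIndices <- function(table, labels, config = discriminationConfig(),
                           targetClass = NULL, seed = NULL,
                           returnTrain = FALSE) {
    m <- .normalizedMatrix(table)
    labels <- .checkLabels(labels, colnames(m), minPerClass = 3L)
    if (is.null(targetClass)) targetClass <- levels(labels)[2L]
    if (!targetClass %in% levels(labels))
        stop("targetClass '", targetClass, "' is not a label level")
    grp <- as.integer(labels == targetClass)
    if (!is.null(seed)) set.seed(seed)
    res <- .looEngine(m, grp, config, returnTrain = returnTrain)
    ri <- setNames(res$ri, colnames(m))
    frac_empty <- mean(is.na(ri))
    if (frac_empty > 0.2)
        stop(sprintf(
            "%.0f%% of leave-one-out folds produced an empty model; %s",
            100 * frac_empty,
            "labels are likely uninformative for these taxa"))
    ok <- !is.na(ri)
    mwu <- suppressWarnings(
        wilcox.test(ri[ok & grp == 1L], ri[ok & grp == 0L],
                    alternative = "two.sided"))$p.value
    folds <- lapply(seq_along(ri), function(i) {
        f <- list(positiveTaxa = rownames(m)[res$pos[[i]] + 1L],
                  negativeTaxa = rownames(m)[res$neg[[i]] + 1L])
        if (returnTrain) {
            f$trainScores <- setNames(res$train_scores[[i]],
                                      colnames(m)[-i])
        }
        f
    })
    new("RiskIndexResult", riskIndex = ri, labels = labels,
        targetClass = targetClass,
        observedDiff = .groupDiff(res$ri, grp), mwuP = mwu,
        nTaxaUsed = as.integer(res$n_taxa), folds = folds)
}

#' Label-permutation test for the risk-index classifier
#'
#' Permutes the class labels `B` times and re-runs the complete leave-one-out
#' pipeline (taxon selection inside every fold) on each permutation,
#' recording the permuted between-class mean difference of held-out risk
#' indices. The empirical two-sided p-value uses the add-one convention:
#' `(1 + #{|diff_perm| >= |diff_obs|}) / (B + 1)`, so it is never below
#' `1/(B+1)`.
#'
#' @inheritParams looRiskIndices
#' @param B number of permutations (default 999).
#' @param fastMode if `TRUE`, taxa are selected once per permutation on the
#'   full permuted data with no inner leave-one-out; orders of magnitude
#'   faster but optimistically biased, intended for smoke tests only.
#' @param result optional [RiskIndexResult-class] from [looRiskIndices()]
#'   with the same data and seed, to avoid recomputing the observed run.
#' @return A [RiskIndexResult-class] with `permP` and `permDiffs` filled.
#' @export
permutationTest <- function(table, labels, config = discriminationConfig(),
                            B = 999, targetClass = NULL, seed = NULL,
                            fastMode = FALSE, result = NULL) {
    if (B < 1) stop("B must be >= 1")
    m <- .normalizedMatrix(table)
    labels <- .checkLabels(labels, colnames(m), minPerClass = 3L)
    if (is.null(targetClass)) targetClass <- levels(labels)[2L]
    grp <- as.integer(labels == targetClass)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(result)) {
        result <- looRiskIndices(table, labels, config,
                                 targetClass = targetClass)
    }
    child_seeds <- sample.int(.Machine$integer.max - 1L, B)
    tr <- if (fastMode) arcsineSqrt(m)
    one_diff <- if (fastMode) {
        function(g) {
            fit <- .cppFitDiscriminant(m, g, kw_alpha = config@kwAlpha,
                                       lda_threshold = config@ldaThreshold,
                                       n_boot = config@nBootstrap,
                                       boot_frac = config@bootstrapFraction,
                                       scaling = config@scaling,
                                       ridge = config@ridge)
            if (!length(fit$pos) && !length(fit$neg)) return(NA_real_)
            ri <- colSums(tr[fit$pos + 1L, , drop = FALSE]) -
                colSums(tr[fit$neg + 1L, , drop = FALSE])
            .groupDiff(ri, g)
        }
    } else {
        function(g) .groupDiff(.looEngine(m, g, config)$ri, g)
    }
    perm_diffs <- vapply(seq_len(B), function(b) {
        set.seed(child_seeds[b])
        one_diff(sample(grp))
    }, numeric(1))
    obs <- result@observedDiff
    exceed <- sum(abs(perm_diffs) >= abs(obs), na.rm = TRUE)
    result@permP <- (1 + exceed) / (B + 1)
    result@permDiffs <- perm_diffs
    validObject(result)
    result
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate correction.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return q-values of the same length (empty input gives empty output).
#' @export
fdrAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(p <= 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in (0, 1]")
    p.adjust(p, method = "BH")
}

#' Apply a fixed risk model to an external cohort
#'
#' Scores each sample of an external abundance table with a previously
#' trained [RiskModel-class]. Taxa are matched by lineage string (stripped
#' tokens, so spaced and unspaced dialects match) at the model's rank; model
#' taxa absent from the table contribute zero and are reported.
#'
#' @param model a [RiskModel-class].
#' @param table external [AbundanceTable-class] (normalized on the fly).
#' @return Named numeric vector of risk indices with attribute
#'   `"missingTaxa"` (model taxa unmatched in the table). Zero matched taxa
#'   is an error.
#' @export
applyModel <- function(model, table) {
    stopifnot(is(model, "RiskModel"))
    m <- .normalizedMatrix(table)
    key <- .lineageKey(rownames(m))
    pos <- match(.lineageKey(model@positiveTaxa), key)
    neg <- match(.lineageKey(model@negativeTaxa), key)
    if (all(is.na(c(pos, neg))))
        stop("no model taxa matched in the external table")
    tr <- arcsineSqrt(m)
    ri <- colSums(tr[pos[!is.na(pos)], , drop = FALSE]) -
        colSums(tr[neg[!is.na(neg)], , drop = FALSE])
    attr(ri, "missingTaxa") <- c(model@positiveTaxa[is.na(pos)],
                                 model@negativeTaxa[is.na(neg)])
    ri
}
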