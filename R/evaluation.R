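# ROC/AUC via stratified k-fold cross-validation, fixed-specificity
# operating points and leave-one-out-refined optimal risk-index cutoffs.

.posNeg <- function(labels, target) {
    labels <- droplevels(as.factor(labels))
    if (is.null(target)) target <- levels(labels)[nlevels(labels)]
    if (!target %in% levels(labels)) stop("unknown target class ", target)
    list(pos = labels == target, target = target)
}

#' Area under the ROC curve
#'
#' The rank-statistic AUC: the Mann-Whitney U statistic scaled by
#' `n_pos * n_neg`, with ties counted 1/2 (so all-equal scores give 0.5).
#'
#' @param scores numeric classifier scores (higher = more target-like).
#' @param labels two-class factor aligned with `scores`.
#' @param target label of the positive class (default: last level).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, target = NULL) {
    pn <- .posNeg(labels, target)
    ok <- !is.na(scores)
    pos <- pn$pos[ok]
    scores <- scores[ok]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) stop("need at least one sample per class")
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Full ROC step curve of one score set: rows ordered by increasing fpr.
.rocCurve <- function(scores, pos) {
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
    data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

# Vertical (fixed-FPR) average of fold curves on a regular grid.
.verticalAverage <- function(curves, grid = seq(0, 1, by = 0.01)) {
    tprs <- vapply(curves, function(cv) {
        stats::approx(x = cv$fpr, y = cv$tpr, xout = grid,
                      ties = max, rule = 2)$y
    }, numeric(length(grid)))
    data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

.trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Seeded stratified fold assignment (round-robin within each class).
.stratifiedFolds <- function(labels, k) {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
        idx <- sample(which(labels == lv))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' ROC curves from stratified k-fold cross-validation
#'
#' Splits the samples into `k` stratified folds; for each fold the
#' discriminant taxa and risk model are re-trained on the other k - 1 folds
#' and the held-out fold is scored. Per-fold ROC curves are computed from
#' the fold-local held-out scores and vertically averaged at a fixed
#' false-positive-rate grid; the reported AUC is the trapezoidal area under
#' the mean curve. Set `k = n` for a leave-one-out ROC (then only the pooled
#' curve/AUC is meaningful).
#'
#' @inheritParams looRiskIndices
#' @param k number of folds (default 10).
#' @return An [ROCResult-class].
#' @export
kfoldRoc <- function(table, labels, k = 10, config = discriminationConfig(),
                     targetClass = NULL, seed = NULL) {
    m <- .normalizedMatrix(table)
    labels <- .checkLabels(labels, colnames(m), minPerClass = 2L)
    if (is.null(targetClass)) targetClass <- levels(labels)[2L]
    grp <- as.integer(labels == targetClass)
    if (min(table(labels)) < k / 2)
        stop("both classes need at least k/2 members")
    if (!is.null(seed)) set.seed(seed)
    fold <- .stratifiedFolds(labels, k)
    scores <- rep(NA_real_, length(labels))
    tr <- arcsineSqrt(m)
    for (f in seq_len(k)) {
        test <- fold == f
        if (sum(!test) < 4L) stop("fold leaves too few training samples")
        fit <- .fitDiscriminant(m[, !test, drop = FALSE],
                                factor(grp[!test], levels = 0:1),
                                config, screenAlpha = config@kwAlpha)
        if (!length(fit$pos) && !length(fit$neg)) next
        scores[test] <- colSums(tr[fit$pos + 1L, test, drop = FALSE]) -
            colSums(tr[fit$neg + 1L, test, drop = FALSE])
    }
    usable <- which(vapply(seq_len(k), function(f) {
        idx <- fold == f & !is.na(scores)
        length(unique(grp[idx])) == 2L
    }, logical(1)))
    if (length(usable) < 2L)
        stop("fewer than two folds contain both classes; cannot average ROC")
    if (length(usable) < k)
        warning(k - length(usable), " fold(s) without both classes ",
                "excluded from the ROC average")
    curves <- lapply(usable, function(f) {
        idx <- fold == f & !is.na(scores)
        .rocCurve(scores[idx], grp[idx] == 1L)
    })
    mean_curve <- .verticalAverage(curves)
    ok <- !is.na(scores)
    new("ROCResult", folds = curves, meanCurve = mean_curve,
        auc = .trapezoid(mean_curve$fpr, mean_curve$tpr),
        pooledAuc = auc(scores[ok], labels[ok], target = targetClass),
        foldAssignments = setNames(fold, colnames(m)),
        scores = setNames(scores, colnames(m)), labels = labels)
}

setMethod("show", "ROCResult", function(object) {
    cat(sprintf(
        "ROCResult: %d folds, mean-curve AUC = %.3f (pooled %.3f)\n",
        length(object@folds), object@auc, object@pooledAuc))
})

setMethod("show", "CutoffResult", function(object) {
    cat(sprintf(
        "CutoffResult: cutoff %.4g | sens %.3f spec %.3f acc %.3f%s\n",
        object@cutoff, object@sensitivity, object@specificity,
        object@accuracy,
        if (object@degenerate) " (requested point unattainable)" else ""))
})

#' Operating point at a fixed specificity
#'
#' Finds the smallest cutoff whose specificity on the reference class is at
#' least `spec` (samples scoring `>= cutoff` are called target) and reports
#' sensitivity and accuracy there. With degenerate scores the closest
#' attainable point is reported and flagged.
#'
#' @inheritParams auc
#' @param spec required minimum specificity (default 0.80).
#' @return A [CutoffResult-class].
#' @export
accuracyAtSpecificity <- function(scores, labels, spec = 0.80,
                                  target = NULL) {
    pn <- .posNeg(labels, target)
    ok <- !is.na(scores)
    pos <- pn$pos[ok]; s <- scores[ok]
    if (!sum(pos) || !sum(!pos)) stop("need both classes")
    cand <- c(sort(unique(s)), Inf)
    specs <- vapply(cand, function(cc) mean(s[!pos] < cc), numeric(1))
    hit <- which(specs >= spec)
    cutoff <- cand[hit[1]]
    sens <- mean(s[pos] >= cutoff)
    acc <- (sum(s[pos] >= cutoff) + sum(s[!pos] < cutoff)) / length(s)
    new("CutoffResult", cutoff = cutoff, sensitivity = sens,
        specificity = specs[hit[1]], accuracy = acc,
        degenerate = !is.finite(cutoff))
}

# Best-accuracy cutoff for one training set; ties resolved by the midpoint
# of the tied cutoff interval.
.bestCutoff <- function(scores, pos) {
    v <- sort(unique(scores))
    cand <- c(v[1] - 1, (head(v, -1) + tail(v, -1)) / 2, v[length(v)] + 1)
    accs <- vapply(cand, function(cc)
        (sum(scores[pos] >= cc) + sum(scores[!pos] < cc)) / length(scores),
        numeric(1))
    best <- which(accs == max(accs))
    mean(range(cand[best]))
}

#' Leave-one-out refined optimal risk-index cutoff
#'
#' Runs the leave-one-out risk-index pipeline; within each fold the cutoff
#' maximising training-set accuracy is chosen (ties resolved by the midpoint
#' of the tied interval) and the held-out sample is classified with it.
#' Reports the aggregate held-out sensitivity, specificity and accuracy, and
#' the mean of the per-fold optimal cutoffs as the refined cutoff.
#'
#' @inheritParams looRiskIndices
#' @param result optional precomputed [looRiskIndices()] result with
#'   `returnTrain = TRUE`.
#' @return A [CutoffResult-class]; per-fold cutoffs and held-out calls are
#'   attached as attributes `"foldCutoffs"` and `"heldOutCalls"`.
#' @export
looOptimalCutoff <- function(table, labels, config = discriminationConfig(),
                             targetClass = NULL, seed = NULL,
                             result = NULL) {
    if (is.null(result)) {
        result <- looRiskIndices(table, labels, config,
                                 targetClass = targetClass, seed = seed,
                                 returnTrain = TRUE)
    }
    lab <- result@labels
    ri <- result@riskIndex
    pos_all <- setNames(lab == result@targetClass, names(ri))
    n <- length(ri)
    cutoffs <- rep(NA_real_, n)
    call_target <- rep(NA, n)
    for (i in seq_len(n)) {
        ts <- result@folds[[i]]$trainScores
        if (is.null(ts))
            stop("looOptimalCutoff needs a result with returnTrain = TRUE")
        if (is.na(ri[i]) || !length(ts)) next
        cutoffs[i] <- .bestCutoff(ts, pos_all[names(ts)])
        call_target[i] <- ri[i] >= cutoffs[i]
    }
    ok <- !is.na(call_target)
    tp <- sum(call_target[ok] & pos_all[ok])
    tn <- sum(!call_target[ok] & !pos_all[ok])
    out <- new("CutoffResult",
               cutoff = mean(cutoffs, na.rm = TRUE),
               sensitivity = tp / sum(pos_all[ok]),
               specificity = tn / sum(!pos_all[ok]),
               accuracy = (tp + tn) / sum(ok),
               degenerate = FALSE)
    attr(out, "foldCutoffs") <- cutoffs
    attr(out, "heldOutCalls") <- call_target
    out
}
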