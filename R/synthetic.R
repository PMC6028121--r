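# Synthetic study generator: sparse log-normal base composition, planted
# multiplicative taxon shifts in labelled samples, Dirichlet-multinomial
# count sampling at realistic sequencing depth, and binary mutation
# features with controllable prevalence and overlap.

.syntheticLineages <- function(nTaxa) {
    sprintf("k__Bacteria;p__SynthPhylum%02d;c__SynthClass;o__SynthOrder;f__SynthFamily%02d;g__SynthGenus%03d",
            (seq_len(nTaxa) - 1L) %% 8L + 1L,
            (seq_len(nTaxa) - 1L) %% 40L + 1L,
            seq_len(nTaxa))
}

#' Expected per-sample compositions with planted shifts
#'
#' Draws one sparse base composition (log-normal relative abundances,
#' normalized) and, for positive-labelled samples, multiplies each planted
#' taxon's proportion by its fold change (direction +1 up, -1 down) before
#' renormalizing — a compositionally realistic shift: boosting one taxon
#' depresses all others.
#'
#' @param config a [SyntheticConfig-class].
#' @param positive logical vector (length `nSamples`) marking the samples
#'   carrying the planted shifts; `NULL` means all negative.
#' @param base optional base composition (length `nTaxa`, summing to 1);
#'   drawn log-normally when `NULL`.
#' @param seed optional integer seed.
#' @return List with `proportions` (taxa x samples matrix of expected
#'   proportions) and `base` (the shared base composition).
#' @export
simulateComposition <- function(config = syntheticConfig(), positive = NULL,
                                base = NULL, seed = NULL) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    if (!is.null(seed)) set.seed(seed)
    n <- config@nSamples
    if (is.null(positive)) positive <- rep(FALSE, n)
    stopifnot(length(positive) == n)
    if (is.null(base))
        base <- rlnorm(config@nTaxa, meanlog = 0,
                       sdlog = config@baseLogmeanSd)
    stopifnot(length(base) == config@nTaxa)
    base <- base / sum(base)
    pl <- config@planted
    if (nrow(pl) && any(pl$taxon < 1 | pl$taxon > config@nTaxa))
        stop("planted taxon index out of range")
    shifted <- base
    if (nrow(pl)) {
        mult <- ifelse(pl$direction >= 0, pl$fold, 1 / pl$fold)
        shifted[pl$taxon] <- shifted[pl$taxon] * mult
        shifted <- shifted / sum(shifted)
    }
    props <- matrix(base, config@nTaxa, n)
    props[, positive] <- shifted
    dimnames(props) <- list(.syntheticLineages(config@nTaxa),
                            sprintf("tumor%03d", seq_len(n)))
    list(proportions = props, base = setNames(base, rownames(props)))
}

#' Sample sequencing counts from expected compositions
#'
#' Per sample, the depth is drawn Poisson around the configured mean depth
#' (floored at 1 read) and counts are Dirichlet-multinomial with
#' concentration `overdispersion * proportions`; `overdispersion = Inf`
#' gives plain multinomial sampling.
#'
#' @param proportions taxa x samples matrix of expected proportions.
#' @param config a [SyntheticConfig-class].
#' @param seed optional integer seed.
#' @return A counts-mode [AbundanceTable-class] at genus rank.
#' @export
simulateCounts <- function(proportions, config = syntheticConfig(),
                           seed = NULL) {
    if (config@depth < 1) stop("depth must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    n <- ncol(proportions)
    depth <- pmax(rpois(n, config@depth), 1L)
    counts <- vapply(seq_len(n), function(j) {
        p <- proportions[, j]
        if (is.finite(config@overdispersion)) {
            a <- config@overdispersion * p
            g <- rgamma(length(a), shape = a, rate = 1)
            if (sum(g) == 0) g[which.max(p)] <- 1
            p <- g / sum(g)
        }
        as.numeric(rmultinom(1, depth[j], p))
    }, numeric(nrow(proportions)))
    dimnames(counts) <- dimnames(proportions)
    AbundanceTable(counts, normalized = FALSE, taxRank = "genus")
}

#' Simulate binary mutation features
#'
#' Per feature, sample labels are Bernoulli at `labelPrevalence`; draws
#' leaving either class empty are rejected (up to 100 tries, then an
#' error). With `overlap` set, every feature after the first is constructed
#' to share samples with the first feature at that Jaccard overlap (1 =
#' identical columns); an infeasible request errors.
#'
#' @param config a [SyntheticConfig-class].
#' @param seed optional integer seed.
#' @return A [MutationMatrix-class] (`featureKind = "gene"`,
#'   `effectScope = "lof"`) with features `SYNGENE01`, `SYNGENE02`, ...
#' @export
simulateMutations <- function(config = syntheticConfig(), seed = NULL) {
    stopifnot(is(config, "SyntheticConfig"))
    if (!is.null(seed)) set.seed(seed)
    n <- config@nSamples
    prev <- config@labelPrevalence
    draw <- function() {
        for (try in 1:100) {
            x <- rbinom(n, 1, prev)
            if (sum(x) > 0 && sum(x) < n) return(x)
        }
        stop("could not draw labels with both classes non-empty at ",
             "prevalence ", prev)
    }
    m <- matrix(0L, config@nFeatures, n,
                dimnames = list(sprintf("SYNGENE%02d",
                                        seq_len(config@nFeatures)),
                                sprintf("tumor%03d", seq_len(n))))
    m[1, ] <- draw()
    if (config@nFeatures > 1L) {
        for (f in 2:config@nFeatures) {
            if (is.na(config@overlap)) {
                m[f, ] <- draw()
            } else {
                s1 <- which(m[1, ] == 1)
                sz <- length(s1)
                k <- round(config@overlap * 2 * sz / (1 + config@overlap))
                k <- min(k, sz)
                need_out <- sz - k
                outside <- setdiff(seq_len(n), s1)
                if (need_out > length(outside))
                    stop("requested overlap ", config@overlap,
                         " infeasible at prevalence ", prev)
                set <- c(if (k > 0) s1[sample.int(sz, k)],
                         if (need_out > 0)
                             outside[sample.int(length(outside), need_out)])
                m[f, set] <- 1L
            }
        }
    }
    se <- SummarizedExperiment(assays = list(calls = m))
    new("MutationMatrix", se, featureKind = "gene", effectScope = "lof")
}

#' Generate a complete synthetic dataset
#'
#' Draws mutation labels, plants the configured abundance shifts into the
#' samples positive for the first feature, samples counts, and bundles a toy
#' pathway map over the synthetic features. With `plantDefault` (the
#' constructor default) the planted set is 5 taxa at a 4-fold upward shift,
#' picked among moderately abundant taxa of the realised base composition
#' (abundance ranks 11-40); features beyond the first carry no planted
#' signal. Fully deterministic given `seed`.
#'
#' @param config a [SyntheticConfig-class].
#' @param seed integer seed (default 1).
#' @return A [SyntheticDataset-class].
#' @examples
#' ds <- generateDataset(syntheticConfig(nTaxa = 60, depth = 5000), seed = 1)
#' ds@truth
#' @export
generateDataset <- function(config = syntheticConfig(), seed = 1) {
    stopifnot(is(config, "SyntheticConfig"))
    set.seed(seed)
    labels <- simulateMutations(config)
    positive <- mutationCalls(labels)[1, ] == 1
    base <- rlnorm(config@nTaxa, 0, config@baseLogmeanSd)
    if (config@plantDefault) {
        ## resolve the default plant against the realised base composition:
        ## 5 taxa at 4-fold, drawn from abundance ranks 11-40
        ord <- order(base, decreasing = TRUE)
        pool <- ord[seq.int(min(11L, length(ord)), min(40L, length(ord)))]
        idx <- sort(pool[sample.int(length(pool), min(5, length(pool)))])
        config@planted <- data.frame(taxon = idx, fold = 4, direction = 1)
    }
    comp <- simulateComposition(config, positive = positive, base = base)
    counts <- simulateCounts(comp$proportions, config)
    pl <- config@planted
    truth <- if (nrow(pl)) {
        data.frame(feature = rownames(mutationCalls(labels))[1],
                   taxon = rownames(comp$proportions)[pl$taxon],
                   fold = pl$fold, direction = pl$direction,
                   stringsAsFactors = FALSE)
    } else {
        data.frame(feature = character(0), taxon = character(0),
                   fold = numeric(0), direction = numeric(0))
    }
    feats <- rownames(mutationCalls(labels))
    pathway_map <- list(synthetic_pathway_A = feats[seq_along(feats) %% 2 == 1],
                        synthetic_pathway_B = feats[seq_along(feats) %% 2 == 0])
    pathway_map <- pathway_map[vapply(pathway_map, length, 1L) > 0]
    new("SyntheticDataset", abundance = counts, labels = labels,
        truth = truth, pathwayMap = pathway_map, config = config)
}

setMethod("show", "SyntheticDataset", function(object) {
    cat(sprintf(
        "SyntheticDataset: %d taxa x %d samples, %d feature(s), %d planted taxa\n",
        nrow(object@abundance), ncol(object@abundance),
        nrow(object@labels), nrow(object@truth)))
})
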