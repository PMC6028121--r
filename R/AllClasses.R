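#' Taxon abundance table
#'
#' A taxa-by-samples abundance matrix (counts or relative abundances) with
#' rank-prefixed lineage strings as row names, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with one assay named
#' `"abundance"`. The `normalized` slot records whether columns are
#' proportions (each summing to 1) and `taxRank` the taxonomic level the
#' rows are collapsed to (`"otu"` for uncollapsed tables).
#'
#' @slot normalized logical; `TRUE` once [relativeAbundance()] has been applied.
#' @slot taxRank character; one of `"otu"`, `"kingdom"`, `"phylum"`,
#'   `"class"`, `"order"`, `"family"`, `"genus"`, `"species"`.
#'
#' @seealso [AbundanceTable()], [readAbundanceTable()], [collapseToRank()],
#'   [relativeAbundance()]
#' @export
setClass("AbundanceTable",
    contains = "SummarizedExperiment",
    representation(normalized = "logical", taxRank = "character"),
    prototype(normalized = FALSE, taxRank = "otu"))

setValidity("AbundanceTable", function(object) {
    msg <- character()
    if (!"abundance" %in% names(assays(object)))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        m <- assay(object, "abundance")
        if (!is.numeric(m))
            msg <- c(msg, "abundance values must be numeric")
        else if (any(m < 0))
            msg <- c(msg, "abundance values must be non-negative")
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "taxon ids (rownames) must be present and unique")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "sample ids (colnames) must be present and unique")
        if (isTRUE(object@normalized) && ncol(m) > 0) {
            ## taxon subsets of a normalized table keep their proportions
            ## relative to the original whole, so sums may fall below 1 but
            ## must never exceed it
            cs <- colSums(m)
            if (any(cs > 1 + 1e-9) || any(cs <= 0))
                msg <- c(msg,
                         "normalized table columns must sum to (0, 1] (1e-9)")
        }
    }
    if (length(object@normalized) != 1L)
        msg <- c(msg, "'normalized' must be a single logical")
    if (length(object@taxRank) != 1L)
        msg <- c(msg, "'taxRank' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Binary mutation feature matrix
#'
#' A features-by-samples 0/1 indicator matrix: entry 1 means the feature
#' (a gene or a pathway) harbours at least one qualifying somatic mutation in
#' that sample. Stored as a [SummarizedExperiment::SummarizedExperiment]
#' with one assay named `"calls"`.
#'
#' @slot featureKind character; `"gene"`, `"kegg_pathway"` or `"pid_pathway"`.
#' @slot effectScope character; which mutation classes qualify: `"total"`
#'   (all), `"missense"` (all non-synonymous) or `"lof"` (premature stop,
#'   stop loss, frameshift).
#'
#' @seealso [buildMutationMatrix()], [collapseToPathways()],
#'   [prevalenceFilter()]
#' @export
setClass("MutationMatrix",
    contains = "SummarizedExperiment",
    representation(featureKind = "character", effectScope = "character"),
    prototype(featureKind = "gene", effectScope = "lof"))

setValidity("MutationMatrix", function(object) {
    msg <- character()
    if (!"calls" %in% names(assays(object)))
        msg <- c(msg, "assay 'calls' is required")
    else {
        m <- assay(object, "calls")
        if (!all(m %in% c(0, 1)))
            msg <- c(msg, "mutation calls must be 0/1")
        if (nrow(m) > 0 && (is.null(rownames(m)) ||
                            anyDuplicated(rownames(m))))
            msg <- c(msg, "feature ids (rownames) must be present and unique")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "sample ids (colnames) must be present and unique")
    }
    if (!object@featureKind %in% c("gene", "kegg_pathway", "pid_pathway"))
        msg <- c(msg, "featureKind must be gene/kegg_pathway/pid_pathway")
    if (!object@effectScope %in% c("total", "missense", "lof"))
        msg <- c(msg, "effectScope must be total/missense/lof")
    if (length(msg)) msg else TRUE
})

#' Risk-index model
#'
#' The two disjoint taxon sets that define the unweighted arcsine-square-root
#' risk index: taxa enriched in the target class (e.g. tumors carrying a
#' loss-of-function mutation) contribute positively, taxa enriched in the
#' reference class negatively.
#'
#' @slot positiveTaxa,negativeTaxa character vectors of lineage strings.
#' @slot targetClass,referenceClass labels of the two classes.
#' @slot taxRank taxonomic rank the model's taxa are collapsed to.
#' @export
setClass("RiskModel",
    representation(positiveTaxa = "character", negativeTaxa = "character",
                   targetClass = "character", referenceClass = "character",
                   taxRank = "character"),
    prototype(taxRank = "genus"))

setValidity("RiskModel", function(object) {
    msg <- character()
    if (length(intersect(object@positiveTaxa, object@negativeTaxa)))
        msg <- c(msg, "positive and negative taxa must be disjoint")
    if (length(object@positiveTaxa) + length(object@negativeTaxa) == 0L)
        msg <- c(msg, "model must contain at least one taxon")
    if (length(msg)) msg else TRUE
})

#' Leave-one-out risk-index result
#'
#' Held-out risk indices for every sample together with the significance of
#' their separation by class: two-sided Mann-Whitney U p-value and (when
#' [permutationTest()] has been run) the empirical label-permutation p-value.
#'
#' @slot riskIndex named numeric; held-out risk index per sample (`NA` when a
#'   fold produced an empty model).
#' @slot labels factor of the two class labels, aligned to `riskIndex`.
#' @slot targetClass label treated as "positive" for the index sign.
#' @slot observedDiff mean risk index of the target class minus the reference
#'   class (missing indices dropped pairwise).
#' @slot mwuP two-sided Mann-Whitney U p-value.
#' @slot permP empirical permutation p-value (`NA_real_` until computed).
#' @slot permDiffs the permuted mean differences behind `permP`.
#' @slot nTaxaUsed integer; per-fold number of model taxa.
#' @slot folds list of per-fold details (selected taxa, training scores).
#' @export
setClass("RiskIndexResult",
    representation(riskIndex = "numeric", labels = "factor",
                   targetClass = "character", observedDiff = "numeric",
                   mwuP = "numeric", permP = "numeric", permDiffs = "numeric",
                   nTaxaUsed = "integer", folds = "list"),
    prototype(permP = NA_real_, permDiffs = numeric(0)))

setValidity("RiskIndexResult", function(object) {
    msg <- character()
    if (length(object@riskIndex) != length(object@labels))
        msg <- c(msg, "riskIndex and labels lengths differ")
    if (nlevels(object@labels) != 2L)
        msg <- c(msg, "labels must have exactly two levels")
    if (length(msg)) msg else TRUE
})

#' SparCC correlation network
#'
#' Taxon co-occurrence network for one mutation stratum: nodes carry the mean
#' relative abundance of each taxon in the stratum, edges the SparCC
#' correlation `r` and its shuffle-based pseudo p-value, already filtered to
#' `|r| >= rMin` and `p <= pMax`.
#'
#' @slot nodes [S4Vectors::DataFrame] with columns `taxon`, `meanAbundance`.
#' @slot edges [S4Vectors::DataFrame] with columns `taxon1`, `taxon2`, `r`,
#'   `p`, `sign` (`"direct"`/`"inverse"`).
#' @slot stratum `"mutated"`, `"wildtype"` or `"pooled"`.
#' @slot feature the mutation feature conditioned on (may be `NA`).
#' @slot rMin,pMax the display filters applied.
#' @export
setClass("CorrelationNetwork",
    representation(nodes = "DataFrame", edges = "DataFrame",
                   stratum = "character", feature = "character",
                   rMin = "numeric", pMax = "numeric"),
    prototype(stratum = "pooled", feature = NA_character_,
              rMin = 0.25, pMax = 0.05))

setValidity("CorrelationNetwork", function(object) {
    msg <- character()
    ed <- object@edges
    if (nrow(ed)) {
        if (any(abs(ed$r) > 1)) msg <- c(msg, "|r| must be <= 1")
        if (any(ed$taxon1 == ed$taxon2)) msg <- c(msg, "self-edges forbidden")
        if (any(abs(ed$r) < object@rMin - 1e-12))
            msg <- c(msg, "edges below the r filter present")
        if (any(ed$p > object@pMax + 1e-12))
            msg <- c(msg, "edges above the p filter present")
    }
    if (length(msg)) msg else TRUE
})

#' ROC result from stratified k-fold cross-validation
#'
#' Per-fold ROC curves over held-out risk indices, their vertical average at
#' a fixed false-positive-rate grid, and the area under the mean curve.
#'
#' @slot folds list of per-fold data.frames (`threshold`, `fpr`, `tpr`).
#' @slot meanCurve data.frame (`fpr`, `tpr`): vertically averaged curve.
#' @slot auc trapezoidal area under the mean curve.
#' @slot pooledAuc rank-statistic AUC of all held-out scores pooled.
#' @slot foldAssignments named integer vector, sample -> fold.
#' @slot scores named numeric vector of held-out risk indices.
#' @slot labels factor aligned with `scores`.
#' @export
setClass("ROCResult",
    representation(folds = "list", meanCurve = "data.frame",
                   auc = "numeric", pooledAuc = "numeric",
                   foldAssignments = "integer", scores = "numeric",
                   labels = "factor"))

setValidity("ROCResult", function(object) {
    if (length(object@auc) == 1L && (object@auc < 0 || object@auc > 1))
        "auc must lie in [0, 1]" else TRUE
})

#' Risk-index cutoff result
#'
#' A risk-index decision threshold with its operating characteristics
#' (samples scoring at or above `cutoff` are called target-class).
#'
#' @slot cutoff risk-index threshold.
#' @slot sensitivity,specificity,accuracy operating characteristics at
#'   `cutoff`.
#' @slot degenerate `TRUE` when the requested operating point was not
#'   attainable and the closest attainable point is reported.
#' @export
setClass("CutoffResult",
    representation(cutoff = "numeric", sensitivity = "numeric",
                   specificity = "numeric", accuracy = "numeric",
                   degenerate = "logical"),
    prototype(degenerate = FALSE))

#' Synthetic dataset bundle
#'
#' Output of [generateDataset()]: a planted-truth synthetic study with a count
#' [AbundanceTable], a binary [MutationMatrix] of simulated features, the
#' planted-association truth table and a toy pathway map.
#'
#' @slot abundance [AbundanceTable] in counts mode.
#' @slot labels [MutationMatrix] of simulated binary features.
#' @slot truth data.frame with columns `feature`, `taxon`, `fold`,
#'   `direction`.
#' @slot pathwayMap named list: pathway name -> character vector of features.
#' @slot config the [SyntheticConfig] used.
#' @export
setClass("SyntheticDataset",
    representation(abundance = "AbundanceTable", labels = "MutationMatrix",
                   truth = "data.frame", pathwayMap = "list",
                   config = "ANY"))

#' Discriminant-screen configuration
#'
#' Tuning parameters of the two-stage discriminant-taxon screen.
#'
#' @slot kwAlpha Kruskal-Wallis screening level (default 0.05).
#' @slot ldaThreshold minimum log10 LDA effect size for selection (default 2).
#' @slot nBootstrap LDA bootstrap iterations (default 30).
#' @slot bootstrapFraction fraction of each class subsampled per bootstrap
#'   (default 2/3).
#' @slot scaling factor mapping proportion-scale effects onto the conventional
#'   per-million log10 scale (default 1e6); the reported score is
#'   `log10(1 + scaling * effect)`.
#' @slot ridge relative ridge added to the pooled covariance diagonal.
#' @export
setClass("DiscriminationConfig",
    representation(kwAlpha = "numeric", ldaThreshold = "numeric",
                   nBootstrap = "integer", bootstrapFraction = "numeric",
                   scaling = "numeric", ridge = "numeric"),
    prototype(kwAlpha = 0.05, ldaThreshold = 2, nBootstrap = 30L,
              bootstrapFraction = 2 / 3, scaling = 1e6, ridge = 1e-6))

setValidity("DiscriminationConfig", function(object) {
    msg <- character()
    if (object@kwAlpha <= 0 || object@kwAlpha >= 1)
        msg <- c(msg, "kwAlpha must be in (0,1)")
    if (object@nBootstrap < 1L) msg <- c(msg, "nBootstrap must be >= 1")
    if (object@bootstrapFraction <= 0 || object@bootstrapFraction > 1)
        msg <- c(msg, "bootstrapFraction must be in (0,1]")
    if (object@scaling <= 0) msg <- c(msg, "scaling must be positive")
    if (length(msg)) msg else TRUE
})

#' SparCC configuration
#'
#' @slot nResamples Dirichlet resamples per estimate (default 20).
#' @slot nExclusionIterations maximum strongly-correlated-pair exclusions
#'   (default 10).
#' @slot exclusionThreshold |r| above which a pair may be excluded from the
#'   basis-variance system (default 0.1).
#' @slot nShuffles shuffled datasets for pseudo p-values (default 100).
#' @export
setClass("SparccConfig",
    representation(nResamples = "integer", nExclusionIterations = "integer",
                   exclusionThreshold = "numeric", nShuffles = "integer"),
    prototype(nResamples = 20L, nExclusionIterations = 10L,
              exclusionThreshold = 0.1, nShuffles = 100L))

setValidity("SparccConfig", function(object) {
    msg <- character()
    if (object@exclusionThreshold <= 0 || object@exclusionThreshold >= 1)
        msg <- c(msg, "exclusionThreshold must be in (0,1)")
    if (object@nShuffles < 1L) msg <- c(msg, "nShuffles must be >= 1")
    if (object@nResamples < 1L) msg <- c(msg, "nResamples must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Synthetic-data configuration
#'
#' Study conditions of the simulator: 44 tumor samples, several hundred
#' sparse taxa with a log-normal base composition, mean sequencing depth
#' 120000 reads per sample, Dirichlet-multinomial overdispersion, binary
#' mutation features at controlled prevalence and multiplicative planted
#' abundance shifts in labelled samples.
#'
#' @slot nSamples number of tumor samples (default 44).
#' @slot nTaxa number of taxa (default 300).
#' @slot depth mean sequencing depth per sample (default 120000).
#' @slot baseLogmeanSd sd of the log-normal base composition (default 2).
#' @slot planted data.frame with columns `taxon` (index), `fold` (> 0) and
#'   `direction` (+1/-1); zero rows means a null dataset.
#' @slot plantDefault logical; when `TRUE` (the constructor's `"default"`
#'   sentinel), [generateDataset()] plants 5 moderately abundant taxa at a
#'   4-fold upward shift, choosing the taxon indices from the realised base
#'   composition.
#' @slot labelPrevalence fraction of samples labelled positive (default 0.5).
#' @slot nFeatures number of mutation features simulated (default 1).
#' @slot overdispersion Dirichlet concentration scale; `Inf` gives plain
#'   multinomial sampling (default 200).
#' @slot overlap target Jaccard overlap between consecutive features'
#'   positive sets (`NA` = independent features).
#' @export
setClass("SyntheticConfig",
    representation(nSamples = "integer", nTaxa = "integer", depth = "numeric",
                   baseLogmeanSd = "numeric", planted = "data.frame",
                   plantDefault = "logical",
                   labelPrevalence = "numeric", nFeatures = "integer",
                   overdispersion = "numeric", overlap = "numeric"),
    prototype(nSamples = 44L, nTaxa = 300L, depth = 120000,
              baseLogmeanSd = 2,
              planted = data.frame(taxon = integer(0), fold = numeric(0),
                                   direction = numeric(0)),
              plantDefault = TRUE,
              labelPrevalence = 0.5, nFeatures = 1L, overdispersion = 200,
              overlap = NA_real_))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
    if (object@labelPrevalence <= 0 || object@labelPrevalence >= 1)
        msg <- c(msg, "labelPrevalence must be in (0,1)")
    pl <- object@planted
    if (nrow(pl)) {
        if (!all(c("taxon", "fold", "direction") %in% names(pl)))
            msg <- c(msg, "planted needs columns taxon, fold, direction")
        else {
            if (any(pl$fold <= 0)) msg <- c(msg, "fold changes must be > 0")
            if (any(pl$taxon < 1 | pl$taxon > object@nTaxa))
                msg <- c(msg, "planted taxon index out of range")
        }
    }
    if (length(msg)) msg else TRUE
})
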