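# Mutation records -> binary gene/pathway LoF matrices, prevalence filters,
# stage groups and the stage/mutation confounding check.

#' @rdname MutationMatrix
#' @export
setMethod("mutationCalls", "MutationMatrix", function(x) assay(x, "calls"))

#' @rdname MutationMatrix
#' @export
setMethod("featureIds", "MutationMatrix", function(x) rownames(x))

#' @rdname MutationMatrix
#' @export
setMethod("sampleIds", "MutationMatrix", function(x) colnames(x))

#' @rdname MutationMatrix
#' @export
setMethod("featureKind", "MutationMatrix", function(x) x@featureKind)

#' @rdname MutationMatrix
#' @export
setMethod("effectScope", "MutationMatrix", function(x) x@effectScope)

setMethod("show", "MutationMatrix", function(object) {
    cat(sprintf("MutationMatrix: %d %s feature(s) x %d samples (scope %s)\n",
                nrow(object), object@featureKind, ncol(object),
                object@effectScope))
})

#' Default effect-annotation alias table
#'
#' Maps variant-effect vocabulary (SnpEff / Sequence Ontology style, matched
#' case-insensitively) to the four effect classes. Loss of function covers
#' premature stop gain, stop loss and frameshift; synonymous covers silent
#' changes; missense covers non-silent amino-acid substitutions; everything
#' unrecognised is `other`.
#'
#' @return Named list of character vectors, one per effect class.
#' @export
effectAliases <- function() {
    list(
        lof = c("stop_gained", "stop gained", "stopgain", "nonsense",
                "stop_lost", "stop lost", "stoploss",
                "frameshift_variant", "frameshift", "frame_shift_del",
                "frame_shift_ins", "frameshift_insertion",
                "frameshift_deletion", "premature_stop"),
        synonymous = c("synonymous_variant", "synonymous", "silent",
                       "synonymous_coding", "stop_retained_variant"),
        missense = c("missense_variant", "missense", "nonsynonymous",
                     "non_synonymous_coding", "nonsynonymous_snv",
                     "missense_mutation"))
}

#' Classify a variant effect annotation
#'
#' @param raw character vector of raw effect annotations. Annotations with
#'   several ampersand- or comma-separated terms are classified by their most
#'   severe matching term (lof > missense > synonymous).
#' @param aliases alias table as returned by [effectAliases()].
#' @return character vector with values in
#'   `c("lof", "missense", "synonymous", "other")`.
#' @examples
#' classifyEffect(c("stop_gained", "missense_variant", "intron_variant"))
#' @export
classifyEffect <- function(raw, aliases = effectAliases()) {
    aliases <- lapply(aliases, tolower)
    vapply(tolower(as.character(raw)), function(x) {
        terms <- strsplit(x, "[&,+]")[[1]]
        terms <- gsub("^\\s+|\\s+$", "", terms)
        if (any(terms %in% aliases$lof)) "lof"
        else if (any(terms %in% aliases$missense)) "missense"
        else if (any(terms %in% aliases$synonymous)) "synonymous"
        else "other"
    }, character(1), USE.NAMES = FALSE)
}

.scopeClasses <- function(effect_scope) {
    switch(effect_scope,
           total = c("lof", "missense", "synonymous", "other"),
           missense = "missense",
           lof = "lof",
           stop("unknown effect scope: ", effect_scope))
}

#' Build a binary gene-by-sample mutation matrix
#'
#' An entry is 1 iff the sample carries at least one mutation record of a
#' qualifying class in that gene (binarization: duplicated records do not
#' change the result). Scope `"total"` counts every class, `"missense"` only
#' amino-acid substitutions and `"lof"` only premature stop, stop loss and
#' frameshift mutations.
#'
#' @param records mutation records as from [readMutations()].
#' @param samples character vector of sample ids defining the columns (the
#'   analysis cohort); records for other samples are ignored.
#' @param effectScope `"total"`, `"missense"` or `"lof"`.
#' @return A [MutationMatrix-class] with `featureKind = "gene"`.
#' @export
buildMutationMatrix <- function(records, samples,
                                effectScope = c("lof", "missense", "total")) {
    effectScope <- match.arg(effectScope)
    keep <- records$effect_class %in% .scopeClasses(effectScope) &
        records$sample_id %in% samples
    rec <- records[keep, , drop = FALSE]
    genes <- sort(unique(records$gene_symbol))
    m <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
    if (nrow(rec)) {
        m[cbind(match(rec$gene_symbol, genes),
                match(rec$sample_id, samples))] <- 1
    } else {
        warning("no qualifying mutation records; all-zero matrix")
    }
    ens <- records$ensembl_gene_id[match(genes, records$gene_symbol)]
    se <- SummarizedExperiment(assays = list(calls = m),
        rowData = S4Vectors::DataFrame(ensembl_gene_id = ens,
                                       row.names = genes))
    new("MutationMatrix", se, featureKind = "gene", effectScope = effectScope)
}

#' Collapse a gene mutation matrix to pathways
#'
#' A pathway is called mutated in a sample iff at least one member gene is
#' mutated there (logical OR over members present in the matrix). Pathway
#' membership is matched on ENSEMBL gene ids when the matrix carries them,
#' falling back to gene symbols; mapping misses are reported in
#' `metadata(x)$mappingReport`, and pathways with no member gene present in
#' the matrix are dropped.
#'
#' @param m a gene-level [MutationMatrix-class].
#' @param map pathway map from [readPathwayMap()].
#' @param database `"KEGG"` or `"PID"` (sets the result's `featureKind`).
#' @return A pathway-level [MutationMatrix-class].
#' @export
collapseToPathways <- function(m, map, database = c("KEGG", "PID")) {
    stopifnot(is(m, "MutationMatrix"))
    if (featureKind(m) != "gene")
        stop("collapseToPathways needs a gene-level matrix")
    database <- match.arg(database)
    calls <- mutationCalls(m)
    ens <- rowData(m)$ensembl_gene_id
    keys <- rownames(calls)
    if (!is.null(ens)) {
        has <- !is.na(ens) & nzchar(ens)
        keys[has] <- ens[has]
    }
    all_map_genes <- unique(unlist(map, use.names = FALSE))
    matched <- keys %in% all_map_genes | rownames(calls) %in% all_map_genes
    pw <- lapply(map, function(genes) {
        idx <- which(keys %in% genes | rownames(calls) %in% genes)
        if (!length(idx)) return(NULL)
        as.numeric(colSums(calls[idx, , drop = FALSE]) > 0)
    })
    empty <- vapply(pw, is.null, logical(1))
    pw <- pw[!empty]
    if (!length(pw))
        stop("no pathway has a member gene present in the matrix")
    out <- do.call(rbind, pw)
    dimnames(out) <- list(names(pw), colnames(calls))
    se <- SummarizedExperiment(assays = list(calls = out))
    res <- new("MutationMatrix", se,
               featureKind = if (database == "KEGG") "kegg_pathway"
                             else "pid_pathway",
               effectScope = effectScope(m))
    metadata(res)$mappingReport <- list(
        genesMatched = sum(matched), genesUnmatched = sum(!matched),
        pathwaysDropped = sum(empty),
        droppedPathways = names(empty)[empty])
    res
}

#' Filter mutation features by patient prevalence
#'
#' Keeps features mutated in at least `minPatients` samples. The kept/dropped
#' counts (and the count a grid of alternative thresholds would keep) are
#' stored in `metadata(x)$prevalenceReport`.
#'
#' @param m a [MutationMatrix-class].
#' @param minPatients minimum number of mutated samples (default 10).
#' @return The filtered [MutationMatrix-class].
#' @export
prevalenceFilter <- function(m, minPatients = 10) {
    stopifnot(is(m, "MutationMatrix"), minPatients >= 1)
    prev <- rowSums(mutationCalls(m))
    keep <- prev >= minPatients
    res <- m[keep, ]
    grid <- seq_len(max(c(prev, 1)))
    metadata(res)$prevalenceReport <- list(
        minPatients = minPatients, kept = sum(keep),
        dropped = sum(!keep), keptFeatures = rownames(m)[keep],
        thresholdGrid = data.frame(
            minPatients = grid,
            nFeatures = vapply(grid, function(k) sum(prev >= k), integer(1))))
    res
}

#' Group tumor stages into low and high
#'
#' Stage 1-2 tumors form the `low` group and stage 3-4 tumors the `high`
#' group; samples without stage information are `NA`.
#'
#' @param metadata data.frame as from [readSampleMetadata()].
#' @return Named factor (`low`/`high`) indexed by sample id.
#' @export
stageGroups <- function(metadata) {
    g <- ifelse(is.na(metadata$stage), NA_character_,
                ifelse(metadata$stage <= 2, "low", "high"))
    setNames(factor(g, levels = c("low", "high")), metadata$sample_id)
}

#' Test mutation features for confounding with stage group
#'
#' For each feature, a two-sided Fisher's exact test on the 2x2 table of
#' mutation status against stage group (samples with missing stage excluded),
#' followed by Benjamini-Hochberg correction across features.
#'
#' @param m a [MutationMatrix-class].
#' @param groups stage groups from [stageGroups()] (named by sample id).
#' @return data.frame with columns `feature`, `odds_ratio`, `p`, `q`.
#' @export
confoundingTest <- function(m, groups) {
    stopifnot(is(m, "MutationMatrix"))
    g <- groups[colnames(m)]
    ok <- !is.na(g)
    if (!any(ok)) stop("all samples are missing stage information")
    g <- droplevels(factor(g[ok], levels = c("low", "high")))
    if (nlevels(g) < 2 || any(table(g) < 2))
        stop("need at least 2 samples per stage group")
    calls <- mutationCalls(m)[, ok, drop = FALSE]
    res <- lapply(rownames(calls), function(f) {
        tab <- table(factor(calls[f, ] > 0, levels = c(FALSE, TRUE)), g)
        ft <- fisher.test(tab)
        data.frame(feature = f, odds_ratio = unname(ft$estimate),
                   p = ft$p.value)
    })
    out <- do.call(rbind, res)
    out$q <- p.adjust(out$p, method = "BH")
    out
}
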