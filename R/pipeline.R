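# End-to-end orchestration: simulate (or load) -> discriminate -> risk index
# -> permutation test -> evaluation -> networks -> robustness, with one
# config, per-feature error isolation and a hashed output manifest.

.pipelineDefaults <- function() {
    list(seed = 1,
         outputDir = ".",
         featureScope = "mutation",   # or "stage" (requires metadata)
         features = NULL,             # default: all features
         stages = c("discriminate", "riskIndex", "evaluate", "network",
                    "robustness"),
         thresholds = list(kwAlpha = 0.05, ldaThreshold = 2,
                           minPatients = NULL, spec = 0.8, B = 99, k = 10),
         sparcc = list(nResamples = 20, nExclusionIterations = 10,
                       exclusionThreshold = 0.1, nShuffles = 100,
                       rMin = 0.25, pMax = 0.05),
         simulate = list(), input = NULL)
}

.mergeConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    defaults <- .pipelineDefaults()
    cfg <- modifyList(defaults, config)
    if (is.null(config$seed))
        stop("config must set a seed (stochastic stages require one)")
    th <- cfg$thresholds
    stopifnot(th$kwAlpha > 0, th$kwAlpha < 1, th$B >= 1, th$k >= 2,
              th$spec > 0, th$spec <= 1)
    cfg
}

.pipelineInputs <- function(cfg) {
    if (!is.null(cfg$input)) {
        need <- c("abundance", "labels")
        miss <- setdiff(need, names(cfg$input))
        if (length(miss))
            stop("input config missing: ", paste(miss, collapse = ", "))
        ab <- readAbundanceTable(cfg$input$abundance)
        lm_raw <- as.matrix(read.delim(cfg$input$labels, row.names = 1,
                                       check.names = FALSE,
                                       comment.char = "#"))
        se <- SummarizedExperiment(assays = list(calls = lm_raw))
        labs <- new("MutationMatrix", se, featureKind = "gene",
                    effectScope = "lof")
        md <- if (!is.null(cfg$input$metadata))
            readSampleMetadata(cfg$input$metadata)
        list(abundance = ab, labels = labs, metadata = md, truth = NULL)
    } else {
        sim <- do.call(syntheticConfig, cfg$simulate)
        ds <- generateDataset(sim, seed = cfg$seed)
        list(abundance = ds@abundance, labels = ds@labels, metadata = NULL,
             truth = ds@truth)
    }
}

#' Run the full joint-analysis pipeline
#'
#' Executes the requested stages for every mutation feature (or the stage
#' grouping): discriminant-taxon selection, leave-one-out risk indices with
#' Mann-Whitney and label-permutation significance, ROC/cutoff evaluation,
#' mutation-conditioned SparCC networks and the linear-model robustness
#' check. Each stage writes provenance-stamped TSVs into `outputDir`; a
#' failure for one feature is recorded and does not abort the others. A
#' manifest (JSON) lists every output file with its MD5 hash together with
#' the seed and parameters, so reruns can be checked for bitwise identity.
#'
#' @param config named list or path to a YAML file. Recognised entries:
#'   `seed` (mandatory), `outputDir`, `featureScope` (`"mutation"` or
#'   `"stage"`), `features`, `stages`, `thresholds` (`kwAlpha`,
#'   `ldaThreshold`, `minPatients`, `spec`, `B`, `k`), `sparcc`, and either
#'   `simulate` (arguments to [syntheticConfig()]) or `input` (paths
#'   `abundance`, `labels`, optional `metadata`).
#' @return Invisibly, a list with `manifest`, `summary` (per-feature
#'   data.frame) and `errors` (named list of per-feature failures).
#' @export
runPipeline <- function(config) {
    cfg <- .mergeConfig(config)
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    inputs <- .pipelineInputs(cfg)
    ab <- inputs$abundance
    norm <- relativeAbundance(ab)
    disc_cfg <- discriminationConfig(kwAlpha = cfg$thresholds$kwAlpha,
                                     ldaThreshold = cfg$thresholds$ldaThreshold)
    sp <- cfg$sparcc
    sp_cfg <- sparccConfig(nResamples = sp$nResamples,
                           nExclusionIterations = sp$nExclusionIterations,
                           exclusionThreshold = sp$exclusionThreshold,
                           nShuffles = sp$nShuffles)

    labels_mm <- inputs$labels
    if (!is.null(cfg$thresholds$minPatients))
        labels_mm <- prevalenceFilter(labels_mm, cfg$thresholds$minPatients)

    if (identical(cfg$featureScope, "stage")) {
        if (is.null(inputs$metadata) ||
            all(is.na(inputs$metadata$stage)))
            stop("featureScope 'stage' requires metadata with a 'stage' ",
                 "column")
        sg <- stageGroups(inputs$metadata)
        sg <- sg[!is.na(sg)]
        feature_sets <- list(stage = setNames(as.integer(sg == "high"),
                                              names(sg)))
    } else {
        feats <- cfg$features
        if (is.null(feats)) feats <- featureIds(labels_mm)
        feature_sets <- lapply(setNames(feats, feats), function(f)
            mutationCalls(labels_mm)[f, ])
    }

    set.seed(cfg$seed)
    child_seeds <- sample.int(.Machine$integer.max - 1L,
                              length(feature_sets))
    files <- character(0)
    errors <- list()
    summary_rows <- list()
    params <- list(seed = cfg$seed, kwAlpha = cfg$thresholds$kwAlpha,
                   ldaThreshold = cfg$thresholds$ldaThreshold,
                   B = cfg$thresholds$B, k = cfg$thresholds$k)

    for (fi in seq_along(feature_sets)) {
        fname <- names(feature_sets)[fi]
        lab_raw <- feature_sets[[fi]]
        res <- tryCatch({
            keep <- intersect(sampleIds(ab), names(lab_raw))
            sub <- norm[, keep]
            lab <- factor(ifelse(lab_raw[keep] == 1, "mutated", "wildtype"),
                          levels = c("wildtype", "mutated"))
            names(lab) <- keep
            row <- list(feature = fname,
                        n_mutated = sum(lab == "mutated"),
                        n_wildtype = sum(lab == "wildtype"))
            out_of <- function(tag, ext = "tsv")
                file.path(cfg$outputDir, paste0(fname, ".", tag, ".", ext))

            disc <- NULL
            if ("discriminate" %in% cfg$stages) {
                disc <- discriminantTaxa(sub, lab, disc_cfg,
                                         seed = child_seeds[fi])
                f <- out_of("discriminants")
                .writeTsv(as.data.frame(disc), f, params)
                files <- c(files, f)
                row$n_discriminant <- nrow(disc)
            }
            if ("riskIndex" %in% cfg$stages) {
                loo <- looRiskIndices(sub, lab, disc_cfg,
                                      targetClass = "mutated",
                                      seed = child_seeds[fi],
                                      returnTrain = TRUE)
                loo <- permutationTest(sub, lab, disc_cfg,
                                       B = cfg$thresholds$B,
                                       targetClass = "mutated",
                                       seed = child_seeds[fi],
                                       result = loo)
                f <- out_of("risk_indices")
                .writeTsv(data.frame(sample = names(riskIndices(loo)),
                                     risk_index = riskIndices(loo),
                                     label = as.character(loo@labels)),
                          f, params)
                files <- c(files, f)
                row$n_taxa_mean <- mean(loo@nTaxaUsed)
                row$observed_diff <- observedDiff(loo)
                row$mwu_p <- mwuP(loo)
                row$perm_p <- permP(loo)
                if ("evaluate" %in% cfg$stages) {
                    roc <- kfoldRoc(sub, lab, k = cfg$thresholds$k,
                                    config = disc_cfg,
                                    targetClass = "mutated",
                                    seed = child_seeds[fi])
                    f <- out_of("roc_mean_curve")
                    .writeTsv(roc@meanCurve, f, params)
                    files <- c(files, f)
                    cut <- looOptimalCutoff(sub, lab, result = loo)
                    acc <- accuracyAtSpecificity(riskIndices(loo), loo@labels,
                                                 spec = cfg$thresholds$spec,
                                                 target = "mutated")
                    row$auc <- roc@auc
                    row$auc_pooled <- roc@pooledAuc
                    row$cutoff <- cut@cutoff
                    row$loo_accuracy <- cut@accuracy
                    row$acc_at_spec <- acc@accuracy
                    row$sens_at_spec <- acc@sensitivity
                }
            }
            if ("network" %in% cfg$stages && !is.null(disc) &&
                nrow(disc) >= 4 && min(table(lab)) >= 4) {
                nets <- differentialNetworks(ab[, keep], lab_raw[keep],
                                             taxa = disc$taxon,
                                             config = sp_cfg,
                                             rMin = sp$rMin, pMax = sp$pMax,
                                             feature = fname,
                                             seed = child_seeds[fi])
                f <- out_of("network_edges")
                writeEdgeList(list(nets$mutated, nets$wildtype), f, params)
                files <- c(files, f)
                row$n_edges_mutated <- nrow(networkEdges(nets$mutated))
                row$n_edges_wildtype <- nrow(networkEdges(nets$wildtype))
            }
            if ("robustness" %in% cfg$stages) {
                filt <- maaslinFilter(sub)
                lmres <- fitPerTaxonLm(filt, lab_raw[keep])
                f <- out_of("robustness_lm")
                .writeTsv(lmres, f, params)
                files <- c(files, f)
                row$lm_min_q <- suppressWarnings(min(lmres$q))
            }
            row
        }, error = function(e) e)
        if (inherits(res, "error")) {
            errors[[fname]] <- conditionMessage(res)
        } else {
            summary_rows[[fname]] <- res
        }
    }

    summary_df <- if (length(summary_rows)) {
        all_cols <- unique(unlist(lapply(summary_rows, names)))
        do.call(rbind, lapply(summary_rows, function(r) {
            r[setdiff(all_cols, names(r))] <- NA
            as.data.frame(r[all_cols])
        }))
    } else {
        data.frame()
    }
    if (nrow(summary_df) && "perm_p" %in% names(summary_df))
        summary_df$q <- fdrAdjust(summary_df$perm_p)
    f_sum <- file.path(cfg$outputDir, "summary.tsv")
    .writeTsv(summary_df, f_sum, params)
    files <- c(files, f_sum)

    manifest <- list(
        package = "micromut",
        version = as.character(packageVersion("micromut")),
        seed = cfg$seed,
        parameters = cfg$thresholds,
        stages = cfg$stages,
        features = names(feature_sets),
        failed = names(errors),
        files = lapply(setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
    f_manifest <- file.path(cfg$outputDir, "manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                         pretty = TRUE)
    if (length(errors))
        warning("pipeline completed with failures for: ",
                paste(names(errors), collapse = ", "))
    invisible(list(manifest = manifest, summary = summary_df,
                   errors = errors))
}
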