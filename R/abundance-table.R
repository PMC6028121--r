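.RANKS <- c(kingdom = 1L, phylum = 2L, class = 3L, order = 4L,
            family = 5L, genus = 6L, species = 7L)
.RANK_PREFIX <- c("k", "p", "c", "o", "f", "g", "s")

# Split a Greengenes-style lineage string into stripped rank tokens.
# Both "k__Bacteria; p__Firmicutes" and "k__Bacteria;p__Firmicutes" parse to
# the same tokens; comparison is always on stripped tokens.
.lineageTokens <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE), function(tok) {
        gsub("^\\s+|\\s+$", "", tok)
    })
}

# Canonical form of a lineage string used for cross-table matching.
.lineageKey <- function(x) {
    vapply(.lineageTokens(x), paste, character(1), collapse = ";")
}

#' Construct an abundance table
#'
#' @param values numeric matrix, taxa in rows (row names are lineage strings)
#'   and samples in columns.
#' @param normalized logical; are columns proportions summing to 1?
#' @param taxRank taxonomic rank of the rows (`"otu"` if uncollapsed).
#' @param sampleData optional data.frame of per-sample metadata (row names
#'   must match sample ids).
#'
#' @return An [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(10, 5, 0, 0, 5, 10), nrow = 3,
#'             dimnames = list(c("g__A", "g__B", "g__C"), c("s1", "s2")))
#' at <- AbundanceTable(m)
#' colSums(abundances(relativeAbundance(at)))
#' @export
AbundanceTable <- function(values, normalized = FALSE, taxRank = "otu",
                           sampleData = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    cd <- if (is.null(sampleData)) {
        S4Vectors::DataFrame(row.names = colnames(values))
    } else {
        S4Vectors::DataFrame(sampleData)
    }
    se <- SummarizedExperiment(assays = list(abundance = values),
                               colData = cd)
    new("AbundanceTable", se, normalized = normalized, taxRank = taxRank)
}

#' @rdname AbundanceTable
#' @export
setMethod("abundances", "AbundanceTable", function(x) assay(x, "abundance"))

#' @rdname AbundanceTable
#' @export
setMethod("taxonIds", "AbundanceTable", function(x) rownames(x))

#' @rdname AbundanceTable
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

#' @rdname AbundanceTable
#' @export
setMethod("isNormalized", "AbundanceTable", function(x) x@normalized)

#' @rdname AbundanceTable
#' @export
setMethod("taxRank", "AbundanceTable", function(x) x@taxRank)

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable: %d taxa x %d samples (%s, rank %s)\n",
                nrow(object), ncol(object),
                if (object@normalized) "relative abundances" else "counts",
                object@taxRank))
})

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total so that columns sum to 1.
#' Calling it on an already-normalized table is a no-op up to numerical
#' round-off (idempotent).
#'
#' @param table an [AbundanceTable-class].
#' @return A normalized [AbundanceTable-class].
#' @export
relativeAbundance <- function(table) {
    stopifnot(is(table, "AbundanceTable"))
    m <- abundances(table)
    tot <- colSums(m)
    if (any(tot == 0))
        stop("all-zero sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    out <- sweep(m, 2, tot, "/")
    res <- table
    assays(res) <- list(abundance = out)
    res@normalized <- TRUE
    validObject(res)
    res
}

#' Collapse taxa to a taxonomic rank
#'
#' Rows whose lineage strings share the same prefix up to `rank` are summed,
#' conserving per-sample totals exactly. Lineages that do not resolve to the
#' requested rank (missing or empty token) are collected into an
#' "unclassified at rank" bucket per their deepest resolved prefix, with a
#' warning.
#'
#' @param table an [AbundanceTable-class] with lineage-string taxon ids.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return An [AbundanceTable-class] collapsed to `rank`.
#' @export
collapseToRank <- function(table, rank = "genus") {
    stopifnot(is(table, "AbundanceTable"))
    rank <- match.arg(rank, names(.RANKS))
    depth <- .RANKS[[rank]]
    toks <- .lineageTokens(taxonIds(table))
    unresolved <- FALSE
    keys <- vapply(toks, function(tk) {
        if (length(tk) < depth) {
            pad <- paste0(.RANK_PREFIX[(length(tk) + 1L):depth], "__")
            tk <- c(tk, pad)
            unresolved <<- TRUE
        }
        paste(tk[seq_len(depth)], collapse = ";")
    }, character(1))
    if (unresolved)
        warning("some lineages do not resolve to rank '", rank,
                "'; assigned to unclassified buckets")
    m <- rowsum(abundances(table), group = keys, reorder = TRUE)
    res <- AbundanceTable(m, normalized = table@normalized, taxRank = rank,
                          sampleData = as.data.frame(colData(table)))
    metadata(res) <- metadata(table)
    res
}

#' @rdname DiscriminationConfig
#' @param kwAlpha,ldaThreshold,nBootstrap,bootstrapFraction,scaling,ridge
#'   see the class slots.
#' @return A [DiscriminationConfig-class].
#' @export
discriminationConfig <- function(kwAlpha = 0.05, ldaThreshold = 2,
                                 nBootstrap = 30, bootstrapFraction = 2 / 3,
                                 scaling = 1e6, ridge = 1e-6) {
    new("DiscriminationConfig", kwAlpha = kwAlpha,
        ldaThreshold = ldaThreshold, nBootstrap = as.integer(nBootstrap),
        bootstrapFraction = bootstrapFraction, scaling = scaling,
        ridge = ridge)
}

#' @rdname SparccConfig
#' @param nResamples,nExclusionIterations,exclusionThreshold,nShuffles
#'   see the class slots.
#' @return A [SparccConfig-class].
#' @export
sparccConfig <- function(nResamples = 20, nExclusionIterations = 10,
                         exclusionThreshold = 0.1, nShuffles = 100) {
    new("SparccConfig", nResamples = as.integer(nResamples),
        nExclusionIterations = as.integer(nExclusionIterations),
        exclusionThreshold = exclusionThreshold,
        nShuffles = as.integer(nShuffles))
}

#' @rdname SyntheticConfig
#' @param nSamples,nTaxa,depth,baseLogmeanSd,planted,labelPrevalence,nFeatures,overdispersion,overlap
#'   see the class slots.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSamples = 44, nTaxa = 300, depth = 120000,
                            baseLogmeanSd = 2, planted = "default",
                            labelPrevalence = 0.5, nFeatures = 1,
                            overdispersion = 200, overlap = NA_real_) {
    plant_default <- identical(planted, "default")
    if (plant_default || is.null(planted))
        planted <- data.frame(taxon = integer(0), fold = numeric(0),
                              direction = numeric(0))
    new("SyntheticConfig", nSamples = as.integer(nSamples),
        nTaxa = as.integer(nTaxa), depth = depth,
        baseLogmeanSd = baseLogmeanSd, planted = planted,
        plantDefault = plant_default,
        labelPrevalence = labelPrevalence, nFeatures = as.integer(nFeatures),
        overdispersion = overdispersion, overlap = overlap)
}
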