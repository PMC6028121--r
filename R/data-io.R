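# Readers/writers for the four tabular input families and the TSV outputs.
# All outputs carry a provenance header comment (package version, seed,
# parameters).

.provenanceHeader <- function(params = list()) {
    extra <- if (length(params)) {
        paste(vapply(names(params), function(n)
            paste0(n, "=", paste(format(params[[n]]), collapse = ",")),
            character(1)), collapse = " ")
    } else ""
    sprintf("# micromut %s %s", as.character(packageVersion("micromut")),
            extra)
}

.writeTsv <- function(df, path, params = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(params), con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

#' Read a QIIME-classic OTU/taxon abundance table
#'
#' Parses the classic tab-separated OTU table dialect: optional leading
#' comment lines, a header row whose first cell may be `#OTU ID`, one id
#' column, numeric sample columns and an optional trailing `taxonomy`
#' (or `Consensus Lineage`) column. When a taxonomy column is present it
#' supplies the lineage-string taxon ids; otherwise the id column is taken
#' to already hold lineage strings (as in genus-collapsed tables). Rows
#' sharing a lineage string are summed. A parse report (rows merged/dropped)
#' is stored in `metadata(x)$parseReport`.
#'
#' @param path TSV file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"` for
#'   transposed input.
#' @return A counts-mode [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, orientation = c("taxa_rows",
                                                     "samples_rows")) {
    orientation <- match.arg(orientation)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    is_comment <- startsWith(lines, "#")
    ## the header may itself be a comment line ("#OTU ID\t..."): the last
    ## leading comment line containing a tab is the header
    first_data <- which(!is_comment)[1]
    if (is.na(first_data)) stop("no data rows in ", path)
    header_idx <- first_data - 1L
    if (header_idx >= 1L && grepl("\t", lines[header_idx])) {
        keep <- c(header_idx, first_data:length(lines))
    } else {
        keep <- first_data:length(lines)
    }
    df <- read.delim(text = paste(lines[keep], collapse = "\n"),
                     header = TRUE, check.names = FALSE,
                     comment.char = "", stringsAsFactors = FALSE,
                     colClasses = "character")
    names(df)[1] <- sub("^#\\s*", "", names(df)[1])

    tax_col <- which(tolower(names(df)) %in%
                     c("taxonomy", "consensus lineage", "consensuslineage"))
    drop_cols <- c(1L, if (length(tax_col)) tax_col[1])
    sample_names <- names(df)[-drop_cols]   # before [ uniquifies duplicates
    if (anyDuplicated(sample_names))
        stop("duplicate sample id(s): ",
             paste(unique(sample_names[duplicated(sample_names)]),
                   collapse = ", "))
    ids <- if (length(tax_col)) df[[tax_col[1]]] else df[[1]]
    df <- df[, -drop_cols, drop = FALSE]
    names(df) <- sample_names

    m <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
    for (j in seq_len(ncol(df))) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(df[[j]]))
        if (length(bad))
            stop(sprintf("non-numeric cell at row '%s', column '%s'",
                         ids[bad[1]], names(df)[j]))
        m[, j] <- v
    }
    if (anyNA(m)) stop("missing values in abundance table ", path)

    if (orientation == "samples_rows") {
        ## rows were samples: ids are sample ids, columns are taxa
        sn <- ids
        m <- t(m)
        colnames(m) <- sn
        ids <- rownames(m)
    }
    key <- .lineageKey(ids)
    n_in <- length(key)
    m <- rowsum(m, group = key, reorder = TRUE)
    report <- list(rowsIn = n_in, rowsOut = nrow(m),
                   rowsMerged = n_in - nrow(m), dropped = 0L,
                   reasons = character(0))
    tab <- AbundanceTable(m, normalized = FALSE, taxRank = "otu")
    metadata(tab)$parseReport <- report
    tab
}

#' Write an abundance table as QIIME-classic TSV
#'
#' @param table an [AbundanceTable-class].
#' @param path output path.
#' @param params named list recorded in the provenance header comment.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(table, path, params = list()) {
    stopifnot(is(table, "AbundanceTable"))
    m <- abundances(table)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(params), con)
    writeLines(paste(c("#OTU ID", colnames(m)), collapse = "\t"), con)
    df <- cbind(rownames(m), as.data.frame(m))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read per-mutation annotation records
#'
#' Reads a tab-separated mutation table (one row per tumor-specific mutation)
#' and classifies each effect annotation with [classifyEffect()]. The column
#' names are configurable because deposited mutation tables vary in schema.
#' Rows missing the gene symbol are skipped and counted in the parse report
#' (attribute `"parseReport"`).
#'
#' @param path TSV file path.
#' @param columns named list mapping the roles `sample`, `gene`, `ensembl`,
#'   `effect` to column names in the file.
#' @param aliases effect alias table, see [classifyEffect()].
#' @return A data.frame with columns `sample_id`, `gene_symbol`,
#'   `ensembl_gene_id`, `raw_effect`, `effect_class`.
#' @export
readMutations <- function(path,
                          columns = list(sample = "sample", gene = "gene",
                                         ensembl = "ensembl",
                                         effect = "effect"),
                          aliases = effectAliases()) {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#")
    need <- unlist(columns[c("sample", "gene", "effect")])
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing column(s) in ", path, ": ",
             paste(miss, collapse = ", "))
    ens <- if (!is.null(columns$ensembl) && columns$ensembl %in% names(df))
        as.character(df[[columns$ensembl]]) else NA_character_
    rec <- data.frame(sample_id = as.character(df[[columns$sample]]),
                      gene_symbol = as.character(df[[columns$gene]]),
                      ensembl_gene_id = ens,
                      raw_effect = as.character(df[[columns$effect]]),
                      stringsAsFactors = FALSE)
    bad <- is.na(rec$gene_symbol) | !nzchar(rec$gene_symbol) |
        is.na(rec$sample_id) | !nzchar(rec$sample_id)
    rec <- rec[!bad, , drop = FALSE]
    rec$effect_class <- classifyEffect(rec$raw_effect, aliases = aliases)
    attr(rec, "parseReport") <- list(
        rowsIn = nrow(df), rowsKept = nrow(rec), rowsSkipped = sum(bad),
        unknownEffects = sum(rec$effect_class == "other"))
    rec
}

#' Read sample metadata
#'
#' @param path TSV with columns (configurable via `columns`) for sample id,
#'   patient id, tissue (`tumor`/`normal`), stage (1-4 or missing), age and
#'   sex. Missing fields become explicit `NA`s; samples are never dropped.
#' @param columns named list mapping roles to column names.
#' @return data.frame with columns `sample_id`, `patient_id`, `tissue`,
#'   `stage`, `age`, `sex`.
#' @export
readSampleMetadata <- function(path,
                               columns = list(sample = "sample",
                                              patient = "patient",
                                              tissue = "tissue",
                                              stage = "stage",
                                              age = "age", sex = "sex")) {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#")
    get <- function(role, coerce = as.character) {
        cn <- columns[[role]]
        if (!is.null(cn) && cn %in% names(df)) coerce(df[[cn]])
        else rep(NA, nrow(df))
    }
    md <- data.frame(sample_id = get("sample"),
                     patient_id = get("patient"),
                     tissue = get("tissue"),
                     stage = suppressWarnings(get("stage", as.integer)),
                     age = suppressWarnings(get("age", as.numeric)),
                     sex = get("sex"), stringsAsFactors = FALSE)
    if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
    bad_stage <- !is.na(md$stage) & !(md$stage %in% 1:4)
    if (any(bad_stage)) stop("stage values outside 1-4")
    tt <- table(md$patient_id[!is.na(md$tissue)],
                md$tissue[!is.na(md$tissue)])
    if (any(tt > 1))
        stop("a patient has more than one tumor or normal sample")
    md
}

#' Read a gene-to-pathway mapping in Uniprot idmapping dialect
#'
#' A three-column file (gene identifier, database tag, pathway name). Only
#' rows whose tag matches `database` are kept and the result is inverted to
#' pathway -> gene set. A gene may belong to multiple pathways.
#'
#' @param path TSV file path (no header).
#' @param database `"KEGG"` or `"PID"` (matched against column 2,
#'   case-insensitively).
#' @return Named list of character vectors (pathway -> gene ids).
#' @export
readPathwayMap <- function(path, database = c("KEGG", "PID")) {
    database <- match.arg(database)
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                     comment.char = "#",
                     col.names = c("gene", "db", "pathway"))
    df <- df[toupper(df$db) == database, , drop = FALSE]
    if (!nrow(df))
        stop("no rows with database tag '", database, "' in ", path)
    split(df$gene, df$pathway) |> lapply(unique)
}
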