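# SparCC compositional correlation inference: Dirichlet-resampled fractions,
# log-ratio variances, basis-variance estimation with iterative exclusion of
# strongly correlated pairs, shuffle-based pseudo p-values, and
# mutation-conditioned network construction.

.sparccCountMatrix <- function(counts) {
    m <- if (is(counts, "AbundanceTable")) {
        if (isNormalized(counts))
            stop("SparCC needs a counts-mode table")
        abundances(counts)
    } else {
        as.matrix(counts)
    }
    if (nrow(m) < 4L)
        stop("SparCC needs >= 4 taxa (the basis-variance system is ",
             "underdetermined below that)")
    if (ncol(m) < 4L) stop("SparCC needs >= 4 samples")
    m
}

# One Dirichlet resample of component fractions: per sample, fractions drawn
# from Dirichlet(counts + 1).
.dirichletFractions <- function(counts) {
    g <- matrix(rgamma(length(counts), shape = counts + 1, rate = 1),
                nrow(counts), ncol(counts))
    sweep(g, 2, colSums(g), "/")
}

# Solve the basis-variance system for one log-ratio variance matrix,
# iteratively excluding the most correlated pair (|r| > threshold).
.sparccBasis <- function(Tmat, exclusionThreshold, nIter) {
    D <- nrow(Tmat)
    M <- matrix(1, D, D)
    diag(M) <- D - 1
    excluded <- matrix(FALSE, D, D)
    n_excl_row <- integer(D)
    clipped <- FALSE
    r <- NULL
    for (it in seq_len(nIter + 1L)) {
        tsum <- rowSums(Tmat * !excluded)
        omega2 <- solve(M, tsum)
        if (any(omega2 <= 0)) {
            clipped <- TRUE
            ## clip to the scale of the remaining basis variances so the
            ## derived correlations stay bounded away from the +-1 rim
            floor_v <- if (any(omega2 > 0)) min(omega2[omega2 > 0])
                       else mean(Tmat[upper.tri(Tmat)]) / 2 + 1e-10
            omega2[omega2 <= 0] <- floor_v
        }
        omega <- sqrt(omega2)
        r <- (outer(omega2, omega2, "+") - Tmat) / (2 * outer(omega, omega))
        r <- pmin(pmax(r, -1), 1)
        diag(r) <- 1
        if (it > nIter) break
        cand <- abs(r)
        cand[excluded | row(cand) == col(cand)] <- 0
        mx <- which.max(cand)
        if (cand[mx] <= exclusionThreshold) break
        i <- row(cand)[mx]; j <- col(cand)[mx]
        # keep every taxon coupled to at least two partners
        if (n_excl_row[i] >= D - 3L || n_excl_row[j] >= D - 3L) break
        excluded[i, j] <- excluded[j, i] <- TRUE
        n_excl_row[i] <- n_excl_row[i] + 1L
        n_excl_row[j] <- n_excl_row[j] + 1L
        M[i, j] <- M[j, i] <- 0
        M[i, i] <- M[i, i] - 1
        M[j, j] <- M[j, j] - 1
    }
    attr(r, "clipped") <- clipped
    r
}

#' SparCC correlations of a compositional count table
#'
#' For each of `nResamples` Dirichlet resamples of the component fractions
#' (counts + 1 prior), computes all pairwise log-ratio variances
#' `t_ij = var(log(x_i / x_j))`, solves the linear system for the basis
#' variances, derives correlations
#' `r_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)` (clipped to \[-1, 1\]) and
#' iteratively excludes the most correlated pair above
#' `exclusionThreshold`, re-solving up to `nExclusionIterations` times. The
#' returned matrix is the element-wise median over resamples.
#'
#' @param counts a counts-mode [AbundanceTable-class] or numeric matrix
#'   (taxa x samples); >= 4 taxa and >= 4 samples.
#' @param config a [SparccConfig-class].
#' @param seed optional integer seed for the Dirichlet resampling.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparccCorrelations <- function(counts, config = sparccConfig(),
                               seed = NULL) {
    m <- .sparccCountMatrix(counts)
    if (!is.null(seed)) set.seed(seed)
    any_clipped <- FALSE
    rs <- vapply(seq_len(config@nResamples), function(b) {
        fr <- .dirichletFractions(m)
        L <- log(fr)
        C <- stats::cov(t(L))
        v <- diag(C)
        Tmat <- outer(v, v, "+") - 2 * C
        diag(Tmat) <- 0
        r1 <- .sparccBasis(Tmat, config@exclusionThreshold,
                           config@nExclusionIterations)
        if (isTRUE(attr(r1, "clipped"))) any_clipped <<- TRUE
        r1
    }, matrix(0, nrow(m), nrow(m)))
    if (any_clipped)
        warning("negative basis variance(s) clipped to a small positive",
                call. = FALSE)
    r <- apply(rs, c(1, 2), median)
    dimnames(r) <- list(rownames(m), rownames(m))
    diag(r) <- 1
    r
}

#' Shuffle-based pseudo p-values for SparCC correlations
#'
#' Generates `nShuffles` null datasets by independently permuting each
#' taxon's counts across samples (destroying correlation, preserving
#' marginals), recomputes the SparCC correlation matrix for each, and
#' reports the two-sided pseudo p-value
#' `(1 + #{|r_shuffled| >= |r_observed|}) / (nShuffles + 1)` per pair.
#'
#' @inheritParams sparccCorrelations
#' @param observedR correlation matrix from [sparccCorrelations()] on the
#'   same counts.
#' @return Symmetric matrix of pseudo p-values (diagonal `NA`).
#' @export
pseudoPvalues <- function(counts, observedR, config = sparccConfig(),
                          seed = NULL) {
    m <- .sparccCountMatrix(counts)
    if (!is.null(seed)) set.seed(seed)
    exceed <- matrix(0, nrow(m), nrow(m))
    for (s in seq_len(config@nShuffles)) {
        shuf <- t(apply(m, 1, sample))
        ## clipping inside shuffled (null) datasets is routine; stay quiet
        r_s <- suppressWarnings(sparccCorrelations(shuf, config))
        exceed <- exceed + (abs(r_s) >= abs(observedR))
    }
    p <- (1 + exceed) / (config@nShuffles + 1)
    dimnames(p) <- dimnames(observedR)
    diag(p) <- NA_real_
    p
}

#' Build a filtered correlation network
#'
#' Keeps edges with `|r| >= rMin` and `p <= pMax`; node sizes carry the mean
#' relative abundance of each taxon in the stratum.
#'
#' @param r,p aligned correlation and pseudo p-value matrices.
#' @param abundance normalized [AbundanceTable-class] (or matrix of
#'   proportions) for the stratum's samples, used for node mean abundances.
#' @param rMin,pMax display filters (defaults 0.25 and 0.05).
#' @param stratum `"mutated"`, `"wildtype"` or `"pooled"`.
#' @param feature mutation feature the stratum is conditioned on.
#' @return A [CorrelationNetwork-class].
#' @export
buildNetwork <- function(r, p, abundance, rMin = 0.25, pMax = 0.05,
                         stratum = "pooled", feature = NA_character_) {
    am <- if (is(abundance, "AbundanceTable"))
        abundances(if (isNormalized(abundance)) abundance
                   else relativeAbundance(abundance))
    else as.matrix(abundance)
    taxa <- rownames(r)
    stopifnot(identical(taxa, rownames(am)))
    nodes <- S4Vectors::DataFrame(taxon = taxa,
                                  meanAbundance = rowMeans(am))
    ut <- which(upper.tri(r), arr.ind = TRUE)
    keep <- abs(r[ut]) >= rMin & !is.na(p[ut]) & p[ut] <= pMax
    ut <- ut[keep, , drop = FALSE]
    edges <- S4Vectors::DataFrame(
        taxon1 = taxa[ut[, 1]], taxon2 = taxa[ut[, 2]],
        r = r[ut], p = p[ut],
        sign = ifelse(r[ut] >= 0, "direct", "inverse"))
    new("CorrelationNetwork", nodes = nodes, edges = edges,
        stratum = stratum, feature = feature, rMin = rMin, pMax = pMax)
}

#' @rdname CorrelationNetwork
#' @export
setMethod("networkEdges", "CorrelationNetwork", function(x) x@edges)

#' @rdname CorrelationNetwork
#' @export
setMethod("networkNodes", "CorrelationNetwork", function(x) x@nodes)

setMethod("show", "CorrelationNetwork", function(object) {
    cat(sprintf(
        "CorrelationNetwork [%s%s]: %d nodes, %d edges (|r| >= %.2f, p <= %.2f)\n",
        object@stratum,
        if (is.na(object@feature)) "" else paste0(", ", object@feature),
        nrow(object@nodes), nrow(object@edges), object@rMin, object@pMax))
})

#' Mutation-conditioned differential taxon networks
#'
#' Runs independent SparCC analyses (correlations + stratum-specific shuffle
#' nulls) on the mutated and wildtype sample strata over a reduced taxon set
#' (normally the discriminant taxa of the feature) and reports both filtered
#' networks plus the symmetric difference of their edge sets.
#'
#' @param counts counts-mode [AbundanceTable-class].
#' @param featureLabels binary vector (1 = mutated), named by sample id or
#'   aligned with the table's samples; both strata need >= 4 samples.
#' @param taxa taxa defining the reduced table (matched by lineage string).
#' @param config a [SparccConfig-class].
#' @param rMin,pMax edge display filters.
#' @param feature feature name recorded on the networks.
#' @param seed optional integer seed.
#' @return List with elements `mutated`, `wildtype`
#'   ([CorrelationNetwork-class]) and `difference` (data.frame of edges
#'   present in exactly one stratum).
#' @export
differentialNetworks <- function(counts, featureLabels, taxa,
                                 config = sparccConfig(), rMin = 0.25,
                                 pMax = 0.05, feature = NA_character_,
                                 seed = NULL) {
    m <- .sparccCountMatrix(counts)
    if (!is.null(names(featureLabels)))
        featureLabels <- featureLabels[colnames(m)]
    stopifnot(length(featureLabels) == ncol(m))
    idx <- match(.lineageKey(taxa), .lineageKey(rownames(m)))
    if (anyNA(idx))
        stop("taxa not in table: ", paste(taxa[is.na(idx)], collapse = ", "))
    if (!is.null(seed)) set.seed(seed)
    run <- function(cols, stratum) {
        if (length(cols) < 4L)
            stop("stratum '", stratum, "' has fewer than 4 samples")
        sub <- m[idx, cols, drop = FALSE]
        r <- sparccCorrelations(sub, config)
        p <- pseudoPvalues(sub, r, config)
        buildNetwork(r, p, sweep(sub, 2, colSums(sub), "/"),
                     rMin = rMin, pMax = pMax, stratum = stratum,
                     feature = feature)
    }
    mut <- run(which(featureLabels == 1), "mutated")
    wt <- run(which(featureLabels == 0), "wildtype")
    key <- function(net) {
        ed <- networkEdges(net)
        paste(pmin(ed$taxon1, ed$taxon2), pmax(ed$taxon1, ed$taxon2),
              sep = " | ")
    }
    km <- key(mut); kw <- key(wt)
    diff_edges <- data.frame(
        edge = c(setdiff(km, kw), setdiff(kw, km)),
        onlyIn = c(rep("mutated", length(setdiff(km, kw))),
                   rep("wildtype", length(setdiff(kw, km)))),
        stringsAsFactors = FALSE)
    list(mutated = mut, wildtype = wt, difference = diff_edges)
}

#' Write a network as an edge-list TSV
#'
#' @param networks a [CorrelationNetwork-class] or list of them.
#' @param path output TSV path.
#' @param params named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(networks, path, params = list()) {
    if (is(networks, "CorrelationNetwork")) networks <- list(networks)
    rows <- lapply(networks, function(net) {
        ed <- as.data.frame(networkEdges(net))
        if (!nrow(ed)) return(NULL)
        ed$stratum <- net@stratum
        ed$feature <- net@feature
        ed
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(taxon1 = character(0), taxon2 = character(0),
                         r = numeric(0), p = numeric(0),
                         sign = character(0), stratum = character(0),
                         feature = character(0))
    .writeTsv(df, path, params)
}

#' Write a network as GraphML
#'
#' @param network a [CorrelationNetwork-class].
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(network, path) {
    stopifnot(is(network, "CorrelationNetwork"))
    nodes <- as.data.frame(networkNodes(network))
    edges <- as.data.frame(networkEdges(network))
    g <- igraph::graph_from_data_frame(
        edges[, c("taxon1", "taxon2", "r", "p", "sign")],
        directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
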