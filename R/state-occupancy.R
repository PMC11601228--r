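#' OccupancyTable: per-perturbation transcriptomic cluster fractions
#'
#' Summarises a CROP-seq style experiment: for each perturbation (gene
#' knockdown or NTC), the fraction of its cells falling in each
#' transcriptomic cluster. Rows are perturbations, columns clusters; each
#' row sums to 1.
#'
#' @slot fractions numeric matrix, perturbation x cluster, row-stochastic.
#' @slot n_cells named integer, cells per reported perturbation.
#' @seealso [occupancy()], [deltaOccupancy()]
#' @export
setClass("OccupancyTable", representation(fractions = "matrix",
                                          n_cells = "integer"))

setValidity("OccupancyTable", function(object) {
    v <- character(0)
    f <- object@fractions
    if (any(f < 0)) v <- c(v, "fractions must be non-negative")
    if (nrow(f) > 0 && any(abs(rowSums(f) - 1) > 1e-9))
        v <- c(v, "each perturbation's fractions must sum to 1")
    if (!identical(sort(names(object@n_cells)), sort(rownames(f))))
        v <- c(v, "n_cells names must match fraction rows")
    if (length(v) == 0) TRUE else v
})

#' @rdname occupancy-accessors
#' @name occupancy-accessors
#' @title Accessors for OccupancyTable
#' @param x an [OccupancyTable-class].
#' @return `occupancyFractions`: the perturbation x cluster matrix;
#'   `cellCounts`: named integer of cells per perturbation.
#' @export
occupancyFractions <- function(x) x@fractions

#' @rdname occupancy-accessors
#' @export
cellCounts <- function(x) x@n_cells

setMethod("show", "OccupancyTable", function(object) {
    cat(sprintf("OccupancyTable: %d perturbation(s) x %d cluster(s)\n",
                nrow(object@fractions), ncol(object@fractions)))
    cat(sprintf("  cells/perturbation: %d-%d\n",
                min(object@n_cells), max(object@n_cells)))
})

#' Cluster occupancy per perturbation
#'
#' Tallies per-cell assignments into per-perturbation cluster fractions.
#' Perturbations represented by fewer than `min_cells` cells are excluded
#' with a warning (their estimates would be dominated by sampling noise), in
#' the spirit of restricting occupancy analysis to well-represented
#' knockdowns.
#'
#' @param assignments data.frame with columns `cell_id`, `perturbation`,
#'   `cluster`.
#' @param min_cells minimum cells for a perturbation to be reported
#'   (default 10).
#' @param strict drop duplicated `cell_id`s (keeping the first) before
#'   tallying; cells with ambiguous sgRNA assignment are expected to be
#'   filtered upstream.
#' @return An [OccupancyTable-class].
#' @export
occupancy <- function(assignments, min_cells = 10L, strict = TRUE) {
    need <- c("cell_id", "perturbation", "cluster")
    miss <- setdiff(need, names(assignments))
    if (length(miss) > 0)
        stop(sprintf("assignments lack column(s): %s",
                     paste(miss, collapse = ", ")))
    if (nrow(assignments) == 0) stop("no cells in assignment table")
    if (strict) assignments <- assignments[!duplicated(assignments$cell_id), ]
    tab <- table(assignments$perturbation, assignments$cluster)
    n <- rowSums(tab)
    drop <- names(n)[n < min_cells]
    if (length(drop) > 0) {
        warning(sprintf("excluding perturbation(s) below %d cells: %s",
                        min_cells, paste(drop, collapse = ", ")))
        tab <- tab[!(rownames(tab) %in% drop), , drop = FALSE]
        n <- n[!(names(n) %in% drop)]
    }
    if (nrow(tab) == 0) stop("no perturbation passes the min-cell filter")
    frac <- sweep(unclass(tab), 1, n, "/")
    new("OccupancyTable", fractions = frac,
        n_cells = stats::setNames(as.integer(n), names(n)))
}

#' Occupancy change relative to a reference perturbation
#'
#' `delta(p, c) = fraction(p, c) - fraction(ref, c)`. The reference row is
#' identically zero and every row sums to zero to machine tolerance.
#'
#' @param table an [OccupancyTable-class].
#' @param reference reference perturbation label (default `"NTC"`).
#' @return Numeric matrix of occupancy deltas, same shape as the fractions.
#' @export
deltaOccupancy <- function(table, reference = "NTC") {
    f <- occupancyFractions(table)
    if (!(reference %in% rownames(f)))
        stop(sprintf("reference perturbation '%s' absent from table",
                     reference))
    sweep(f, 2, f[reference, ], "-")
}

#' Correlation between two states' occupancy changes
#'
#' Pearson correlation of the two clusters' occupancy deltas across
#' non-reference perturbations; quantifies trade-offs such as the
#' anti-correlated interferon and chemokine state shifts.
#'
#' @param deltas matrix from [deltaOccupancy()].
#' @param state_a,state_b cluster (column) names.
#' @param reference reference row to exclude (default `"NTC"`).
#' @return Pearson r, or `NA_real_` when either state has zero variance.
#' @export
stateCorrelation <- function(deltas, state_a, state_b, reference = "NTC") {
    stopifnot(state_a %in% colnames(deltas), state_b %in% colnames(deltas))
    d <- deltas[setdiff(rownames(deltas), reference), , drop = FALSE]
    if (nrow(d) < 3) stop("need at least 3 non-reference perturbations")
    a <- d[, state_a]
    b <- d[, state_b]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
}

#' Simulate per-cell perturbation/cluster assignments
#'
#' Draws each perturbation's cells from a multinomial over clusters, using
#' the baseline fractions plus that perturbation's (additive) shifts,
#' renormalised. The reference perturbation `"NTC"` always uses the
#' baseline.
#'
#' @param baseline named numeric cluster fractions summing to 1.
#' @param shifts named list: perturbation -> named numeric additive shifts
#'   (clusters absent from a shift vector are unshifted). Shifted
#'   probabilities must remain non-negative.
#' @param cells_per_perturbation cells drawn per perturbation (recycled).
#' @param seed integer seed.
#' @return data.frame (`cell_id`, `perturbation`, `cluster`) including the
#'   NTC reference cells.
#' @export
simulateStates <- function(baseline, shifts, cells_per_perturbation = 200L,
                           seed = 1L) {
    stopifnot(abs(sum(baseline) - 1) < 1e-9, !is.null(names(baseline)))
    perts <- c("NTC", names(shifts))
    ncells <- rep_len(cells_per_perturbation, length(perts))
    set.seed(seed)
    out <- vector("list", length(perts))
    for (i in seq_along(perts)) {
        p <- baseline
        if (perts[i] != "NTC") {
            sh <- shifts[[perts[i]]]
            p[names(sh)] <- p[names(sh)] + sh
            if (any(p < -1e-12))
                stop(sprintf("shift for '%s' drives a cluster below zero",
                             perts[i]))
            p <- pmax(p, 0)
            p <- p / sum(p)
        }
        cl <- sample(names(baseline), ncells[i], replace = TRUE, prob = p)
        out[[i]] <- data.frame(
            cell_id = sprintf("%s_cell%05d", perts[i], seq_len(ncells[i])),
            perturbation = perts[i], cluster = cl)
    }
    do.call(rbind, out)
}

#' Bootstrap confidence intervals for occupancy deltas
#'
#' Resamples cells within each perturbation (and the reference) to give
#' percentile confidence intervals for each occupancy delta. Provided as a
#' descriptive uncertainty summary; no significance flagging is applied.
#'
#' @param assignments per-cell table as in [occupancy()].
#' @param reference reference perturbation (default `"NTC"`).
#' @param n_boot bootstrap resamples (default 500).
#' @param conf confidence level (default 0.95).
#' @param min_cells passed through to [occupancy()].
#' @param seed integer seed.
#' @return data.frame: `perturbation`, `cluster`, `delta`, `lower`, `upper`.
#' @export
deltaBootstrapCI <- function(assignments, reference = "NTC", n_boot = 500L,
                             conf = 0.95, min_cells = 10L, seed = 1L) {
    obs_tab <- occupancy(assignments, min_cells = min_cells)
    obs <- deltaOccupancy(obs_tab, reference)
    set.seed(seed)
    groups <- split(seq_len(nrow(assignments)), assignments$perturbation)
    draws <- array(NA_real_, c(dim(obs), n_boot),
                   dimnames = c(dimnames(obs), NULL))
    for (b in seq_len(n_boot)) {
        idx <- unlist(lapply(groups, function(g)
            g[sample.int(length(g), length(g), replace = TRUE)]),
            use.names = FALSE)
        bt <- suppressWarnings(occupancy(assignments[idx, ],
                                         min_cells = min_cells,
                                         strict = FALSE))
        bd <- deltaOccupancy(bt, reference)
        draws[rownames(bd), colnames(bd), b] <- bd
    }
    alpha <- (1 - conf) / 2
    out <- expand.grid(perturbation = rownames(obs), cluster = colnames(obs),
                       stringsAsFactors = FALSE)
    out$delta <- obs[cbind(out$perturbation, out$cluster)]
    qs <- apply(draws, c(1, 2), stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE)
    out$lower <- qs[1, , ][cbind(out$perturbation, out$cluster)]
    out$upper <- qs[2, , ][cbind(out$perturbation, out$cluster)]
    out
}
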