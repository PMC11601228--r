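#' Simulate a flow-cytometry event table
#'
#' Generates per-event channel intensities for a marker-gated uptake assay:
#' the marker channel (e.g. nuclear BFP identifying microglia) is a
#' two-component log10-normal mixture of marker-negative and marker-positive
#' events, and the uptake channel (e.g. Gamillus-FITC) is log10-normal with a
#' condition-specific mean for marker-positive events and a common
#' background for the rest.
#'
#' @param conditions data.frame with one row per well:
#'   `well_id`, `condition`, `n_events`, `pos_fraction` (marker-positive
#'   fraction), `marker_log_mean_pos`, `marker_log_mean_neg`,
#'   `marker_log_sd`, `green_log_mean` (uptake of the positive population),
#'   `green_log_sd`, `green_log_mean_bg` (background of negatives).
#' @param seed integer seed; one sub-seed per well.
#' @return data.frame: `well_id`, `condition`, `marker`, `green` (linear
#'   intensities), one row per event.
#' @export
simulateFlow <- function(conditions, seed = 1L) {
    need <- c("well_id", "condition", "n_events", "pos_fraction",
              "marker_log_mean_pos", "marker_log_mean_neg", "marker_log_sd",
              "green_log_mean", "green_log_sd", "green_log_mean_bg")
    miss <- setdiff(need, names(conditions))
    if (length(miss) > 0)
        stop(sprintf("conditions lack column(s): %s",
                     paste(miss, collapse = ", ")))
    out <- vector("list", nrow(conditions))
    for (i in seq_len(nrow(conditions))) {
        cfg <- conditions[i, ]
        set.seed(.subSeed(seed, i))
        n <- cfg$n_events
        pos <- stats::runif(n) < cfg$pos_fraction
        marker <- 10^stats::rnorm(
            n, ifelse(pos, cfg$marker_log_mean_pos, cfg$marker_log_mean_neg),
            cfg$marker_log_sd)
        green <- 10^stats::rnorm(
            n, ifelse(pos, cfg$green_log_mean, cfg$green_log_mean_bg),
            cfg$green_log_sd)
        out[[i]] <- data.frame(well_id = cfg$well_id,
                               condition = cfg$condition,
                               marker = marker, green = green)
    }
    do.call(rbind, out)
}

#' Gate marker-positive events
#'
#' Gates on `log10(intensity + 1)`. The threshold is either a fixed value on
#' that log scale, or (default) the boundary of a two-component Gaussian
#' mixture fitted to the log intensities — the valley between the
#' marker-negative and marker-positive populations. Wells yielding fewer
#' than `min_events` gated events are flagged (attribute `flagged`), not
#' dropped.
#'
#' @param events data.frame of per-event intensities.
#' @param channel channel column to gate on (default `"marker"`).
#' @param threshold fixed log10 threshold, or `NULL` for the mixture valley.
#' @param min_events minimum gated events before flagging (default 100).
#' @return The gated subset with attributes `threshold` (log10 scale) and
#'   `flagged` (logical).
#' @importFrom mclust Mclust mclustBIC
#' @export
gatePositive <- function(events, channel = "marker", threshold = NULL,
                         min_events = 100L) {
    stopifnot(channel %in% names(events))
    lx <- log10(events[[channel]] + 1)
    if (is.null(threshold)) {
        fit <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
        mu <- fit$parameters$mean
        lo <- which.min(mu)
        hi <- which.max(mu)
        cl <- fit$classification
        # boundary between the classified populations
        threshold <- (max(lx[cl == lo]) + min(lx[cl == hi])) / 2
    }
    gated <- events[lx > threshold, , drop = FALSE]
    attr(gated, "threshold") <- threshold
    attr(gated, "flagged") <- nrow(gated) < min_events
    gated
}

#' Median uptake intensity of gated events
#'
#' Sample median (midpoint rule for even n) of the uptake channel over the
#' gated events; the standard summary of per-cell uptake in a
#' marker-gated flow assay.
#'
#' @param gated gated event data.frame.
#' @param channel uptake channel (default `"green"`).
#' @return Median intensity.
#' @export
medianUptake <- function(gated, channel = "green") {
    stopifnot(channel %in% names(gated))
    if (nrow(gated) == 0) stop("no gated events")
    stats::median(gated[[channel]])
}

#' Per-well uptake summary for a flow experiment
#'
#' Gates each well on the marker channel and reports the median uptake
#' intensity per well and condition, plus uptake normalised to the same
#' well's reference condition when present.
#'
#' @param events event table from [simulateFlow()] or a CSV export
#'   (columns `well_id`, `condition`, marker and uptake channels).
#' @param marker_channel,green_channel channel columns.
#' @param reference condition used as the in-well reference (default
#'   `"NTC"`).
#' @param threshold,min_events passed to [gatePositive()].
#' @return data.frame: `well_id`, `condition`, `n_gated`, `median_green`,
#'   `normalized_uptake` (NA when the well has no reference), `flagged`.
#' @export
summarizeUptake <- function(events, marker_channel = "marker",
                            green_channel = "green", reference = "NTC",
                            threshold = NULL, min_events = 100L) {
    keys <- unique(events[, c("well_id", "condition")])
    out <- keys
    out$n_gated <- NA_integer_
    out$median_green <- NA_real_
    out$flagged <- NA
    for (i in seq_len(nrow(keys))) {
        sub <- events[events$well_id == keys$well_id[i] &
                      events$condition == keys$condition[i], ]
        g <- gatePositive(sub, marker_channel, threshold, min_events)
        out$n_gated[i] <- nrow(g)
        out$median_green[i] <- if (nrow(g) > 0)
            medianUptake(g, green_channel) else NA_real_
        out$flagged[i] <- attr(g, "flagged")
    }
    ref <- out[out$condition == reference, c("well_id", "median_green")]
    names(ref)[2] <- "ref_median"
    out <- merge(out, ref, by = "well_id", all.x = TRUE, sort = FALSE)
    out$normalized_uptake <- out$median_green / out$ref_median
    out$ref_median <- NULL
    out
}

#' In-well paired comparison of knockdown vs control uptake
#'
#' Pairs each well's knockdown median with the same well's control median
#' and runs a two-sided paired t-test on the differences, alongside the mean
#' per-well normalised uptake ratio. With zero-variance differences the test
#' degenerates: identical pairs give `t = 0, p = 1`; a constant nonzero
#' difference gives `p = 0` (sentinel) with infinite t.
#'
#' @param kd numeric, per-well knockdown medians.
#' @param ntc numeric, per-well control medians (same wells, same order).
#' @return list: `mean_normalized_uptake`, `ratios`, `t`, `df`, `p_value`,
#'   `mean_difference`.
#' @importFrom stats t.test
#' @export
inwellPairedCompare <- function(kd, ntc) {
    if (length(kd) != length(ntc))
        stop("kd and ntc must pair well-for-well")
    n <- length(kd)
    if (n < 2) stop("paired comparison needs at least 2 wells")
    d <- kd - ntc
    if (stats::sd(d) == 0) {
        t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        p <- if (mean(d) == 0) 1 else 0
    } else {
        ht <- stats::t.test(kd, ntc, paired = TRUE)
        t_stat <- unname(ht$statistic)
        p <- ht$p.value
    }
    list(mean_normalized_uptake = mean(kd / ntc), ratios = kd / ntc,
         t = t_stat, df = n - 1L, p_value = p, mean_difference = mean(d))
}

#' Knockdown fold change by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,KD - Ct_housekeeping,KD) - (Ct_target,ref -
#' Ct_housekeeping,ref)`; fold change `= 2^(-ddCt)`. Values are vectorised,
#' so replicate Ct sets give per-replicate fold changes.
#'
#' @param ct_target_kd,ct_housekeeping_kd Ct values in the knockdown
#'   condition.
#' @param ct_target_ref,ct_housekeeping_ref Ct values in the reference
#'   condition.
#' @return Expression fold change(s) of the target in KD relative to
#'   reference.
#' @export
ddctFoldChange <- function(ct_target_kd, ct_housekeeping_kd,
                           ct_target_ref, ct_housekeeping_ref) {
    stopifnot(all(is.finite(c(ct_target_kd, ct_housekeeping_kd,
                              ct_target_ref, ct_housekeeping_ref))))
    ddct <- (ct_target_kd - ct_housekeeping_kd) -
        (ct_target_ref - ct_housekeeping_ref)
    2^(-ddct)
}
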