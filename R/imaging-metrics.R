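#' Synthetic moving-cell time lapse
#'
#' Renders a disk of fixed radius along a supplied trajectory of centre
#' positions, one frame per trajectory row, returning both a noisy intensity
#' stack and the exact ground-truth binary masks. A stand-in for
#' membrane-labelled microglia movies when developing or testing
#' segmentation and surveillance code.
#'
#' @param dim frame size `c(height, width)` in pixels.
#' @param radius disk radius in pixels.
#' @param centers T x 2 matrix of (row, col) centre coordinates; see
#'   [linearTrajectory()] and [brownianTrajectory()].
#' @param noise_sd SD of additive Gaussian intensity noise (default 0; the
#'   clean disk has intensity 1 on background 0).
#' @param seed integer seed for the noise.
#' @return list with `intensity` (H x W x T numeric array) and `masks`
#'   (H x W x T logical array).
#' @export
generateTimelapse <- function(dim, radius, centers, noise_sd = 0, seed = 1L) {
    centers <- as.matrix(centers)
    stopifnot(ncol(centers) == 2, radius > 0)
    if (any(centers[, 1] - radius < 0.5) || any(centers[, 2] - radius < 0.5) ||
        any(centers[, 1] + radius > dim[1] + 0.5) ||
        any(centers[, 2] + radius > dim[2] + 0.5))
        stop("trajectory leaves the frame: disk does not fit at every step")
    T <- nrow(centers)
    rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
    cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    masks <- array(FALSE, c(dim[1], dim[2], T))
    for (t in seq_len(T)) {
        masks[, , t] <- (rows - centers[t, 1])^2 +
            (cols - centers[t, 2])^2 <= radius^2
    }
    set.seed(seed)
    intensity <- masks * 1
    if (noise_sd > 0)
        intensity <- intensity + stats::rnorm(length(intensity), 0, noise_sd)
    list(intensity = intensity, masks = masks)
}

#' @rdname trajectories
#' @name trajectories
#' @title Trajectory builders for the synthetic time lapse
#' @description `linearTrajectory` moves the centre by a fixed step per
#'   frame; `brownianTrajectory` takes Gaussian steps, seeded.
#' @param start centre `c(row, col)` at frame 1.
#' @param step per-frame displacement `c(drow, dcol)` (linear) or step SD in
#'   pixels (Brownian).
#' @param n_frames number of frames.
#' @param seed integer seed (Brownian only).
#' @return n_frames x 2 matrix of centres.
#' @export
linearTrajectory <- function(start, step, n_frames) {
    cbind(start[1] + (seq_len(n_frames) - 1) * step[1],
          start[2] + (seq_len(n_frames) - 1) * step[2])
}

#' @rdname trajectories
#' @export
brownianTrajectory <- function(start, step, n_frames, seed = 1L) {
    set.seed(seed)
    dr <- rbind(c(0, 0), matrix(stats::rnorm(2 * (n_frames - 1), 0, step),
                                ncol = 2))
    cbind(start[1] + cumsum(dr[, 1]), start[2] + cumsum(dr[, 2]))
}

.otsuThreshold <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(r[1])
    EBImage::otsu(EBImage::Image(matrix(as.numeric(x), nrow = 1)),
                  range = r, levels = 256)
}

#' Segment an intensity stack into binary masks
#'
#' Per frame: global thresholding (Otsu over the frame, or a fixed value),
#' connected-component labelling, removal of components below `min_size`
#' pixels, and optionally retention of only the largest component
#' (single-cell mode). A frame with no foreground yields an empty mask with
#' a warning rather than an error.
#'
#' @param intensity H x W x T numeric array (a single H x W frame is
#'   accepted).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold for `method = "fixed"`.
#' @param min_size minimum component area in pixels (default 0).
#' @param single_cell keep only the largest component per frame
#'   (default TRUE).
#' @return H x W x T logical mask array.
#' @export
segmentFrames <- function(intensity, method = c("otsu", "fixed"),
                          threshold = NULL, min_size = 0L,
                          single_cell = TRUE) {
    method <- match.arg(method)
    if (length(dim(intensity)) == 2)
        intensity <- array(intensity, c(dim(intensity), 1))
    out <- array(FALSE, dim(intensity))
    for (t in seq_len(dim(intensity)[3])) {
        fr <- intensity[, , t]
        thr <- if (method == "fixed") {
            if (is.null(threshold)) stop("fixed method needs a threshold")
            threshold
        } else .otsuThreshold(fr)
        bw <- fr > thr
        if (!any(bw)) {
            warning(sprintf("frame %d has no foreground", t))
            next
        }
        lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
        sizes <- tabulate(lab[lab > 0])
        keep <- which(sizes >= min_size)
        if (single_cell && length(keep) > 0)
            keep <- keep[which.max(sizes[keep])]
        if (length(keep) == 0) {
            warning(sprintf("frame %d: all components below min_size", t))
            next
        }
        out[, , t] <- matrix(as.integer(lab) %in% keep, dim(intensity)[1])
    }
    out
}

#' Stabilize a mask stack by integer-pixel translation
#'
#' Registers every frame to frame 1 by the integer (row, col) shift that
#' maximises binary overlap, searching shifts up to `max_shift` in each
#' direction; vacated pixels are background. Registration should be driven
#' by a stationary field reference (e.g. background landmarks or a fixed
#' fiducial channel segmented into the masks); registering on a single
#' moving cell would cancel the very motion the surveillance metric
#' measures.
#'
#' @param masks H x W x T logical array; frame 1 must be non-empty.
#' @param max_shift search bound in pixels (default 10). A best shift on the
#'   search boundary aborts with an error, since the true shift may lie
#'   outside the searched window.
#' @return list with `masks` (stabilised stack) and `shifts` (T x 2 matrix
#'   of applied (row, col) shifts).
#' @export
stabilizeStack <- function(masks, max_shift = 10L) {
    d <- dim(masks)
    stopifnot(length(d) == 3)
    if (!any(masks[, , 1])) stop("frame 1 is empty; nothing to register to")
    ref <- masks[, , 1]
    out <- masks
    shifts <- matrix(0L, d[3], 2)
    rng <- (-max_shift):max_shift
    for (t in seq_len(d[3])[-1]) {
        fr <- masks[, , t]
        best <- c(0L, 0L)
        best_ov <- -1
        for (dr in rng) for (dc in rng) {
            ov <- .shiftOverlap(ref, fr, dr, dc)
            if (ov > best_ov) {
                best_ov <- ov
                best <- c(dr, dc)
            }
        }
        if (any(abs(best) >= max_shift))
            stop(sprintf(
                "frame %d: best shift (%d, %d) reaches the max_shift bound %d",
                t, best[1], best[2], max_shift))
        out[, , t] <- .translate(fr, best[1], best[2])
        shifts[t, ] <- best
    }
    list(masks = out, shifts = shifts)
}

# overlap of ref with fr translated by (dr, dc)
.shiftOverlap <- function(ref, fr, dr, dc) {
    d <- dim(ref)
    r1 <- max(1, 1 + dr); r2 <- min(d[1], d[1] + dr)
    c1 <- max(1, 1 + dc); c2 <- min(d[2], d[2] + dc)
    if (r1 > r2 || c1 > c2) return(0)
    sum(ref[r1:r2, c1:c2] & fr[(r1:r2) - dr, (c1:c2) - dc])
}

.translate <- function(fr, dr, dc) {
    d <- dim(fr)
    out <- matrix(FALSE, d[1], d[2])
    r1 <- max(1, 1 + dr); r2 <- min(d[1], d[1] + dr)
    c1 <- max(1, 1 + dc); c2 <- min(d[2], d[2] + dc)
    if (r1 <= r2 && c1 <= c2)
        out[r1:r2, c1:c2] <- fr[(r1:r2) - dr, (c1:c2) - dc]
    out
}

#' Surveillance area of a cell from its mask stack
#'
#' The area a cell surveys over a time lapse: the pixel area of the maximum
#' projection (logical OR over frames) of its stabilised segmentation stack,
#' normalised to the cell's initial area. A stationary cell scores exactly 1;
#' any excursion adds union area, so the ratio is always >= 1.
#'
#' @param masks H x W x T logical array; frame 1 must be non-empty.
#' @param pixel_size optional pixel edge length (micrometres) used to also
#'   report areas in physical units.
#' @return list: `initial_area`, `union_area` (pixels), `ratio`, and when
#'   `pixel_size` is given, `initial_area_um2` / `union_area_um2`.
#' @export
surveillanceArea <- function(masks, pixel_size = NULL) {
    if (length(dim(masks)) == 2) masks <- array(masks, c(dim(masks), 1))
    initial <- sum(masks[, , 1])
    if (initial == 0) stop("frame 1 is empty: initial area undefined")
    union <- sum(apply(masks, c(1, 2), any))
    res <- list(initial_area = initial, union_area = union,
                ratio = union / initial)
    if (!is.null(pixel_size)) {
        res$initial_area_um2 <- initial * pixel_size^2
        res$union_area_um2 <- union * pixel_size^2
    }
    res
}

#' Pixel-wise colocalization of two channels within a cell mask
#'
#' Pearson correlation of the two channels over in-mask pixels, plus Manders
#' overlap coefficients: `m1` is the fraction of channel A intensity lying
#' in B-positive pixels, `m2` the converse. Positivity thresholds default to
#' Otsu computed per channel within the mask. Swapping the channels swaps
#' `m1`/`m2` and leaves `pearson_r` unchanged.
#'
#' @param channel_a,channel_b numeric matrices of identical shape.
#' @param mask logical matrix restricting the analysed pixels (default: all).
#' @param thresholds optional `c(a =, b =)` positivity thresholds overriding
#'   Otsu.
#' @return list: `pearson_r` (NA when a channel is constant), `m1`, `m2`,
#'   `n_pixels`.
#' @export
colocalize <- function(channel_a, channel_b, mask = NULL, thresholds = NULL) {
    stopifnot(identical(dim(channel_a), dim(channel_b)))
    if (is.null(mask)) mask <- array(TRUE, dim(channel_a))
    if (!any(mask)) stop("empty mask")
    a <- channel_a[mask]
    b <- channel_b[mask]
    ta <- if (!is.null(thresholds)) thresholds[["a"]] else .otsuThreshold(a)
    tb <- if (!is.null(thresholds)) thresholds[["b"]] else .otsuThreshold(b)
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
         else stats::cor(a, b)
    m1 <- if (sum(a) > 0) sum(a[b > tb]) / sum(a) else NA_real_
    m2 <- if (sum(b) > 0) sum(b[a > ta]) / sum(b) else NA_real_
    list(pearson_r = r, m1 = m1, m2 = m2, n_pixels = length(a))
}

#' Classify nuclei as live or dead by marker intensity
#'
#' Dead cells carry high mean intensity of a membrane-impermeant nuclear dye;
#' a nucleus is called dead when its mean intensity exceeds the threshold
#' (a fixed value, or Otsu over the population of nuclei).
#'
#' @param intensities numeric, mean dye intensity per nucleus.
#' @param threshold numeric, or `"otsu"` (default) for a population Otsu
#'   threshold.
#' @return list: `labels` (`"live"`/`"dead"` per nucleus), `dead_fraction`,
#'   `threshold`.
#' @export
classifyViability <- function(intensities, threshold = "otsu") {
    stopifnot(length(intensities) >= 1)
    thr <- if (identical(threshold, "otsu")) .otsuThreshold(intensities)
           else as.numeric(threshold)
    dead <- intensities > thr
    list(labels = ifelse(dead, "dead", "live"),
         dead_fraction = mean(dead), threshold = thr)
}

#' Quantify a dot-blot / antibody-array plate
#'
#' Averages technical-replicate dot intensities per analyte, then subtracts
#' the mean of the negative-control dots. Negative results are reported
#' as-is (no clipping), preserving information about analytes below
#' background.
#'
#' @param dots data.frame with columns `analyte` and `intensity`; one row
#'   per dot.
#' @param negative label of the negative-control group (default
#'   `"negative"`).
#' @return data.frame: `analyte`, `n_dots`, `mean_intensity`, `value`
#'   (background-subtracted), excluding the negative group itself.
#' @export
quantifyDotArray <- function(dots, negative = "negative") {
    stopifnot(all(c("analyte", "intensity") %in% names(dots)))
    if (!(negative %in% dots$analyte))
        stop(sprintf("negative-control group '%s' absent", negative))
    bg <- mean(dots$intensity[dots$analyte == negative])
    keep <- dots[dots$analyte != negative, ]
    agg <- stats::aggregate(intensity ~ analyte, keep, mean)
    n <- stats::aggregate(intensity ~ analyte, keep, length)
    data.frame(analyte = agg$analyte, n_dots = n$intensity,
               mean_intensity = agg$intensity, value = agg$intensity - bg)
}

#' Read / write a binary mask stack as multi-page TIFF
#'
#' Masks are stored as 8-bit images (0 background, 255 foreground).
#'
#' @param masks H x W x T logical array.
#' @param path TIFF path.
#' @return `writeMaskStack`: `path` invisibly; `readMaskStack`: an
#'   H x W x T logical array.
#' @export
writeMaskStack <- function(masks, path) {
    if (length(dim(masks)) == 2) masks <- array(masks, c(dim(masks), 1))
    frames <- lapply(seq_len(dim(masks)[3]),
                     function(t) masks[, , t] * 1)
    tiff::writeTIFF(frames, path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeMaskStack
#' @export
readMaskStack <- function(path) {
    frames <- tiff::readTIFF(path, all = TRUE)
    arr <- array(FALSE, c(dim(frames[[1]])[1:2], length(frames)))
    for (t in seq_along(frames)) {
        f <- frames[[t]]
        if (length(dim(f)) == 3) f <- f[, , 1]
        arr[, , t] <- f > 0.5
    }
    arr
}
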