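test_that("synthetic time lapse renders exact disks along the trajectory", {
    traj <- linearTrajectory(c(30, 20), c(0, 1), 5)
    tl <- generateTimelapse(c(60, 80), radius = 8, centers = traj)
    expect_equal(dim(tl$masks), c(60, 80, 5))
    # stationary disk: all frames identical
    still <- generateTimelapse(c(40, 40), 8, linearTrajectory(c(20, 20),
                                                              c(0, 0), 4))
    for (t in 2:4) expect_identical(still$masks[, , t], still$masks[, , 1])
    # 1 px/frame step moves the truth centroid 1 px/frame
    cents <- sapply(1:5, function(t) {
        idx <- which(tl$masks[, , t], arr.ind = TRUE)
        colMeans(idx)
    })
    expect_equal(diff(cents[2, ]), rep(1, 4), tolerance = 1e-9)

    b1 <- generateTimelapse(c(40, 40), 5,
                            brownianTrajectory(c(20, 20), 1, 6, seed = 3),
                            noise_sd = 0.1, seed = 8)
    b2 <- generateTimelapse(c(40, 40), 5,
                            brownianTrajectory(c(20, 20), 1, 6, seed = 3),
                            noise_sd = 0.1, seed = 8)
    expect_identical(b1$intensity, b2$intensity)

    expect_error(generateTimelapse(c(30, 30), 10,
                                   linearTrajectory(c(15, 25), c(0, 2), 5)),
                 "leaves the frame")
})

test_that("segmentation recovers the truth mask and honours min_size", {
    traj <- linearTrajectory(c(25, 25), c(0, 0), 3)
    tl <- generateTimelapse(c(50, 50), 10, traj, noise_sd = 0.05, seed = 2)
    seg <- segmentFrames(tl$intensity, method = "otsu")
    for (t in 1:3) {
        jac <- sum(seg[, , t] & tl$masks[, , t]) /
            sum(seg[, , t] | tl$masks[, , t])
        expect_gte(jac, 0.98)
    }

    expect_warning(blank <- segmentFrames(matrix(0, 20, 20),
                                          method = "fixed", threshold = 0.5),
                   "no foreground")
    expect_false(any(blank))

    # two disks; min_size above the smaller one's area keeps one component
    rows <- matrix(seq_len(60), 60, 60)
    cols <- t(rows)
    img <- ((rows - 15)^2 + (cols - 15)^2 <= 100) * 1 +
           ((rows - 45)^2 + (cols - 45)^2 <= 9) * 1
    seg2 <- segmentFrames(img, method = "fixed", threshold = 0.5,
                          min_size = 50, single_cell = FALSE)
    lab <- EBImage::bwlabel(EBImage::Image(seg2[, , 1] * 1))
    expect_equal(max(lab), 1)
})

test_that("stabilization recovers injected global jitter", {
    base <- generateTimelapse(c(50, 50), 9,
                              linearTrajectory(c(25, 25), c(0, 0), 4))$masks
    jitter <- rbind(c(0, 0), c(3, -2), c(-3, 3), c(1, 2))
    shaken <- base
    for (t in 2:4) {
        shaken[, , t] <- phagoScreen:::.translate(base[, , t],
                                                  jitter[t, 1], jitter[t, 2])
    }
    st <- stabilizeStack(shaken, max_shift = 6)
    expect_equal(st$shifts, -jitter, ignore_attr = TRUE)
    for (t in 2:4) expect_identical(st$masks[, , t], base[, , 1])

    aligned <- stabilizeStack(base, max_shift = 5)
    expect_true(all(aligned$shifts == 0))

    big <- base
    big[, , 2] <- phagoScreen:::.translate(base[, , 2], 9, 0)
    expect_error(stabilizeStack(big, max_shift = 5), "max_shift")
})

test_that("surveillance ratio is 1 for a stationary cell and matches the stadium formula", {
    still <- generateTimelapse(c(40, 40), 8,
                               linearTrajectory(c(20, 20), c(0, 0), 6))$masks
    res <- surveillanceArea(still)
    expect_equal(res$ratio, 1)

    # disk r = 20 translated d = 40 px in unit steps: union is a stadium,
    # ratio -> 1 + 2 d / (pi r) ~ 2.273
    traj <- linearTrajectory(c(30, 25), c(0, 1), 41)
    masks <- generateTimelapse(c(60, 110), 20, traj)$masks
    res <- surveillanceArea(masks)
    analytic <- 1 + 2 * 40 / (pi * 20)
    expect_lt(abs(res$ratio - analytic) / analytic, 0.02)

    # union is monotone as frames accrue
    ratios <- sapply(2:41, function(T)
        surveillanceArea(masks[, , 1:T])$ratio)
    expect_true(all(diff(ratios) >= 0))
    expect_gte(min(ratios), 1)

    expect_error(surveillanceArea(array(FALSE, c(5, 5, 2))), "empty")
})

test_that("stabilized surveillance is invariant to constant field offset", {
    traj <- linearTrajectory(c(25, 20), c(0, 1), 8)
    masks <- generateTimelapse(c(50, 60), 8, traj)$masks
    shifted <- masks
    for (t in 1:8) {
        shifted[, , t] <- phagoScreen:::.translate(masks[, , t], 2, 2)
    }
    expect_equal(surveillanceArea(shifted)$ratio,
                 surveillanceArea(masks)$ratio)
})

test_that("colocalization matches the 4-pixel closed form and its symmetries", {
    a <- matrix(c(1, 2, 3, 4), 2)
    b <- matrix(c(2, 1, 4, 3), 2)
    res <- colocalize(a, b, thresholds = c(a = 2, b = 2))
    # hand computation: cov 0.75, var 1.25 each -> r = 0.6
    expect_equal(res$pearson_r, 0.6)
    # B-positive pixels hold a = 3, 4 of 10; A-positive hold b = 4, 3 of 10
    expect_equal(res$m1, 0.7)
    expect_equal(res$m2, 0.7)

    # identical channels with a zero positivity floor: total overlap
    ident <- colocalize(a, a, thresholds = c(a = 0, b = 0))
    expect_equal(ident$pearson_r, 1)
    expect_equal(ident$m1, 1)
    expect_equal(ident$m2, 1)

    disjoint <- colocalize(matrix(c(5, 0, 0, 0), 2),
                           matrix(c(0, 0, 0, 5), 2),
                           thresholds = c(a = 1, b = 1))
    expect_equal(disjoint$m1, 0)
    expect_equal(disjoint$m2, 0)

    const <- colocalize(matrix(1, 2, 2), b, thresholds = c(a = 0.5, b = 2))
    expect_true(is.na(const$pearson_r))
    expect_false(is.na(const$m1))
})

test_that("colocalization bounds and channel-swap symmetry hold on random fields", {
    set.seed(14)
    for (i in 1:100) {
        a <- matrix(runif(64), 8)
        b <- matrix(runif(64), 8)
        r1 <- colocalize(a, b)
        r2 <- colocalize(b, a)
        expect_true(r1$pearson_r >= -1 && r1$pearson_r <= 1)
        expect_true(r1$m1 >= 0 && r1$m1 <= 1 && r1$m2 >= 0 && r1$m2 <= 1)
        expect_equal(r1$pearson_r, r2$pearson_r)
        expect_equal(r1$m1, r2$m2)
        expect_equal(r1$m2, r2$m1)
    }
})

test_that("viability classification thresholds a bimodal dye mixture", {
    expect_equal(classifyViability(c(1, 2, 3), threshold = 5)$dead_fraction, 0)
    expect_equal(classifyViability(c(1, 2, 3), threshold = 3)$dead_fraction, 0)

    set.seed(21)
    live <- rnorm(300, 100, 15)
    dead <- rnorm(100, 400, 40)
    res <- classifyViability(c(live, dead), threshold = "otsu")
    truth <- c(rep("live", 300), rep("dead", 100))
    expect_gte(mean(res$labels == truth), 0.95)
})

test_that("dot-array quantification averages replicates then subtracts background", {
    dots <- data.frame(analyte = c("IL6", "IL6", "TNF", "negative", "negative"),
                       intensity = c(10, 12, 1, 1, 1))
    res <- quantifyDotArray(dots)
    expect_equal(res$value[res$analyte == "IL6"], 10)
    expect_equal(res$value[res$analyte == "TNF"], 0)   # equal to background
    expect_equal(res$n_dots[res$analyte == "TNF"], 1)  # mean of one is fine
    expect_error(quantifyDotArray(dots[dots$analyte != "negative", ]),
                 "negative")
})

test_that("mask stacks round trip through multi-page TIFF", {
    masks <- generateTimelapse(c(30, 30), 6,
                               linearTrajectory(c(15, 10), c(0, 2), 4))$masks
    path <- withr::local_tempfile(fileext = ".tif")
    writeMaskStack(masks, path)
    back <- readMaskStack(path)
    expect_identical(back, masks)
})
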