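oneKeypointSkeleton <- function(x, y, part = 1L) {
    coords <- matrix(0, 16, 2); vis <- integer(16)
    coords[part, ] <- c(x, y); vis[part] <- 2L
    cowSkeleton(coords, vis)
}

test_that("heatmap encoding evaluates the Gaussian kernel", {
    hm <- encodeHeatmaps(list(oneKeypointSkeleton(7, 5)), 20, 30,
                         sigma = 2)
    expect_equal(hm@values[5 + 1, 7 + 1, 1], 1)
    # pixel at Euclidean distance 2 -> exp(-4 / (2 * 4)) = exp(-0.5)
    expect_equal(hm@values[5 + 1, 9 + 1, 1], exp(-0.5), tolerance = 1e-12)
    expect_true(all(hm@values[, , 2:16] == 0))
    expect_error(encodeHeatmaps(list(), 10, 10, sigma = 0), "positive")
})

test_that("multi-instance heatmaps take the pixelwise maximum", {
    a <- oneKeypointSkeleton(5, 5); b <- oneKeypointSkeleton(11, 5)
    hm <- encodeHeatmaps(list(a, b), 20, 30, sigma = 2)
    ha <- encodeHeatmaps(list(a), 20, 30, sigma = 2)
    hb <- encodeHeatmaps(list(b), 20, 30, sigma = 2)
    expect_equal(hm@values[, , 1], pmax(ha@values[, , 1], hb@values[, , 1]))
    expect_true(max(hm@values) <= 1)
})

test_that("heatmaps are symmetric under skeleton reflection", {
    sk <- simpleSkeleton()
    W <- 200; H <- 120
    hm <- encodeHeatmaps(list(sk), H, W, sigma = 2)
    refl <- kpCoords(sk); refl[, 1] <- (W - 1) - refl[, 1]
    hmR <- encodeHeatmaps(list(cowSkeleton(refl, kpVisibility(sk))), H, W,
                          sigma = 2)
    expect_equal(hmR@values[, W:1, ], hm@values, tolerance = 1e-12)
})

test_that("PAF encoding writes unit vectors on the band and zero off it", {
    sk <- cowSkeleton({
        m <- matrix(0, 16, 2); m[1, ] <- c(0, 10); m[14, ] <- c(10, 10); m
    }, {v <- integer(16); v[c(1, 14)] <- 2L; v})
    paf <- encodePafs(list(sk), H = 30, W = 30, limbWidth = 4)
    # limb 1 of the default graph is head -> neck
    expect_equal(paf@values[10 + 1, 5 + 1, , 1], c(1, 0))
    expect_equal(paf@values[10 + 1, 25 + 1, , 1], c(0, 0))  # beyond b
    expect_equal(paf@values[25 + 1, 5 + 1, , 1], c(0, 0))   # far off band
    mag <- sqrt(paf@values[, , 1, ]^2 + paf@values[, , 2, ]^2)
    expect_true(all(mag <= 1 + 1e-12))
})

test_that("overlapping opposite limbs average to the zero vector", {
    mk <- function(a, b) cowSkeleton({
        m <- matrix(0, 16, 2); m[1, ] <- a; m[14, ] <- b; m
    }, {v <- integer(16); v[c(1, 14)] <- 2L; v})
    paf <- encodePafs(list(mk(c(0, 10), c(10, 10)),
                           mk(c(10, 10), c(0, 10))), H = 30, W = 30)
    expect_equal(paf@values[10 + 1, 5 + 1, , 1], c(0, 0))
})

test_that("zero-length limbs are skipped with a warning", {
    sk <- cowSkeleton({
        m <- matrix(0, 16, 2); m[1, ] <- c(5, 5); m[14, ] <- c(5, 5); m
    }, {v <- integer(16); v[c(1, 14)] <- 2L; v})
    expect_warning(paf <- encodePafs(list(sk), H = 20, W = 20),
                   "zero-length")
    expect_true(all(paf@values[, , , 1] == 0))
})

test_that("PAF band area grows linearly with limb length", {
    area <- vapply(c(20, 40, 80), function(len) {
        sk <- cowSkeleton({
            m <- matrix(0, 16, 2); m[1, ] <- c(5, 50)
            m[14, ] <- c(5 + len, 50); m
        }, {v <- integer(16); v[c(1, 14)] <- 2L; v})
        paf <- encodePafs(list(sk), H = 100, W = 120, limbWidth = 4)
        sum(paf@values[, , 1, 1] != 0)
    }, numeric(1))
    # area = (len + 1) * (2 * width + 1) within discretization
    expect_equal(area / (c(20, 40, 80) + 1), rep(9, 3), tolerance = 0.05)
})

test_that("peak extraction finds encoded maxima deterministically", {
    hm <- encodeHeatmaps(list(oneKeypointSkeleton(7, 5)), 20, 30, 2)
    pk <- extractPeaks(hm, 0.1)
    expect_equal(nrow(pk), 1)
    expect_equal(unlist(pk[1, c("x", "y", "score")], use.names = FALSE),
                 c(7, 5, 1))

    two <- encodeHeatmaps(list(oneKeypointSkeleton(5, 8),
                               oneKeypointSkeleton(25, 8)), 20, 40, 2)
    pk2 <- extractPeaks(two, 0.1)
    # oracle: brute-force scan of the encoded grid
    m <- two@values[, , 1]
    brute <- 0
    for (r in 1:20) for (c in 1:40) {
        nb <- m[max(1, r - 1):min(20, r + 1), max(1, c - 1):min(40, c + 1)]
        if (m[r, c] >= max(nb) && m[r, c] >= 0.1) brute <- brute + 1
    }
    expect_equal(nrow(pk2), brute)
    expect_equal(nrow(pk2), 2)
    expect_equal(sort(pk2$x), c(5, 25))

    empty <- extractPeaks(encodeHeatmaps(list(), 10, 10, 2), 0.1)
    expect_equal(nrow(empty), 0)
    expect_error(extractPeaks(hm, 0), "between 0 and 1")
})

test_that("well-separated skeletons are recovered exactly by encode/extract", {
    set.seed(11)
    for (rep in 1:3) {
        sc <- composeScene(2, seed = rep * 13, jitterSd = 0)
        gt <- sceneAnnotation(sc)@skeletons
        hm <- encodeHeatmaps(gt, 270, 480, sigma = 2)
        pk <- extractPeaks(hm, 0.1)
        for (sk in gt) for (p in which(kpVisibility(sk) > 0)) {
            hit <- pk[pk$part_id == p & pk$x == kpCoords(sk)[p, 1] &
                      pk$y == kpCoords(sk)[p, 2], ]
            expect_equal(nrow(hit), 1)
            expect_equal(hit$score, 1)
        }
        expect_equal(nrow(pk), sum(vapply(gt, nLabeled, numeric(1))))
    }
})
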