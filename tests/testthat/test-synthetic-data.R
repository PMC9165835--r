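test_that("standing cows have all hooves on a common ground line", {
    sk <- sampleSkeleton(poseParams("standing", jitterSd = 0, seed = 1))
    hooves <- partId(c("left_front_hoof", "right_front_hoof",
                       "left_hind_hoof", "right_hind_hoof"))
    expect_equal(length(unique(kpCoords(sk)[hooves, 2])), 1)
    expect_true(all(kpVisibility(sk) == 2L))
})

test_that("lying cows are flatter than standing cows", {
    ly <- sampleSkeleton(poseParams("lying", jitterSd = 0, seed = 1))
    st <- sampleSkeleton(poseParams("standing", jitterSd = 0, seed = 1))
    hw <- function(s) {
        bb <- skeletonBBox(s)
        c(h = bb$ymax - bb$ymin, w = bb$xmax - bb$xmin)
    }
    expect_lt(hw(ly)["h"] / hw(ly)["w"], hw(st)["h"] / hw(st)["w"])
    expect_lt(hw(ly)["h"], 0.5 * hw(st)["h"])
    # folded legs: knee and hoof close to the leg root
    G <- 70
    for (leg in 1:4) {
        r <- kpCoords(ly)[partId(CowPose:::.LEGS$root[leg]), ]
        for (seg in c("knee", "hoof")) {
            p <- kpCoords(ly)[partId(CowPose:::.LEGS[[seg]][leg]), ]
            expect_lt(sqrt(sum((p - r)^2)), 0.3 * G + 2)
        }
    }
})

test_that("skeleton sampling is deterministic given its seed", {
    p <- poseParams("walking", seed = 77)
    expect_identical(kpCoords(sampleSkeleton(p)),
                     kpCoords(sampleSkeleton(p)))
    ds1 <- samplePoseDataset(10, seed = 3)
    ds2 <- samplePoseDataset(10, seed = 3)
    expect_identical(lapply(ds1$skeletons, kpCoords),
                     lapply(ds2$skeletons, kpCoords))
})

test_that("non-overlapping scenes have pairwise-disjoint boxes", {
    sc <- composeScene(5, overlap = "none", seed = 9)
    b <- sceneAnnotation(sc)@boxes
    expect_equal(nrow(b), 5)
    for (i in 1:4) for (j in (i + 1):5)
        expect_equal(boxIou(b[i, ], b[j, ]), 0)
    expect_true(all(vapply(sceneAnnotation(sc)@skeletons, function(s)
        all(kpCoords(s)[, 1] <= 480 & kpCoords(s)[, 2] <= 270),
        logical(1))))
})

test_that("partial overlap forces one occluded pair and masks keypoints", {
    sc <- composeScene(2, overlap = "partial", seed = 4)
    b <- sceneAnnotation(sc)@boxes
    i2 <- boxIou(b[1, ], b[2, ])
    expect_gte(i2, 0.1); expect_lte(i2, 0.4)
    vis <- kpVisibility(sceneAnnotation(sc)@skeletons[[2]])
    expect_true(any(vis < 2L))
    expect_gt(sc@occlusionFraction[2], 0)
})

test_that("scenes too crowded for the canvas raise an error", {
    expect_error(composeScene(4, H = 150, W = 200, seed = 1),
                 "canvas too small")
})

test_that("night scenes are darker and noisier than day scenes", {
    day <- composeScene(2, lighting = "day", seed = 6)
    night <- composeScene(2, lighting = "night", seed = 6)
    expect_lt(mean(sceneImage(night)), mean(sceneImage(day)) * 0.6)
    expect_true(all(sceneImage(night) >= 0 & sceneImage(night) <= 1))
})

test_that("scene annotations survive the COCO round trip", {
    sc <- composeScene(3, seed = 15)
    f <- withr::local_tempfile(fileext = ".json")
    writeCocoKeypoints(list(sceneAnnotation(sc)), f)
    back <- readCocoKeypoints(f)[[1]]
    orig <- sceneAnnotation(sc)
    expect_length(back@skeletons, 3)
    for (i in 1:3)
        expect_equal(kpCoords(back@skeletons[[i]]),
                     kpCoords(orig@skeletons[[i]]))
    expect_equal(back@boxes$xmin, orig@boxes$xmin)
})

test_that("identity mosaic places keypoints at quadrant offsets", {
    sc <- composeScene(1, seed = 31, H = 134, W = 240)
    mo <- mosaicAugment(list(sc, sc, sc, sc), outSize = c(268, 480),
                        identity = TRUE)
    expect_equal(dim(sceneImage(mo)), c(268, 480))
    offs <- list(c(0, 0), c(240, 0), c(0, 134), c(240, 134))
    orig <- sceneAnnotation(sc)@skeletons[[1]]
    skels <- sceneAnnotation(mo)@skeletons
    expect_length(skels, 4)
    for (q in 1:4) {
        lab <- kpVisibility(skels[[q]]) > 0
        expect_equal(kpCoords(skels[[q]])[lab, 1],
                     kpCoords(orig)[lab, 1] + offs[[q]][1])
        expect_equal(kpCoords(skels[[q]])[lab, 2],
                     kpCoords(orig)[lab, 2] + offs[[q]][2])
    }
})

test_that("random mosaics keep annotations inside the canvas", {
    scenes <- lapply(1:4, function(i) composeScene(1, seed = 40 + i))
    mo <- mosaicAugment(scenes, seed = 5)
    ann <- sceneAnnotation(mo)
    expect_lte(length(ann@skeletons), 4)
    if (nrow(ann@boxes)) {
        expect_true(all(ann@boxes$xmin >= 0 & ann@boxes$xmax <= 480))
        expect_true(all(ann@boxes$ymin >= 0 & ann@boxes$ymax <= 270))
    }
    mo2 <- mosaicAugment(scenes, seed = 5)
    expect_identical(sceneImage(mo), sceneImage(mo2))
    expect_error(mosaicAugment(scenes[1:3]), "exactly 4")
})

test_that("brightness adjustment is a clipped multiplication", {
    img <- matrix(0.4, 20, 20)
    expect_identical(adjustBrightness(img, 1), img)
    expect_equal(mean(adjustBrightness(img, 1.5)), 0.6, tolerance = 1e-12)
    set.seed(2)
    noisy <- matrix(runif(400), 20, 20)
    expect_equal(adjustBrightness(adjustBrightness(noisy, 0.5), 0.5),
                 adjustBrightness(noisy, 0.25), tolerance = 1e-12)
    expect_true(all(adjustBrightness(noisy, 3) <= 1))
    expect_error(adjustBrightness(img, 0), "positive")
})

test_that("scene rasters write as PNG files", {
    sc <- composeScene(1, seed = 2)
    f <- withr::local_tempfile(fileext = ".png")
    writeScenePng(sc, f)
    expect_true(file.exists(f))
    img <- png::readPNG(f)
    expect_equal(dim(img)[1:2], dim(sceneImage(sc)))
})
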