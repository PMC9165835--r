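test_that("featurization normalizes to the skeleton bounding box", {
    sk <- simpleSkeleton()
    f <- featurizeSkeleton(sk)
    expect_length(f, 32)
    expect_true(all(f >= 0 & f <= 1))
    # translation invariance
    expect_equal(featurizeSkeleton(simpleSkeleton(shift = c(100, 50))), f)
    # uniform scaling invariance
    sk2 <- cowSkeleton(kpCoords(sk) * 3, kpVisibility(sk))
    expect_equal(featurizeSkeleton(sk2), f, tolerance = 1e-12)
})

test_that("missing parts map to zeroed feature slots", {
    sk <- simpleSkeleton()
    vis <- kpVisibility(sk); vis[c(2, 5, 9, 13)] <- 0L
    f <- featurizeSkeleton(cowSkeleton(kpCoords(sk), vis))
    slots <- c(3, 4, 9, 10, 17, 18, 25, 26)
    expect_true(all(f[slots] == 0))
})

test_that("degenerate bounding boxes fall back to unit scale", {
    coords <- matrix(0, 16, 2); coords[, 1] <- 5; coords[, 2] <- 1:16
    expect_warning(f <- featurizeSkeleton(cowSkeleton(coords,
                                                      rep(2L, 16))),
                   "degenerate")
    expect_true(all(is.finite(f)))
})

test_that("the network has the stated architecture and parameter count", {
    model <- buildPoseClassifier(seed = 1)
    expect_equal(model@config$sizes, c(32, 128, 64, 16, 4))
    # dense: (32*128+128) + (128*64+64) + (64*16+16) + (16*4+4) = 13588
    # batch-norm gamma+beta: 2 * (128 + 64 + 16) = 416
    expect_equal(nParams(model), 13588 + 416)
})

test_that("untrained forward passes are valid softmax distributions", {
    model <- buildPoseClassifier(seed = 1)
    X <- matrix(runif(5 * 32), 5, 32)
    p <- predictPoseProb(model, X)
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
    expect_true(all(p >= 0))
    # same seed, same outputs
    p2 <- predictPoseProb(buildPoseClassifier(seed = 1), X)
    expect_identical(p, p2)
    expect_false(identical(p, predictPoseProb(buildPoseClassifier(2), X)))
})

test_that("analytic gradients match finite differences through batch norm", {
    model <- buildPoseClassifier(seed = 5, hidden = c(6, 5, 4))
    params <- model@params
    set.seed(5)
    X <- matrix(rnorm(7 * 32), 7, 32)
    Y <- diag(4)[sample(1:4, 7, replace = TRUE), ]
    lossAt <- function(par) {
        fwd <- mlpForward(par, X, training = TRUE)
        ix <- cbind(seq_len(nrow(Y)), max.col(Y))
        mean(-log(pmax(fwd$probs[ix], 1e-12)))
    }
    fwd <- mlpForward(params, X, training = TRUE)
    grads <- mlpBackward(params, fwd, Y)
    eps <- 1e-5
    checkOne <- function(getter, setter, g) {
        v <- getter(params)
        probe <- sample(length(v), min(6, length(v)))
        for (ix in probe) {
            vPlus <- v; vPlus[ix] <- vPlus[ix] + eps
            vMinus <- v; vMinus[ix] <- vMinus[ix] - eps
            num <- (lossAt(setter(params, vPlus)) -
                    lossAt(setter(params, vMinus))) / (2 * eps)
            expect_equal(num, g[ix], tolerance = 1e-4)
        }
    }
    for (l in 1:4)
        checkOne(function(p) p$dense[[l]]$W,
                 function(p, v) { p$dense[[l]]$W <- matrix(
                     v, nrow(p$dense[[l]]$W)); p },
                 grads$dense[[l]]$W)
    for (l in 1:3)
        checkOne(function(p) p$bn[[l]]$gamma,
                 function(p, v) { p$bn[[l]]$gamma <- v; p },
                 grads$bn[[l]]$gamma)
})

test_that("training reduces loss and is reproducible from its seed", {
    ds <- samplePoseDataset(60, seed = 4)
    X <- t(vapply(ds$skeletons, featurizeSkeleton, numeric(32)))
    m1 <- trainPoseClassifier(buildPoseClassifier(0), X, ds$labels,
                              epochs = 6, seed = 1)
    expect_true(all(is.finite(m1@history$loss)))
    expect_lt(tail(m1@history$loss, 1), m1@history$loss[1])
    m2 <- trainPoseClassifier(buildPoseClassifier(0), X, ds$labels,
                              epochs = 6, seed = 1)
    expect_identical(m1@params, m2@params)
    expect_error(trainPoseClassifier(buildPoseClassifier(0), X,
                                     rep("lying", nrow(X)), epochs = 1),
                 "two classes")
})

test_that("a trained classifier recognizes canonical poses", {
    model <- trainSmallClassifier()
    p <- classifyPose(model,
                      sampleSkeleton(poseParams("lying", jitterSd = 0,
                                                seed = 2)))
    expect_equal(sum(p$probs), 1, tolerance = 1e-6)
    expect_equal(p$label, "lying")
    st <- classifyPose(model,
                       sampleSkeleton(poseParams("standing", jitterSd = 0,
                                                 seed = 2)))
    expect_equal(st$label, "standing")
    # translation invariance carries through the classifier
    sk <- sampleSkeleton(poseParams("walking", jitterSd = 1, seed = 3))
    moved <- cowSkeleton(kpCoords(sk) + 40, kpVisibility(sk))
    expect_equal(classifyPose(model, sk)$probs,
                 classifyPose(model, moved)$probs, tolerance = 1e-9)
})

test_that("classifier round-trips through save/load", {
    model <- buildPoseClassifier(3)
    f <- withr::local_tempfile(fileext = ".rds")
    savePoseClassifier(model, f)
    back <- loadPoseClassifier(f)
    X <- matrix(runif(32), 1)
    expect_identical(predictPoseProb(model, X), predictPoseProb(back, X))
})
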