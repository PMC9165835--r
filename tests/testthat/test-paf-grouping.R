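# A PAF whose first channel is a constant field (vx, vy) everywhere.
constantPaf <- function(vx, vy, H = 20, W = 20) {
    vals <- array(0, c(H, W, 2, 15))
    vals[, , 1, 1] <- vx; vals[, , 2, 1] <- vy
    new("PafStack", values = vals, limbWidth = 4,
        limbGraph = defaultLimbGraph())
}

test_that("line integral of aligned and orthogonal constant fields", {
    paf <- constantPaf(1, 0)
    expect_equal(pafLineIntegral(paf, 1, c(0, 0), c(10, 0)), 1)
    paf2 <- constantPaf(0, 1)
    expect_equal(pafLineIntegral(paf2, 1, c(0, 0), c(10, 0)), 0)
    expect_error(pafLineIntegral(paf, 1, c(3, 3), c(3, 3)), "degenerate")
    expect_error(pafLineIntegral(paf, 1, c(0, 0), c(1, 0), nSamples = 1),
                 "nSamples")
})

test_that("the encoded ground-truth limb integrates to exactly 1", {
    coords <- matrix(0, 16, 2)
    coords[1, ] <- c(4, 17); coords[14, ] <- c(33, 6)
    vis <- integer(16); vis[c(1, 14)] <- 2L
    sk <- cowSkeleton(coords, vis)
    paf <- encodePafs(list(sk), H = 40, W = 50, limbWidth = 4)
    e <- pafLineIntegral(paf, 1, coords[1, ], coords[14, ])
    expect_equal(e, 1, tolerance = 1e-12)
})

test_that("line integral is antisymmetric in its endpoints", {
    sk <- simpleSkeleton()
    paf <- encodePafs(list(sk), H = 120, W = 200)
    for (ci in c(1, 5, 9)) {
        a <- kpCoords(sk)[limbEdges(defaultLimbGraph())[ci, 1], ]
        b <- kpCoords(sk)[limbEdges(defaultLimbGraph())[ci, 2], ]
        expect_equal(pafLineIntegral(paf, ci, a, b),
                     -pafLineIntegral(paf, ci, b, a), tolerance = 1e-12)
    }
})

test_that("assignment matches the exhaustive-search oracle", {
    set.seed(99)
    for (rep in 1:30) {
        nA <- sample(1:5, 1); nB <- sample(1:5, 1)
        scores <- matrix(runif(nA * nB, -1, 1), nA, nB)
        got <- matchByScores(scores)
        oracle <- bruteForceAssignment(scores)
        expect_equal(sum(got$score), oracle$total, tolerance = 1e-12)
        expect_equal(nrow(got), min(nA, nB))
        expect_false(anyDuplicated(got$a) > 0)
        expect_false(anyDuplicated(got$b) > 0)
    }
})

test_that("assignment is globally optimal where greedy is not", {
    # greedy would take (1,1) = 0.9 and be left with (2,2) = 0.1
    # (total 1.0); optimal is 0.8 + 0.7 = 1.5
    scores <- rbind(c(0.9, 0.8), c(0.7, 0.1))
    got <- matchByScores(scores)
    expect_equal(sort(got$score), c(0.7, 0.8))
    expect_equal(sum(got$score), bruteForceAssignment(scores)$total)
})

test_that("lowering the score threshold never loses matched pairs", {
    set.seed(3)
    scores <- matrix(runif(16, -1, 1), 4, 4)
    counts <- vapply(c(0.5, 0.2, 0.05, -1),
                     function(t) nrow(matchByScores(scores, t)),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("matchLimb pairs candidates through the PAF and drops weak pairs", {
    coords <- matrix(0, 16, 2)
    coords[1, ] <- c(5, 10); coords[14, ] <- c(25, 10)
    vis <- integer(16); vis[c(1, 14)] <- 2L
    paf <- encodePafs(list(cowSkeleton(coords, vis)), H = 30, W = 40)
    candA <- data.frame(part_id = 1, x = 5, y = 10, score = 1, cand_id = 1)
    candB <- data.frame(part_id = 14, x = 25, y = 10, score = 1,
                        cand_id = 2)
    m <- matchLimb(candA, candB, paf, 1)
    expect_equal(nrow(m), 1)
    expect_equal(m$score, 1, tolerance = 1e-12)
    # empty side -> empty result
    expect_equal(nrow(matchLimb(candA[0, ], candB, paf, 1)), 0)
    # a pair fighting the field direction scores -1 and is dropped
    m2 <- matchLimb(candB, candA, paf, 1, scoreThreshold = 0.05)
    expect_equal(nrow(m2), 0)
})

test_that("assembly merges limbs into instances and applies minParts", {
    # two separated cows end-to-end
    sc <- composeScene(2, seed = 21, jitterSd = 0)
    gt <- sceneAnnotation(sc)@skeletons
    hm <- encodeHeatmaps(gt, 270, 480, 2)
    paf <- encodePafs(gt, H = 270, W = 480)
    res <- decodePose(hm, paf)
    expect_length(res$skeletons, 2)
    for (sk in res$skeletons) expect_equal(nLabeled(sk), 16)
    expect_equal(nrow(res$unassigned), 0)

    # zero matches -> zero skeletons, everything unassigned
    peaks <- data.frame(cand_id = 1:3, part_id = c(1, 14, 15),
                        x = c(1, 2, 3), y = c(1, 2, 3), score = 1)
    noMatch <- data.frame(limb_index = integer(), a_id = integer(),
                          b_id = integer(), score = numeric())
    res0 <- assembleSkeletons(noMatch, peaks, defaultLimbGraph())
    expect_length(res0$skeletons, 0)
    expect_equal(nrow(res0$unassigned), 3)

    # one isolated matched limb with minParts = 3 is discarded
    oneMatch <- data.frame(limb_index = 1, a_id = 1, b_id = 2,
                           score = 0.9)
    res1 <- assembleSkeletons(oneMatch, peaks[1:2, ], defaultLimbGraph(),
                              minParts = 3)
    expect_length(res1$skeletons, 0)
    expect_equal(nrow(res1$unassigned), 2)
    # ... but kept with minParts = 2
    res2 <- assembleSkeletons(oneMatch, peaks[1:2, ], defaultLimbGraph(),
                              minParts = 2)
    expect_length(res2$skeletons, 1)
    expect_equal(nLabeled(res2$skeletons[[1]]), 2)
})

test_that("multi-cow scenes decode to one skeleton per cow with OKS 1", {
    for (K in c(1, 3)) {
        sc <- composeScene(K, seed = 100 + K, jitterSd = 0)
        gt <- sceneAnnotation(sc)@skeletons
        hm <- encodeHeatmaps(gt, 270, 480, 2)
        paf <- encodePafs(gt, H = 270, W = 480)
        res <- decodePose(hm, paf)
        expect_length(res$skeletons, K)
        expect_equal(oksAp(res$skeletons, gt), 1)
    }
})
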