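#' Parameters for one synthetic cow skeleton
#'
#' The generator draws side-view stick cows whose three poses differ in the
#' features a skeleton classifier can exploit: standing cows have straight
#' legs on a common ground line, walking cows displace knees and hooves by
#' sinusoids of a gait phase (with a per-sample stride scale, so that
#' low-stride walking frames resemble standing — the confusable pair),
#' and lying cows have a lowered body axis with legs folded close to their
#' roots.
#'
#' @param pose "standing", "walking" or "lying".
#' @param bodyLength coccyx-to-neck distance in pixels (default 120).
#' @param legLength root-to-hoof distance when extended, pixels
#'   (default 70).
#' @param gaitPhase walking gait phase in radians (default: drawn uniformly
#'   from [0, 2*pi)).
#' @param strideScale walking stride amplitude multiplier in (0, 1]
#'   (default: drawn uniformly from [0.1, 1]).
#' @param jitterSd per-coordinate Gaussian jitter in pixels (default 2).
#' @param flip mirror the cow left-right (default FALSE).
#' @param seed optional RNG seed; NULL draws from the current RNG stream.
#' @return list of parameters for [sampleSkeleton()].
#' @export
poseParams <- function(pose = c("standing", "walking", "lying"),
                       bodyLength = 120, legLength = 70,
                       gaitPhase = NULL, strideScale = NULL,
                       jitterSd = 2, flip = FALSE, seed = NULL) {
    pose <- match.arg(pose)
    stopifnot(bodyLength > 0, legLength > 0, jitterSd >= 0)
    list(pose = pose, bodyLength = bodyLength, legLength = legLength,
         gaitPhase = gaitPhase, strideScale = strideScale,
         jitterSd = jitterSd, flip = flip, seed = seed)
}

## Leg layout: roots sit on a line 0.1 L below the body axis; front legs
## near the neck, hind legs near the coccyx, left/right offset in x.
.LEGS <- data.frame(
    root = c("left_front_leg_root", "right_front_leg_root",
             "left_hind_leg_root", "right_hind_leg_root"),
    knee = c("left_front_knee", "right_front_knee",
             "left_hind_knee", "right_hind_knee"),
    hoof = c("left_front_hoof", "right_front_hoof",
             "left_hind_hoof", "right_hind_hoof"),
    rootX = c(0.84, 0.94, 0.06, 0.16),
    phase = c(0, pi, pi / 2, 3 * pi / 2),  # four-beat lateral gait
    fold = c(-1, -1, 1, 1),        # lying fold direction along x
    stringsAsFactors = FALSE)

#' Draw one synthetic cow skeleton
#'
#' Deterministic given `params$seed`.  All 16 keypoints are visible
#' (visibility 2); coordinates are rounded to integer pixels (the
#' annotation-tool convention) and clipped at 0.
#'
#' @param params from [poseParams()].
#' @param origin (x, y) pixel offset of the cow (default c(0, 0); the
#'   local frame has the coccyx near the origin).
#' @return a [CowSkeleton-class] with `poseLabel` set.
#' @examples
#' sk <- sampleSkeleton(poseParams("lying", seed = 42))
#' poseLabel(sk)
#' @export
sampleSkeleton <- function(params, origin = c(0, 0)) {
    withSeed(params$seed, {
        L <- params$bodyLength; G <- params$legLength
        xy <- matrix(0, 16, 2, dimnames = list(.COW_PARTS$name, c("x", "y")))
        if (params$pose == "lying") {
            axisY <- 0.25 * G
            xy["coccyx", ] <- c(0, axisY)
            xy["spine", ] <- c(0.5 * L, axisY)
            xy["neck", ] <- c(L, axisY)
            xy["head", ] <- c(1.15 * L, axisY - 0.05 * L)
            rootY <- axisY + 0.05 * L
            for (i in 1:4) {
                r <- c(.LEGS$rootX[i] * L, rootY)
                xy[.LEGS$root[i], ] <- r
                xy[.LEGS$knee[i], ] <- r + c(.LEGS$fold[i] * 0.15 * G,
                                             0.12 * G)
                xy[.LEGS$hoof[i], ] <- r + c(.LEGS$fold[i] * 0.28 * G,
                                             0.08 * G)
            }
        } else {
            xy["coccyx", ] <- c(0, 0)
            xy["spine", ] <- c(0.5 * L, 0)
            xy["neck", ] <- c(L, 0)
            xy["head", ] <- c(1.18 * L, -0.10 * L)
            rootY <- 0.10 * L
            stride <- if (params$pose == "walking") {
                sc <- params$strideScale %||% stats::runif(1, 0.1, 1)
                ph <- params$gaitPhase %||% stats::runif(1, 0, 2 * pi)
                list(amp = 0.35 * G * sc, lift = 0.15 * G * sc, ph = ph)
            } else list(amp = 0, lift = 0, ph = 0)
            for (i in 1:4) {
                r <- c(.LEGS$rootX[i] * L, rootY)
                s <- sin(stride$ph + .LEGS$phase[i])
                xy[.LEGS$root[i], ] <- r
                xy[.LEGS$knee[i], ] <- r + c(0.5 * stride$amp * s, G / 2)
                xy[.LEGS$hoof[i], ] <- r +
                    c(stride$amp * s, G - stride$lift * max(0, s))
            }
        }
        ## shift the local frame to nonnegative coordinates
        xy[, 1] <- xy[, 1] - min(xy[, 1])
        xy[, 2] <- xy[, 2] - min(xy[, 2])
        if (params$flip)
            xy[, 1] <- max(xy[, 1]) - xy[, 1]
        if (params$jitterSd > 0)
            xy <- xy + matrix(stats::rnorm(32, sd = params$jitterSd), 16, 2)
        xy[, 1] <- pmax(round(xy[, 1] + origin[1]), 0)
        xy[, 2] <- pmax(round(xy[, 2] + origin[2]), 0)
        cowSkeleton(xy, rep(2L, 16), poseLabel = params$pose)
    })
}

#' Generate a labeled synthetic pose dataset
#'
#' Draws `nPerPose` skeletons for each of the three poses with randomized
#' stride, gait phase, flip and jitter, mirroring an annotated still-image
#' collection.  Bit-reproducible given `seed`.
#'
#' @param nPerPose skeletons per pose class (default 600).
#' @param seed RNG seed (default 0).
#' @param jitterSd,bodyLength,legLength geometry parameters (see
#'   [poseParams()]).
#' @return list with `skeletons` (list of [CowSkeleton-class]) and
#'   `labels` (character vector).
#' @export
samplePoseDataset <- function(nPerPose = 600, seed = 0, jitterSd = 2,
                              bodyLength = 120, legLength = 70) {
    withSeed(seed, {
        poses <- rep(c("standing", "walking", "lying"), each = nPerPose)
        skels <- lapply(poses, function(p)
            sampleSkeleton(poseParams(p, bodyLength = bodyLength,
                                      legLength = legLength,
                                      jitterSd = jitterSd,
                                      flip = stats::runif(1) < 0.5)))
        list(skeletons = skels, labels = poses)
    })
}

## Draw one line segment onto a grayscale matrix (0-based endpoint coords).
drawSegment <- function(img, a, b, value = 0.95) {
    H <- nrow(img); W <- ncol(img)
    n <- max(2, ceiling(2 * sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n)
    px <- round(a[1] + t * (b[1] - a[1]))
    py <- round(a[2] + t * (b[2] - a[2]))
    ok <- px >= 0 & px < W & py >= 0 & py < H
    img[cbind(py[ok] + 1, px[ok] + 1)] <- value
    img
}

renderSkeletons <- function(skeletons, H, W, graph = defaultLimbGraph(),
                            background = 0.35) {
    img <- matrix(background, H, W)
    for (sk in skeletons) {
        for (ci in seq_len(nrow(graph@edges))) {
            pa <- graph@edges[ci, 1]; pb <- graph@edges[ci, 2]
            if (sk@visibility[pa] > 0L && sk@visibility[pb] > 0L)
                img <- drawSegment(img, sk@coords[pa, ], sk@coords[pb, ])
        }
    }
    img
}

#' Compose a multi-cow scene
#'
#' Places `nCows` synthetic cows on a canvas and renders a stick-figure
#' raster.  With `overlap = "none"` all bounding boxes are pairwise
#' disjoint with a minimum 12-pixel gap; with `overlap = "partial"` one
#' pair of cows is forced to bounding-box IoU in [0.1, 0.4] and the
#' occluded cow's keypoints inside the intersection rectangle are set to
#' visibility 1, a random half of which are further removed to 0.  Night
#' lighting scales intensities by 0.4 and adds Gaussian sensor noise.
#' Deterministic given `seed`.
#'
#' @param nCows number of cows (>= 1).
#' @param overlap "none" or "partial".
#' @param lighting "day" or "night".
#' @param seed RNG seed.
#' @param H,W canvas size in pixels (default 270 x 480, a scaled-down
#'   surveillance frame).
#' @param jitterSd keypoint jitter in pixels (default 2).
#' @param bodyLength,legLength cow geometry (defaults 120, 70).
#' @param poses optional character vector of poses per cow (recycled);
#'   default random.
#' @return a [CowScene-class]; its annotation holds one skeleton and one
#'   ground-truth box per cow.
#' @export
composeScene <- function(nCows = 1, overlap = c("none", "partial"),
                         lighting = c("day", "night"), seed = NULL,
                         H = 270, W = 480, jitterSd = 2,
                         bodyLength = 120, legLength = 70, poses = NULL) {
    overlap <- match.arg(overlap)
    lighting <- match.arg(lighting)
    stopifnot(nCows >= 1)
    withSeed(seed, {
        poseSet <- c("standing", "walking", "lying")
        poses <- if (is.null(poses)) sample(poseSet, nCows, replace = TRUE)
                 else rep_len(poses, nCows)
        gap <- 12
        sceneDone <- FALSE
        ## dense scenes can jam under one unlucky arrangement; restart the
        ## whole placement with fresh randomness a few times before giving up
        for (attempt in seq_len(25)) {
        skels <- list(); boxes <- emptyBoxes()
        for (i in seq_len(nCows)) {
            placed <- FALSE
            sk <- sampleSkeleton(
                poseParams(poses[i], bodyLength = bodyLength,
                           legLength = legLength, jitterSd = jitterSd,
                           flip = stats::runif(1) < 0.5))
            bb0 <- skeletonBBox(sk)
            bw <- bb0$xmax - bb0$xmin; bh <- bb0$ymax - bb0$ymin
            if (bw + 2 > W || bh + 2 > H)
                stop("canvas too small to place ", nCows, " cows (",
                     H, " x ", W, ")")
            ## random placements first; densely packed scenes fall back to
            ## a shuffled scan of a coarse origin grid
            origins <- cbind(
                floor(stats::runif(200, 1, W - bw - 1)),
                floor(stats::runif(200, 1, H - bh - 1)))
            grid <- as.matrix(expand.grid(
                x = seq(1, W - bw - 1, by = 6),
                y = seq(1, H - bh - 1, by = 6)))
            origins <- rbind(origins,
                             grid[sample.int(nrow(grid)), , drop = FALSE])
            for (try in seq_len(nrow(origins))) {
                ox <- origins[try, 1]; oy <- origins[try, 2]
                coords <- sk@coords
                coords[, 1] <- coords[, 1] - bb0$xmin + ox
                coords[, 2] <- coords[, 2] - bb0$ymin + oy
                cand <- cowSkeleton(coords, sk@visibility,
                                    poseLabel = sk@poseLabel)
                bb <- skeletonBBox(cand)
                wantPartial <- overlap == "partial" && i == 2L
                ok <- TRUE
                if (nrow(boxes)) {
                    dil <- makeBoxes(boxes$xmin - gap / 2,
                                     boxes$ymin - gap / 2,
                                     boxes$xmax + gap / 2,
                                     boxes$ymax + gap / 2,
                                     boxes$confidence, boxes$label)
                    for (j in seq_len(nrow(boxes))) {
                        i2 <- boxIou(bb, boxes[j, ])
                        if (wantPartial && j == 1L) {
                            if (i2 < 0.1 || i2 > 0.4) { ok <- FALSE; break }
                        } else if (boxIou(
                                       makeBoxes(bb$xmin - gap / 2,
                                                 bb$ymin - gap / 2,
                                                 bb$xmax + gap / 2,
                                                 bb$ymax + gap / 2),
                                       dil[j, ]) > 0) {
                            ok <- FALSE; break
                        }
                    }
                }
                if (ok) {
                    skels[[i]] <- cand
                    boxes <- rbind(boxes, bb)
                    placed <- TRUE
                    break
                }
            }
            if (!placed) break
        }
        if (placed) { sceneDone <- TRUE; break }
        }
        if (!sceneDone)
            stop("canvas too small to place ", nCows, " cows (",
                 H, " x ", W, ")")
        occFrac <- numeric(nCows)
        if (overlap == "partial" && nCows >= 2) {
            inter <- c(max(boxes$xmin[1], boxes$xmin[2]),
                       max(boxes$ymin[1], boxes$ymin[2]),
                       min(boxes$xmax[1], boxes$xmax[2]),
                       min(boxes$ymax[1], boxes$ymax[2]))
            sk <- skels[[2]]
            vis <- sk@visibility
            covered <- which(sk@coords[, 1] >= inter[1] &
                             sk@coords[, 1] <= inter[3] &
                             sk@coords[, 2] >= inter[2] &
                             sk@coords[, 2] <= inter[4])
            vis[covered] <- 1L
            drop <- covered[stats::runif(length(covered)) < 0.5]
            vis[drop] <- 0L
            if (!any(vis > 0L)) vis[covered[1]] <- 1L
            skels[[2]] <- cowSkeleton(sk@coords, vis,
                                      poseLabel = sk@poseLabel)
            occFrac[2] <- length(covered) / 16
        }
        img <- renderSkeletons(skels, H, W)
        if (lighting == "night") {
            img <- img * 0.4 +
                matrix(stats::rnorm(H * W, sd = 0.02), H, W)
            img <- clamp(img, 0, 1)
        }
        ann <- new("AnnotatedImage", imagePath = "", width = W,
                   height = H, skeletons = skels, boxes = boxes)
        new("CowScene", image = img, annotation = ann,
            lighting = lighting, occlusionFraction = occFrac)
    })
}

setMethod("show", "CowScene", function(object) {
    cat(sprintf("CowScene %g x %g (%s): %d cows\n",
                object@annotation@width, object@annotation@height,
                object@lighting, length(object@annotation@skeletons)))
})

#' @describeIn composeScene the scene's grayscale image matrix.
#' @param scene a [CowScene-class].
#' @export
sceneImage <- function(scene) scene@image

#' @describeIn composeScene the scene's [AnnotatedImage-class] ground
#'   truth.
#' @export
sceneAnnotation <- function(scene) scene@annotation

#' Write a scene's raster as PNG
#'
#' @param scene a [CowScene-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScenePng <- function(scene, path) {
    png::writePNG(scene@image, path)
    invisible(path)
}

## Apply mirror/flip/rot90 transforms to an image matrix and a coordinate
## transformer; returns list(img, fxy) with fxy mapping old (x, y) to new.
applyOrientation <- function(img, mirror, flipud, rot90k) {
    fxy <- function(x, y) list(x = x, y = y)
    if (mirror) {
        W <- ncol(img); img <- img[, ncol(img):1, drop = FALSE]
        f0 <- fxy
        fxy <- function(x, y) { p <- f0(x, y); p$x <- W - 1 - p$x; p }
    }
    if (flipud) {
        H <- nrow(img); img <- img[nrow(img):1, , drop = FALSE]
        f1 <- fxy
        fxy <- function(x, y) { p <- f1(x, y); p$y <- H - 1 - p$y; p }
    }
    for (k in seq_len(rot90k)) {
        H <- nrow(img)
        img <- t(img)[, H:1, drop = FALSE]  # 90 degrees clockwise
        f2 <- fxy
        fxy <- local({
            f2 <- f2; H <- H
            function(x, y) {
                p <- f2(x, y)
                list(x = H - 1 - p$y, y = p$x)
            }
        })
    }
    list(img = img, fxy = fxy)
}

#' Mosaic augmentation of four annotated scenes
#'
#' Builds one composite from exactly four input scenes: each input is
#' independently mirrored, flipped and rotated by a random multiple of 90
#' degrees, cropped to its quadrant, and the four quadrants are stitched at
#' a random split point of the output canvas.  Boxes and keypoints are
#' transformed consistently; keypoints falling outside their quadrant crop
#' become missing (visibility 0), boxes are clipped, and an annotation
#' whose clipped box area drops below 20% of its original area is dropped.
#' Deterministic given `seed`.
#'
#' @param scenes list of exactly four [CowScene-class] objects.
#' @param outSize output (H, W) in pixels (default: size of the first
#'   input).
#' @param seed RNG seed.
#' @param identity if TRUE, skip the random orientation changes and stitch
#'   the four inputs at the canvas midpoint (useful for testing).
#' @return a [CowScene-class].
#' @export
mosaicAugment <- function(scenes, outSize = NULL, seed = NULL,
                          identity = FALSE) {
    if (length(scenes) != 4)
        stop("mosaic augmentation takes exactly 4 input scenes")
    withSeed(seed, {
        H <- if (is.null(outSize)) nrow(scenes[[1]]@image) else outSize[1]
        W <- if (is.null(outSize)) ncol(scenes[[1]]@image) else outSize[2]
        sx <- if (identity) floor(W / 2)
              else floor(stats::runif(1, 0.3, 0.7) * W)
        sy <- if (identity) floor(H / 2)
              else floor(stats::runif(1, 0.3, 0.7) * H)
        quads <- list(c(0, 0, sy, sx), c(0, sx, sy, W - sx),
                      c(sy, 0, H - sy, sx), c(sy, sx, H - sy, W - sx))
        out <- matrix(0.35, H, W)
        skels <- list(); boxes <- emptyBoxes()
        for (q in 1:4) {
            sc <- scenes[[q]]
            tr <- if (identity)
                applyOrientation(sc@image, FALSE, FALSE, 0L)
            else applyOrientation(sc@image,
                                  stats::runif(1) < 0.5,
                                  stats::runif(1) < 0.5,
                                  sample(0:3, 1))
            qy <- quads[[q]][1]; qx <- quads[[q]][2]
            qh <- quads[[q]][3]; qw <- quads[[q]][4]
            ih <- nrow(tr$img); iw <- ncol(tr$img)
            ch <- min(qh, ih); cw <- min(qw, iw)
            r0 <- if (identity || ih <= qh) 0
                  else floor(stats::runif(1, 0, ih - ch))
            c0 <- if (identity || iw <= qw) 0
                  else floor(stats::runif(1, 0, iw - cw))
            out[qy + 1:ch, qx + 1:cw] <-
                tr$img[r0 + 1:ch, c0 + 1:cw]
            for (sk in sc@annotation@skeletons) {
                origBB <- skeletonBBox(sk)
                origArea <- (origBB$xmax - origBB$xmin) *
                            (origBB$ymax - origBB$ymin)
                coords <- sk@coords; vis <- sk@visibility
                for (p in which(vis > 0L)) {
                    np <- tr$fxy(coords[p, 1], coords[p, 2])
                    x <- np$x - c0; y <- np$y - r0
                    if (x < 0 || x >= cw || y < 0 || y >= ch) {
                        vis[p] <- 0L
                        coords[p, ] <- 0
                    } else coords[p, ] <- c(x + qx, y + qy)
                }
                if (!any(vis > 0L)) next
                nsk <- cowSkeleton(coords, vis, poseLabel = sk@poseLabel)
                nbb <- skeletonBBox(nsk)
                newArea <- (nbb$xmax - nbb$xmin) * (nbb$ymax - nbb$ymin)
                if (origArea > 0 && newArea < 0.2 * origArea) next
                skels[[length(skels) + 1L]] <- nsk
                boxes <- rbind(boxes, nbb)
            }
        }
        ann <- new("AnnotatedImage", imagePath = "", width = W,
                   height = H, skeletons = skels, boxes = boxes)
        new("CowScene", image = out, annotation = ann, lighting = "day",
            occlusionFraction = numeric(length(skels)))
    })
}

#' Multiply image brightness with clipping
#'
#' Per-pixel multiplication by `factor` followed by clipping to [0, 1];
#' annotations are unaffected by brightness changes.  Factors 0.5/0.75/
#' 1.25/1.5 emulate the +/- 25% and 50% front-light/back-light conditions
#' of open-barn surveillance.
#'
#' @param image numeric matrix/array with values in [0, 1].
#' @param factor positive brightness multiplier.
#' @return the adjusted image.
#' @export
adjustBrightness <- function(image, factor) {
    if (factor <= 0) stop("brightness factor must be positive")
    clamp(image * factor, 0, 1)
}
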