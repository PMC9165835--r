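#' Encode ground-truth keypoint heatmaps
#'
#' For part j, the confidence at pixel p is
#' `exp(-||p - x_j||^2 / (2 sigma^2))` for the keypoint location `x_j`;
#' with several animals in the scene, each pixel takes the maximum over
#' animals, so that peaks of nearby animals are preserved rather than
#' blurred together.  Keypoints with visibility 0 are skipped; parts absent
#' from every skeleton give an all-zero channel.  Heatmaps are computed at
#' full image resolution.
#'
#' @param skeletons list of [CowSkeleton-class].
#' @param H,W canvas size in pixels.
#' @param sigma Gaussian spread in pixels (default 2).
#' @return a [HeatmapStack-class] (H x W x 16 array).
#' @export
encodeHeatmaps <- function(skeletons, H, W, sigma = 2) {
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
        stop("sigma must be a single positive number")
    if (is(skeletons, "CowSkeleton")) skeletons <- list(skeletons)
    vals <- array(0, c(H, W, 16))
    xs <- 0:(W - 1); ys <- 0:(H - 1)
    for (sk in skeletons) {
        for (p in which(sk@visibility > 0L)) {
            kx <- sk@coords[p, 1]; ky <- sk@coords[p, 2]
            g <- outer(exp(-(ys - ky)^2 / (2 * sigma^2)),
                       exp(-(xs - kx)^2 / (2 * sigma^2)))
            vals[, , p] <- pmax(vals[, , p], g)
        }
    }
    new("HeatmapStack", values = vals, sigma = sigma)
}

#' Encode ground-truth part affinity fields
#'
#' For each limb of each animal, every pixel within the rectangular band
#' around the segment from part_a to part_b (along-segment projection in
#' `[0, limb length]`, perpendicular distance at most `limbWidth`) receives
#' the unit vector pointing from part_a toward part_b; pixels off every band
#' are (0, 0).  Where bands of several animals overlap, the field is the
#' arithmetic mean of their unit vectors (opposing limbs therefore cancel).
#' A limb is only encoded when both endpoints have visibility > 0;
#' zero-length limbs are skipped with a warning.
#'
#' @param skeletons list of [CowSkeleton-class].
#' @param graph [LimbGraph-class] fixing the limb/channel order.
#' @param H,W canvas size in pixels.
#' @param limbWidth band half-width in pixels (default 4).
#' @return a [PafStack-class] (H x W x 2 x C array).
#' @export
encodePafs <- function(skeletons, graph = defaultLimbGraph(), H, W,
                       limbWidth = 4) {
    if (is(skeletons, "CowSkeleton")) skeletons <- list(skeletons)
    C <- nrow(graph@edges)
    vsum <- array(0, c(H, W, 2, C))
    cnt <- array(0L, c(H, W, C))
    X <- matrix(0:(W - 1), H, W, byrow = TRUE)
    Y <- matrix(0:(H - 1), H, W)
    for (sk in skeletons) {
        for (ci in seq_len(C)) {
            pa <- graph@edges[ci, 1]; pb <- graph@edges[ci, 2]
            if (sk@visibility[pa] == 0L || sk@visibility[pb] == 0L) next
            a <- sk@coords[pa, ]; b <- sk@coords[pb, ]
            len <- sqrt(sum((b - a)^2))
            if (len == 0) {
                warning(sprintf(
                    "zero-length limb %d (parts %d-%d); skipped",
                    ci, pa, pb))
                next
            }
            u <- (b - a) / len
            dx <- X - a[1]; dy <- Y - a[2]
            along <- dx * u[1] + dy * u[2]
            perp <- abs(dx * u[2] - dy * u[1])
            band <- along >= 0 & along <= len & perp <= limbWidth
            vx <- vsum[, , 1, ci]; vy <- vsum[, , 2, ci]
            vx[band] <- vx[band] + u[1]
            vy[band] <- vy[band] + u[2]
            vsum[, , 1, ci] <- vx; vsum[, , 2, ci] <- vy
            cc <- cnt[, , ci]; cc[band] <- cc[band] + 1L
            cnt[, , ci] <- cc
        }
    }
    for (ci in seq_len(C)) {
        nz <- cnt[, , ci] > 0L
        if (any(nz)) {
            for (d in 1:2) {
                v <- vsum[, , d, ci]
                v[nz] <- v[nz] / cnt[, , ci][nz]
                vsum[, , d, ci] <- v
            }
        }
    }
    new("PafStack", values = vsum, limbWidth = limbWidth,
        limbGraph = graph)
}

#' Extract keypoint candidates from a heatmap stack
#'
#' A pixel is a candidate when its value is at least the value of each of
#' its 8 neighbors (3 x 3 non-maximum criterion, ties allowed) and at least
#' `peakThreshold`.  Candidates are returned sorted per part by descending
#' score, plateau ties broken by the smaller y then the smaller x, so the
#' output is deterministic.
#'
#' @param hm a [HeatmapStack-class].
#' @param peakThreshold minimum heatmap value in (0, 1) (default 0.1).
#' @return data.frame with columns part_id, x, y, score (pixel coordinates,
#'   0-based).
#' @export
extractPeaks <- function(hm, peakThreshold = 0.1) {
    if (peakThreshold <= 0 || peakThreshold >= 1)
        stop("peakThreshold must lie strictly between 0 and 1")
    d <- dim(hm@values); H <- d[1]; W <- d[2]
    out <- vector("list", 16)
    for (p in 1:16) {
        m <- hm@values[, , p]
        pad <- matrix(-Inf, H + 2, W + 2)
        pad[2:(H + 1), 2:(W + 1)] <- m
        nb <- matrix(-Inf, H, W)
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            nb <- pmax(nb, pad[2:(H + 1) + dr, 2:(W + 1) + dc])
        }
        hit <- which(m >= nb & m >= peakThreshold, arr.ind = TRUE)
        if (nrow(hit) == 0) next
        df <- data.frame(part_id = p, x = hit[, 2] - 1, y = hit[, 1] - 1,
                         score = m[hit])
        out[[p]] <- df[order(-df$score, df$y, df$x), , drop = FALSE]
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res))
        res <- data.frame(part_id = integer(), x = numeric(),
                          y = numeric(), score = numeric())
    rownames(res) <- NULL
    res
}

#' Save or load a heatmap/PAF stack
#'
#' Stacks are stored in R's portable binary serialization.  Channel order
#' is part_id ascending for heatmaps and limb-graph order for PAFs.
#'
#' @param x a [HeatmapStack-class] or [PafStack-class].
#' @param path file path.
#' @return `saveStack` returns `path` invisibly; `loadStack` the object.
#' @export
saveStack <- function(x, path) {
    stopifnot(is(x, "HeatmapStack") || is(x, "PafStack"))
    saveRDS(x, path)
    invisible(path)
}

#' @rdname saveStack
#' @export
loadStack <- function(path) readRDS(path)
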