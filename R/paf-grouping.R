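#' PAF line integral between two candidate keypoints
#'
#' The association confidence of a limb hypothesis: the mean, over
#' `nSamples` points placed uniformly on the segment from `a` to `b`, of the
#' dot product between the part affinity field (nearest-pixel lookup) and
#' the unit vector from `a` to `b`.  The result lies in [-1, 1]; it is 1
#' when the field is everywhere aligned with the segment and negative when
#' the field opposes it, so swapping `a` and `b` flips the sign.
#'
#' @param paf a [PafStack-class].
#' @param limbIndex which limb channel to integrate (1-based, limb-graph
#'   order).
#' @param a,b numeric (x, y) endpoints in 0-based pixel coordinates.
#' @param nSamples number of quadrature samples (>= 2, default 10).
#' @return a single score in [-1, 1].
#' @export
pafLineIntegral <- function(paf, limbIndex, a, b, nSamples = 10) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (all(a == b)) stop("degenerate limb: a == b")
    if (nSamples < 2) stop("nSamples must be >= 2")
    d <- dim(paf@values); H <- d[1]; W <- d[2]
    u <- (b - a) / sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = nSamples)
    px <- clamp(round(a[1] + t * (b[1] - a[1])), 0, W - 1)
    py <- clamp(round(a[2] + t * (b[2] - a[2])), 0, H - 1)
    vx <- paf@values[cbind(py + 1, px + 1, 1, limbIndex)]
    vy <- paf@values[cbind(py + 1, px + 1, 2, limbIndex)]
    mean(vx * u[1] + vy * u[2])
}

#' Optimal one-to-one matching of a bipartite score matrix
#'
#' Solves the linear assignment problem maximizing the total score over
#' complete assignments of `min(nrow, ncol)` pairs (Hungarian algorithm via
#' `clue::solve_LSAP`), then removes pairs whose individual score falls
#' below `scoreThreshold`.  Output is sorted by descending score.
#'
#' @param scores numeric matrix, rows = candidates on side a, columns =
#'   candidates on side b.
#' @param scoreThreshold pairs with score below this are dropped after
#'   assignment (default `-Inf`: keep all).
#' @return data.frame with columns a, b (row/column indices) and score.
#' @export
matchByScores <- function(scores, scoreThreshold = -Inf) {
    if (length(scores) == 0 || nrow(scores) == 0 || ncol(scores) == 0)
        return(data.frame(a = integer(), b = integer(), score = numeric()))
    flip <- nrow(scores) > ncol(scores)
    m <- if (flip) t(scores) else scores
    shift <- min(m, 0)
    sol <- clue::solve_LSAP(m - shift, maximum = TRUE)
    a <- seq_len(nrow(m)); b <- as.integer(sol)
    if (flip) { tmp <- a; a <- b; b <- tmp }
    out <- data.frame(a = a, b = b, score = scores[cbind(a, b)])
    out <- out[out$score >= scoreThreshold, , drop = FALSE]
    out <- out[order(-out$score, out$a), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Match keypoint candidates across one limb
#'
#' Scores every (candidate_a, candidate_b) pair by the PAF line integral,
#' finds the one-to-one assignment maximizing the total score
#' ([matchByScores()]) and drops pairs scoring below `scoreThreshold`.
#'
#' @param candA,candB data.frames of peak candidates (columns part_id, x,
#'   y, score, optionally cand_id) for the limb's part_a and part_b; either
#'   may be empty.
#' @param paf a [PafStack-class].
#' @param limbIndex limb channel index.
#' @param scoreThreshold minimum retained line-integral score
#'   (default 0.05).
#' @param nSamples quadrature samples for the line integral.
#' @return data.frame with columns limb_index, a (row in candA), b (row in
#'   candB), a_id, b_id (candidate ids when provided), and score, sorted by
#'   descending score.
#' @export
matchLimb <- function(candA, candB, paf, limbIndex, scoreThreshold = 0.05,
                      nSamples = 10) {
    empty <- data.frame(limb_index = integer(), a = integer(),
                        b = integer(), a_id = integer(), b_id = integer(),
                        score = numeric())
    nA <- nrow(candA); nB <- nrow(candB)
    if (is.null(nA) || is.null(nB) || nA == 0 || nB == 0) return(empty)
    scores <- matrix(NA_real_, nA, nB)
    for (i in seq_len(nA)) for (j in seq_len(nB)) {
        a <- c(candA$x[i], candA$y[i]); b <- c(candB$x[j], candB$y[j])
        scores[i, j] <- if (all(a == b)) -Inf
            else pafLineIntegral(paf, limbIndex, a, b, nSamples)
    }
    m <- matchByScores(scores, scoreThreshold)
    if (nrow(m) == 0) return(empty)
    data.frame(limb_index = limbIndex, a = m$a, b = m$b,
               a_id = if (!is.null(candA$cand_id)) candA$cand_id[m$a]
                      else m$a,
               b_id = if (!is.null(candB$cand_id)) candB$cand_id[m$b]
                      else m$b,
               score = m$score)
}

#' Assemble matched limbs into skeletons
#'
#' Candidates linked by matched limbs are merged into animal instances with
#' union-find; every instance becomes a [CowSkeleton-class] whose matched
#' parts get visibility 2 at the candidate coordinates and whose unmatched
#' parts get visibility 0.  Since per-limb matching is one-to-one and the
#' default limb graph is a tree, no instance can claim two candidates for
#' the same part; this is asserted and violation is an error.  Instances
#' with fewer than `minParts` keypoints, and candidates never matched at
#' all, are returned as unassigned.
#'
#' @param matches data.frame of matched limbs with columns limb_index,
#'   a_id, b_id, score (as produced by [matchLimb()] over all limbs).
#' @param peaks data.frame of all candidates with columns cand_id, part_id,
#'   x, y, score.
#' @param graph the [LimbGraph-class] used for matching.
#' @param minParts minimum keypoints for a kept instance (default 4).
#' @return list with elements `skeletons` (list of [CowSkeleton-class])
#'   and `unassigned` (data.frame of leftover candidates).
#' @export
assembleSkeletons <- function(matches, peaks, graph, minParts = 4) {
    n <- nrow(peaks)
    idx <- seq_len(n)
    names(idx) <- as.character(peaks$cand_id)
    parent <- ufNew(n)
    if (nrow(matches))
        for (k in seq_len(nrow(matches))) {
            i <- idx[[as.character(matches$a_id[k])]]
            j <- idx[[as.character(matches$b_id[k])]]
            parent <- ufUnion(parent, i, j)
        }
    matchedIds <- unique(c(matches$a_id, matches$b_id))
    root <- vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
    skeletons <- list()
    unassigned <- integer()
    for (r in sort(unique(root))) {
        members <- which(root == r)
        members <- members[peaks$cand_id[members] %in% matchedIds]
        if (length(members) < minParts || length(members) == 0L) {
            unassigned <- c(unassigned, which(root == r))
            next
        }
        parts <- peaks$part_id[members]
        if (anyDuplicated(parts))
            stop("assembly conflict: instance claims two candidates for ",
                 "part(s) ", paste(unique(parts[duplicated(parts)]),
                                   collapse = ", "))
        coords <- matrix(0, 16, 2)
        vis <- integer(16)
        coords[parts, ] <- cbind(peaks$x[members], peaks$y[members])
        vis[parts] <- 2L
        skeletons[[length(skeletons) + 1L]] <-
            cowSkeleton(coords, vis, instanceId = length(skeletons) + 1L)
    }
    list(skeletons = skeletons,
         unassigned = peaks[sort(unique(unassigned)), , drop = FALSE])
}

#' Decode multi-animal skeletons from heatmaps and PAFs
#'
#' The full bottom-up grouping pipeline: extract peak candidates from the
#' heatmaps, match candidates across every limb by PAF line integral and
#' Hungarian assignment, then assemble matched limbs into skeletons.
#'
#' @param hm a [HeatmapStack-class].
#' @param paf a [PafStack-class] (its limb graph drives the matching).
#' @param peakThreshold minimum heatmap value for a candidate (default 0.1).
#' @param scoreThreshold minimum retained line-integral score
#'   (default 0.05).
#' @param minParts minimum keypoints per kept instance (default 4).
#' @param nSamples line-integral quadrature samples (default 10).
#' @return as [assembleSkeletons()].
#' @examples
#' sk <- sampleSkeleton(poseParams(pose = "standing", jitterSd = 0, seed = 1))
#' hm <- encodeHeatmaps(list(sk), H = 200, W = 300)
#' paf <- encodePafs(list(sk), H = 200, W = 300)
#' res <- decodePose(hm, paf)
#' length(res$skeletons)
#' @export
decodePose <- function(hm, paf, peakThreshold = 0.1, scoreThreshold = 0.05,
                       minParts = 4, nSamples = 10) {
    peaks <- extractPeaks(hm, peakThreshold)
    if (nrow(peaks)) peaks$cand_id <- seq_len(nrow(peaks))
    else peaks$cand_id <- integer()
    graph <- paf@limbGraph
    matches <- list()
    for (ci in seq_len(nrow(graph@edges))) {
        pa <- graph@edges[ci, 1]; pb <- graph@edges[ci, 2]
        matches[[ci]] <- matchLimb(
            peaks[peaks$part_id == pa, , drop = FALSE],
            peaks[peaks$part_id == pb, , drop = FALSE],
            paf, ci, scoreThreshold, nSamples)
    }
    matches <- do.call(rbind, matches)
    assembleSkeletons(matches, peaks, graph, minParts)
}
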