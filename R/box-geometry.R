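## Accept either a one-row box data.frame or a numeric
## (xmin, ymin, xmax, ymax) vector.
asBoxVec <- function(b) {
    if (is.data.frame(b)) {
        stopifnot(nrow(b) == 1L)
        return(c(b$xmin, b$ymin, b$xmax, b$ymax))
    }
    stopifnot(is.numeric(b), length(b) >= 4L)
    as.numeric(b[1:4])
}

#' Decode a grid-cell prediction into a bounding box
#'
#' The detector head expresses a box through a grid cell `(Cx, Cy)` of an
#' `S x S` grid, center offsets `(tx, ty)` and extents `(tw, th)`.  Two
#' decodings are provided:
#' \describe{
#'   \item{`"literal"`}{the logistic function applied to the whole sum:
#'     `xmin = sigmoid(tx + Cx - tw/2)` and so on for the other three
#'     corners.  Outputs lie in (0, 1) as image fractions, and
#'     `xmin <= xmax` is guaranteed by monotonicity of the logistic.}
#'   \item{`"canonical"`}{the conventional YOLO decoding:
#'     center `(sigmoid(tx) + Cx)/S`, extents `exp(tw)/S`, corners
#'     center +/- extent/2, clipped to [0, 1].}
#' }
#'
#' @param tx,ty center offsets.
#' @param tw,th box width and height parameters.
#' @param Cx,Cy grid cell coordinates (0-based, `0 <= C < S`).
#' @param S grid size (needed for `"canonical"`; typically 52, 26 or 13).
#' @param confidence box confidence in [0, 1].
#' @param mode `"literal"` (default) or `"canonical"`.
#' @return one-row box data.frame in normalized image fractions.
#' @export
decodeBox <- function(tx, ty, tw, th, Cx = 0, Cy = 0, S = 13,
                      confidence = 1, mode = c("literal", "canonical")) {
    mode <- match.arg(mode)
    if (mode == "literal") {
        xmin <- stats::plogis(tx + Cx - tw / 2)
        xmax <- stats::plogis(tx + Cx + tw / 2)
        ymin <- stats::plogis(ty + Cy - th / 2)
        ymax <- stats::plogis(ty + Cy + th / 2)
    } else {
        cx <- (stats::plogis(tx) + Cx) / S
        cy <- (stats::plogis(ty) + Cy) / S
        w <- exp(tw) / S; h <- exp(th) / S
        xmin <- clamp(cx - w / 2, 0, 1); xmax <- clamp(cx + w / 2, 0, 1)
        ymin <- clamp(cy - h / 2, 0, 1); ymax <- clamp(cy + h / 2, 0, 1)
    }
    makeBoxes(xmin, ymin, xmax, ymax, confidence = confidence)
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as one-row data.frames or numeric
#'   (xmin, ymin, xmax, ymax) vectors.
#' @return IoU in [0, 1]; 0 for disjoint boxes and for a zero-area union.
#' @export
boxIou <- function(a, b) {
    a <- asBoxVec(a); b <- asBoxVec(b)
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    un <- (a[3] - a[1]) * (a[4] - a[2]) +
          (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (un <= 0) return(0)
    inter / un
}

#' Complete-IoU (CIoU) regression loss
#'
#' `L = 1 - IoU + d^2/c^2 + alpha * upsilon`, where `d` is the distance
#' between box centers, `c` the diagonal of the smallest enclosing box,
#' `upsilon = (4/pi^2) (arctan(w_gt/h_gt) - arctan(w/h))^2` the
#' aspect-ratio penalty and `alpha = upsilon / ((1 - IoU) + upsilon)`
#' (defined as 0 when `upsilon = 0`).  The loss is 0 iff the boxes
#' coincide and always at least `1 - IoU`.
#'
#' @param pred,gt boxes as one-row data.frames or numeric vectors.
#' @return the scalar loss.
#' @examples
#' ciouLoss(c(0, 0, 2, 2), c(4, 0, 6, 2))  # 1 - 0 + 16/40 = 1.4
#' @export
ciouLoss <- function(pred, gt) {
    p <- asBoxVec(pred); g <- asBoxVec(gt)
    wp <- p[3] - p[1]; hp <- p[4] - p[2]
    wg <- g[3] - g[1]; hg <- g[4] - g[2]
    if (hp <= 0 || hg <= 0)
        stop("zero box height: aspect-ratio term arctan(w/h) undefined")
    i <- boxIou(p, g)
    d2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
          ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
    c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
          (max(p[4], g[4]) - min(p[2], g[2]))^2
    ups <- (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
    alpha <- if (ups == 0) 0 else ups / ((1 - i) + ups)
    1 - i + d2 / c2 + alpha * ups
}

#' Binary cross-entropy for box confidence
#'
#' `-(target * log(pred) + (1 - target) * log(1 - pred))` with `pred`
#' clipped to `[eps, 1 - eps]`; vectorized.
#'
#' @param pred predicted confidence in [0, 1].
#' @param target 0 or 1.
#' @param eps clipping constant (default 1e-7).
#' @return nonnegative loss, same length as the inputs.
#' @export
confidenceBce <- function(pred, target, eps = 1e-7) {
    p <- clamp(pred, eps, 1 - eps)
    -(target * log(p) + (1 - target) * log(1 - p))
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-confidence box, drops every box with IoU at least
#' `iouThreshold` against any kept box, and repeats.  Order among kept
#' boxes is by descending confidence, ties by input position, so the
#' result is deterministic.
#'
#' @param boxes data.frame of boxes (columns xmin, ymin, xmax, ymax,
#'   confidence).
#' @param iouThreshold overlap at or above which a box is suppressed
#'   (default 0.5).
#' @return the kept subset of `boxes`.
#' @export
nmsBoxes <- function(boxes, iouThreshold = 0.5) {
    if (nrow(boxes) == 0) return(boxes)
    ord <- order(-boxes$confidence, seq_len(nrow(boxes)))
    keep <- integer()
    for (i in ord) {
        ok <- TRUE
        for (k in keep)
            if (boxIou(boxes[i, ], boxes[k, ]) >= iouThreshold) {
                ok <- FALSE; break
            }
        if (ok) keep <- c(keep, i)
    }
    out <- boxes[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
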