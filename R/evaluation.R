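#' Classify detections into TP/FP/FN
#'
#' Predictions are greedily matched, in order of descending confidence, to
#' their best still-unmatched ground-truth box.  A prediction whose match
#' reaches `iouThreshold` is a true positive; any other prediction is a
#' false positive.  Two false-negative conventions are provided:
#' \describe{
#'   \item{`"literal"`}{(default) a ground-truth box is a false negative
#'     only when it has zero overlap with every prediction — so a GT that
#'     is weakly overlapped but unmatched counts neither as TP nor FN.}
#'   \item{`"coco"`}{every unmatched ground-truth box is a false negative,
#'     the convention of the COCO detection metric.}
#' }
#'
#' @param preds data.frame of predicted boxes (with `confidence`).
#' @param gts data.frame of ground-truth boxes.
#' @param iouThreshold IoU at or above which a match is a TP, in (0, 1).
#' @param mode `"literal"` or `"coco"`.
#' @return list with counts `tp`, `fp`, `fn` and ratios `precision`,
#'   `recall` (NA when undefined).
#' @export
classifyDetections <- function(preds, gts, iouThreshold = 0.5,
                               mode = c("literal", "coco")) {
    mode <- match.arg(mode)
    if (iouThreshold <= 0 || iouThreshold >= 1)
        stop("iouThreshold must lie strictly between 0 and 1")
    nP <- nrow(preds); nG <- nrow(gts)
    gtMatched <- rep(FALSE, nG)
    tp <- 0L; fp <- 0L
    iouMat <- matrix(0, max(nP, 1), max(nG, 1))
    if (nP && nG)
        for (i in seq_len(nP)) for (j in seq_len(nG))
            iouMat[i, j] <- boxIou(preds[i, ], gts[j, ])
    for (i in order(-preds$confidence)) {
        best <- 0; bestJ <- 0L
        if (nG) for (j in seq_len(nG))
            if (!gtMatched[j] && iouMat[i, j] > best) {
                best <- iouMat[i, j]; bestJ <- j
            }
        if (bestJ > 0L && best >= iouThreshold) {
            tp <- tp + 1L
            gtMatched[bestJ] <- TRUE
        } else fp <- fp + 1L
    }
    fn <- if (nG == 0) 0L else if (mode == "coco") sum(!gtMatched)
        else sum(!gtMatched &
                 apply(iouMat[, seq_len(nG), drop = FALSE], 2,
                       function(col) all(col == 0) || nP == 0))
    list(tp = tp, fp = fp, fn = as.integer(fn),
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Average precision from precision/recall points
#'
#' All-point interpolation of the precision-recall curve: with the points
#' sorted by recall, `AP = sum over i of (r_i - r_[i-1]) * p_interp(r_i)`
#' where `p_interp(r)` is the maximum precision attained at recall at least
#' `r` and `r_0 = 0`.
#'
#' @param precision,recall numeric vectors of equal length in [0, 1].
#' @return AP in [0, 1]; 0 for empty input.
#' @export
averagePrecision <- function(precision, recall) {
    stopifnot(length(precision) == length(recall))
    if (length(recall) == 0) return(0)
    ord <- order(recall, -precision)
    r <- recall[ord]; p <- precision[ord]
    pint <- rev(cummax(rev(p)))  # max precision at recall >= r_i
    sum((r - c(0, r[-length(r)])) * pint)
}

#' Object keypoint similarity between two skeletons
#'
#' `OKS = mean over labeled GT keypoints of exp(-d_i^2 / (2 s^2 k_i^2))`,
#' where `d_i` is the Euclidean distance between the ground-truth keypoint
#' and the prediction for the same part, `s` is the object scale and `k_i`
#' the per-part normalization constant.  "Labeled" means visibility > 0 in
#' the ground truth.  Parts missing from the prediction contribute a zero
#' term (distance infinity).  OKS is 1 iff every labeled keypoint matches
#' exactly, and is invariant to a rigid translation applied to both
#' skeletons.
#'
#' @param pred,gt [CowSkeleton-class] objects.
#' @param s object scale; default `sqrt(area of the GT skeleton's bounding
#'   box)`.  A zero default scale (degenerate box) is an error; pass `s`
#'   explicitly then.
#' @param k per-part constants, length 1 or 16 (default 0.1).
#' @return list with `value` in [0, 1] and the named `per_keypoint` terms.
#' @export
computeOks <- function(pred, gt, s = NULL, k = 0.1) {
    lab <- which(gt@visibility > 0L)
    if (length(lab) == 0)
        stop("ground-truth skeleton has no labeled keypoints")
    if (is.null(s)) {
        bb <- skeletonBBox(gt)
        s <- sqrt((bb$xmax - bb$xmin) * (bb$ymax - bb$ymin))
    }
    if (!is.finite(s) || s <= 0)
        stop("object scale s must be positive; pass s explicitly for ",
             "degenerate skeletons")
    k <- rep_len(k, 16)
    if (any(k <= 0)) stop("per-part constants k must be positive")
    terms <- vapply(lab, function(p) {
        if (pred@visibility[p] == 0L) return(0)
        d2 <- sum((pred@coords[p, ] - gt@coords[p, ])^2)
        exp(-d2 / (2 * s^2 * k[p]^2))
    }, numeric(1))
    names(terms) <- .COW_PARTS$name[lab]
    list(value = mean(terms), per_keypoint = terms)
}

#' OKS-thresholded average precision over a set of objects
#'
#' Predictions are matched one-to-one to ground-truth skeletons greedily by
#' descending OKS; `AP = (number of matched pairs with OKS > threshold) /
#' (number of ground-truth objects)`.
#'
#' @param preds,gts lists of [CowSkeleton-class]; `preds` may be empty.
#' @param threshold OKS threshold (default 0.5, strict inequality).
#' @param s,k passed to [computeOks()] (per-GT default scale when `s` is
#'   NULL).
#' @return AP in [0, 1].
#' @export
oksAp <- function(preds, gts, threshold = 0.5, s = NULL, k = 0.1) {
    if (length(gts) == 0) stop("no ground-truth skeletons")
    if (length(preds) == 0) return(0)
    oks <- matrix(0, length(preds), length(gts))
    for (i in seq_along(preds)) for (j in seq_along(gts))
        oks[i, j] <- computeOks(preds[[i]], gts[[j]], s = s, k = k)$value
    hits <- 0L
    for (step in seq_len(min(dim(oks)))) {
        best <- which(oks == max(oks), arr.ind = TRUE)[1, ]
        if (oks[best[1], best[2]] > threshold) hits <- hits + 1L
        oks[best[1], ] <- -Inf
        oks[, best[2]] <- -Inf
    }
    hits / length(gts)
}

#' Metrics from a 3 x 3 pose confusion matrix
#'
#' Rows are actual poses (standing, walking, lying), columns predicted.
#' Per-class precision is column-wise (`cm[j,j] / colsum_j`), per-class
#' recall row-wise, accuracy is `trace / total`, and the column-share
#' matrix gives, within each predicted class, the fraction coming from each
#' actual class (`cm[i,j] / colsum_j`).  Classes with a zero column or row
#' total report NA rather than 0 for the undefined ratio.
#'
#' @param cm numeric 3 x 3 matrix of nonnegative counts.
#' @return list with `correct`, `total`, `accuracy`, `precision`,
#'   `recall` (named length-3 vectors) and `columnShare` (3 x 3 matrix).
#' @examples
#' cm <- rbind(c(121, 9, 0), c(10, 119, 1), c(1, 0, 129))
#' confusionMetrics(cm)$accuracy  # 369/390
#' @export
confusionMetrics <- function(cm) {
    cm <- as.matrix(cm)
    if (!all(dim(cm) == c(3, 3)))
        stop("cm must be a 3 x 3 matrix")
    if (any(cm < 0)) stop("confusion counts must be nonnegative")
    if (sum(cm) == 0) stop("all-zero confusion matrix")
    cls <- c("standing", "walking", "lying")
    dimnames(cm) <- list(actual = cls, predicted = cls)
    colsum <- colSums(cm); rowsum <- rowSums(cm)
    precision <- ifelse(colsum > 0, diag(cm) / colsum, NA_real_)
    recall <- ifelse(rowsum > 0, diag(cm) / rowsum, NA_real_)
    names(precision) <- names(recall) <- cls
    share <- sweep(cm, 2, colsum, "/")
    share[, colsum == 0] <- NA_real_
    list(correct = sum(diag(cm)), total = sum(cm),
         accuracy = sum(diag(cm)) / sum(cm),
         precision = precision, recall = recall, columnShare = share)
}
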