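#' The 16-part cow keypoint table
#'
#' Part ids 1..16 and their names: the head, the left/right front leg roots,
#' knees and hooves, the left/right hind leg roots, knees and hooves, the
#' neck, the spine and the coccyx.  All skeleton containers index keypoints
#' in this order.
#'
#' @return data.frame with columns `part_id` and `name`.
#' @examples
#' cowParts()
#' @export
cowParts <- function() .COW_PARTS

#' Look up part ids by name
#'
#' @param names character vector of part names (see [cowParts()]).
#' @return integer part ids.
#' @export
partId <- function(names) {
    id <- match(names, .COW_PARTS$name)
    if (anyNA(id))
        stop("unknown part name(s): ",
             paste(names[is.na(id)], collapse = ", "),
             "; valid names are: ", paste(.COW_PARTS$name, collapse = ", "))
    id
}

#' Construct a CowSkeleton
#'
#' @param coords numeric 16 x 2 matrix of (x, y) pixel coordinates in
#'   part-id order.  Coordinates use the image convention: origin at the
#'   top-left, x rightward, y downward, 0-based.
#' @param visibility integer vector of length 16 in {0, 1, 2}
#'   (2 visible, 1 occluded-but-labeled, 0 missing).  Default: all visible.
#' @param poseLabel optional pose class.
#' @param instanceId optional integer animal id.
#' @return a [CowSkeleton-class] object.
#' @examples
#' sk <- cowSkeleton(matrix(runif(32, 0, 100), 16, 2))
#' kpVisibility(sk)
#' @export
cowSkeleton <- function(coords, visibility = rep(2L, 16),
                        poseLabel = "unknown", instanceId = NA_integer_) {
    coords <- as.matrix(coords)
    dimnames(coords) <- list(.COW_PARTS$name, c("x", "y"))
    new("CowSkeleton", coords = coords,
        visibility = as.integer(visibility),
        poseLabel = as.character(poseLabel),
        instanceId = as.integer(instanceId))
}

#' @describeIn cowSkeleton keypoint coordinate matrix (16 x 2).
#' @param x a `CowSkeleton`.
#' @export
kpCoords <- function(x) x@coords

#' @describeIn cowSkeleton visibility flags (length 16).
#' @export
kpVisibility <- function(x) x@visibility

#' @describeIn cowSkeleton pose label.
#' @export
poseLabel <- function(x) x@poseLabel

#' @describeIn cowSkeleton number of labeled keypoints (visibility > 0).
#' @export
nLabeled <- function(x) sum(x@visibility > 0L)

setMethod("show", "CowSkeleton", function(object) {
    cat(sprintf("CowSkeleton: %d/16 labeled keypoints, pose '%s'\n",
                sum(object@visibility > 0L), object@poseLabel))
})

#' Construct a limb graph
#'
#' @param pairs character C x 2 matrix (or list of 2-element vectors) of
#'   part names, or an integer C x 2 matrix of part ids.
#' @return a [LimbGraph-class].
#' @seealso [defaultLimbGraph()]
#' @export
limbGraph <- function(pairs) {
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    if (is.character(pairs))
        pairs <- matrix(partId(pairs), ncol = 2)
    new("LimbGraph", edges = matrix(as.integer(pairs), ncol = 2))
}

#' @describeIn limbGraph integer C x 2 edge matrix of part ids.
#' @param x a `LimbGraph`.
#' @export
limbEdges <- function(x) x@edges

#' @describeIn limbGraph number of limbs.
#' @export
nLimbs <- function(x) nrow(x@edges)

setMethod("show", "LimbGraph", function(object) {
    cat(sprintf("LimbGraph with %d limbs over 16 parts\n",
                nrow(object@edges)))
})

#' The default anatomical limb tree
#'
#' A 15-edge spanning tree over the 16 parts: the head-neck-spine-coccyx
#' axis, the two front legs hanging from the neck and the two hind legs
#' hanging from the coccyx, each leg a root-knee-hoof chain.  Hooves and the
#' head are leaves.  The edge list is configurable through the pipeline
#' config for users whose labeling differs.
#'
#' @return a [LimbGraph-class] with 15 limbs.
#' @examples
#' nLimbs(defaultLimbGraph())
#' @export
defaultLimbGraph <- function() {
    limbGraph(rbind(
        c("head", "neck"),
        c("neck", "spine"),
        c("spine", "coccyx"),
        c("neck", "left_front_leg_root"),
        c("neck", "right_front_leg_root"),
        c("left_front_leg_root", "left_front_knee"),
        c("left_front_knee", "left_front_hoof"),
        c("right_front_leg_root", "right_front_knee"),
        c("right_front_knee", "right_front_hoof"),
        c("coccyx", "left_hind_leg_root"),
        c("coccyx", "right_hind_leg_root"),
        c("left_hind_leg_root", "left_hind_knee"),
        c("left_hind_knee", "left_hind_hoof"),
        c("right_hind_leg_root", "right_hind_knee"),
        c("right_hind_knee", "right_hind_hoof")))
}

#' Is a limb graph connected over the 16 parts?
#'
#' @param graph a [LimbGraph-class].
#' @return logical.
#' @export
isConnectedGraph <- function(graph) {
    e <- graph@edges
    seen <- logical(16)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
        nb <- nb[!seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
    }
    all(seen)
}

#' Tight bounding box of a skeleton's labeled keypoints
#'
#' The axis-aligned envelope of all keypoints with visibility > 0;
#' keypoints with visibility 0 are ignored.  Used as the object scale for
#' OKS and as the normalization frame for the pose classifier.
#'
#' @param skel a [CowSkeleton-class].
#' @return one-row data.frame (xmin, ymin, xmax, ymax, confidence = 1,
#'   label = "cow"); degenerate (zero-area) boxes are possible for single
#'   labeled points.
#' @examples
#' sk <- cowSkeleton(cbind(0:15, 15:0))
#' skeletonBBox(sk)
#' @export
skeletonBBox <- function(skel) {
    lab <- skel@visibility > 0L
    if (!any(lab))
        stop("empty skeleton: no keypoint has visibility > 0")
    xy <- skel@coords[lab, , drop = FALSE]
    makeBoxes(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]),
              confidence = 1)
}
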