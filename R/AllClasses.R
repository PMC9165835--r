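#' @import methods
NULL

## Canonical part table: ids 1..16 in the order the field uses for the
## bovine skeleton (head, front legs, hind legs, neck, spine, coccyx).
.COW_PARTS <- data.frame(
    part_id = 1:16,
    name = c("head",
             "left_front_leg_root", "right_front_leg_root",
             "left_front_knee", "right_front_knee",
             "left_front_hoof", "right_front_hoof",
             "left_hind_leg_root", "right_hind_leg_root",
             "left_hind_knee", "right_hind_knee",
             "left_hind_hoof", "right_hind_hoof",
             "neck", "spine", "coccyx"),
    stringsAsFactors = FALSE
)

.POSE_LEVELS <- c("standing", "walking", "lying", "unknown")

#' CowSkeleton: a 16-keypoint cow skeleton
#'
#' Holds one animal's keypoints in pixel coordinates (origin at the image
#' top-left, x rightward, y downward, 0-based) together with the three-state
#' visibility flag used by annotation tools: 2 = labeled and visible,
#' 1 = labeled but occluded, 0 = missing.  Coordinates of missing keypoints
#' (visibility 0) carry no information and are ignored by every consumer.
#'
#' @slot coords numeric 16 x 2 matrix of (x, y) pixel coordinates, rows in
#'   part-id order (see [cowParts()]).
#' @slot visibility integer vector of length 16 with values in {0, 1, 2}.
#' @slot poseLabel one of "standing", "walking", "lying", "unknown".
#' @slot instanceId optional integer identity of the animal (NA if unset).
#'
#' @seealso [cowSkeleton()], [skeletonBBox()], [cowParts()]
#' @export
setClass("CowSkeleton",
    representation(coords = "matrix", visibility = "integer",
                   poseLabel = "character", instanceId = "integer"),
    prototype(coords = matrix(0, 16, 2,
                  dimnames = list(.COW_PARTS$name, c("x", "y"))),
              visibility = integer(16),
              poseLabel = "unknown", instanceId = NA_integer_))

setValidity("CowSkeleton", function(object) {
    msg <- character()
    if (!is.numeric(object@coords) || !all(dim(object@coords) == c(16, 2)))
        msg <- c(msg, "coords must be a numeric 16 x 2 matrix")
    if (length(object@visibility) != 16L ||
        !all(object@visibility %in% 0:2))
        msg <- c(msg, "visibility must be 16 integers in {0, 1, 2}")
    if (length(object@poseLabel) != 1L ||
        !object@poseLabel %in% .POSE_LEVELS)
        msg <- c(msg, sprintf("poseLabel must be one of %s",
                              paste(.POSE_LEVELS, collapse = ", ")))
    if (length(msg) == 0 && length(object@visibility) == 16L) {
        lab <- object@visibility > 0L
        xy <- object@coords[lab, , drop = FALSE]
        if (any(!is.finite(xy)) || any(xy < 0))
            msg <- c(msg,
                "labeled keypoints (visibility > 0) need finite coords >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' LimbGraph: the limb edge set over the 16 parts
#'
#' An ordered list of (part_a, part_b) pairs defining which keypoint pairs
#' form limbs.  The limb order fixes the channel order of [PafStack] objects
#' and the matching order during grouping.  The default graph
#' ([defaultLimbGraph()]) is a 15-edge anatomical spanning tree.
#'
#' @slot edges integer C x 2 matrix of part ids in 1..16.
#' @export
setClass("LimbGraph", representation(edges = "matrix"))

setValidity("LimbGraph", function(object) {
    e <- object@edges
    if (!is.numeric(e) || ncol(e) != 2L || nrow(e) < 1L)
        return("edges must be a C x 2 matrix of part ids")
    if (!all(e %in% 1:16))
        return("part ids must be in 1..16")
    if (any(e[, 1] == e[, 2]))
        return("self-loop limbs are not allowed")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key))
        return("duplicate (unordered) limb pairs are not allowed")
    TRUE
})

#' HeatmapStack: per-part keypoint confidence grids
#'
#' One confidence channel per part; the value at pixel p is the Gaussian
#' similarity exp(-||p - x||^2 / (2 sigma^2)) to the nearest annotated
#' keypoint of that part (maximum over animals).  Stored as an
#' H x W x 16 array indexed `values[y + 1, x + 1, part_id]` for 0-based
#' pixel coordinates (x, y).
#'
#' @slot values numeric H x W x 16 array with entries in [0, 1].
#' @slot sigma Gaussian spread in pixels.
#' @export
setClass("HeatmapStack",
    representation(values = "array", sigma = "numeric"))

setValidity("HeatmapStack", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[3] != 16L)
        return("values must be an H x W x 16 array")
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
        return("sigma must be a single positive number")
    rng <- range(object@values)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        return("heatmap entries must lie in [0, 1]")
    TRUE
})

#' PafStack: per-limb part affinity fields
#'
#' Two vector-component channels per limb: at every pixel lying on a limb
#' (within `limbWidth` of the segment between its two keypoints) the field
#' holds the unit vector pointing from part_a toward part_b; elsewhere it is
#' (0, 0).  Where limbs of several animals overlap, the field is the
#' arithmetic mean of their unit vectors.  Stored as an H x W x 2 x C array,
#' `values[y + 1, x + 1, 1:2, limb]`, limb order as in the [LimbGraph].
#'
#' @slot values numeric H x W x 2 x C array; every (vx, vy) has norm <= 1.
#' @slot limbWidth half-width of the on-limb band, in pixels.
#' @slot limbGraph the [LimbGraph] defining the channel order.
#' @export
setClass("PafStack",
    representation(values = "array", limbWidth = "numeric",
                   limbGraph = "LimbGraph"))

setValidity("PafStack", function(object) {
    d <- dim(object@values)
    if (length(d) != 4L || d[3] != 2L)
        return("values must be an H x W x 2 x C array")
    if (d[4] != nrow(object@limbGraph@edges))
        return("limb channel count must match the limb graph")
    if (length(object@limbWidth) != 1L || object@limbWidth <= 0)
        return("limbWidth must be a single positive number")
    TRUE
})

#' AnnotatedImage: one image's skeletons and bounding boxes
#'
#' @slot imagePath path of the underlying raster (may be "" for in-memory
#'   scenes).
#' @slot width,height image size in pixels.
#' @slot skeletons list of [CowSkeleton] objects.
#' @slot boxes data.frame with columns xmin, ymin, xmax, ymax, confidence,
#'   label (pixel units).
#' @export
setClass("AnnotatedImage",
    representation(imagePath = "character", width = "numeric",
                   height = "numeric", skeletons = "list",
                   boxes = "data.frame"),
    prototype(imagePath = "", width = 1, height = 1, skeletons = list(),
              boxes = data.frame(xmin = numeric(), ymin = numeric(),
                                 xmax = numeric(), ymax = numeric(),
                                 confidence = numeric(),
                                 label = character())))

setValidity("AnnotatedImage", function(object) {
    if (object@width <= 0 || object@height <= 0)
        return("width and height must be positive")
    if (!all(vapply(object@skeletons, is, logical(1), "CowSkeleton")))
        return("skeletons must all be CowSkeleton objects")
    need <- c("xmin", "ymin", "xmax", "ymax", "confidence", "label")
    if (!all(need %in% names(object@boxes)))
        return(sprintf("boxes needs columns %s", paste(need, collapse = ", ")))
    b <- object@boxes
    if (nrow(b) && (any(b$xmin > b$xmax) || any(b$ymin > b$ymax)))
        return("boxes must satisfy xmin <= xmax and ymin <= ymax")
    TRUE
})

#' CowScene: a rendered synthetic scene plus its ground truth
#'
#' @slot image numeric H x W grayscale matrix in [0, 1].
#' @slot annotation the [AnnotatedImage] ground truth.
#' @slot lighting "day" or "night".
#' @slot occlusionFraction per-skeleton fraction of keypoints masked by
#'   occlusion.
#' @export
setClass("CowScene",
    representation(image = "matrix", annotation = "AnnotatedImage",
                   lighting = "character", occlusionFraction = "numeric"))

#' PoseClassifier: fully connected pose-classification network
#'
#' The skeleton-coordinate classifier: 32 inputs (x, y per part, normalized
#' to the skeleton bounding box) through three hidden layers of 128, 64 and
#' 16 units, each followed by batch normalization and ReLU, into a 4-way
#' softmax over {standing, walking, lying, other}.
#'
#' @slot params list of per-layer weights, biases and batch-norm
#'   parameters/running statistics.
#' @slot config list of architecture and training hyperparameters.
#' @slot history data.frame of per-epoch loss and accuracy (empty until
#'   trained).
#' @slot trained logical.
#' @export
setClass("PoseClassifier",
    representation(params = "list", config = "list",
                   history = "data.frame", trained = "logical"))
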