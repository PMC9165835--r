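#' Read Labelme point annotations into skeletons
#'
#' Parses a Labelme JSON file whose point shapes encode cow keypoints.
#' Labels follow the convention `"part_name:visibility"` (for example
#' `"neck:2"`); a bare part name defaults to visibility 2.  Shapes are
#' grouped into animals by Labelme's `group_id` (missing `group_id` puts a
#' shape in instance 0).  Parts absent from an instance get visibility 0.
#' Points outside the image bounds are clipped to them with a warning.
#'
#' @param path path to a Labelme JSON file.
#' @return an [AnnotatedImage-class] with one [CowSkeleton-class] per
#'   annotated instance.
#' @export
readLabelmeKeypoints <- function(path) {
    doc <- tryCatch(
        jsonlite::read_json(path, simplifyVector = FALSE),
        error = function(e)
            stop("malformed Labelme JSON in '", path, "': ",
                 conditionMessage(e)))
    w <- as.numeric(doc$imageWidth %||% stop("missing imageWidth in ", path))
    h <- as.numeric(doc$imageHeight %||% stop("missing imageHeight in ", path))
    groups <- list()
    for (shape in doc$shapes %||% list()) {
        if (!identical(shape$shape_type, "point")) next
        lab <- strsplit(as.character(shape$label), ":", fixed = TRUE)[[1]]
        pid <- partId(lab[1])
        vis <- if (length(lab) >= 2) as.integer(lab[2]) else 2L
        gid <- as.character(shape$group_id %||% 0L)
        pt <- unlist(shape$points[[1]])
        if (pt[1] < 0 || pt[1] > w || pt[2] < 0 || pt[2] > h) {
            warning(sprintf(
                "point for '%s' at (%.1f, %.1f) outside %gx%g image '%s'; clipped",
                lab[1], pt[1], pt[2], w, h, path))
            pt <- c(clamp(pt[1], 0, w), clamp(pt[2], 0, h))
        }
        if (is.null(groups[[gid]]))
            groups[[gid]] <- list(coords = matrix(0, 16, 2),
                                  vis = integer(16))
        groups[[gid]]$coords[pid, ] <- pt
        groups[[gid]]$vis[pid] <- vis
    }
    skels <- lapply(groups, function(g)
        cowSkeleton(g$coords, g$vis))
    new("AnnotatedImage",
        imagePath = as.character(doc$imagePath %||% ""),
        width = w, height = h, skeletons = unname(skels),
        boxes = emptyBoxes())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read PascalVOC XML bounding boxes
#'
#' Reads the LabelImg dialect of PascalVOC XML: one `<object>` per box with
#' `<name>` and `<bndbox>` (xmin, ymin, xmax, ymax).  Inverted boxes are
#' normalized (min/max swapped) with a warning; a missing `<size>` element
#' is an error.
#'
#' @param path path to a VOC XML file.
#' @return an [AnnotatedImage-class] with boxes only.
#' @export
readVocBoxes <- function(path) {
    doc <- xml2::read_xml(path)
    size <- xml2::xml_find_first(doc, ".//size")
    if (inherits(size, "xml_missing"))
        stop("missing <size> element in '", path, "'")
    w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
    h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
    objs <- xml2::xml_find_all(doc, ".//object")
    boxes <- emptyBoxes()
    for (obj in objs) {
        nm <- xml2::xml_text(xml2::xml_find_first(obj, "./name"))
        bb <- xml2::xml_find_first(obj, "./bndbox")
        val <- function(tag)
            as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
        x1 <- val("xmin"); y1 <- val("ymin")
        x2 <- val("xmax"); y2 <- val("ymax")
        if (x1 > x2 || y1 > y2) {
            warning(sprintf(
                "inverted box (%g,%g,%g,%g) in '%s'; normalized", x1, y1,
                x2, y2, path))
        }
        boxes <- rbind(boxes,
            makeBoxes(min(x1, x2), min(y1, y2), max(x1, x2), max(y1, y2),
                      confidence = 1, label = nm))
    }
    new("AnnotatedImage", imagePath = "", width = w, height = h,
        skeletons = list(), boxes = boxes)
}

#' Write annotated images as COCO-keypoints JSON
#'
#' Serializes a list of [AnnotatedImage-class] objects into the COCO
#' keypoints layout: `images`, `annotations` and a single `categories` entry
#' whose `keypoints` are the 16 part names and whose `skeleton` is the limb
#' graph.  Each skeleton becomes one annotation with a flat
#' `(x, y, v) x 16` keypoint vector; keypoints with visibility 0 are written
#' as `(0, 0, 0)`.  Detection boxes (if present) are written as keypoint-free
#' annotations carrying `bbox` and `score`.
#'
#' @param images list of [AnnotatedImage-class].
#' @param path output file path.
#' @param graph [LimbGraph-class] recorded in the category (default:
#'   [defaultLimbGraph()]).
#' @return `path`, invisibly.
#' @seealso [readCocoKeypoints()]
#' @export
writeCocoKeypoints <- function(images, path, graph = defaultLimbGraph()) {
    imgRecs <- list(); annRecs <- list(); annId <- 0L
    for (i in seq_along(images)) {
        img <- images[[i]]
        imgRecs[[i]] <- list(id = i, file_name = img@imagePath,
                             width = img@width, height = img@height)
        for (sk in img@skeletons) {
            annId <- annId + 1L
            kp <- numeric(48)
            for (p in 1:16) {
                v <- sk@visibility[p]
                if (v > 0L)
                    kp[(p - 1) * 3 + 1:3] <- c(sk@coords[p, ], v)
            }
            bb <- skeletonBBox(sk)
            annRecs[[annId]] <- list(
                id = annId, image_id = i, category_id = 1,
                keypoints = kp, num_keypoints = sum(sk@visibility > 0L),
                bbox = c(bb$xmin, bb$ymin, bb$xmax - bb$xmin,
                         bb$ymax - bb$ymin),
                area = (bb$xmax - bb$xmin) * (bb$ymax - bb$ymin),
                iscrowd = 0, pose = sk@poseLabel)
        }
        if (nrow(img@boxes))
            for (j in seq_len(nrow(img@boxes))) {
                annId <- annId + 1L
                b <- img@boxes[j, ]
                annRecs[[annId]] <- list(
                    id = annId, image_id = i, category_id = 1,
                    keypoints = numeric(48), num_keypoints = 0,
                    bbox = c(b$xmin, b$ymin, b$xmax - b$xmin,
                             b$ymax - b$ymin),
                    area = (b$xmax - b$xmin) * (b$ymax - b$ymin),
                    iscrowd = 0, score = b$confidence, label = b$label)
            }
    }
    doc <- list(
        images = imgRecs,
        annotations = annRecs,
        categories = list(list(
            id = 1, name = "cow", supercategory = "animal",
            keypoints = .COW_PARTS$name,
            skeleton = lapply(seq_len(nrow(graph@edges)),
                              function(k) graph@edges[k, ]))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read COCO-keypoints JSON back into annotated images
#'
#' Inverse of [writeCocoKeypoints()]: annotations with `num_keypoints > 0`
#' become skeletons (zero-visibility slots stay missing), keypoint-free
#' annotations become detection boxes.
#'
#' @param path path to a COCO-keypoints JSON file.
#' @return list of [AnnotatedImage-class], in image-id order.
#' @export
readCocoKeypoints <- function(path) {
    doc <- tryCatch(
        jsonlite::read_json(path, simplifyVector = FALSE),
        error = function(e)
            stop("malformed COCO JSON in '", path, "': ",
                 conditionMessage(e)))
    imgs <- list()
    for (rec in doc$images)
        imgs[[as.character(rec$id)]] <- new("AnnotatedImage",
            imagePath = as.character(rec$file_name %||% ""),
            width = as.numeric(rec$width), height = as.numeric(rec$height),
            skeletons = list(), boxes = emptyBoxes())
    for (ann in doc$annotations) {
        key <- as.character(ann$image_id)
        if (is.null(imgs[[key]]))
            stop("annotation ", ann$id, " references unknown image ",
                 ann$image_id)
        if ((ann$num_keypoints %||% 0) > 0) {
            kp <- unlist(ann$keypoints)
            coords <- cbind(kp[seq(1, 46, 3)], kp[seq(2, 47, 3)])
            vis <- as.integer(kp[seq(3, 48, 3)])
            sk <- cowSkeleton(coords, vis,
                              poseLabel = ann$pose %||% "unknown")
            imgs[[key]]@skeletons <-
                c(imgs[[key]]@skeletons, sk)
        } else {
            bb <- unlist(ann$bbox)
            imgs[[key]]@boxes <- rbind(imgs[[key]]@boxes,
                makeBoxes(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4],
                          confidence = ann$score %||% 1,
                          label = ann$label %||% "cow"))
        }
    }
    unname(imgs[order(as.integer(names(imgs)))])
}
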