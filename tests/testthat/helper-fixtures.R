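# Fixture builders; all annotation files are generated in code at test time.

# A fully visible skeleton at arbitrary but valid positions.
simpleSkeleton <- function(shift = c(0, 0), pose = "unknown") {
    coords <- cbind(x = seq(10, 160, by = 10) + shift[1],
                    y = rep(c(20, 60, 40, 80), 4) + shift[2])
    cowSkeleton(coords, rep(2L, 16), poseLabel = pose)
}

# Write a Labelme JSON file with `n` labeled parts for one cow.
writeLabelmeFixture <- function(path, nParts = 16, width = 640,
                                height = 480, outOfBounds = FALSE) {
    parts <- cowParts()$name[seq_len(nParts)]
    shapes <- lapply(seq_along(parts), function(i) {
        pt <- c(10 * i, 5 * i)
        if (outOfBounds && i == 1) pt <- c(width + 50, -10)
        list(label = paste0(parts[i], ":2"),
             points = list(pt), group_id = 1L,
             shape_type = "point", flags = structure(list(), names = character()))
    })
    jsonlite::write_json(
        list(version = "5.0.1", imagePath = "img.png",
             imageWidth = width, imageHeight = height, shapes = shapes),
        path, auto_unbox = TRUE, digits = NA)
    path
}

# Write a PascalVOC XML file with the given box rows.
writeVocFixture <- function(path, boxes, width = 640, height = 480,
                            omitSize = FALSE) {
    obj <- paste(vapply(seq_len(nrow(boxes)), function(i) sprintf(
        "<object><name>cow</name><bndbox><xmin>%g</xmin><ymin>%g</ymin><xmax>%g</xmax><ymax>%g</ymax></bndbox></object>",
        boxes$xmin[i], boxes$ymin[i], boxes$xmax[i], boxes$ymax[i]),
        character(1)), collapse = "")
    size <- if (omitSize) "" else sprintf(
        "<size><width>%d</width><height>%d</height><depth>3</depth></size>",
        width, height)
    writeLines(sprintf("<annotation>%s%s</annotation>", size, obj), path)
    path
}

trainSmallClassifier <- function(nPerPose = 120, epochs = 12, seed = 7) {
    ds <- samplePoseDataset(nPerPose, seed = seed)
    X <- t(vapply(ds$skeletons, featurizeSkeleton, numeric(32)))
    trainPoseClassifier(buildPoseClassifier(seed), X, ds$labels,
                        epochs = epochs, seed = seed)
}
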