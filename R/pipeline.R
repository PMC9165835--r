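.CONFIG_DEFAULTS <- list(
    sigma = 2, limbWidth = 4, peakThreshold = 0.1, scoreThreshold = 0.05,
    minParts = 4, nSamples = 10, nmsIou = 0.5, oksK = 0.1,
    oksThreshold = 0.5, epochs = 30, batchSize = 32, lr = 1e-3,
    nPerPose = 600, holdoutFraction = 0.1, nCows = 3, overlap = "none",
    lighting = "day", jitterSd = 2, bodyLength = 120, legLength = 70,
    canvasH = 270, canvasW = 480, seed = 0)

#' Pipeline configuration
#'
#' All tunable parameters of the simulate/encode/group/classify/evaluate
#' pipeline with their defaults: `sigma` (heatmap Gaussian spread, px),
#' `limbWidth` (PAF band half-width, px), `peakThreshold`,
#' `scoreThreshold`, `minParts`, `nSamples` (grouping), `nmsIou`, `oksK`,
#' `oksThreshold` (evaluation), `epochs`, `batchSize`, `lr`, `nPerPose`,
#' `holdoutFraction` (classifier), `nCows`, `overlap`, `lighting`,
#' `jitterSd`, `bodyLength`, `legLength`, `canvasH`, `canvasW` (scene) and
#' `seed`.  Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @examples
#' cfg <- poseConfig(sigma = 3, nCows = 2)
#' @export
poseConfig <- function(...) {
    over <- list(...)
    unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             "; valid keys are: ",
             paste(names(.CONFIG_DEFAULTS), collapse = ", "))
    cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
    stopifnot(cfg$sigma > 0, cfg$limbWidth > 0,
              cfg$peakThreshold > 0, cfg$peakThreshold < 1,
              cfg$minParts >= 1, cfg$nSamples >= 2,
              cfg$nmsIou > 0, cfg$nmsIou < 1, cfg$oksK > 0,
              cfg$holdoutFraction > 0, cfg$holdoutFraction < 1)
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a flat mapping of config keys; unknown keys
#'   are rejected before any computation.
#' @return as [poseConfig()].
#' @export
readPoseConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(poseConfig, vals)
}

#' Run the full synthetic pose-estimation pipeline
#'
#' Stage sequence: simulate a multi-cow scene ([composeScene()]); encode
#' ground-truth heatmaps and PAFs ([encodeHeatmaps()], [encodePafs()]);
#' group candidates back into skeletons ([decodePose()]); classify each
#' recovered skeleton's pose (training a classifier on a synthetic dataset
#' first unless one is supplied); evaluate OKS-AP against ground truth and
#' the 3 x 3 pose confusion matrix.  A stage failure is reported with the
#' stage name.  Deterministic given the config seed.
#'
#' @param config from [poseConfig()].
#' @param classifier optional pre-trained [PoseClassifier-class]; when
#'   NULL one is trained on [samplePoseDataset()] output.
#' @param outDir optional directory for the JSON report and artifacts.
#' @return list with `oksAp`, `confusion` (3 x 3 matrix), `metrics`
#'   ([confusionMetrics()] output or NULL when no poses were matched),
#'   `skeletons`, `scene` and `classifier`.
#' @export
runPipeline <- function(config = poseConfig(), classifier = NULL,
                        outDir = NULL) {
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    scene <- stage("simulate",
        composeScene(config$nCows, config$overlap, config$lighting,
                     seed = config$seed, H = config$canvasH,
                     W = config$canvasW, jitterSd = config$jitterSd,
                     bodyLength = config$bodyLength,
                     legLength = config$legLength))
    gt <- scene@annotation@skeletons
    hm <- stage("encode",
        encodeHeatmaps(gt, config$canvasH, config$canvasW, config$sigma))
    paf <- stage("encode",
        encodePafs(gt, defaultLimbGraph(), config$canvasH, config$canvasW,
                   config$limbWidth))
    grouped <- stage("group",
        decodePose(hm, paf, config$peakThreshold, config$scoreThreshold,
                   config$minParts, config$nSamples))
    if (is.null(classifier)) {
        classifier <- stage("train-pose", {
            ds <- samplePoseDataset(config$nPerPose, seed = config$seed,
                                    jitterSd = config$jitterSd,
                                    bodyLength = config$bodyLength,
                                    legLength = config$legLength)
            X <- t(vapply(ds$skeletons, featurizeSkeleton, numeric(32)))
            trainPoseClassifier(buildPoseClassifier(seed = config$seed),
                                X, ds$labels, epochs = config$epochs,
                                batchSize = config$batchSize,
                                lr = config$lr, seed = config$seed)
        })
    }
    evalRes <- stage("evaluate", {
        ap <- oksAp(grouped$skeletons, gt,
                    threshold = config$oksThreshold, k = config$oksK)
        cls <- c("standing", "walking", "lying")
        cm <- matrix(0L, 3, 3, dimnames = list(actual = cls,
                                               predicted = cls))
        for (sk in grouped$skeletons) {
            best <- which.max(vapply(gt, function(g)
                computeOks(sk, g, k = config$oksK)$value, numeric(1)))
            actual <- gt[[best]]@poseLabel
            predicted <- classifyPose(classifier, sk)$label
            if (actual %in% cls && predicted %in% cls)
                cm[actual, predicted] <- cm[actual, predicted] + 1L
        }
        list(ap = ap, cm = cm,
             metrics = if (sum(cm) > 0) confusionMetrics(cm) else NULL)
    })
    report <- list(oksAp = evalRes$ap, confusion = evalRes$cm,
                   metrics = evalRes$metrics,
                   skeletons = grouped$skeletons, scene = scene,
                   classifier = classifier)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
            list(oksAp = evalRes$ap,
                 confusion = unclass(evalRes$cm),
                 accuracy = evalRes$metrics$accuracy,
                 precision = evalRes$metrics$precision,
                 recall = evalRes$metrics$recall),
            file.path(outDir, "report.json"),
            auto_unbox = TRUE, digits = NA)
        writeScenePng(scene, file.path(outDir, "scene.png"))
        writeCocoKeypoints(
            list(new("AnnotatedImage", imagePath = "scene.png",
                     width = config$canvasW, height = config$canvasH,
                     skeletons = grouped$skeletons,
                     boxes = emptyBoxes())),
            file.path(outDir, "predictions.json"))
    }
    report
}
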