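.POSE_CLASSES <- c("standing", "walking", "lying", "other")
.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

#' Turn a skeleton into a 32-vector classifier feature
#'
#' Keypoint coordinates are translated and scaled to the skeleton's own
#' bounding box so that each present part's (x, y) lies in [0, 1]; the
#' feature is therefore invariant to pixel translation and to uniform
#' scaling of the animal in the image.  Missing parts (visibility 0) map to
#' (0, 0).  A degenerate (zero-extent) axis is scaled by `max(extent, 1)`
#' with a warning.  Feature order is (x, y) per part in part-id order.
#'
#' @param skel a [CowSkeleton-class].
#' @param normalize if `FALSE`, raw pixel coordinates are used instead of
#'   bounding-box normalization.
#' @return numeric vector of length 32.
#' @export
featurizeSkeleton <- function(skel, normalize = TRUE) {
    lab <- skel@visibility > 0L
    if (!any(lab)) stop("empty skeleton: no keypoint has visibility > 0")
    out <- numeric(32)
    xy <- skel@coords
    if (normalize) {
        xr <- range(xy[lab, 1]); yr <- range(xy[lab, 2])
        wx <- diff(xr); wy <- diff(yr)
        if (wx == 0 || wy == 0) {
            warning("degenerate skeleton bounding box; scaling by max(extent, 1)")
            wx <- max(wx, 1); wy <- max(wy, 1)
        }
        xy <- cbind((xy[, 1] - xr[1]) / wx, (xy[, 2] - yr[1]) / wy)
    }
    for (p in which(lab)) out[c(2 * p - 1, 2 * p)] <- xy[p, ]
    out
}

relu <- function(x) pmax(x, 0)

## He-style normal initialization for a dense layer.
denseInit <- function(nin, nout) {
    list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                    nin, nout),
         b = numeric(nout))
}

bnInit <- function(n) {
    list(gamma = rep(1, n), beta = numeric(n),
         runMean = numeric(n), runVar = rep(1, n))
}

#' Build the pose-classification network
#'
#' Architecture: 32 inputs, three hidden dense layers of 128, 64 and 16
#' units, each followed by batch normalization and ReLU, and a dense
#' softmax output of size 4.  The four output units are the poses
#' standing, walking and lying plus an "other/transition" unit that is
#' reported but receives no training data by default.  Initialization is
#' deterministic given `seed`.
#'
#' @param seed RNG seed for weight initialization (default 0).
#' @param hidden hidden layer widths (default `c(128, 64, 16)`).
#' @return an untrained [PoseClassifier-class].
#' @export
buildPoseClassifier <- function(seed = 0, hidden = c(128, 64, 16)) {
    sizes <- c(32, hidden, 4)
    params <- withSeed(seed, {
        p <- list(dense = list(), bn = list())
        for (l in seq_len(length(sizes) - 1)) {
            p$dense[[l]] <- denseInit(sizes[l], sizes[l + 1])
            if (l < length(sizes) - 1) p$bn[[l]] <- bnInit(sizes[l + 1])
        }
        p
    })
    new("PoseClassifier", params = params,
        config = list(sizes = sizes, classes = .POSE_CLASSES, seed = seed),
        history = data.frame(), trained = FALSE)
}

#' Number of trainable parameters of a pose classifier
#'
#' Dense weights and biases plus batch-norm scale/shift parameters
#' (running statistics are not trainable and are not counted).
#'
#' @param model a [PoseClassifier-class].
#' @return integer count.
#' @export
nParams <- function(model) {
    n <- sum(vapply(model@params$dense,
                    function(d) length(d$W) + length(d$b), numeric(1)))
    n + sum(vapply(model@params$bn,
                   function(b) length(b$gamma) + length(b$beta),
                   numeric(1)))
}

## Forward pass.  `training = TRUE` uses batch statistics (and returns the
## cache needed for backprop); inference uses running statistics.
mlpForward <- function(params, X, training = FALSE) {
    nh <- length(params$bn)
    cache <- list(A = list(X))
    A <- X
    for (l in seq_len(nh)) {
        d <- params$dense[[l]]; bn <- params$bn[[l]]
        Z <- sweep(A %*% d$W, 2, d$b, "+")
        if (training) {
            mu <- colMeans(Z)
            va <- colMeans(sweep(Z, 2, mu)^2)
        } else {
            mu <- bn$runMean; va <- bn$runVar
        }
        Zc <- sweep(Z, 2, mu)
        inv <- 1 / sqrt(va + .BN_EPS)
        Zh <- sweep(Zc, 2, inv, "*")
        Zb <- sweep(sweep(Zh, 2, bn$gamma, "*"), 2, bn$beta, "+")
        A <- relu(Zb)
        if (training)
            cache[[paste0("l", l)]] <- list(Z = Z, Zc = Zc, Zh = Zh,
                                            Zb = Zb, inv = inv, mu = mu,
                                            va = va)
        cache$A[[l + 1]] <- A
    }
    d <- params$dense[[nh + 1]]
    logits <- sweep(A %*% d$W, 2, d$b, "+")
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    probs <- e / rowSums(e)
    list(probs = probs, cache = cache)
}

## Backward pass; Y is the one-hot target matrix.  Returns gradients with
## the same structure as params plus fresh batch statistics for the
## running-average update.
mlpBackward <- function(params, fwd, Y) {
    nh <- length(params$bn)
    n <- nrow(Y)
    grads <- list(dense = vector("list", nh + 1),
                  bn = vector("list", nh))
    dZ <- (fwd$probs - Y) / n
    A <- fwd$cache$A[[nh + 1]]
    d <- params$dense[[nh + 1]]
    grads$dense[[nh + 1]] <- list(W = t(A) %*% dZ, b = colSums(dZ))
    dA <- dZ %*% t(d$W)
    for (l in nh:1) {
        cc <- fwd$cache[[paste0("l", l)]]
        bn <- params$bn[[l]]
        dZb <- dA * (cc$Zb > 0)
        grads$bn[[l]] <- list(gamma = colSums(dZb * cc$Zh),
                              beta = colSums(dZb))
        dZh <- sweep(dZb, 2, bn$gamma, "*")
        dva <- colSums(dZh * cc$Zc) * (-0.5) * cc$inv^3
        dmu <- colSums(dZh) * (-cc$inv) +
               dva * (-2) * colMeans(cc$Zc)
        dZ <- sweep(dZh, 2, cc$inv, "*") +
              sweep(cc$Zc, 2, 2 * dva / n, "*") +
              matrix(dmu / n, n, length(dmu), byrow = TRUE)
        Aprev <- fwd$cache$A[[l]]
        d <- params$dense[[l]]
        grads$dense[[l]] <- list(W = t(Aprev) %*% dZ, b = colSums(dZ))
        if (l > 1) dA <- dZ %*% t(d$W)
    }
    grads
}

## One Adam update over the flat parameter list.
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    state$t <- state$t + 1
    upd <- function(p, g, key) {
        if (is.null(state$m[[key]])) {
            state$m[[key]] <<- 0 * g
            state$v[[key]] <<- 0 * g
        }
        state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * g
        state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * g^2
        mh <- state$m[[key]] / (1 - beta1^state$t)
        vh <- state$v[[key]] / (1 - beta2^state$t)
        p - lr * mh / (sqrt(vh) + eps)
    }
    for (l in seq_along(params$dense)) {
        params$dense[[l]]$W <- upd(params$dense[[l]]$W,
                                   grads$dense[[l]]$W, paste0("dW", l))
        params$dense[[l]]$b <- upd(params$dense[[l]]$b,
                                   grads$dense[[l]]$b, paste0("db", l))
    }
    for (l in seq_along(params$bn)) {
        params$bn[[l]]$gamma <- upd(params$bn[[l]]$gamma,
                                    grads$bn[[l]]$gamma, paste0("g", l))
        params$bn[[l]]$beta <- upd(params$bn[[l]]$beta,
                                   grads$bn[[l]]$beta, paste0("be", l))
    }
    list(params = params, state = state)
}

#' Train the pose classifier
#'
#' Minimizes multiclass cross-entropy with the Adam optimizer on
#' mini-batches; batch normalization uses batch statistics during training
#' and exponentially averaged running statistics at inference.  Training is
#' deterministic given `seed` (which drives the per-epoch shuffling).
#'
#' @param model an untrained or trained [PoseClassifier-class].
#' @param features numeric n x 32 matrix (rows from
#'   [featurizeSkeleton()]).
#' @param labels character/factor of pose labels among standing, walking,
#'   lying, other; at least two classes must be present.
#' @param epochs training epochs (default 30).
#' @param batchSize mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed for shuffling (default 0).
#' @return the trained model; `@history` holds per-epoch loss and accuracy.
#' @export
trainPoseClassifier <- function(model, features, labels, epochs = 30,
                                batchSize = 32, lr = 1e-3, seed = 0) {
    X <- as.matrix(features)
    stopifnot(ncol(X) == model@config$sizes[1])
    cls <- match(as.character(labels), .POSE_CLASSES)
    if (anyNA(cls))
        stop("labels must be among: ", paste(.POSE_CLASSES, collapse = ", "))
    if (length(unique(cls)) < 2)
        stop("training needs at least two classes present")
    Y <- matrix(0, nrow(X), 4)
    Y[cbind(seq_len(nrow(X)), cls)] <- 1
    params <- model@params
    state <- list(t = 0, m = list(), v = list())
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       accuracy = numeric())
    withSeed(seed, {
        for (ep in seq_len(epochs)) {
            ord <- sample.int(nrow(X))
            starts <- seq(1, nrow(X), by = batchSize)
            for (s in starts) {
                ix <- ord[s:min(s + batchSize - 1, nrow(X))]
                if (length(ix) < 2) next  # batch norm needs >= 2 rows
                fwd <- mlpForward(params, X[ix, , drop = FALSE],
                                  training = TRUE)
                ## update running statistics
                for (l in seq_along(params$bn)) {
                    cc <- fwd$cache[[paste0("l", l)]]
                    params$bn[[l]]$runMean <-
                        .BN_MOMENTUM * params$bn[[l]]$runMean +
                        (1 - .BN_MOMENTUM) * cc$mu
                    params$bn[[l]]$runVar <-
                        .BN_MOMENTUM * params$bn[[l]]$runVar +
                        (1 - .BN_MOMENTUM) * cc$va
                }
                grads <- mlpBackward(params, fwd,
                                     Y[ix, , drop = FALSE])
                stepped <- adamStep(params, grads, state, lr)
                params <- stepped$params
                state <- stepped$state
            }
            fwd <- mlpForward(params, X, training = FALSE)
            loss <- mean(-log(pmax(fwd$probs[cbind(seq_len(nrow(X)),
                                                   cls)], 1e-12)))
            acc <- mean(max.col(fwd$probs) == cls)
            hist <- rbind(hist, data.frame(epoch = ep, loss = loss,
                                           accuracy = acc))
        }
    })
    new("PoseClassifier", params = params, config = model@config,
        history = hist, trained = TRUE)
}

#' Predict class probabilities for a feature matrix
#'
#' @param model a [PoseClassifier-class].
#' @param X numeric n x 32 matrix.
#' @return n x 4 probability matrix with columns standing, walking, lying,
#'   other.
#' @export
predictPoseProb <- function(model, X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    p <- mlpForward(model@params, X, training = FALSE)$probs
    colnames(p) <- .POSE_CLASSES
    p
}

#' Classify a skeleton's pose
#'
#' Featurizes the skeleton ([featurizeSkeleton()]) and runs the classifier;
#' probabilities are invariant to pixel translation and uniform scaling of
#' the skeleton.  The "other" unit is reported but never trained on by
#' default.
#'
#' @param model a trained [PoseClassifier-class].
#' @param skel a [CowSkeleton-class].
#' @return list with `probs` (named, sums to 1) and `label` (argmax).
#' @export
classifyPose <- function(model, skel) {
    p <- predictPoseProb(model, featurizeSkeleton(skel))[1, ]
    list(probs = p, label = names(p)[which.max(p)])
}

setMethod("show", "PoseClassifier", function(object) {
    cat(sprintf("PoseClassifier %s (%s, %d parameters)\n",
                paste(object@config$sizes, collapse = "-"),
                if (object@trained) "trained" else "untrained",
                nParams(object)))
})

#' Save or load a pose classifier
#'
#' @param model a [PoseClassifier-class].
#' @param path file path.
#' @return `savePoseClassifier` returns `path` invisibly;
#'   `loadPoseClassifier` the model.
#' @export
savePoseClassifier <- function(model, path) {
    saveRDS(model, path)
    invisible(path)
}

#' @rdname savePoseClassifier
#' @export
loadPoseClassifier <- function(path) readRDS(path)
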