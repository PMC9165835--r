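## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else
                assign(".Random.seed", old, envir = globalenv())
        }, add = TRUE)
        set.seed(as.integer(seed))
    }
    expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Empty canonical box data.frame.
emptyBoxes <- function() {
    data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
               ymax = numeric(), confidence = numeric(),
               label = character(), stringsAsFactors = FALSE)
}

makeBoxes <- function(xmin, ymin, xmax, ymax, confidence = 1,
                      label = "cow") {
    n <- length(xmin)
    data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
               xmax = as.numeric(xmax), ymax = as.numeric(ymax),
               confidence = rep_len(as.numeric(confidence), n),
               label = rep_len(as.character(label), n),
               stringsAsFactors = FALSE)
}

## Simple union-find over 1..n with path compression.
ufNew <- function(n) seq_len(n)
ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}
ufUnion <- function(parent, i, j) {
    ri <- ufFind(parent, i); rj <- ufFind(parent, j)
    if (ri != rj) parent[rj] <- ri
    parent
}
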