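# Independent brute-force oracles used across tests.

# All ordered selections of `k` items from `n` (injections row -> column).
injections <- function(n, k) {
    if (k == 0) return(list(integer()))
    out <- list()
    recurse <- function(chosen, remaining) {
        if (length(chosen) == k) {
            out[[length(out) + 1L]] <<- chosen
            return(invisible())
        }
        for (r in remaining)
            recurse(c(chosen, r), setdiff(remaining, r))
    }
    recurse(integer(), seq_len(n))
    out
}

# Maximum total score over complete one-to-one assignments of
# min(nrow, ncol) pairs, by exhaustive enumeration.
bruteForceAssignment <- function(scores) {
    nA <- nrow(scores); nB <- ncol(scores)
    flip <- nA > nB
    m <- if (flip) t(scores) else scores
    best <- -Inf; bestSel <- NULL
    for (sel in injections(ncol(m), nrow(m))) {
        tot <- sum(m[cbind(seq_len(nrow(m)), sel)])
        if (tot > best) { best <- tot; bestSel <- sel }
    }
    pairs <- cbind(a = seq_len(nrow(m)), b = bestSel)
    if (flip) pairs <- pairs[, 2:1, drop = FALSE]
    list(total = best, pairs = pairs)
}

# Quadratic-reference non-maximum suppression.
referenceNms <- function(boxes, thr) {
    remaining <- order(-boxes$confidence, seq_len(nrow(boxes)))
    keep <- integer()
    while (length(remaining)) {
        i <- remaining[1]
        keep <- c(keep, i)
        remaining <- remaining[-1]
        remaining <- remaining[vapply(remaining, function(j)
            boxIou(boxes[i, ], boxes[j, ]) < thr, logical(1))]
    }
    boxes[keep, , drop = FALSE]
}

# Direct step-sum AP: integrate the interpolated precision envelope.
referenceAp <- function(precision, recall) {
    if (!length(recall)) return(0)
    ord <- order(recall)
    r <- recall[ord]; p <- precision[ord]
    total <- 0; prev <- 0
    for (i in seq_along(r)) {
        pint <- max(p[i:length(p)])
        total <- total + (r[i] - prev) * pint
        prev <- r[i]
    }
    total
}
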