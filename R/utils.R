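# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

softmax <- function(logw) {
    w <- exp(logw - max(logw))
    w / sum(w)
}

# Named-vector signature sanity check.
checkSignature <- function(sig) {
    if (!is.numeric(sig) || is.null(names(sig)))
        stop("signature must be a named numeric vector")
    if (anyDuplicated(names(sig)))
        stop("signature gene ids must be unique")
    if (any(!is.finite(sig)))
        stop("signature contains non-finite scores")
    invisible(sig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
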