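## Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream index. Keeps results in
# [0, 2^31 - 2] so they are valid R integer seeds on every platform.
.deriveSeed <- function(seed, index) {
    as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483647)
}

.assertCount <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        x != floor(x))
        stop("'", name, "' must be a single non-negative integer")
    as.integer(x)
}

.assertScalar <- function(x, name, lower = -Inf, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("'", name, "' must be a single finite number")
    if (strict && x <= lower) stop("'", name, "' must be > ", lower)
    if (!strict && x < lower) stop("'", name, "' must be >= ", lower)
    x
}

# Run an expression under a seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Call accounting for the encoder-only deployment contract: decode() bumps
# this counter so the evaluation path can be audited.
.callEnv <- new.env(parent = emptyenv())
.callEnv$decode <- 0L

#' Number of decoder evaluations since the last reset
#'
#' The deployed detection pipeline is encoder-only: once the autoencoder is
#' trained the decoder is discarded and classification never reconstructs the
#' signal. \code{decodeCallCount} exposes a process-wide counter of
#' \code{\link{decode}} calls so this contract can be audited.
#'
#' @param reset if \code{TRUE}, reset the counter to zero after reading it.
#' @return integer count of \code{decode} evaluations.
#' @export
decodeCallCount <- function(reset = FALSE) {
    n <- .callEnv$decode
    if (reset) .callEnv$decode <- 0L
    n
}
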