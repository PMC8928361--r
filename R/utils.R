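#' @useDynLib alffradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor mad median pnorm predict pt qnorm quantile
#'   rbinom rnorm runif sd t.test var
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Classed errors so callers can distinguish failure modes.
af_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "alffradiomics_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Pipeline logging
#'
#' Stage logging used throughout the pipeline: every stage reports its seed,
#' input shapes and output dimensions so a run can be audited. Messages are
#' emitted via `message()` and suppressed unless
#' `options(alffradiomics.verbose = TRUE)`.
#'
#' @param stage character stage name.
#' @param fmt `sprintf` format string.
#' @param ... values for `fmt`.
#' @return invisibly, the formatted message.
#' @export
af_log <- function(stage, fmt, ...) {
  txt <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  if (isTRUE(getOption("alffradiomics.verbose", FALSE))) message("INFO ", txt)
  invisible(txt)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stage offset, kept inside the
# 32-bit signed range.
derive_seed <- function(base_seed, offset) {
  as.integer((as.double(base_seed) * 1000003 + offset) %% 2147483629L)
}
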