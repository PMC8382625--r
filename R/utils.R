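#' Derive a reproducible sub-seed from a top-level seed
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' top-level seed and a string label (stage name, cohort id, replicate), so
#' that regenerating one stage never perturbs another.  The derivation is a
#' small deterministic string hash, stable across platforms and R sessions.
#'
#' @param seed Integer top-level seed.
#' @param ... Character or numeric labels identifying the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", "DCS")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  label <- paste(c(format(seed), vapply(list(...), format, character(1))),
                 collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## stop with a classed condition so callers can test on error class
abort_diabclust <- function(msg, class) {
  rlang::abort(msg, class = c(class, "diabclust_error"))
}

assert_cols <- function(data, cols, what = "input") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort_diabclust(
      sprintf("%s is missing mandatory column%s: %s", what,
              if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")),
      "diabclust_schema_error")
  }
  invisible(data)
}
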