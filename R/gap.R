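#' Gap statistic over a range of cluster counts
#'
#' For each `k = 1..kmax`, compares the log within-cluster dispersion of the
#' best-of-restarts k-means solution on `X` with its expectation under `B`
#' reference data sets drawn uniformly over the observed per-column range
#' (the simplest reference distribution of the gap method).  The reported
#' spread `s_k` is the reference standard deviation inflated by
#' `sqrt(1 + 1/B)` to account for the Monte Carlo error of the mean.
#'
#' @param X Numeric data matrix (typically a z-score matrix).
#' @param kmax Largest number of clusters to evaluate (>= 2).
#' @param B Number of reference data sets (>= 10, default 50).
#' @param seed Integer seed; reference draws and k-means restarts derive
#'   sub-seeds from it.
#' @param n_restarts Restarts per k-means fit (default 10; dispersion curves
#'   need many fits, so fewer restarts than a final fit).
#' @return A `gap_curve` tibble with columns `k`, `log_W` (observed),
#'   `E_log_W` (reference mean), `s` (inflated reference sd) and
#'   `gap = E_log_W - log_W`.
#' @seealso [select_k()]
#' @export
gap_statistic <- function(X, kmax, B = 50, seed = 1, n_restarts = 10) {
  X <- as.matrix(X)
  if (kmax < 2) abort_diabclust("kmax must be at least 2", "diabclust_usage_error")
  if (B < 10) abort_diabclust("B must be at least 10", "diabclust_usage_error")
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, range)

  # fits chained over increasing k: the previous solution's centroids plus
  # the point farthest from its centroid seed one extra restart, so W_k is
  # non-increasing in k by construction
  logW_for <- function(M, seed_base) {
    W <- numeric(kmax)
    prev <- NULL
    for (k in seq_len(kmax)) {
      warm <- NULL
      if (!is.null(prev)) {
        resid <- rowSums((M - prev$centroids[prev$cluster, , drop = FALSE])^2)
        warm <- rbind(prev$centroids, M[which.max(resid), ])
      }
      fit <- kmeans_restarts(M, k, n_restarts = n_restarts,
                             seed = derive_seed(seed_base, "k", k),
                             warm_start = warm)
      W[k] <- fit$objective
      prev <- fit
    }
    log(W)
  }
  log_W <- logW_for(X, derive_seed(seed, "obs"))
  ref <- matrix(NA_real_, B, kmax)
  for (b in seq_len(B)) {
    M <- with_seed(derive_seed(seed, "ref", b), {
      matrix(runif(n * p), n, p) %*% diag(rng[2, ] - rng[1, ], p) +
        matrix(rng[1, ], n, p, byrow = TRUE)
    })
    ref[b, ] <- logW_for(M, derive_seed(seed, "reffit", b))
  }
  structure(tibble(k = seq_len(kmax),
                   log_W = log_W,
                   E_log_W = colMeans(ref),
                   s = apply(ref, 2, sd) * sqrt(1 + 1 / B),
                   gap = colMeans(ref) - log_W),
            class = c("gap_curve", "tbl_df", "tbl", "data.frame"),
            B = B, n_restarts = n_restarts, seed = seed)
}

#' Choose the number of clusters from a gap curve
#'
#' Two selection rules.  `"one_se"` is the standard conservative rule: the
#' smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}`.  `"flatten"` mirrors
#' reading the curve by eye for its flattening point: the smallest `k` whose
#' forward increment `Gap(k+1) - Gap(k)` falls below `flatten_eps` times the
#' largest forward increment (little added value in increasing `k` further).
#'
#' @param curve A `gap_curve` from [gap_statistic()].
#' @param rule `"one_se"` or `"flatten"`.
#' @param flatten_eps Relative increment threshold for the flatten rule
#'   (default 0.25).
#' @return The selected `k`, in `[1, kmax]`.
#' @export
#' @examples
#' curve <- tibble::tibble(k = 1:6, gap = c(0.2, 0.5, 0.7, 0.9, 0.92, 0.93),
#'                         s = rep(0.05, 6))
#' class(curve) <- c("gap_curve", class(curve))
#' select_k(curve, "one_se")   # 4
select_k <- function(curve, rule = c("one_se", "flatten"), flatten_eps = 0.25) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "gap_curve"), all(c("k", "gap", "s") %in% names(curve)))
  gap <- curve$gap; s <- curve$s; kmax <- max(curve$k)
  if (rule == "one_se") {
    for (k in seq_len(kmax - 1)) {
      if (gap[k] >= gap[k + 1] - s[k + 1]) return(k)
    }
    return(kmax)
  }
  inc <- diff(gap)
  if (all(inc <= 0)) return(1L)
  thr <- flatten_eps * max(inc)
  # search from the steepest rise onward: an early shallow increment before
  # the curve's main ascent is not yet "flattening"
  for (k in which.max(inc):(kmax - 1)) {
    if (inc[k] < thr) return(k)
  }
  kmax
}

#' Plot a gap curve
#'
#' Gap statistic against the number of clusters, with `+/- s_k` error bars.
#'
#' @param object A `gap_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gap_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$s,
                                          ymax = .data$gap + .data$s)) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)") +
    ggplot2::theme_minimal()
}
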