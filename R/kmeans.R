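#' Standardize the clustering variables of one sex stratum
#'
#' Extracts the five clustering variables for subjects of the given sex and
#' z-scores each column (sample standard deviation, `n - 1` denominator).
#' Standardization is always per cohort and per sex, so that no variable
#' dominates the squared-Euclidean metric through its numeric range.
#'
#' @param cohort A cohort tibble.
#' @param sex `"male"` or `"female"`.
#' @return A list: `z`, an n x 5 matrix (rownames = subject ids) with each
#'   column mean 0 and sd 1; and `scaler`, the fitted per-variable means and
#'   sds (a `diabclust_scaler`), reusable via [apply_scaler()].
#' @export
standardize <- function(cohort, sex = c("male", "female")) {
  sex <- match.arg(sex)
  assert_cols(cohort, c("subject_id", "sex", CLUSTER_VARS), "cohort")
  sub <- cohort[cohort$sex == sex & complete.cases(cohort[CLUSTER_VARS]), ,
                drop = FALSE]
  if (nrow(sub) < 2) {
    abort_diabclust(sprintf("need at least 2 complete %s subjects to standardize",
                            sex), "diabclust_data_error")
  }
  X <- as.matrix(sub[CLUSTER_VARS])
  rownames(X) <- sub$subject_id
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  zero <- which(sdev == 0)
  if (length(zero) > 0) {
    abort_diabclust(sprintf("variable %s has zero variance in the %s stratum",
                            CLUSTER_VARS[zero[1]], sex), "diabclust_data_error")
  }
  scaler <- structure(list(mean = mu, sd = sdev, variables = CLUSTER_VARS),
                      class = "diabclust_scaler")
  list(z = apply_scaler(scaler, sub), scaler = scaler)
}

#' Apply a fitted scaler to new subjects
#'
#' @param scaler A `diabclust_scaler` from [standardize()].
#' @param cohort A cohort tibble (or any data frame with the five clustering
#'   variables).
#' @return An n x 5 z-score matrix in the scaler's variable order.
#' @export
apply_scaler <- function(scaler, cohort) {
  stopifnot(inherits(scaler, "diabclust_scaler"))
  assert_cols(cohort, scaler$variables, "data")
  X <- as.matrix(cohort[scaler$variables])
  if ("subject_id" %in% names(cohort)) rownames(X) <- cohort$subject_id
  sweep(sweep(X, 2, scaler$mean, `-`), 2, scaler$sd, `/`)
}

#' k-means with random restarts
#'
#' Lloyd's algorithm under the squared-Euclidean metric, run from
#' `n_restarts` random-point initializations; the restart with the smallest
#' total within-cluster sum of squares is returned.  Distance ties assign to
#' the lowest cluster index; a cluster that empties during iteration is
#' reseeded to the point farthest from its current centroid.  Fully
#' deterministic given `seed`.
#'
#' @param X Numeric data matrix (rows = observations).
#' @param k Number of clusters; must not exceed the number of distinct rows.
#' @param n_restarts Number of random initializations (default 100).
#' @param seed Integer seed for the initializations.
#' @param max_iter Iteration cap per restart (default 300).
#' @param warm_start Optional k x p matrix of starting centroids evaluated as
#'   one extra (deterministic) restart — used when chaining fits across
#'   increasing `k` so the dispersion curve is non-increasing by
#'   construction.
#' @return A `kmeans_solution`: `centroids` (k x p), `cluster` (integer
#'   assignment, named by rownames), `objective` (total within-cluster sum
#'   of squares), `n_iter`, `restart_index` (0 when the warm start won), `k`.
#' @export
kmeans_restarts <- function(X, k, n_restarts = 100, seed = 1, max_iter = 300,
                            warm_start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_distinct_rows <- nrow(unique(X))
  if (k > n_distinct_rows) {
    abort_diabclust(sprintf("k = %d exceeds the %d distinct rows of X",
                            k, n_distinct_rows), "diabclust_data_error")
  }
  init <- with_seed(seed, {
    m <- matrix(0L, n_restarts, k)
    for (r in seq_len(n_restarts)) m[r, ] <- sample.int(n, k)
    m
  })
  fit <- lloyd_kmeans(X, init, as.integer(max_iter))
  if (!is.null(warm_start)) {
    stopifnot(ncol(warm_start) == ncol(X), nrow(warm_start) == k)
    warm <- lloyd_from_centers(X, warm_start, as.integer(max_iter))
    if (warm$tot_withinss < fit$tot_withinss) {
      fit <- warm
      fit$restart <- 0L      # 0 marks the warm start
    }
  }
  cl <- fit$cluster
  names(cl) <- rownames(X)
  structure(list(centroids = fit$centers, cluster = cl,
                 objective = fit$tot_withinss, n_iter = fit$iter,
                 restart_index = fit$restart, k = k),
            class = "kmeans_solution")
}

#' @export
print.kmeans_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, n = %d, W = %.4f (restart %d, %d iterations)\n",
              x$k, length(x$cluster), x$objective, x$restart_index, x$n_iter))
  invisible(x)
}
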