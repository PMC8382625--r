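# all permutations of 1..k, one per row (k is small: k! pairings are searched
# exhaustively when merging per-sex solutions)
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Match two centroid sets by minimal total squared distance
#'
#' Finds the permutation `p` minimizing
#' `sum_i || centroids_a[i, ] - centroids_b[p[i], ] ||^2` by exhaustive
#' search over all `k!` pairings.  Used to merge the independently fitted
#' male and female solutions into unified cluster ids, and as the fallback
#' alignment between cohort models.
#'
#' @param centroids_a,centroids_b Two k x p centroid matrices with equal `k`.
#' @return An integer permutation `p` with attribute `"cost"`, such that row
#'   `i` of `centroids_a` is matched to row `p[i]` of `centroids_b`.
#' @export
merge_sexes <- function(centroids_a, centroids_b) {
  ka <- nrow(centroids_a); kb <- nrow(centroids_b)
  if (ka != kb) {
    abort_diabclust(sprintf("centroid sets have different k (%d vs %d)", ka, kb),
                    "diabclust_usage_error")
  }
  if (ka > 9) {
    abort_diabclust("exhaustive centroid matching supports k <= 9",
                    "diabclust_usage_error")
  }
  cost <- outer(seq_len(ka), seq_len(ka),
                Vectorize(function(i, j) sum((centroids_a[i, ] - centroids_b[j, ])^2)))
  perms <- all_permutations(ka)
  total_cost <- vapply(seq_len(nrow(perms)), function(r)
    sum(cost[cbind(seq_len(ka), perms[r, ])]), numeric(1))
  best <- which.min(total_cost)
  structure(perms[best, ], cost = total_cost[best])
}

#' Fit a sex-stratified cluster model for one cohort
#'
#' Standardizes and clusters the male and female strata independently
#' (per-sex z-scoring, then [kmeans_restarts()]), and merges the two
#' solutions into unified cluster ids by minimal-cost centroid matching
#' ([merge_sexes()]).  Cluster ids follow the male solution; the female
#' centroids are re-indexed through the matching permutation.
#'
#' @param cohort A cohort tibble with complete clustering variables.
#' @param k Number of clusters (default 5).
#' @param n_restarts Restarts per sex (default 100).
#' @param seed Top-level seed; per-sex sub-seeds are derived from it.
#' @param min_per_sex Minimum complete subjects required per sex
#'   (default `10 * k`).
#' @return A `cluster_model`: per-sex scalers and centroids (rows = unified
#'   cluster id, z-space), the sex-merge permutation, per-subject
#'   assignments, and slots for archetype names (see [name_archetypes()]).
#' @export
#' @examples
#' sim <- simulate_cross_section(mixture_config(n_subjects = 400, seed = 3), "DCS")
#' model <- fit_sex_stratified(sim$cohort, k = 5, n_restarts = 10, seed = 1)
#' model
fit_sex_stratified <- function(cohort, k = 5, n_restarts = 100, seed = 1,
                               min_per_sex = 10 * k) {
  assert_cols(cohort, c("subject_id", "cohort_id", "sex", CLUSTER_VARS), "cohort")
  fits <- list()
  for (sx in c("male", "female")) {
    n_sx <- sum(cohort$sex == sx & complete.cases(cohort[CLUSTER_VARS]))
    if (n_sx < min_per_sex) {
      abort_diabclust(sprintf("only %d complete %s subjects; %d required for k = %d",
                              n_sx, sx, min_per_sex, k), "diabclust_data_error")
    }
    std <- standardize(cohort, sx)
    km <- kmeans_restarts(std$z, k, n_restarts = n_restarts,
                          seed = derive_seed(seed, "kmeans", sx))
    fits[[sx]] <- list(scaler = std$scaler, km = km)
  }
  perm <- merge_sexes(fits$male$km$centroids, fits$female$km$centroids)
  centroids <- list(male = fits$male$km$centroids,
                    female = fits$female$km$centroids[perm, , drop = FALSE])
  for (sx in c("male", "female")) {
    colnames(centroids[[sx]]) <- CLUSTER_VARS
  }
  inv <- order(perm)   # female raw index -> unified id
  assignments <- bind_rows(
    tibble(subject_id = names(fits$male$km$cluster),
           cluster = as.integer(fits$male$km$cluster)),
    tibble(subject_id = names(fits$female$km$cluster),
           cluster = inv[fits$female$km$cluster]))
  structure(list(cohort_id = cohort$cohort_id[1], k = k,
                 variables = CLUSTER_VARS,
                 scalers = list(male = fits$male$scaler,
                                female = fits$female$scaler),
                 centroids = centroids,
                 merge_permutation = as.integer(perm),
                 merge_cost = attr(perm, "cost"),
                 objective = c(male = fits$male$km$objective,
                               female = fits$female$km$objective),
                 assignments = assignments,
                 archetypes = NULL, naming_evidence = NULL,
                 n_restarts = n_restarts, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Sex-stratified cluster model: cohort %s, k = %d, %d subjects\n",
              x$cohort_id, x$k, nrow(x$assignments)))
  if (!is.null(x$archetypes)) {
    cat("  archetypes:", paste(sprintf("%d=%s", seq_len(x$k), x$archetypes),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a cluster model: one row per cluster and sex with z-profile
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return A tibble `cluster`, `archetype`, `sex`, one column per clustering
#'   variable (z-scale centroid), and `n` subjects assigned.
#' @export
tidy.cluster_model <- function(x, ...) {
  sizes <- x$assignments |> count(.data$cluster)
  out <- purrr::map_dfr(c("male", "female"), function(sx) {
    as_tibble(x$centroids[[sx]]) |>
      mutate(cluster = row_number(), sex = sx, .before = 1)
  })
  out |>
    mutate(archetype = if (is.null(x$archetypes)) NA_character_ else
      x$archetypes[.data$cluster], .after = "cluster") |>
    left_join(rename(sizes, n_cluster = "n"), by = "cluster")
}

#' @export
glance.cluster_model <- function(x, ...) {
  tibble(cohort_id = x$cohort_id, k = x$k, n = nrow(x$assignments),
         objective_male = x$objective[["male"]],
         objective_female = x$objective[["female"]],
         merge_cost = x$merge_cost, named = !is.null(x$archetypes))
}

#' Serialize a cluster model to JSON
#'
#' The JSON carries everything needed to classify new subjects: variable
#' order, per-sex scalers, per-sex centroids in unified order, the sex-merge
#' permutation, archetype names, `k`, the seed and the package version.
#'
#' @param model A `cluster_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  ser <- list(
    cohort_id = model$cohort_id, k = model$k, variables = model$variables,
    scalers = lapply(model$scalers, function(s)
      list(mean = as.list(s$mean), sd = as.list(s$sd))),
    centroids = lapply(model$centroids, function(m)
      lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))),
    merge_permutation = model$merge_permutation,
    archetypes = model$archetypes,
    n_restarts = model$n_restarts, seed = model$seed,
    package_version = as.character(utils::packageVersion("diabclust")))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  raw <- jsonlite::read_json(path)
  scalers <- lapply(raw$scalers, function(s)
    structure(list(mean = unlist(s$mean), sd = unlist(s$sd),
                   variables = unlist(raw$variables)),
              class = "diabclust_scaler"))
  centroids <- lapply(raw$centroids, function(m) {
    mat <- do.call(rbind, lapply(m, unlist))
    colnames(mat) <- unlist(raw$variables)
    mat
  })
  structure(list(cohort_id = raw$cohort_id, k = raw$k,
                 variables = unlist(raw$variables),
                 scalers = scalers, centroids = centroids,
                 merge_permutation = unlist(raw$merge_permutation),
                 merge_cost = NA_real_,
                 objective = c(male = NA_real_, female = NA_real_),
                 assignments = NULL,
                 archetypes = if (is.null(raw$archetypes)) NULL else
                   unlist(raw$archetypes),
                 naming_evidence = NULL,
                 n_restarts = raw$n_restarts, seed = raw$seed),
            class = "cluster_model")
}
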