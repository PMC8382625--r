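# minimal hand-built cluster model
toy_model <- function(centroids, archetypes = NULL) {
  scaler <- structure(list(mean = setNames(rep(0, 5), diabclust::cohort_schema()[5:9]),
                           sd = setNames(rep(1, 5), diabclust::cohort_schema()[5:9]),
                           variables = c("age_at_first_visit", "bmi",
                                         "hba1c_mmol_mol", "c_peptide_nmol_l",
                                         "hdl_mmol_l")),
                      class = "diabclust_scaler")
  colnames(centroids) <- scaler$variables
  structure(list(cohort_id = "toy", k = nrow(centroids),
                 variables = scaler$variables,
                 scalers = list(male = scaler, female = scaler),
                 centroids = list(male = centroids, female = centroids),
                 merge_permutation = seq_len(nrow(centroids)),
                 archetypes = archetypes),
            class = "cluster_model")
}

one_hot_centroids <- function() {
  # +2 on the defining variable of each archetype, in scrambled row order:
  # row 1 high hdl (MDH), row 2 high hba1c (SIDD), row 3 high bmi (MOD),
  # row 4 high c-peptide (SIRD), row 5 plain (MD)
  rbind(c(0, 0, 0, 0, 2),
        c(0, 0, 2, 0, 0),
        c(0, 2, 0, 0, 0),
        c(0, 0, 0, 2, 0),
        c(0, 0, 0, 0, 0))
}

test_that("centroid matching finds the identity, known shuffles and the brute-force optimum", {
  set.seed(2); C <- matrix(rnorm(25), 5, 5)
  p_id <- merge_sexes(C, C)
  expect_equal(as.integer(p_id), 1:5)
  expect_equal(attr(p_id, "cost"), 0)

  shuffle <- c(3, 1, 5, 2, 4)
  p <- merge_sexes(C, C[shuffle, ])
  expect_equal(shuffle[as.integer(p)], 1:5)  # recovers the applied shuffle

  for (i in 1:10) {
    set.seed(100 + i)
    A <- matrix(rnorm(25), 5, 5); B <- matrix(rnorm(25), 5, 5)
    got <- merge_sexes(A, B)
    costs <- vapply(oracle_perms(5), function(pp)
      sum((A - B[pp, ])^2), numeric(1))
    expect_equal(attr(got, "cost"), min(costs))
  }
  expect_error(merge_sexes(matrix(0, 4, 5), matrix(0, 5, 5)),
               class = "diabclust_usage_error")
})

test_that("archetype naming is the expected bijection and is index-invariant", {
  m <- name_archetypes(toy_model(one_hot_centroids()))
  expect_equal(m$archetypes, c("MDH", "SIDD", "MOD", "SIRD", "MD"))

  perm <- c(4, 2, 5, 1, 3)
  m2 <- name_archetypes(toy_model(one_hot_centroids()[perm, ]))
  expect_equal(m2$archetypes, m$archetypes[perm])  # same name per centroid

  expect_error(name_archetypes(toy_model(one_hot_centroids()[1:4, ])),
               class = "diabclust_usage_error")
})

test_that("naming matches the generator's archetypes on synthetic cohorts", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_cross_section(mixture_config(n_subjects = 1500,
                                                 seed = 600 + s), "A")
    m <- name_archetypes(fit_sex_stratified(sim$cohort, 5, n_restarts = 10,
                                            seed = s))
    est <- assign_clusters(sim$cohort, m)
    truth <- sim$labels$archetype[match(est$subject_id, sim$labels$subject_id)]
    tab <- table(truth, est$archetype)
    # a cluster is correctly named when its majority truth class agrees
    sum(vapply(rownames(tab), function(a)
      colnames(tab)[which.max(tab[a, ])] == a, logical(1)))
  }, numeric(1))
  expect_true(all(hits >= 4))
})

test_that("assignment is nearest-centroid with deterministic tie-breaking", {
  C <- one_hot_centroids()
  m <- name_archetypes(toy_model(C))
  at_centroid <- tibble::tibble(
    subject_id = "x", cohort_id = "toy", sex = "male",
    age_at_first_visit = 0, bmi = 2, hba1c_mmol_mol = 0,
    c_peptide_nmol_l = 0, hdl_mmol_l = 0)
  expect_equal(assign_clusters(at_centroid, m)$cluster, 3)
  expect_equal(assign_clusters(at_centroid, m)$archetype, "MOD")

  # equidistant to centroids 2 (hba1c) and 4 (c-peptide): lowest index wins
  tie <- at_centroid
  tie$bmi <- 0; tie$hba1c_mmol_mol <- 1; tie$c_peptide_nmol_l <- 1
  expect_equal(assign_clusters(tie, m)$cluster, 2)

  other_sex <- at_centroid; other_sex$sex <- "other"
  expect_error(assign_clusters(other_sex, m), class = "diabclust_usage_error")
  incomplete <- at_centroid; incomplete$bmi <- NA
  expect_error(assign_clusters(incomplete, m), class = "diabclust_data_error")
})

test_that("self-validation yields a diagonal confusion with unit sensitivity", {
  sim <- simulate_cross_section(mixture_config(n_subjects = 800, seed = 31), "A")
  m <- name_archetypes(fit_sex_stratified(sim$cohort, 5, n_restarts = 10, seed = 3))
  cv <- cross_validate(sim$cohort, m, m)
  expect_true(all(cv$metrics$sensitivity == 1))
  expect_true(all(cv$metrics$specificity == 1))
  expect_equal(sum(cv$table) - sum(diag(cv$table)), 0)
})

test_that("sensitivity, specificity and exact CIs match hand and stats::binom.test values", {
  # hand matrix [[90, 10], [20, 80]]
  ref <- rep(c("A", "B"), c(100, 100))
  pred <- c(rep("A", 90), rep("B", 10), rep("A", 20), rep("B", 80))
  cm <- compare_to_external(tibble::tibble(subject_id = as.character(1:200),
                                           archetype = pred),
                            tibble::tibble(subject_id = as.character(1:200),
                                           label = ref))
  mA <- cm$metrics[cm$metrics$archetype == "A", ]
  expect_equal(mA$sensitivity, 0.90)
  expect_equal(mA$specificity, 0.80)
  bt_sens <- stats::binom.test(90, 100)$conf.int
  bt_spec <- stats::binom.test(80, 100)$conf.int
  expect_equal(c(mA$sens_lo, mA$sens_hi), as.numeric(bt_sens), tolerance = 1e-10)
  expect_equal(c(mA$spec_lo, mA$spec_hi), as.numeric(bt_spec), tolerance = 1e-10)
  # CI contains the point estimate; width shrinks with n at fixed proportion
  expect_true(mA$sens_lo <= mA$sensitivity && mA$sensitivity <= mA$sens_hi)
  w100 <- diff(as.numeric(stats::binom.test(90, 100)$conf.int))
  ours_1000 <- compare_to_external(
    tibble::tibble(subject_id = as.character(1:1000),
                   archetype = rep(c("A", "B"), c(900, 100))),
    tibble::tibble(subject_id = as.character(1:1000),
                   label = rep("A", 1000)))
  m1000 <- ours_1000$metrics
  expect_lt(m1000$sens_hi[1] - m1000$sens_lo[1], w100)
})

test_that("confusion metrics equal brute-force recomputation from the raw labels", {
  set.seed(55)
  sim <- simulate_cross_section(mixture_config(n_subjects = 500, seed = 9), "A")
  ma <- name_archetypes(fit_sex_stratified(sim$cohort, 5, 10, seed = 1))
  simb <- simulate_cross_section(mixture_config(n_subjects = 500, seed = 10), "B")
  mb <- name_archetypes(fit_sex_stratified(simb$cohort, 5, 10, seed = 2))
  cv <- cross_validate(sim$cohort, ma, mb)
  ref <- assign_clusters(sim$cohort, ma)$archetype
  pred <- assign_clusters(sim$cohort, mb)$archetype
  for (a in unique(ref)) {
    row <- cv$metrics[cv$metrics$archetype == a, ]
    expect_equal(row$sensitivity, sum(ref == a & pred == a) / sum(ref == a))
    expect_equal(row$specificity, sum(ref != a & pred != a) / sum(ref != a))
  }
  expect_equal(sum(cv$table), 500)
  expect_equal(unname(rowSums(cv$table)),
               as.numeric(table(factor(ref, rownames(cv$table)))))
})

test_that("cross-validation is invariant to either model's internal cluster indexing", {
  sim <- simulate_cross_section(mixture_config(n_subjects = 400, seed = 17), "A")
  ma <- name_archetypes(fit_sex_stratified(sim$cohort, 5, 10, seed = 4))
  simb <- simulate_cross_section(mixture_config(n_subjects = 400, seed = 18), "B")
  mb <- name_archetypes(fit_sex_stratified(simb$cohort, 5, 10, seed = 5))
  base <- cross_validate(sim$cohort, ma, mb)

  perm <- c(5, 3, 1, 4, 2)
  mb_perm <- mb
  mb_perm$centroids <- lapply(mb$centroids, function(m) m[perm, ])
  mb_perm$archetypes <- mb$archetypes[perm]
  shuffled <- cross_validate(sim$cohort, ma, mb_perm)
  expect_equal(shuffled$metrics, base$metrics)
  expect_equal(shuffled$table, base$table)

  unnamed <- mb; unnamed$archetypes <- NULL
  expect_error(cross_validate(sim$cohort, ma, unnamed),
               class = "diabclust_usage_error")
})

test_that("external comparison pools merged archetypes and checks subject coverage", {
  ids <- sprintf("p%02d", 1:40)
  predicted <- tibble::tibble(subject_id = ids,
                              archetype = rep(c("MD", "MDH", "SIDD", "SIRD"), 10))
  external <- tibble::tibble(subject_id = ids,
                             label = rep(c("MARD", "MARD", "SIDD", "SIRD"), 10))
  pooled <- compare_to_external(predicted, external, merge = c("MD", "MDH"))
  mard <- pooled$metrics[pooled$metrics$archetype == "MARD", ]
  expect_equal(mard$sensitivity, 1.0)
  expect_equal(mard$matched_prediction, "MD+MDH")

  unpooled <- compare_to_external(predicted, external)
  u <- unpooled$metrics[unpooled$metrics$archetype == "MARD", ]
  expect_gte(mard$sensitivity, u$sensitivity)  # pooling can only help

  # identical label sets, no merge: identity confusion
  same <- compare_to_external(
    tibble::tibble(subject_id = ids, archetype = external$label), external)
  expect_true(all(same$metrics$sensitivity == 1))

  expect_error(compare_to_external(predicted[-1, ], external), "p01",
               class = "diabclust_usage_error")
})

test_that("confusion results serialize to CSV and JSON", {
  ids <- as.character(1:20)
  cm <- compare_to_external(
    tibble::tibble(subject_id = ids, archetype = rep(c("A", "B"), 10)),
    tibble::tibble(subject_id = ids, label = rep(c("A", "B"), 10)))
  prefix <- file.path(withr::local_tempdir(), "cv")
  write_confusion(cm, prefix)
  expect_true(file.exists(paste0(prefix, ".json")))
  counts <- readr::read_csv(paste0(prefix, "_counts.csv"),
                            show_col_types = FALSE)
  expect_equal(sum(counts$count), 20)
  expect_s3_class(tidy(cm), "tbl_df")
  expect_equal(glance(cm)$accuracy, 1)
})
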