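# two standing oral prescriptions covering the whole window
two_orals <- function(id = "s1") {
  dplyr::bind_rows(rx_row(id, "metformin", FALSE, 0, 1460),
                   rx_row(id, "sulfonylurea", FALSE, 0, 1460))
}

test_that("episode merging follows the gap rule", {
  single <- rx_row("s1", "insulin", TRUE, 100, 300)
  ep <- treatment_episodes(single)
  expect_equal(nrow(ep), 1)
  expect_equal(as.numeric(ep$episode_start - as.Date("2010-01-01")), 100)
  expect_equal(ep$duration_days, 200)

  # two insulin intervals 30 days apart merge under a 90-day gap
  near <- dplyr::bind_rows(rx_row("s1", "insulin", TRUE, 0, 100),
                           rx_row("s1", "insulin", TRUE, 130, 300))
  ep <- treatment_episodes(near, max_gap_days = 90)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_days, 300)
  expect_equal(ep$n_intervals, 2L)

  # 120 days apart stay two episodes
  far <- dplyr::bind_rows(rx_row("s1", "insulin", TRUE, 0, 100),
                          rx_row("s1", "insulin", TRUE, 220, 300))
  ep <- treatment_episodes(far, max_gap_days = 90)
  expect_equal(nrow(ep), 2)

  # nested/overlapping intervals collapse; open end extends indefinitely
  messy <- dplyr::bind_rows(rx_row("s1", "metformin", FALSE, 0, 200),
                            rx_row("s1", "metformin", FALSE, 50, 120),
                            rx_row("s1", "metformin", FALSE, 250, NA))
  ep <- treatment_episodes(messy, max_gap_days = 90)
  expect_equal(nrow(ep), 1)
  expect_true(is.na(ep$episode_end))
  expect_equal(ep$duration_days, Inf)

  bad <- rx_row("s1", "insulin", TRUE, 100, 50)
  expect_error(treatment_episodes(bad), class = "diabclust_invariant_error")
})

test_that("sustained insulin requires strictly more than the minimum duration", {
  ep200 <- detect_sustained_insulin(rx_row("s1", "insulin", TRUE, 400, 600))
  expect_equal(nrow(ep200), 1)
  expect_equal(as.numeric(ep200$event_date - as.Date("2010-01-01")), 400)

  expect_equal(nrow(detect_sustained_insulin(
    rx_row("s1", "insulin", TRUE, 400, 500))), 0)             # 100 days
  expect_equal(nrow(detect_sustained_insulin(
    rx_row("s1", "insulin", TRUE, 400, 583))), 0)             # exactly 183
  expect_equal(nrow(detect_sustained_insulin(
    rx_row("s1", "insulin", TRUE, 400, 584))), 1)             # 184 days
  expect_equal(nrow(detect_sustained_insulin(two_orals())), 0) # no insulin at all
})

test_that("the glycaemic pathway needs two high values, separation and two oral classes", {
  cfg <- endpoint_config()
  base_hba <- dplyr::bind_rows(hba_row("s1", 100, 75), hba_row("s1", 220, 72))

  hit <- detect_glycaemic_requirement(base_hba, two_orals(), cfg)
  expect_equal(as.numeric(hit$event_date - as.Date("2010-01-01")), 220)

  # only one oral class active: no event
  one <- rx_row("s1", "metformin", FALSE, 0, 1460)
  expect_equal(nrow(detect_glycaemic_requirement(base_hba, one, cfg)), 0)

  # 70 then 68: second value not above threshold
  low2 <- dplyr::bind_rows(hba_row("s1", 100, 70), hba_row("s1", 220, 68))
  expect_equal(nrow(detect_glycaemic_requirement(low2, two_orals(), cfg)), 0)

  # threshold is strict: 69 exactly does not qualify, 69.1 does
  at <- dplyr::bind_rows(hba_row("s1", 100, 69), hba_row("s1", 220, 69))
  expect_equal(nrow(detect_glycaemic_requirement(at, two_orals(), cfg)), 0)
  just <- dplyr::bind_rows(hba_row("s1", 100, 69.1), hba_row("s1", 220, 69.1))
  expect_equal(nrow(detect_glycaemic_requirement(just, two_orals(), cfg)), 1)

  # separation boundary: exactly 90 days qualifies, 89 does not
  at90 <- dplyr::bind_rows(hba_row("s1", 100, 75), hba_row("s1", 190, 75))
  expect_equal(as.numeric(detect_glycaemic_requirement(at90, two_orals(), cfg)$event_date -
                            as.Date("2010-01-01")), 190)
  at89 <- dplyr::bind_rows(hba_row("s1", 100, 75), hba_row("s1", 189, 75))
  expect_equal(nrow(detect_glycaemic_requirement(at89, two_orals(), cfg)), 0)

  # the second oral class must be active at BOTH qualifying dates
  late_second <- dplyr::bind_rows(rx_row("s1", "metformin", FALSE, 0, 1460),
                                  rx_row("s1", "sulfonylurea", FALSE, 150, 1460))
  expect_equal(nrow(detect_glycaemic_requirement(base_hba, late_second, cfg)), 0)
  # ... and with three high readings the first pair fully on treatment wins
  three <- dplyr::bind_rows(hba_row("s1", 100, 75), hba_row("s1", 220, 72),
                            hba_row("s1", 400, 74))
  hit2 <- detect_glycaemic_requirement(three, late_second, cfg)
  expect_equal(as.numeric(hit2$event_date - as.Date("2010-01-01")), 400)
})

test_that("the composite endpoint takes the earlier pathway and censors otherwise", {
  fu <- fu_row("s1")
  # both fire, glycaemic earlier
  rx <- dplyr::bind_rows(two_orals(), rx_row("s1", "insulin", TRUE, 400, 1460))
  hb <- dplyr::bind_rows(hba_row("s1", 100, 75), hba_row("s1", 220, 72))
  res <- time_to_insulin_requirement(fu, rx, hb)
  expect_equal(res$time_days, 220)
  expect_true(res$event)
  expect_equal(res$pathway, "glycaemic_requirement")

  # sustained insulin only, at day 400
  res2 <- time_to_insulin_requirement(fu, rx, hba_row("s1", 100, 50))
  expect_equal(res2$time_days, 400)
  expect_equal(res2$pathway, "sustained_insulin")

  # neither: censored at 1460
  res3 <- time_to_insulin_requirement(fu, two_orals(), hba_row("s1", 100, 50))
  expect_equal(res3$time_days, 1460)
  expect_false(res3$event)
  expect_equal(res3$pathway, "censored")

  # event before time zero is a data error
  early <- dplyr::bind_rows(two_orals("s2"),
                            rx_row("s2", "insulin", TRUE, -400, 1460))
  expect_error(time_to_insulin_requirement(fu_row("s2"), early,
                                           hba_row("s2", 100, 50)),
               class = "diabclust_data_error")
})

test_that("adding records never delays the endpoint and row order is irrelevant", {
  set.seed(99)
  for (i in 1:20) {
    n_rx <- sample(1:4, 1)
    rx <- dplyr::bind_rows(lapply(seq_len(n_rx), function(j) {
      s <- sample(0:1200, 1)
      rx_row("s1", sample(c("metformin", "sulfonylurea", "insulin"), 1),
             NA, s, s + sample(50:500, 1))
    }))
    rx$is_insulin <- rx$drug_class == "insulin"
    hb <- dplyr::bind_rows(lapply(1:4, function(j)
      hba_row("s1", sample(0:1400, 1), runif(1, 50, 90))))
    base <- time_to_insulin_requirement(fu_row("s1"), rx, hb)

    extra <- dplyr::bind_rows(rx, rx_row("s1", "insulin", TRUE,
                                         sample(0:1200, 1), 1460))
    more <- time_to_insulin_requirement(fu_row("s1"), extra, hb)
    expect_lte(more$time_days, base$time_days)

    shuf <- time_to_insulin_requirement(fu_row("s1"),
                                        rx[sample(nrow(rx)), ],
                                        hb[sample(nrow(hb)), ])
    expect_equal(shuf, base)
  }
})

test_that("detected event dates equal the simulated insulin-initiation dates", {
  sim <- simulate_cross_section(mixture_config(n_subjects = 400, seed = 71), "A")
  fu <- simulate_followup(sim$cohort, sim$labels, followup_config(seed = 72))
  ep <- time_to_insulin_requirement(fu$followup, fu$prescriptions, fu$hba1c)
  ins <- ep[ep$pathway == "sustained_insulin", ]
  truth <- fu$followup$insulin_start_day[match(ins$subject_id,
                                               fu$followup$subject_id)]
  expect_gt(nrow(ins), 50)
  expect_equal(ins$time_days, truth)
  # every simulated initiation early enough to sustain is detected
  detectable <- fu$followup$subject_id[
    !is.na(fu$followup$insulin_start_day) &
      fu$followup$insulin_start_day < 3650 - 183]
  expect_true(all(detectable %in% ep$subject_id[ep$event]))
})

test_that("longitudinal CSVs round-trip", {
  rx <- dplyr::bind_rows(two_orals(), rx_row("s1", "insulin", TRUE, 10, NA))
  hb <- dplyr::bind_rows(hba_row("s1", 0, 48.5), hba_row("s1", 365, 71.2))
  d <- withr::local_tempdir()
  readr::write_csv(rx, file.path(d, "rx.csv"), na = "")
  readr::write_csv(hb, file.path(d, "hb.csv"))
  expect_equal(as.data.frame(read_prescriptions(file.path(d, "rx.csv"))),
               as.data.frame(rx))
  expect_equal(as.data.frame(read_hba1c(file.path(d, "hb.csv"))),
               as.data.frame(hb))
})
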