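e3_cat <- condition_catalog("E3")
e3_long <- e3_cat[e3_cat$condition_id == "long_5s", ]
e3_short <- e3_cat[e3_cat$condition_id == "short_1.5s", ]
e1_long <- condition_catalog("E1")[3, ]
no_uo <- condition_catalog("E1")[1, ]

test_that("constant-hazard noticing follows the exponential closed form", {
  set.seed(101)
  lam <- 0.2
  for (cond in list(e3_short, e3_long)) {
    got <- mean(sample_noticing(noticing_model("constant_hazard",
                                               hazard_per_s = lam),
                                cond, n = 10000)$noticed)
    want <- 1 - exp(-lam * cond$visible_s)
    se <- sqrt(want * (1 - want) / 10000)
    expect_lt(abs(got - want), 2.5 * se)
  }
})

test_that("event-triggered models are exposure invariant, hazard is not", {
  set.seed(102)
  onset <- noticing_model("onset_window", p_detect = 0.45)
  n_short <- sum(sample_noticing(onset, e3_short, n = 8000)$noticed)
  n_long <- sum(sample_noticing(onset, e3_long, n = 8000)$noticed)
  p <- suppressWarnings(stats::prop.test(c(n_short, n_long),
                                         c(8000, 8000))$p.value)
  expect_gt(p, 0.01)

  hz <- noticing_model("constant_hazard", hazard_per_s = 0.3)
  h_short <- mean(sample_noticing(hz, e3_short, n = 8000)$noticed)
  h_long <- mean(sample_noticing(hz, e3_long, n = 8000)$noticed)
  expect_gt(h_long, h_short + 0.1)
})

test_that("noticing times respect each model's anchor", {
  set.seed(103)
  w <- 0.8
  on <- sample_noticing(noticing_model("onset_window", p_detect = 1,
                                       window_s = w), e3_long, n = 500)
  expect_true(all(on$noticed))
  expect_true(all(on$t_notice >= e3_long$onset_time_s &
                    on$t_notice <= e3_long$onset_time_s + w))

  off <- sample_noticing(noticing_model("offset_window", p_detect = 1,
                                        window_s = w), e3_long, n = 500)
  expect_true(all(off$t_notice >= 13 - w & off$t_notice <= 13))

  fx <- sample_noticing(noticing_model("fixation_cross", p_detect = 1,
                                       window_s = w), e3_long, n = 500)
  t_cross <- e3_long$onset_time_s + (350 - 70) / 132
  expect_true(all(fx$t_notice >= t_cross & fx$t_notice <= t_cross + w))

  # a path that never reaches the fixation column cannot trigger
  e2 <- condition_catalog("E2")
  edge15 <- e2[e2$condition_id == "edge_1.5s", ]
  fx2 <- sample_noticing(noticing_model("fixation_cross", p_detect = 1),
                         edge15, "LtoR", n = 200)
  expect_false(any(fx2$noticed))

  expect_false(any(sample_noticing(noticing_model("onset_window",
                                                  p_detect = 1),
                                   no_uo, n = 200)$noticed))
})

test_that("edge onsets receive the configured boost", {
  set.seed(104)
  e2 <- condition_catalog("E2")
  m <- noticing_model("onset_window", p_detect = 0.4, edge_boost = 0.2)
  p_edge <- mean(sample_noticing(m, e2[e2$condition_id == "edge_5s", ],
                                 n = 8000)$noticed)
  p_mid <- mean(sample_noticing(m, e2[e2$condition_id == "mid_5s", ],
                                n = 8000)$noticed)
  expect_lt(abs(p_edge - 0.6), 0.02)
  expect_lt(abs(p_mid - 0.4), 0.02)
})

test_that("noise-free noticer reports sit exactly at the noticing position", {
  quiet <- report_noise(loc_sigma_px = 0, extrapolation_px = 0)
  rep1 <- sample_location_report(TRUE, e1_long$onset_time_s, e1_long, "LtoR",
                                 quiet)
  expect_equal(rep1$loc_x, 2 / 3 * 70)
  expect_equal(rep1$loc_y, 2 / 3 * 300)
  rep2 <- sample_location_report(TRUE, e1_long$onset_time_s, e1_long, "RtoL",
                                 quiet)
  expect_equal(rep2$loc_x, 2 / 3 * 630)

  # extrapolation shifts opposite the motion direction
  rep3 <- sample_location_report(TRUE, e1_long$onset_time_s, e1_long, "LtoR",
                                 report_noise(loc_sigma_px = 0,
                                              extrapolation_px = 30))
  expect_equal(rep3$loc_x, 2 / 3 * 40)

  expect_error(sample_location_report(TRUE, NA_real_, e1_long, "LtoR", quiet))
})

test_that("noticer reports cluster on the onset side; non-noticers centre", {
  set.seed(105)
  nt <- sample_noticing(noticing_model("onset_window", p_detect = 1,
                                       window_s = 0.5), e1_long, "LtoR",
                        n = 2000)
  loc <- sample_location_report(nt$noticed, nt$t_notice, e1_long, "LtoR",
                                report_noise(loc_sigma_px = 30))
  onset_side <- mean(loc$loc_x / (2 / 3) < 350)
  expect_gt(onset_side, 0.5)

  non <- sample_location_report(rep(FALSE, 4000), rep(NA_real_, 4000),
                                e1_long, "LtoR", report_noise())
  y_full <- non$loc_y / (2 / 3)
  expect_lt(abs(mean(y_full) - 300), 10)
  expect_gt(stats::sd(y_full), 2 * stats::sd(loc$loc_y / (2 / 3)))
  expect_true(all(non$loc_x >= 0 & non$loc_x <= 700 * 2 / 3))
  expect_true(all(non$loc_y >= 0 & non$loc_y <= 600 * 2 / 3))
})

test_that("feature reports hit chance for non-noticers, truth for noticers", {
  set.seed(106)
  n <- 10000
  non <- sample_feature_reports(rep(FALSE, n), "E3", report_noise(),
                                true_hue_deg = rep(90, n))
  acc <- mean(non$shape_report == "cross")
  se <- sqrt((1 / 9) * (8 / 9) / n)
  expect_lt(abs(acc - 1 / 9), 2.5 * se)
  dev <- angular_deviation_deg(wrap_angle_deg(non$hue_report_deg - 90))
  expect_lt(abs(dev - sqrt(2) * 180 / pi), 1.5)

  # extreme concentration degenerates to an exact hue report
  sharp <- sample_feature_reports(rep(TRUE, 500), "E3",
                                  report_noise(colour_kappa = 1e7),
                                  true_hue_deg = rep(123, 500))
  err <- wrap_angle_deg(sharp$hue_report_deg - 123)
  expect_lt(max(abs(err)), 1)

  menu <- sample_feature_reports(rep(TRUE, n), "E1",
                                 report_noise(q_shape = 0.9))
  expect_lt(abs(mean(menu$shape_report == "cross") - 0.9), 0.01)
  expect_lt(abs(mean(menu$colour_report_label == "grey") - 0.9), 0.01)
})

test_that("non-noticer hue reports carry no information about the truth", {
  set.seed(107)
  n <- 6000
  truth <- sample(seq(0, 330, 30), n, replace = TRUE)
  rep_hue <- sample_feature_reports(rep(FALSE, n), "E3", report_noise(),
                                    true_hue_deg = truth)$hue_report_deg
  bins <- cut(rep_hue, seq(0, 360, 90))
  p <- suppressWarnings(stats::chisq.test(table(truth, bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("count reports follow the multiplicative error model", {
  exact <- sample_covariates_and_counts(
    matrix(10, 4, 3), report_noise(count_error_sd = 0),
    exclusion_probs(), "E1")
  expect_true(all(exact$reported_bounces_1 == 10 &
                    exact$reported_bounces_2 == 10 &
                    exact$reported_bounces_3 == 10))
  expect_true(all(is.na(exact$d15_arrangement)))

  set.seed(108)
  e3cov <- sample_covariates_and_counts(
    matrix(10, 2000, 3), report_noise(),
    exclusion_probs(p_d15_deficient = 0.25), "E3")
  frac_perfect <- mean(e3cov$d15_arrangement == paste(1:15, collapse = "-"))
  expect_lt(abs(frac_perfect - 0.75), 0.03)
})

test_that("cohorts are reproducible and follow the assignment odds", {
  a <- generate_cohort("E1", n_per_condition = 40, seed = 9, trace_pool = 2)
  b <- generate_cohort("E1", n_per_condition = 40, seed = 9, trace_pool = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 100)

  set.seed(109)
  big <- generate_cohort("E1", n_per_condition = 2000, seed = 110,
                         trace_pool = 0)
  share <- mean(big$condition_id == "none")
  se <- sqrt(0.2 * 0.8 / nrow(big))
  expect_lt(abs(share - 0.2), 3 * se)

  # perfect detection and benign covariates: every UO subject is a noticer
  ideal <- generate_cohort(
    "E3", noticing_model("onset_window", p_detect = 1),
    report_noise(count_error_sd = 0, colour_kappa = 50, q_shape = 1),
    n_per_condition = 50, seed = 11, trace_pool = 0,
    probs = exclusion_probs(0, 0, 0, 0, 0))
  expect_true(all(classify_noticer(ideal)))
})

test_that("cohort CSV round-trips through the exporters", {
  coh <- generate_cohort("E3", n_per_condition = 20, seed = 12,
                         trace_pool = 0)
  tmp <- tempfile(fileext = ".csv")
  diag <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, tmp, diag)
  back <- read_cohort_csv(tmp)
  expect_equal(nrow(back), nrow(coh))
  expect_false("t_notice" %in% names(back))
  expect_equal(back$loc_x, coh$loc_x)
  expect_equal(attr(back, "experiment"), "E3")
  dg <- utils::read.csv(diag)
  expect_equal(names(dg), c("subject_id", "t_notice"))
  unlink(c(tmp, diag))
})
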