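# Generative observer models: candidate accounts of when noticing happens,
# plus report-noise models, turned into complete synthetic subject records so
# the screening / analysis / evaluation stages run without human data.

SHAPE_MENU <- c("square", "triangle", "diamond", "circle", "cross",
                "star", "pentagon", "hexagon", "heart")
COLOUR_MENU <- c("grey", "red", "orange", "yellow", "green", "cyan",
                 "blue", "purple", "pink")
HUE_GRID_DEG <- seq(0, 330, by = 30)
PANEL_SCALE <- 2 / 3

#' A candidate noticing model
#'
#' Four generative accounts of when an unexpected object is noticed:
#' \describe{
#'   \item{onset_window}{Noticing is triggered (with probability `p_detect`,
#'     plus `edge_boost` when the object onsets at a display edge) by the
#'     onset event; the noticing time falls uniformly in a `window_s`-wide
#'     window after onset. Predicts exposure-invariant rates and reports near
#'     the onset point.}
#'   \item{offset_window}{Same, anchored at the offset (13 s); reports cluster
#'     near the offset point.}
#'   \item{fixation_cross}{Triggered when the object's centre crosses
#'     fixation; never fires for paths that do not reach the fixation column.}
#'   \item{constant_hazard}{Detection is a Poisson arrival at rate
#'     `hazard_per_s` while the object is visible, so
#'     P(notice) = 1 - exp(-hazard * T) grows with exposure T.}
#' }
#'
#' @param variant Model name (see above).
#' @param p_detect Event-triggered detection probability.
#' @param hazard_per_s Hazard rate for `constant_hazard`.
#' @param window_s Width of the post-event opportunity window, seconds.
#' @param edge_boost Additive probability for edge onsets (onset_window).
#' @return A list of class `ib_model`.
#' @export
noticing_model <- function(variant = c("onset_window", "offset_window",
                                       "fixation_cross", "constant_hazard"),
                           p_detect = 0.45, hazard_per_s = 0.2,
                           window_s = 1, edge_boost = 0) {
  variant <- match.arg(variant)
  stopifnot(
    p_detect >= 0, p_detect <= 1,
    p_detect + edge_boost >= 0, p_detect + edge_boost <= 1,
    hazard_per_s >= 0, window_s >= 0
  )
  structure(
    list(variant = variant, p_detect = p_detect, hazard_per_s = hazard_per_s,
         window_s = window_s, edge_boost = edge_boost),
    class = "ib_model"
  )
}

#' Report-noise parameters
#'
#' Governs how latent noticing states become observable reports. Noticers
#' place the object at its position at their noticing time, shifted
#' `extrapolation_px` opposite the motion direction (an overshoot toward where
#' the motion came from), with isotropic Gaussian noise `loc_sigma_px`;
#' non-noticers place diffusely around the display centre with dispersion
#' `nonnoticer_loc_sigma_px`. Noticers report the correct shape with
#' probability `q_shape` and hue concentrated on the truth (von Mises
#' `colour_kappa`); non-noticers respond uniformly. Bounce reports are the
#' true count times `1 + e`, `e ~ N(0, count_error_sd)`.
#'
#' All pixel quantities are full-scale display pixels; location reports are
#' scaled to the two-thirds placement panel afterwards.
#'
#' @param loc_sigma_px Noticer placement noise (px).
#' @param extrapolation_px Signed shift of noticer reports along the motion
#'   axis toward the motion's origin (px).
#' @param colour_kappa von Mises concentration of noticer hue reports.
#' @param q_shape Probability a noticer picks the correct shape from the
#'   9-option menu.
#' @param q_colour Probability a noticer picks the correct colour label
#'   (menu experiments); defaults to `q_shape`.
#' @param nonnoticer_loc_sigma_px Non-noticer placement dispersion (px).
#' @param count_error_sd Relative s.d. of bounce-count reports.
#' @param false_report_rate Probability a subject who did not notice (or saw
#'   no unexpected object) still answers "yes" to the noticing probe.
#' @return A list of class `ib_noise`.
#' @export
report_noise <- function(loc_sigma_px = 70, extrapolation_px = 20,
                         colour_kappa = 5, q_shape = 0.88,
                         q_colour = q_shape, nonnoticer_loc_sigma_px = 140,
                         count_error_sd = 0.55, false_report_rate = 0) {
  stopifnot(
    loc_sigma_px >= 0, colour_kappa >= 0,
    q_shape >= 1 / length(SHAPE_MENU), q_shape <= 1,
    q_colour >= 0, q_colour <= 1,
    nonnoticer_loc_sigma_px >= 0, count_error_sd >= 0,
    false_report_rate >= 0, false_report_rate <= 1
  )
  structure(
    list(loc_sigma_px = loc_sigma_px, extrapolation_px = extrapolation_px,
         colour_kappa = colour_kappa, q_shape = q_shape, q_colour = q_colour,
         nonnoticer_loc_sigma_px = nonnoticer_loc_sigma_px,
         count_error_sd = count_error_sd,
         false_report_rate = false_report_rate),
    class = "ib_noise"
  )
}

#' Covariate and colour-vision probabilities for synthetic cohorts
#'
#' Marginal rates of the screening covariates, chosen to emulate the
#' exclusion profile of online crowdsourced cohorts.
#'
#' @param p_underage Probability of reporting age under 18.
#' @param p_uncorrected_vision Probability of needing vision correction but
#'   not wearing it.
#' @param p_technical Probability of reporting a technical problem.
#' @param p_prior_ib Probability of prior inattentional-blindness experience.
#' @param p_d15_deficient Probability of a colour-deficient D-15 arrangement.
#' @param d15_severity Number of random cap transpositions applied to a
#'   deficient arrangement.
#' @return A list of class `ib_probs`.
#' @export
exclusion_probs <- function(p_underage = 0.001, p_uncorrected_vision = 0.08,
                            p_technical = 0.12, p_prior_ib = 0.03,
                            p_d15_deficient = 0.18, d15_severity = 4) {
  p <- c(p_underage, p_uncorrected_vision, p_technical, p_prior_ib,
         p_d15_deficient)
  stopifnot(all(p >= 0 & p <= 1), d15_severity >= 1)
  structure(
    list(p_underage = p_underage,
         p_uncorrected_vision = p_uncorrected_vision,
         p_technical = p_technical, p_prior_ib = p_prior_ib,
         p_d15_deficient = p_d15_deficient,
         d15_severity = as.integer(d15_severity)),
    class = "ib_probs"
  )
}

#' Sample noticing outcomes under a model
#'
#' @param model An [noticing_model()].
#' @param condition A single catalog row.
#' @param direction `"LtoR"` or `"RtoL"`.
#' @param n Number of independent subjects to draw.
#' @param geometry Display geometry.
#' @return A tibble with logical `noticed` and `t_notice` (seconds; `NA` when
#'   not noticed). For a condition without an unexpected object, `noticed` is
#'   always `FALSE`.
#' @export
#' @examples
#' cond <- condition_catalog("E3")[2, ]
#' set.seed(1)
#' mean(sample_noticing(noticing_model("constant_hazard", hazard_per_s = 0.2),
#'                      cond, n = 1000)$noticed)
sample_noticing <- function(model, condition, direction = c("LtoR", "RtoL"),
                            n = 1, geometry = display_geometry()) {
  stopifnot(inherits(model, "ib_model"))
  cond <- .condition_row(condition)
  direction <- match.arg(direction)
  if (!isTRUE(cond$has_uo)) {
    return(tibble::tibble(noticed = rep(FALSE, n), t_notice = NA_real_))
  }
  path <- uo_path(cond, direction, geometry)
  noticed <- rep(FALSE, n)
  t_notice <- rep(NA_real_, n)
  clamp <- function(t) pmin(pmax(t, path$first_visible_s), path$offset_time_s)
  if (model$variant == "onset_window") {
    p <- model$p_detect +
      if (identical(cond$onset_type, "edge")) model$edge_boost else 0
    noticed <- stats::runif(n) < p
    t_notice[noticed] <- clamp(path$onset_time_s +
                                 stats::runif(sum(noticed), 0, model$window_s))
  } else if (model$variant == "offset_window") {
    noticed <- stats::runif(n) < model$p_detect
    t_notice[noticed] <- clamp(path$offset_time_s -
                                 stats::runif(sum(noticed), 0, model$window_s))
  } else if (model$variant == "fixation_cross") {
    fx <- geometry$fixation_x
    lo <- min(path$x_on, path$x_off) - UO_HALF_PX
    hi <- max(path$x_on, path$x_off) + UO_HALF_PX
    if (fx > lo && fx < hi) {
      t_cross <- path$onset_time_s + (fx - path$x_on) / (path$dir * UO_SPEED_PX_S)
      noticed <- stats::runif(n) < model$p_detect
      t_notice[noticed] <- clamp(t_cross +
                                   stats::runif(sum(noticed), 0, model$window_s))
    }
  } else { # constant_hazard
    if (model$hazard_per_s > 0) {
      arrival <- stats::rexp(n, model$hazard_per_s)
      noticed <- arrival <= path$visible_s
      t_notice[noticed] <- path$first_visible_s + arrival[noticed]
    }
  }
  tibble::tibble(noticed = noticed, t_notice = t_notice)
}

#' Sample location reports on the two-thirds placement panel
#'
#' Noticers report the unexpected object's position at their noticing time,
#' shifted `extrapolation_px` opposite the motion direction, with isotropic
#' Gaussian noise; non-noticers place around the display centre with large
#' dispersion. Reports are then scaled by 2/3 and clipped to the panel.
#'
#' @param noticed Logical vector.
#' @param t_notice Noticing times (required where `noticed`).
#' @param condition A single catalog row (may lack an unexpected object only
#'   if no entry of `noticed` is `TRUE`).
#' @param direction `"LtoR"` or `"RtoL"`.
#' @param noise A [report_noise()].
#' @param geometry Display geometry.
#' @return A tibble with `loc_x`, `loc_y` in panel (two-thirds-scale)
#'   coordinates.
#' @export
sample_location_report <- function(noticed, t_notice, condition,
                                   direction = c("LtoR", "RtoL"),
                                   noise = report_noise(),
                                   geometry = display_geometry()) {
  direction <- match.arg(direction)
  cond <- .condition_row(condition)
  n <- length(noticed)
  stopifnot(length(t_notice) == n)
  if (any(noticed & is.na(t_notice))) {
    stop("t_notice must be supplied for every noticer")
  }
  x <- geometry$fixation_x + stats::rnorm(n, 0, noise$nonnoticer_loc_sigma_px)
  y <- geometry$fixation_y + stats::rnorm(n, 0, noise$nonnoticer_loc_sigma_px)
  if (any(noticed)) {
    path <- uo_path(cond, direction, geometry)
    cx <- path$x_on + path$dir * UO_SPEED_PX_S *
      (t_notice[noticed] - path$onset_time_s)
    x[noticed] <- cx - path$dir * noise$extrapolation_px +
      stats::rnorm(sum(noticed), 0, noise$loc_sigma_px)
    y[noticed] <- path$y + stats::rnorm(sum(noticed), 0, noise$loc_sigma_px)
  }
  tibble::tibble(
    loc_x = pmin(pmax(x * PANEL_SCALE, 0), geometry$width_px * PANEL_SCALE),
    loc_y = pmin(pmax(y * PANEL_SCALE, 0), geometry$height_px * PANEL_SCALE)
  )
}

#' Sample shape and colour reports
#'
#' Noticers report the correct shape with probability `q_shape` (otherwise a
#' uniform draw over the remaining 8 menu options) and a hue concentrated on
#' the truth (continuous-slider experiments) or the correct colour label with
#' probability `q_colour` (menu experiments). Non-noticers respond uniformly:
#' over the 9 shapes, over the hue circle, or over the 9 colour labels.
#'
#' @param noticed Logical vector.
#' @param experiment `"E1"`, `"E2"` (menu colour) or `"E3"` (hue slider).
#' @param noise A [report_noise()].
#' @param true_hue_deg True hue per subject (degrees; `E3`).
#' @param true_shape True shape (always the cross in these designs).
#' @param true_colour_label True colour label (menu experiments).
#' @return A tibble with `shape_report`, `colour_report_label` (menu; `NA` in
#'   E3) and `hue_report_deg` (E3; `NA` otherwise).
#' @export
sample_feature_reports <- function(noticed, experiment,
                                   noise = report_noise(),
                                   true_hue_deg = NULL,
                                   true_shape = "cross",
                                   true_colour_label = "grey") {
  n <- length(noticed)
  experiment <- match.arg(experiment, c("E1", "E2", "E3"))
  pick_menu <- function(n_pick, menu, truth, q) {
    out <- sample(menu, n_pick, replace = TRUE)
    correct <- stats::runif(n_pick) < q
    out[correct] <- truth
    if (any(!correct)) {
      out[!correct] <- sample(setdiff(menu, truth), sum(!correct),
                              replace = TRUE)
    }
    out
  }
  shape <- sample(SHAPE_MENU, n, replace = TRUE)
  if (any(noticed)) {
    shape[noticed] <- pick_menu(sum(noticed), SHAPE_MENU, true_shape,
                                noise$q_shape)
  }
  label <- rep(NA_character_, n)
  hue <- rep(NA_real_, n)
  if (experiment == "E3") {
    stopifnot(!is.null(true_hue_deg), length(true_hue_deg) == n)
    hue <- stats::runif(n, 0, 360)
    if (any(noticed)) {
      hue[noticed] <- rvonmises_deg(sum(noticed),
                                    mu_deg = true_hue_deg[noticed],
                                    kappa = noise$colour_kappa)
    }
  } else {
    label <- sample(COLOUR_MENU, n, replace = TRUE)
    if (any(noticed)) {
      label[noticed] <- pick_menu(sum(noticed), COLOUR_MENU,
                                  true_colour_label, noise$q_colour)
    }
  }
  tibble::tibble(shape_report = shape, colour_report_label = label,
                 hue_report_deg = hue)
}

#' A synthetic Farnsworth D-15 arrangement
#'
#' Colour-normal subjects produce the identity ordering; deficient subjects
#' produce the identity corrupted by `severity` random cap transpositions.
#'
#' @param deficient Logical.
#' @param severity Number of random transpositions.
#' @return An integer permutation of 1:15.
#' @export
make_d15_arrangement <- function(deficient = FALSE, severity = 4) {
  arr <- 1:15
  if (deficient) {
    for (k in seq_len(severity)) {
      ij <- sample(15, 2)
      arr[ij] <- arr[rev(ij)]
    }
  }
  arr
}

#' Sample bounce-count reports, covariates and D-15 arrangements
#'
#' Reported counts are `round(true * (1 + e))`, `e ~ N(0, count_error_sd)`,
#' floored at zero. Covariates are independent Bernoulli draws with the
#' configured probabilities; D-15 arrangements (colour-slider experiments
#' only) are the identity with probability `1 - p_d15_deficient`, else a
#' transposition-corrupted arrangement.
#'
#' @param true_counts An n x 3 matrix of ground-truth bounce counts (one
#'   column per trial).
#' @param noise A [report_noise()].
#' @param probs An [exclusion_probs()].
#' @param experiment Experiment label; D-15 arrangements are generated only
#'   for `"E3"`.
#' @return A tibble with `reported_bounces_1..3`, `true_bounces_1..3`,
#'   `age_ok`, `vision_corrected_ok`, `technical_problem`,
#'   `prior_ib_experience` and `d15_arrangement` (dash-separated cap order or
#'   `NA`).
#' @export
sample_covariates_and_counts <- function(true_counts,
                                         noise = report_noise(),
                                         probs = exclusion_probs(),
                                         experiment = "E1") {
  true_counts <- as.matrix(true_counts)
  stopifnot(ncol(true_counts) == 3)
  n <- nrow(true_counts)
  eps <- matrix(stats::rnorm(3 * n, 0, noise$count_error_sd), n, 3)
  reported <- pmax(round(true_counts * (1 + eps)), 0)
  d15 <- rep(NA_character_, n)
  if (experiment == "E3") {
    deficient <- stats::runif(n) < probs$p_d15_deficient
    d15 <- vapply(deficient, function(d) {
      paste(make_d15_arrangement(d, probs$d15_severity), collapse = "-")
    }, character(1))
  }
  tibble::tibble(
    true_bounces_1 = true_counts[, 1], true_bounces_2 = true_counts[, 2],
    true_bounces_3 = true_counts[, 3],
    reported_bounces_1 = reported[, 1], reported_bounces_2 = reported[, 2],
    reported_bounces_3 = reported[, 3],
    age_ok = stats::runif(n) >= probs$p_underage,
    vision_corrected_ok = stats::runif(n) >= probs$p_uncorrected_vision,
    technical_problem = stats::runif(n) < probs$p_technical,
    prior_ib_experience = stats::runif(n) < probs$p_prior_ib,
    d15_arrangement = d15
  )
}

#' Generate a complete synthetic cohort
#'
#' Assigns subjects to the experiment's conditions with the design's odds
#' (E1: 2:2:1 over the two unexpected-object conditions and the control;
#' E2: uniform over six; E3: uniform over two), randomises motion direction
#' and attended colour, draws latent noticing under `model`, and emits every
#' observable report: bounce counts (from a seeded pool of simulated trials),
#' the noticing probe, shape/colour reports, the panel location report, the
#' screening covariates and (E3) a D-15 arrangement.
#'
#' `n_per_condition` is the expected number of subjects per unexpected-object
#' condition; the total recruited is scaled accordingly (E1: 2.5x, E2: 6x,
#' E3: 2x).
#'
#' @param experiment `"E1"`, `"E2"` or `"E3"`.
#' @param model A [noticing_model()].
#' @param noise A [report_noise()].
#' @param n_per_condition Expected subjects per unexpected-object condition.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param probs An [exclusion_probs()].
#' @param trace_pool Number of simulated 15-s trials in the bounce-count
#'   pool; each subject's three trials are drawn from it.
#' @param dt Trial simulation timestep (s).
#' @return A tibble of class `ib_cohort`, one row per subject, with
#'   attributes `experiment`, `model`, `noise`, `seed`.
#' @export
generate_cohort <- function(experiment, model = noticing_model(),
                            noise = report_noise(), n_per_condition = 100,
                            seed = NULL, probs = exclusion_probs(),
                            trace_pool = 12, dt = 1 / 60) {
  experiment <- match.arg(experiment, c("E1", "E2", "E3"))
  stopifnot(n_per_condition >= 1)
  if (!is.null(seed)) set.seed(seed)
  cat <- condition_catalog(experiment)
  mult <- switch(experiment, E1 = 2.5, E2 = 6, E3 = 2)
  n_total <- round(n_per_condition * mult)
  idx <- sample(nrow(cat), n_total, replace = TRUE,
                prob = cat$assignment_prob)
  direction <- sample(c("LtoR", "RtoL"), n_total, replace = TRUE)
  attended <- sample(c("white", "black"), n_total, replace = TRUE)

  # seeded pool of trials supplying ground-truth bounce counts;
  # trace_pool = 0 skips trial simulation (all counts zero, nobody flagged)
  if (trace_pool > 0) {
    pool <- vapply(seq_len(trace_pool), function(k) {
      simulate_trial(NULL, seed = NULL, dt = dt,
                     keep_positions = FALSE)$true_bounces
    }, c(white = 0, black = 0))
    trial_idx <- matrix(sample(trace_pool, 3 * n_total, replace = TRUE),
                        n_total, 3)
    col_row <- ifelse(attended == "white", 1L, 2L)
    true_counts <- matrix(pool[cbind(rep(col_row, 3), as.vector(trial_idx))],
                          n_total, 3)
  } else {
    true_counts <- matrix(0, n_total, 3)
  }

  hue_true <- rep(NA_real_, n_total)
  if (experiment == "E3") {
    hue_true <- sample(HUE_GRID_DEG, n_total, replace = TRUE)
  }

  noticed <- logical(n_total)
  t_notice <- rep(NA_real_, n_total)
  loc <- tibble::tibble(loc_x = numeric(n_total), loc_y = numeric(n_total))
  for (ci in seq_len(nrow(cat))) {
    for (dr in c("LtoR", "RtoL")) {
      sel <- which(idx == ci & direction == dr)
      if (!length(sel)) next
      nt <- sample_noticing(model, cat[ci, ], dr, n = length(sel))
      noticed[sel] <- nt$noticed
      t_notice[sel] <- nt$t_notice
      lr <- sample_location_report(nt$noticed, nt$t_notice, cat[ci, ], dr,
                                   noise)
      loc$loc_x[sel] <- lr$loc_x
      loc$loc_y[sel] <- lr$loc_y
    }
  }
  feats <- sample_feature_reports(noticed, experiment, noise,
                                  true_hue_deg = hue_true)
  cov <- sample_covariates_and_counts(true_counts, noise, probs, experiment)
  reported_noticed <- noticed |
    (stats::runif(n_total) < noise$false_report_rate)
  colour_true <- if (experiment == "E3") NA_character_ else "grey"

  cohort <- tibble::tibble(
    subject_id = seq_len(n_total),
    experiment = experiment,
    condition_id = cat$condition_id[idx],
    direction = direction,
    attended_colour = attended,
    reported_noticed = reported_noticed,
    t_notice = t_notice,
    shape_true = "cross",
    colour_true_label = colour_true,
    hue_true_deg = hue_true,
    loc_x = loc$loc_x, loc_y = loc$loc_y
  )
  cohort <- tibble::as_tibble(cbind(cohort, feats, cov))
  class(cohort) <- c("ib_cohort", class(cohort))
  attr(cohort, "experiment") <- experiment
  attr(cohort, "model") <- model
  attr(cohort, "noise") <- noise
  attr(cohort, "seed") <- seed
  cohort
}

#' Write a cohort to CSV
#'
#' Observable columns go to `path`; latent diagnostics (`t_notice`) go to a
#' separate file when `diagnostics_path` is given.
#'
#' @param cohort An `ib_cohort`.
#' @param path Output CSV path.
#' @param diagnostics_path Optional CSV path for latent fields.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, diagnostics_path = NULL) {
  obs <- cohort[, setdiff(names(cohort), "t_notice")]
  utils::write.csv(obs, path, row.names = FALSE)
  if (!is.null(diagnostics_path)) {
    utils::write.csv(cohort[, c("subject_id", "t_notice")],
                     diagnostics_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#'
#' @param path CSV path.
#' @param experiment Experiment label; taken from the file when present.
#' @return An `ib_cohort` tibble.
#' @export
read_cohort_csv <- function(path, experiment = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (is.null(experiment)) experiment <- df$experiment[1]
  class(df) <- c("ib_cohort", class(df))
  attr(df, "experiment") <- experiment
  df
}
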