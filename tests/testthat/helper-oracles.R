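# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# Analytic bounce count for constant-speed 45-degree motion over [0, T]:
# unfold the reflected 1-D motion into a straight line and count boundary
# crossings per axis (a corner contact crosses both axes and so counts twice).
oracle_axis_crossings <- function(p0, v, T, lo, hi) {
  if (v == 0 || T <= 0) return(0L)
  L <- hi - lo
  if (v < 0) { # mirror so the motion is rightward
    p0 <- lo + hi - p0
    v <- -v
  }
  a <- p0 - lo
  b <- p0 + v * T - lo
  # crossings of the lattice {k * L} strictly after the start
  floor(b / L) - floor(a / L)
}

oracle_bounce_count <- function(x0, y0, sx, sy, speed, T, geometry, half_w,
                                half_h) {
  comp <- speed / sqrt(2)
  oracle_axis_crossings(x0, sx * comp, T, half_w,
                        geometry$width_px - half_w) +
    oracle_axis_crossings(y0, sy * comp, T, half_h,
                          geometry$height_px - half_h)
}

# Expected angular deviation (degrees) of n uniform angles: the resultant
# length is Rayleigh-distributed with density 2 n r exp(-n r^2), so integrate
# sqrt(2 (1 - r)) against it.
oracle_uniform_angdev_deg <- function(n) {
  f <- function(r) sqrt(2 * (1 - r)) * 2 * n * r * exp(-n * r^2)
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value * 180 / pi
}

# Monte-Carlo mean distance of uniform placements to a point, as a baseline
# for centre-weighted placement tests.
oracle_uniform_mean_dist <- function(px, py, geometry, n = 2e5) {
  x <- stats::runif(n, 0, geometry$width_px)
  y <- stats::runif(n, 0, geometry$height_px)
  mean(sqrt((x - px)^2 + (y - py)^2))
}

# Minimal hand-built cohort with just the columns the screening and analysis
# modules contract on; every field overridable.
make_fixture_cohort <- function(n, experiment = "E1",
                                condition_id = "long_5s",
                                direction = "LtoR", ...) {
  is_e3 <- experiment == "E3"
  base <- tibble::tibble(
    subject_id = seq_len(n),
    experiment = experiment,
    condition_id = condition_id,
    direction = direction,
    attended_colour = "white",
    reported_noticed = FALSE,
    t_notice = NA_real_,
    shape_true = "cross",
    colour_true_label = if (is_e3) NA_character_ else "grey",
    hue_true_deg = if (is_e3) 90 else NA_real_,
    loc_x = 233, loc_y = 200,
    shape_report = "star",
    colour_report_label = if (is_e3) NA_character_ else "red",
    hue_report_deg = if (is_e3) 45 else NA_real_,
    true_bounces_1 = 10, true_bounces_2 = 10, true_bounces_3 = 10,
    reported_bounces_1 = 10, reported_bounces_2 = 10, reported_bounces_3 = 10,
    age_ok = TRUE, vision_corrected_ok = TRUE, technical_problem = FALSE,
    prior_ib_experience = FALSE,
    d15_arrangement = if (is_e3) paste(1:15, collapse = "-") else NA_character_
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  attr(base, "experiment") <- experiment
  class(base) <- c("ib_cohort", class(base))
  base
}
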