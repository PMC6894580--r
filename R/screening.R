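# Exclusion pipeline: bounce-count accuracy, self-reported covariates and
# Farnsworth D-15 colour-vision screening.

#' Chromaticities of the Farnsworth D-15 caps
#'
#' CIELUV (u*, v*) coordinates of the reference cap (cap 0) and caps 1--15 of
#' the standard (saturated) D-15 panel, as tabulated for the
#' moment-of-inertia scoring method of Vingrys and King-Smith (1988),
#' *Investigative Ophthalmology & Visual Science* 29, 50--63.
#'
#' @return A data frame with `cap` (0 = reference), `u`, `v`.
#' @export
d15_caps <- function() {
  data.frame(
    cap = 0:15,
    u = c(-21.54, -23.26, -22.41, -23.11, -22.45, -21.67, -14.08, -2.72,
          8.86, 19.43, 23.13, 27.06, 29.51, 29.38, 23.65, 14.75),
    v = c(-38.39, -25.56, -15.53, -7.45, 1.09, 7.35, 18.74, 28.13, 31.13,
          27.35, 20.54, 11.62, -1.30, -14.05, -25.30, -34.26)
  )
}

# major radius (root of the larger eigenvalue of the second-moment matrix of
# the colour-difference vectors between consecutively placed caps; the fixed
# reference cap anchors the task but contributes no vector, which keeps the
# index invariant under a full reversal of the arrangement)
.d15_major_radius <- function(order, caps) {
  seq_uv <- caps[match(order, caps$cap), c("u", "v")]
  du <- diff(seq_uv$u)
  dv <- diff(seq_uv$v)
  p <- sum(du^2); q <- sum(dv^2); t <- sum(du * dv)
  lmax <- ((p + q) + sqrt((p - q)^2 + 4 * t^2)) / 2
  sqrt(lmax)
}

#' Score a D-15 arrangement with the confusion index
#'
#' Moment-of-inertia scoring: colour-difference vectors are formed between
#' consecutively placed caps, the inertia ellipse of those vectors is
#' computed, and the confusion index is the ratio of the arrangement's major
#' radius to the perfect arrangement's. The fixed reference cap anchors the
#' task but contributes no difference vector, so the index is invariant under
#' a full reversal of the arrangement (every vector just flips sign). A
#' perfect ordering scores exactly 1; clinically significant colour confusion
#' is conventionally taken as an index above 1.78.
#'
#' @param arrangement A permutation of the integers 1--15 (cap placement
#'   order), or a dash-separated string such as `"1-2-3-..."`.
#' @param caps Cap chromaticity table; see [d15_caps()].
#' @return The confusion index (>= 1 up to numerical noise).
#' @export
#' @examples
#' score_d15(1:15)      # 1
#' score_d15(15:1)      # also 1: sign-flipped difference vectors
score_d15 <- function(arrangement, caps = d15_caps()) {
  if (is.character(arrangement) && length(arrangement) == 1) {
    arrangement <- as.integer(strsplit(arrangement, "-", fixed = TRUE)[[1]])
  }
  arrangement <- as.integer(arrangement)
  if (length(arrangement) != 15 || !setequal(arrangement, 1:15)) {
    stop("arrangement must be a permutation of caps 1-15")
  }
  .d15_major_radius(arrangement, caps) / .d15_major_radius(1:15, caps)
}

#' Bounce-count accuracy rule
#'
#' A trial is flagged when the reported count errs by more than 50% of the
#' true count in either direction (strictly greater; a nonzero report against
#' a true count of zero is flagged as the limit of relative error). The
#' subject is flagged when two or more of the three trials are flagged.
#'
#' @param true_counts,reported_counts Numeric vectors of length 3, or n x 3
#'   matrices (rows = subjects).
#' @return A logical vector: flagged subjects.
#' @export
#' @examples
#' bounce_error_rule(c(10, 10, 10), c(15, 10, 10))  # 50% exactly: retained
#' bounce_error_rule(c(10, 10, 10), c(16, 4, 10))   # flagged
bounce_error_rule <- function(true_counts, reported_counts) {
  true_counts <- rbind(true_counts)
  reported_counts <- rbind(reported_counts)
  stopifnot(ncol(true_counts) == 3,
            all(dim(true_counts) == dim(reported_counts)))
  trial_flag <- abs(reported_counts - true_counts) > 0.5 * true_counts
  rowSums(trial_flag) >= 2
}

D15_THRESHOLD <- 1.78

#' Apply the full exclusion pipeline to a cohort
#'
#' Applies, in the reporting order of the design: the bounce-count accuracy
#' rule, the age rule, the uncorrected-vision rule, the technical-problem
#' rule, the prior-experience rule and (colour-slider experiments only) the
#' D-15 confusion-index rule with its strict threshold (`index > 1.78`
#' excludes). Subjects can be flagged by several rules but are excluded once.
#'
#' @param cohort An `ib_cohort` tibble.
#' @param experiment Experiment label; defaults to the cohort attribute.
#' @param d15_threshold Confusion-index threshold (exclusion is strictly
#'   above it).
#' @return A list of class `ib_screening` with `retained` (the surviving
#'   cohort), `report` (per-rule counts plus totals) and `flags` (per-subject
#'   logical matrix).
#' @export
apply_exclusions <- function(cohort, experiment = NULL,
                             d15_threshold = D15_THRESHOLD) {
  if (is.null(experiment)) experiment <- attr(cohort, "experiment")
  if (is.null(experiment)) experiment <- cohort$experiment[1]
  n <- nrow(cohort)
  tc <- as.matrix(cohort[, paste0("true_bounces_", 1:3)])
  rc <- as.matrix(cohort[, paste0("reported_bounces_", 1:3)])
  flags <- cbind(
    miscount = bounce_error_rule(tc, rc),
    underage = !cohort$age_ok,
    uncorrected_vision = !cohort$vision_corrected_ok,
    technical_problem = cohort$technical_problem,
    prior_experience = cohort$prior_ib_experience
  )
  if (experiment == "E3") {
    ci <- vapply(cohort$d15_arrangement, function(a) {
      if (is.na(a)) NA_real_ else score_d15(a)
    }, numeric(1), USE.NAMES = FALSE)
    flags <- cbind(flags, d15 = !is.na(ci) & ci > d15_threshold)
  }
  excluded <- rowSums(flags) > 0
  report <- tibble::tibble(
    rule = c(
      "bounce counts erred by more than 50% on two or more trials",
      "reported being younger than 18",
      "needed vision correction but was not wearing it",
      "reported a technical problem",
      "prior experience with inattentional blindness tasks",
      if (experiment == "E3") "D-15 confusion index greater than 1.78"
    ),
    excluded = colSums(flags)
  )
  structure(
    list(
      retained = cohort[!excluded, , drop = FALSE],
      report = report,
      flags = flags,
      total_excluded = sum(excluded),
      total_retained = sum(!excluded),
      total_recruited = n
    ),
    class = "ib_screening"
  )
}

#' @export
print.ib_screening <- function(x, ...) {
  cat("Exclusion report:", x$total_recruited, "recruited,",
      x$total_excluded, "excluded,", x$total_retained, "retained\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-55s %d\n", x$report$rule[i], x$report$excluded[i]))
  }
  invisible(x)
}

#' Write an exclusion report to CSV (and optionally JSON)
#'
#' @param screening An `ib_screening` result.
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_exclusion_report <- function(screening, csv_path, json_path = NULL) {
  df <- rbind(
    data.frame(rule = screening$report$rule,
               count = screening$report$excluded),
    data.frame(rule = c("total excluded", "total retained",
                        "total recruited"),
               count = c(screening$total_excluded, screening$total_retained,
                         screening$total_recruited))
  )
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_rule = as.list(stats::setNames(screening$report$excluded,
                                              screening$report$rule)),
           total_excluded = screening$total_excluded,
           total_retained = screening$total_retained,
           total_recruited = screening$total_recruited),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
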