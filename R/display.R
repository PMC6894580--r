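# Unexpected-object constants shared across experiments: a 40 x 40 px cross
# travelling at 132 px/s along the vertical midline, gone with 2 s left in a
# 15 s trial.
UO_SPEED_PX_S <- 132
UO_HALF_PX <- 20
TRIAL_LENGTH_S <- 15
UO_OFFSET_TIME_S <- 13

#' Display geometry of the tracking window
#'
#' The bounce-counting display is a 700 px wide by 600 px tall window with a
#' small fixation square at its exact centre, (350, 300). Coordinates have the
#' origin at the top-left corner, x increasing rightward and y downward;
#' positions are continuous object centres.
#'
#' @param width_px Horizontal extent in pixels.
#' @param height_px Vertical extent in pixels.
#' @param fixation_size_px Side of the central fixation square.
#' @return An object of class `ib_geometry`: a list with `width_px`,
#'   `height_px`, `fixation_x`, `fixation_y`, `fixation_size_px`.
#' @export
#' @examples
#' g <- display_geometry()
#' c(g$fixation_x, g$fixation_y)
display_geometry <- function(width_px = 700, height_px = 600,
                             fixation_size_px = 10) {
  stopifnot(width_px > 0, height_px > 0)
  structure(
    list(
      width_px = width_px, height_px = height_px,
      fixation_x = width_px / 2, fixation_y = height_px / 2,
      fixation_size_px = fixation_size_px
    ),
    class = "ib_geometry"
  )
}

#' Motion parameters of the tracked objects
#'
#' Objects move along 45-degree diagonals at one of three speeds (66, 132 or
#' 198 px/s). At random intervals of 300--1000 ms each object's speed changes
#' by +/-66 px/s, reflected at the two extremes so the speed set is closed.
#'
#' @param speed_min,speed_max,speed_step Speed grid in px/s.
#' @param change_interval_min_ms,change_interval_max_ms Bounds of the uniform
#'   distribution of times between speed changes, in milliseconds.
#' @return An object of class `ib_motion`.
#' @export
motion_params <- function(speed_min = 66, speed_max = 198, speed_step = 66,
                          change_interval_min_ms = 300,
                          change_interval_max_ms = 1000) {
  stopifnot(
    speed_min > 0, speed_step > 0, speed_max >= speed_min,
    (speed_max - speed_min) %% speed_step == 0,
    change_interval_min_ms > 0,
    change_interval_max_ms >= change_interval_min_ms
  )
  structure(
    list(
      speed_min = speed_min, speed_max = speed_max, speed_step = speed_step,
      change_interval_min_ms = change_interval_min_ms,
      change_interval_max_ms = change_interval_max_ms,
      speeds = seq(speed_min, speed_max, by = speed_step)
    ),
    class = "ib_motion"
  )
}

#' Dimensions of the tracked shapes
#'
#' Each colour set (4 white, 4 black) contains one square (40 x 40), triangle
#' (50 x 50), diamond (56 x 56) and circle (46 px diameter). The unexpected
#' object is always a cross, 40 x 40 with 14 px arms.
#'
#' @return A data frame with `shape_id`, `width_px`, `height_px`.
#' @export
shape_table <- function() {
  data.frame(
    shape_id = c("square", "triangle", "diamond", "circle", "cross"),
    width_px = c(40, 50, 56, 46, 40),
    height_px = c(40, 50, 56, 46, 40),
    stringsAsFactors = FALSE
  )
}

# internal: derived unexpected-object timing for a travel distance.
# The cross centre crosses the onset-occluder boundary at onset_time_s and its
# trailing edge clears the offset-occluder boundary exactly at 13 s; partial
# visibility while emerging adds 20 px of path on each side.
.uo_timing <- function(travel_px) {
  onset_time_s <- UO_OFFSET_TIME_S - (travel_px + UO_HALF_PX) / UO_SPEED_PX_S
  list(
    onset_time_s = onset_time_s,
    first_visible_s = onset_time_s - UO_HALF_PX / UO_SPEED_PX_S,
    visible_s = (travel_px + 2 * UO_HALF_PX) / UO_SPEED_PX_S
  )
}

.make_condition <- function(experiment, condition_id, has_uo, exposure_label_s,
                            onset_type, travel_px, onset_occluder_px,
                            offset_occluder_px, onset_nominal_s,
                            assignment_prob, width_px = 700) {
  if (has_uo) {
    stopifnot(onset_occluder_px + travel_px + offset_occluder_px == width_px)
    tm <- .uo_timing(travel_px)
  } else {
    tm <- list(onset_time_s = NA_real_, first_visible_s = NA_real_,
               visible_s = NA_real_)
  }
  tibble::tibble(
    experiment = experiment, condition_id = condition_id, has_uo = has_uo,
    exposure_label_s = exposure_label_s, onset_type = onset_type,
    travel_px = travel_px, onset_occluder_px = onset_occluder_px,
    offset_occluder_px = offset_occluder_px,
    onset_nominal_s = onset_nominal_s, onset_time_s = tm$onset_time_s,
    first_visible_s = tm$first_visible_s, visible_s = tm$visible_s,
    offset_time_s = ifelse(has_uo, UO_OFFSET_TIME_S, NA_real_),
    uo_speed_px_s = ifelse(has_uo, UO_SPEED_PX_S, NA_real_),
    trial_length_s = TRIAL_LENGTH_S, assignment_prob = assignment_prob
  )
}

#' Catalog of unexpected-object conditions for each experiment
#'
#' Returns every condition of the named experiment with its full geometry:
#' occluder placements, travel distance, onset type and timing. Occluder and
#' travel distances always sum to the display width (700 px), and in every
#' condition the unexpected object is last visible at 13 s (2 s before the
#' trial ends).
#'
#' Experiment `"E1"` has two centred unexpected-object conditions (2.67 s with
#' 210/210 px occluders and 280 px of travel; 5 s with 70/70 px occluders and
#' 560 px of travel) plus a no-unexpected-object control, with 2:2:1 assignment
#' odds. `"E2"` fully crosses three exposures (1.5/2.67/5 s; travel
#' 140/280/560 px) with edge versus mid-display onset. `"E3"` has two centred
#' conditions (1.5 s, travel 140; 5 s, travel 560).
#'
#' The nominal exposure labels and printed onset times (`onset_nominal_s`) are
#' labels; kinematic timing (`onset_time_s`, `first_visible_s`, `visible_s`)
#' is derived from travel distance, the 132 px/s speed and the offset-at-13-s
#' rule, counting partial visibility during the 40-px emergence.
#'
#' @param experiment One of `"E1"`, `"E2"`, `"E3"`.
#' @return A tibble of class `ib_catalog`, one row per condition. The
#'   `assignment_prob` column carries the per-subject assignment odds.
#' @export
#' @examples
#' condition_catalog("E1")
condition_catalog <- function(experiment) {
  experiment <- match.arg(experiment, c("E1", "E2", "E3"))
  cat <- switch(experiment,
    E1 = rbind(
      .make_condition("E1", "none", FALSE, NA_real_, "none", NA_real_,
                      NA_real_, NA_real_, NA_real_, 1 / 5),
      .make_condition("E1", "short_2.67s", TRUE, 2.67, "centred", 280,
                      210, 210, 10.33, 2 / 5),
      .make_condition("E1", "long_5s", TRUE, 5, "centred", 560, 70, 70, 8,
                      2 / 5)
    ),
    E2 = {
      travels <- c(140, 280, 560)
      labels <- c(1.5, 2.67, 5)
      rows <- list()
      for (i in seq_along(travels)) {
        tr <- travels[i]
        rows[[length(rows) + 1]] <- .make_condition(
          "E2", sprintf("edge_%gs", labels[i]), TRUE, labels[i], "edge",
          tr, 0, 700 - tr, 13 - labels[i], 1 / 6)
        rows[[length(rows) + 1]] <- .make_condition(
          "E2", sprintf("mid_%gs", labels[i]), TRUE, labels[i], "mid_display",
          tr, 700 - tr, 0, 13 - labels[i], 1 / 6)
      }
      do.call(rbind, rows)
    },
    E3 = rbind(
      .make_condition("E3", "short_1.5s", TRUE, 1.5, "centred", 140,
                      280, 280, 11.5, 1 / 2),
      .make_condition("E3", "long_5s", TRUE, 5, "centred", 560, 70, 70, 8,
                      1 / 2)
    )
  )
  class(cat) <- c("ib_catalog", class(cat))
  cat
}

# internal: one catalog row as a plain list, validating the id.
.condition_row <- function(condition) {
  if (inherits(condition, "ib_catalog") || is.data.frame(condition)) {
    stopifnot(nrow(condition) == 1)
    return(as.list(condition))
  }
  stopifnot(is.list(condition))
  condition
}

#' Unexpected-object path endpoints for one condition and direction
#'
#' @param condition A single catalog row.
#' @param direction `"LtoR"` or `"RtoL"`.
#' @param geometry Display geometry.
#' @return List with onset/offset x-coordinates (`x_on`, `x_off`), signed
#'   direction `dir` (+1 rightward), and the timing fields of the condition.
#' @export
uo_path <- function(condition, direction = c("LtoR", "RtoL"),
                    geometry = display_geometry()) {
  cond <- .condition_row(condition)
  direction <- match.arg(direction)
  stopifnot(isTRUE(cond$has_uo))
  dir <- if (direction == "LtoR") 1 else -1
  x_on <- if (dir > 0) cond$onset_occluder_px else
    geometry$width_px - cond$onset_occluder_px
  x_off <- x_on + dir * cond$travel_px
  list(
    x_on = x_on, x_off = x_off, dir = dir, direction = direction,
    onset_time_s = cond$onset_time_s, first_visible_s = cond$first_visible_s,
    offset_time_s = cond$offset_time_s, visible_s = cond$visible_s,
    y = geometry$fixation_y
  )
}

#' Unexpected-object position and visibility at time t
#'
#' The cross centre moves at 132 px/s along the vertical midline
#' (y = 300), crossing the onset-occluder boundary at `onset_time_s` and
#' disappearing (trailing edge at the offset-occluder boundary) at 13 s.
#' `visible_fraction` is the fraction of the 40 px cross width inside the
#' unoccluded strip between the two occluders, clipped to the display; it is 0
#' before emergence begins and after offset.
#'
#' @param condition A single catalog row with an unexpected object.
#' @param t Time(s) in seconds from the start of motion; must lie in
#'   `[0, trial_length_s]`.
#' @param direction `"LtoR"` or `"RtoL"`.
#' @param geometry Display geometry.
#' @return A tibble with `time_s`, `x`, `y`, `visible_fraction`. `x` and `y`
#'   are `NA` while the object is absent (fully occluded or outside its path).
#' @export
uo_kinematics <- function(condition, t, direction = c("LtoR", "RtoL"),
                          geometry = display_geometry()) {
  cond <- .condition_row(condition)
  if (any(t < 0 | t > cond$trial_length_s)) {
    stop("t must lie within [0, ", cond$trial_length_s, "] s")
  }
  path <- uo_path(cond, direction, geometry)
  centre <- path$x_on + path$dir * UO_SPEED_PX_S * (t - path$onset_time_s)
  present <- t >= path$first_visible_s & t <= path$offset_time_s
  # unoccluded strip along x, clipped to the display
  strip_lo <- max(min(path$x_on, path$x_off), 0)
  strip_hi <- min(max(path$x_on, path$x_off), geometry$width_px)
  lo <- pmax(centre - UO_HALF_PX, strip_lo)
  hi <- pmin(centre + UO_HALF_PX, strip_hi)
  vis <- pmax(hi - lo, 0) / (2 * UO_HALF_PX)
  vis[!present] <- 0
  tibble::tibble(
    time_s = t,
    x = ifelse(present, centre, NA_real_),
    y = ifelse(present, path$y, NA_real_),
    visible_fraction = vis
  )
}

#' Initial placement of the eight tracked objects
#'
#' Four white and four black objects (one square, triangle, diamond and circle
#' per colour) are placed uniformly at random, fully inside the display.
#' Initial speed is uniform over \{66, 132, 198\} px/s, heading uniform over
#' the four diagonals, and the first speed-change time uniform over
#' 300--1000 ms.
#'
#' @param geometry Display geometry.
#' @param motion Motion parameters.
#' @param seed Optional integer seed; identical seeds give identical states.
#' @return A data frame of class `ib_states` with one row per object: `id`,
#'   `colour`, `shape`, position `x`, `y`, heading signs `sx`, `sy`
#'   (components of the diagonal unit heading times `sqrt(2)`), `speed`
#'   (px/s along the diagonal), countdown `next_change_s`, and half-extents
#'   `half_w`, `half_h`.
#' @export
init_trial <- function(geometry = display_geometry(),
                       motion = motion_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shp <- shape_table()
  shp <- shp[shp$shape_id != "cross", ]
  n <- 2 * nrow(shp)
  half_w <- rep(shp$width_px / 2, 2)
  half_h <- rep(shp$height_px / 2, 2)
  st <- data.frame(
    id = seq_len(n),
    colour = rep(c("white", "black"), each = nrow(shp)),
    shape = rep(shp$shape_id, 2),
    x = stats::runif(n, half_w, geometry$width_px - half_w),
    y = stats::runif(n, half_h, geometry$height_px - half_h),
    sx = sample(c(-1, 1), n, replace = TRUE),
    sy = sample(c(-1, 1), n, replace = TRUE),
    speed = .sample_from(motion$speeds, n),
    next_change_s = stats::runif(n, motion$change_interval_min_ms / 1000,
                                 motion$change_interval_max_ms / 1000),
    half_w = half_w,
    half_h = half_h,
    stringsAsFactors = FALSE
  )
  class(st) <- c("ib_states", class(st))
  st
}

# sample() that never interprets a length-1 vector as 1:n
.sample_from <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# internal: one +/-66 step of the reflecting speed walk, vectorised.
.step_speed <- function(speed, motion) {
  up <- stats::runif(length(speed)) < 0.5
  delta <- ifelse(up, motion$speed_step, -motion$speed_step)
  delta[speed <= motion$speed_min] <- motion$speed_step
  delta[speed >= motion$speed_max] <- -motion$speed_step
  delta[speed <= motion$speed_min & speed >= motion$speed_max] <- 0
  speed + delta
}

#' Advance object states by one timestep
#'
#' Objects whose scheduled change time falls within the step have their speed
#' changed by +/-66 px/s (forced upward at 66, downward at 198) and a new
#' change interval drawn uniformly from 300--1000 ms. All objects then advance
#' along their 45-degree heading; each velocity component is
#' `speed / sqrt(2)`.
#'
#' @param states An `ib_states` data frame.
#' @param motion Motion parameters.
#' @param dt Timestep in seconds (1/60 s recommended); `dt = 0` returns the
#'   states unchanged.
#' @return The advanced states (positions may lie outside the display until
#'   [reflect_at_edges()] is applied).
#' @export
step_objects <- function(states, motion = motion_params(), dt = 1 / 60) {
  stopifnot(dt >= 0)
  if (dt == 0) return(states)
  due <- states$next_change_s <= dt
  if (any(due)) {
    states$speed[due] <- .step_speed(states$speed[due], motion)
    states$next_change_s[due] <- stats::runif(
      sum(due), motion$change_interval_min_ms / 1000,
      motion$change_interval_max_ms / 1000)
  }
  states$next_change_s[!due] <- states$next_change_s[!due] - dt
  comp <- states$speed / sqrt(2) * dt
  states$x <- states$x + states$sx * comp
  states$y <- states$y + states$sy * comp
  states
}

#' Reflect objects off the display edges
#'
#' An object contacting the left or right edge has its horizontal direction
#' reversed; top or bottom contact reverses the vertical direction. Speed is
#' preserved and the overshoot is mirrored back inside. A corner contact
#' reverses both components and emits two bounce events in the same frame.
#'
#' @param states An `ib_states` data frame (after [step_objects()]).
#' @param geometry Display geometry.
#' @return A list with `states` (corrected) and `bounces`, a data frame of
#'   bounce events (`object_id`, `edge`).
#' @export
reflect_at_edges <- function(states, geometry = display_geometry()) {
  lo_x <- states$half_w; hi_x <- geometry$width_px - states$half_w
  lo_y <- states$half_h; hi_y <- geometry$height_px - states$half_h
  ev_id <- integer(0); ev_edge <- character(0)
  hit <- states$x < lo_x
  if (any(hit)) {
    states$x[hit] <- 2 * lo_x[hit] - states$x[hit]
    states$sx[hit] <- -states$sx[hit]
    ev_id <- c(ev_id, states$id[hit]); ev_edge <- c(ev_edge, rep("left", sum(hit)))
  }
  hit <- states$x > hi_x
  if (any(hit)) {
    states$x[hit] <- 2 * hi_x[hit] - states$x[hit]
    states$sx[hit] <- -states$sx[hit]
    ev_id <- c(ev_id, states$id[hit]); ev_edge <- c(ev_edge, rep("right", sum(hit)))
  }
  hit <- states$y < lo_y
  if (any(hit)) {
    states$y[hit] <- 2 * lo_y[hit] - states$y[hit]
    states$sy[hit] <- -states$sy[hit]
    ev_id <- c(ev_id, states$id[hit]); ev_edge <- c(ev_edge, rep("top", sum(hit)))
  }
  hit <- states$y > hi_y
  if (any(hit)) {
    states$y[hit] <- 2 * hi_y[hit] - states$y[hit]
    states$sy[hit] <- -states$sy[hit]
    ev_id <- c(ev_id, states$id[hit]); ev_edge <- c(ev_edge, rep("bottom", sum(hit)))
  }
  list(
    states = states,
    bounces = data.frame(object_id = ev_id, edge = ev_edge,
                         stringsAsFactors = FALSE)
  )
}

#' Simulate one full tracking trial
#'
#' Runs the eight tracked objects for 15 s of motion at a fixed timestep,
#' recording per-frame positions, every bounce event with its time, edge and
#' object colour, the per-colour ground-truth bounce counts, and (when the
#' condition has one) the unexpected object's centre and visible fraction at
#' each frame. Fully deterministic given the seed.
#'
#' @param condition A single catalog row (or `NULL` for a plain trial with no
#'   unexpected object).
#' @param geometry Display geometry.
#' @param motion Motion parameters.
#' @param seed Integer seed.
#' @param direction `"LtoR"` or `"RtoL"` for the unexpected object.
#' @param dt Timestep in seconds.
#' @param keep_positions Record the full per-frame position matrices.
#' @return An object of class `ib_trial`: a list with `condition`,
#'   `direction`, `dt`, `times`, `objects`, optional `pos_x`/`pos_y`
#'   (frames x objects matrices), `bounce_events` (`time_s`, `object_id`,
#'   `colour`, `edge`), `true_bounces` (named count per colour), and `uo`
#'   (per-frame tibble or `NULL`).
#' @export
simulate_trial <- function(condition = NULL, geometry = display_geometry(),
                           motion = motion_params(), seed = NULL,
                           direction = c("LtoR", "RtoL"), dt = 1 / 60,
                           keep_positions = TRUE) {
  direction <- match.arg(direction)
  cond <- if (is.null(condition)) NULL else .condition_row(condition)
  if (!is.null(seed)) set.seed(seed)
  states <- init_trial(geometry, motion, seed = NULL)
  n_frames <- ceiling(TRIAL_LENGTH_S / dt)
  times <- seq_len(n_frames) * dt
  pos_x <- if (keep_positions) matrix(NA_real_, n_frames, nrow(states)) else NULL
  pos_y <- pos_x
  ev_time <- numeric(0); ev_id <- integer(0); ev_edge <- character(0)
  for (k in seq_len(n_frames)) {
    states <- step_objects(states, motion, dt)
    res <- reflect_at_edges(states, geometry)
    states <- res$states
    if (nrow(res$bounces)) {
      ev_time <- c(ev_time, rep(times[k], nrow(res$bounces)))
      ev_id <- c(ev_id, res$bounces$object_id)
      ev_edge <- c(ev_edge, res$bounces$edge)
    }
    if (keep_positions) {
      pos_x[k, ] <- states$x
      pos_y[k, ] <- states$y
    }
  }
  colour_of <- states$colour
  bounce_events <- data.frame(
    time_s = ev_time, object_id = ev_id,
    colour = colour_of[ev_id], edge = ev_edge, stringsAsFactors = FALSE)
  true_bounces <- c(
    white = sum(bounce_events$colour == "white"),
    black = sum(bounce_events$colour == "black"))
  uo <- NULL
  if (!is.null(cond) && isTRUE(cond$has_uo)) {
    uo <- uo_kinematics(cond, times, direction, geometry)
  }
  structure(
    list(
      condition = cond, direction = direction, dt = dt, times = times,
      objects = states[, c("id", "colour", "shape", "half_w", "half_h")],
      pos_x = pos_x, pos_y = pos_y, bounce_events = bounce_events,
      true_bounces = true_bounces, uo = uo, seed = seed
    ),
    class = "ib_trial"
  )
}

#' Long-run simulation of the speed-change process
#'
#' Simulates a single object's speed as it performs the reflecting +/-66 px/s
#' walk on \{66, 132, 198\} with uniform 300--1000 ms holding times, and
#' returns the time-averaged speed. The stationary distribution of the
#' embedded chain is (1/4, 1/2, 1/4), so the long-run mean is 132 px/s.
#'
#' @param motion Motion parameters.
#' @param seed Integer seed.
#' @param duration_s Simulated time span in seconds (used if `n_changes` is
#'   `NULL`).
#' @param n_changes Alternatively, the number of speed-change events.
#' @return A list with `mean_speed` (time-weighted, px/s), `n_changes`,
#'   `duration_s`, and the per-interval `speeds` vector.
#' @export
simulate_speed_process <- function(motion = motion_params(), seed = NULL,
                                   duration_s = 1e5, n_changes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- motion$change_interval_min_ms / 1000
  hi <- motion$change_interval_max_ms / 1000
  if (is.null(n_changes)) {
    n <- ceiling(duration_s / lo) + 1L
  } else {
    n <- n_changes
    duration_s <- NULL
  }
  iv <- stats::runif(n, lo, hi)
  up <- stats::runif(n) < 0.5
  speeds <- numeric(n)
  s <- .sample_from(motion$speeds, 1)
  smin <- motion$speed_min; smax <- motion$speed_max; step <- motion$speed_step
  for (k in seq_len(n)) {
    speeds[k] <- s
    if (s <= smin) s <- s + step
    else if (s >= smax) s <- s - step
    else s <- s + if (up[k]) step else -step
  }
  if (!is.null(duration_s)) {
    tt <- cumsum(iv)
    last <- which(tt >= duration_s)[1]
    iv <- iv[seq_len(last)]
    iv[last] <- iv[last] - (tt[last] - duration_s)
    speeds <- speeds[seq_len(last)]
    n <- last
  } else {
    duration_s <- sum(iv)
  }
  list(
    mean_speed = sum(speeds * iv) / sum(iv),
    n_changes = n, duration_s = duration_s, speeds = speeds
  )
}

#' Export a trial trace to JSON-lines and a bounce-event CSV
#'
#' @param trial An `ib_trial`.
#' @param jsonl_path Path for the per-frame JSON-lines records.
#' @param bounce_csv_path Optional path for the bounce-event table (columns
#'   `time_s`, `object_id`, `colour`, `edge`).
#' @return `jsonl_path`, invisibly.
#' @export
export_trace <- function(trial, jsonl_path, bounce_csv_path = NULL) {
  stopifnot(inherits(trial, "ib_trial"), !is.null(trial$pos_x))
  con <- file(jsonl_path, "w")
  on.exit(close(con))
  for (k in seq_along(trial$times)) {
    rec <- list(
      time_s = trial$times[k],
      x = trial$pos_x[k, ], y = trial$pos_y[k, ]
    )
    if (!is.null(trial$uo)) {
      rec$uo <- list(x = trial$uo$x[k], y = trial$uo$y[k],
                     visible_fraction = trial$uo$visible_fraction[k])
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  if (!is.null(bounce_csv_path)) {
    utils::write.csv(trial$bounce_events, bounce_csv_path, row.names = FALSE)
  }
  invisible(jsonl_path)
}
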