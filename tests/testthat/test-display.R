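test_that("condition catalogs carry the published geometry", {
  e1 <- condition_catalog("E1")
  expect_equal(nrow(e1), 3)
  expect_equal(sum(!e1$has_uo), 1)
  long <- e1[e1$condition_id == "long_5s", ]
  expect_equal(long$exposure_label_s, 5)
  expect_equal(long$onset_occluder_px, 70)
  expect_equal(long$offset_occluder_px, 70)
  expect_equal(long$travel_px, 560)
  expect_equal(long$onset_nominal_s, 8)
  short <- e1[e1$condition_id == "short_2.67s", ]
  expect_equal(short$onset_occluder_px, 210)
  expect_equal(short$travel_px, 280)
  expect_equal(short$onset_nominal_s, 10.33)

  e2 <- condition_catalog("E2")
  expect_equal(nrow(e2), 6)
  edge15 <- e2[e2$condition_id == "edge_1.5s", ]
  expect_equal(edge15$travel_px, 140)
  expect_equal(edge15$onset_occluder_px, 0)
  expect_equal(edge15$offset_occluder_px, 560)

  e3 <- condition_catalog("E3")
  expect_equal(nrow(e3), 2)
  expect_setequal(e3$travel_px, c(140, 560))

  for (ex in c("E1", "E2", "E3")) {
    uo <- condition_catalog(ex)
    uo <- uo[uo$has_uo, ]
    expect_true(all(uo$onset_occluder_px + uo$travel_px +
                      uo$offset_occluder_px == 700))
    expect_true(all(uo$offset_time_s == 13))
  }
  expect_error(condition_catalog("E4"))
})

test_that("initial placement is seeded, contained and uniform", {
  a <- init_trial(seed = 42)
  b <- init_trial(seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 8)
  expect_equal(sum(a$colour == "white"), 4)
  expect_equal(sum(a$colour == "black"), 4)
  expect_equal(anyDuplicated(paste(a$colour, a$shape)), 0L)

  g <- display_geometry()
  set.seed(7)
  xs <- replicate(3000, {
    st <- init_trial()
    ok <- all(st$x >= st$half_w & st$x <= g$width_px - st$half_w &
                st$y >= st$half_h & st$y <= g$height_px - st$half_h)
    expect_true(ok)
    st$x[1]
  })
  # object 1 is the white square (half-extent 20): x uniform on [20, 680]
  ks <- stats::ks.test(xs, "punif", 20, 680)
  expect_gt(ks$p.value, 0.01)
})

test_that("speed updates form a closed reflecting walk with mean 132", {
  st <- init_trial(seed = 1)
  expect_identical(step_objects(st, dt = 0), st)

  # a speed of 66 can only rise, 198 can only fall
  st$speed <- rep(c(66, 198), 4)
  st$next_change_s <- 0
  set.seed(2)
  st2 <- step_objects(st, dt = 1 / 60)
  expect_true(all(st2$speed == 132))

  sp <- simulate_speed_process(seed = 3, duration_s = 5e4)
  expect_true(all(sp$speeds %in% c(66, 132, 198)))
  expect_lt(abs(sp$mean_speed - 132), 1)

  big <- simulate_speed_process(seed = 4, n_changes = 1e6)
  expect_true(all(big$speeds %in% c(66, 132, 198)))
})

test_that("edge reflection preserves speed and reverses the right component", {
  g <- display_geometry()
  st <- init_trial(seed = 5)[1, ]
  st$x <- 15; st$y <- 300; st$sx <- -1; st$sy <- 1; st$speed <- 132
  res <- reflect_at_edges(st, g)
  expect_equal(res$states$sx, 1)
  expect_equal(res$states$sy, 1)
  expect_equal(res$states$speed, 132)
  expect_equal(res$states$x, 2 * st$half_w - 15)
  expect_equal(res$bounces$edge, "left")

  # corner contact reverses both and emits two events
  st$x <- g$width_px - 10; st$y <- g$height_px - 12
  st$sx <- 1; st$sy <- 1
  res <- reflect_at_edges(st, g)
  expect_equal(res$states$sx, -1)
  expect_equal(res$states$sy, -1)
  expect_equal(nrow(res$bounces), 2)
  expect_setequal(res$bounces$edge, c("right", "bottom"))
})

test_that("bounce counts on pinned-speed traces match the analytic oracle", {
  g <- display_geometry()
  pinned <- motion_params(132, 132, 66, 1e6, 1e6)
  for (seed in c(11, 12, 13)) {
    tr <- simulate_trial(NULL, g, pinned, seed = seed)
    st0 <- init_trial(g, pinned, seed = seed)
    for (i in 1:8) {
      want <- oracle_bounce_count(st0$x[i], st0$y[i], st0$sx[i], st0$sy[i],
                                  132, 15, g, st0$half_w[i], st0$half_h[i])
      got <- sum(tr$bounce_events$object_id == i)
      expect_equal(got, want)
    }
  }
})

test_that("unexpected-object kinematics follow the occluder geometry", {
  e1 <- condition_catalog("E1")
  long <- e1[e1$condition_id == "long_5s", ]

  at_onset <- uo_kinematics(long, long$onset_time_s, "LtoR")
  expect_equal(at_onset$x, 70)
  expect_equal(at_onset$y, 300)
  expect_equal(at_onset$visible_fraction, 0.5)

  # 1 s after onset the centre has moved 132 px in the motion direction
  short <- e1[e1$condition_id == "short_2.67s", ]
  later <- uo_kinematics(short, short$onset_time_s + 1, "LtoR")
  expect_equal(later$x, 210 + 132)
  rtl <- uo_kinematics(short, short$onset_time_s + 1, "RtoL")
  expect_equal(rtl$x, 700 - 210 - 132)

  # centred paths pass fixation at the temporal midpoint of the traversal
  t_mid <- long$onset_time_s + (long$travel_px / 2) / 132
  expect_equal(uo_kinematics(long, t_mid, "LtoR")$x, 350)
  expect_equal(uo_kinematics(long, t_mid, "RtoL")$x, 350)

  expect_error(uo_kinematics(long, 15.5, "LtoR"))
  expect_error(uo_kinematics(long, -0.1, "LtoR"))
})

test_that("the unexpected object is last visible at 13 s in every condition", {
  dt <- 1 / 60
  times <- seq(dt, 15, by = dt)
  for (ex in c("E1", "E2", "E3")) {
    cat0 <- condition_catalog(ex)
    for (i in which(cat0$has_uo)) {
      for (dir in c("LtoR", "RtoL")) {
        k <- uo_kinematics(cat0[i, ], times, dir)
        last_vis <- max(times[k$visible_fraction > 0])
        expect_lt(abs(last_vis - 13), dt + 1e-9)
        expect_true(all(k$y[k$visible_fraction > 0] == 300))
        # visible duration matches (travel + 40) / 132 to within a frame
        vis <- sum(k$visible_fraction > 0) * dt
        expect_lt(abs(vis - cat0$visible_s[i]), 2 * dt)
      }
    }
  }
})

test_that("trials are reproducible and stay inside the display", {
  cond <- condition_catalog("E1")[3, ]
  a <- simulate_trial(cond, seed = 21)
  b <- simulate_trial(cond, seed = 21)
  expect_identical(a$true_bounces, b$true_bounces)
  expect_identical(a$bounce_events, b$bounce_events)
  expect_identical(a$pos_x, b$pos_x)

  g <- display_geometry()
  hw <- matrix(a$objects$half_w, nrow(a$pos_x), 8, byrow = TRUE)
  hh <- matrix(a$objects$half_h, nrow(a$pos_y), 8, byrow = TRUE)
  expect_true(all(a$pos_x >= hw - 1e-9 & a$pos_x <= g$width_px - hw + 1e-9))
  expect_true(all(a$pos_y >= hh - 1e-9 & a$pos_y <= g$height_px - hh + 1e-9))

  none <- condition_catalog("E1")[1, ]
  expect_null(simulate_trial(none, seed = 3)$uo)
})

test_that("white and black bounce counts are exchangeable", {
  set.seed(31)
  counts <- t(replicate(150, simulate_trial(keep_positions = FALSE)$true_bounces))
  d <- counts[, "white"] - counts[, "black"]
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 2 * se + 1e-9)
})
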