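# Advection, diffusion, decay engines and single-event tracking.

test_that("velocity interpolation is exact at nodes and bilinear between", {
  f <- make_uniform_field(u = 0.3, v = -0.1, half_span_km = 2, hours = 3)
  uv <- interpolate_velocity(f, f$lon[2] + 1e-4, f$lat[3] + 2e-4, 0.5)
  expect_equal(unname(uv[, 1]), c(0.3, -0.1))
  # node / slice exactness on a non-uniform field
  p <- quiet_site_profile()
  g <- field_grid_spec(-4.62, 47.6, nx = 6, ny = 5, spacing_m = 700,
                       time_start = "2018-01-01", time_end = "2018-01-01 04:00")
  fq <- generate_flow_field(p, g, seed = 3)
  got <- interpolate_velocity(fq, fq$lon[4], fq$lat[2], fq$time_h[3])
  expect_equal(unname(got["u", 1]), fq$u[4, 2, 3], tolerance = 1e-12)
  expect_equal(unname(got["v", 1]), fq$v[4, 2, 3], tolerance = 1e-12)
  # hand bilinear: midpoint of 4 nodes valued (0, 0, 1, 1)
  ff <- make_uniform_field(u = 0, half_span_km = 1, spacing_m = 1000, hours = 1)
  ff$u[, , 1] <- 0
  ic <- (length(ff$lon) + 1L) %/% 2L
  ff$u[ic:(ic + 1L), ic + 1L, 1] <- 1   # northern pair = 1, southern pair = 0
  midlon <- mean(ff$lon[ic:(ic + 1L)])
  midlat <- mean(ff$lat[ic:(ic + 1L)])
  expect_equal(unname(interpolate_velocity(ff, midlon, midlat, 0)["u", 1]), 0.5)
  # out-of-domain query signals NA
  expect_true(is.na(interpolate_velocity(ff, max(ff$lon) + 1, midlat, 0)["u", 1]))
})

test_that("RK4 is exact for zero and constant flow", {
  f0 <- make_uniform_field(u = 0, v = 0, hours = 2)
  pos <- rk4_step(-4.6, 47.6, f0, 0, 180)
  expect_equal(unname(pos[1, ]), c(-4.6, 47.6))
  f1 <- make_uniform_field(u = 1, v = 0, hours = 2)
  pos <- rk4_step(-4.6, 47.6, f1, 0, 180)
  # 180 m east, converted at the particle latitude
  expect_equal(haversine_km(-4.6, 47.6, pos[1, 1], pos[1, 2]), 0.180,
               tolerance = 1e-6)
  expect_equal(unname(pos[1, 2]), 47.6)
})

test_that("RK4 closes a solid-body rotation orbit to within 0.1% of its radius", {
  period_s <- 6 * 3600
  f <- make_rotation_field(omega = 2 * pi / period_s)
  mper <- 6371000 * pi / 180
  start <- c(5000 / (mper * cos(45 * pi / 180)), 45)   # 5 km east of centre
  cur <- start
  for (i in seq_len(period_s / 180))
    cur <- rk4_step(cur[1], cur[2], f, 0, 180)[1, ]
  err_km <- haversine_km(cur[1], cur[2], start[1], start[2])
  expect_lt(err_km / 5, 0.001)
})

test_that("diffusion reproduces the 2-D mean-squared-displacement law", {
  set.seed(1)
  n <- 1e5
  lon <- rep(0, n); lat <- rep(45, n)
  for (i in 1:20) {
    d <- diffusion_step(lon, lat, K = 1, dt = 180)
    lon <- d[, 1]; lat <- d[, 2]
  }
  mper <- 6371000 * pi / 180
  msd <- mean((lon * mper * cos(45 * pi / 180))^2 + ((lat - 45) * mper)^2)
  expect_equal(msd, 4 * 1 * 3600, tolerance = 0.02)
  # K = 0 leaves positions untouched; same seed repeats the draws
  d0 <- diffusion_step(c(1, 2), c(40, 41), K = 0, dt = 180)
  expect_equal(unname(d0[, 1]), c(1, 2))
  set.seed(7); a <- diffusion_step(0, 45, 1, 180)
  set.seed(7); b <- diffusion_step(0, 45, 1, 180)
  expect_identical(a, b)
})

test_that("release schedule counts match the two-month 2-hourly design", {
  p <- quiet_site_profile()
  one <- build_release_schedule(list(c(2018, 1), c(2018, 9)), 2, p, "exponential")
  expect_equal(nrow(one), 732)
  four <- build_release_schedule(list(c(2018, 1), c(2018, 9)), 2, p,
                                 c("exponential", "biphasic", "delayed",
                                   "no_decay"))
  expect_equal(nrow(four), 2928)
  # a single 31-day month at daily cadence
  daily <- build_release_schedule(list(c(2018, 1)), 24, p, "no_decay")
  expect_equal(nrow(daily), 31)
  # the same release occasion keeps one release_id across scenarios
  expect_equal(length(unique(four$release_id)), 732)
  expect_error(build_release_schedule(list(c(2018, 13)), 2, p, "no_decay"),
               "month")
  expect_error(build_release_schedule(list(c(2018, 1)), 7, p, "no_decay"),
               "divide")
})

test_that("survival probability obeys the exponential semigroup", {
  expect_equal(survival_probability(0, 1), 1)
  expect_equal(survival_probability(0.1083, 6.4), 0.5, tolerance = 1e-4)
  dt <- 0.05
  expect_equal(survival_probability(0.3, dt)^2, survival_probability(0.3, 2 * dt))
})

test_that("biphasic group assignment is an exact-count split", {
  set.seed(1)
  g <- assign_biphasic_groups(10000)
  expect_equal(sum(g == 0.50), 7000)
  expect_equal(sum(g == 0.013), 3000)
  g10 <- assign_biphasic_groups(10)
  expect_equal(sum(g10 == 0.50), 7)
  # re-seeding permutes membership but not counts
  set.seed(2)
  g2 <- assign_biphasic_groups(10000)
  expect_false(identical(g, g2))
  expect_equal(as.integer(table(g)), as.integer(table(g2)))
  expect_error(assign_biphasic_groups(10, fractions = c(0.7, 0.2)), "sum to 1")
})

test_that("decay step matches closed-form survival on an ensemble", {
  set.seed(42)
  sc <- decay_scenario("exponential")
  alive <- rep(TRUE, 10000)
  # one hour of 3-min steps at 12.24 C (k = 0.1083/h)
  Tq <- log(0.1083 / 0.0419) / 0.0776
  for (i in 1:20)
    alive <- apply_decay_step(alive, sc, Tq, 0.05)
  expected <- 10000 * exp(-0.1083)
  se <- sqrt(10000 * exp(-0.1083) * (1 - exp(-0.1083)))
  expect_lt(abs(sum(alive) - expected), 4 * se)
  # no-decay leaves everything alive; dead particles never resurrect
  expect_true(all(apply_decay_step(alive, decay_scenario("no_decay"), 12, 0.05)
                  == alive))
  dead <- rep(FALSE, 10)
  expect_false(any(apply_decay_step(dead, sc, 12, 0.05)))
  # biphasic requires a group assignment
  expect_error(apply_decay_step(rep(TRUE, 5), decay_scenario("biphasic"),
                                12, 0.05), "group_rates")
})

test_that("delayed division triples the population over six hourly rounds", {
  set.seed(3)
  st <- list(lon = rep(0, 10000), lat = rep(45, 10000),
             alive = rep(TRUE, 10000), id = 1:10000,
             parent_id = rep(NA_integer_, 10000),
             group_rates = rep(NA_real_, 10000), birth_hour = rep(0, 10000))
  st1 <- apply_delayed_division(st, 1)
  expect_equal(sum(st1$alive), 12000)
  # children appear at their parent's exact position
  kid <- which(!is.na(st1$parent_id))[1]
  par <- match(st1$parent_id[kid], st1$id)
  expect_equal(st1$lon[kid], st1$lon[par])
  for (h in 2:6) st1 <- apply_delayed_division(st1, h)
  expect_true(sum(st1$alive) >= 29859 && sum(st1$alive) <= 29861)
  # beyond the growth phase the call is a no-op
  st7 <- apply_delayed_division(st1, 7)
  expect_equal(sum(st7$alive), sum(st1$alive))
  expect_error(apply_delayed_division(st, 1, fraction = 1.2), "fraction")
})

test_that("a no-decay event in still water keeps every particle at the origin", {
  f <- make_uniform_field(u = 0, v = 0, hours = 7)
  ev <- make_event(f, "no_decay")
  cfg <- simulation_config(diffusivity_K = 0, n_particles = 50L,
                           tracking_horizon_h = 6, seed = 1L)
  tr <- run_event(ev, f, cfg)
  expect_true(all(tr$alive))
  expect_true(all(tr$lon == ev$release_lon))
  expect_true(all(tr$lat == ev$release_lat))
  expect_equal(sort(unique(tr$hour)), 0:6)
})

test_that("event trajectories conserve counts and never resurrect particles", {
  f <- make_uniform_field(u = 0.2, v = 0.05, temp = 12, hours = 13)
  ev <- make_event(f, "delayed")
  cfg <- simulation_config(n_particles = 400L, tracking_horizon_h = 12,
                           seed = 5L)
  tr <- run_event(ev, f, cfg)
  alive_h <- tapply(tr$alive, tr$hour, sum)
  created_h <- tapply(tr$alive, tr$hour, length)
  expect_true(all(alive_h <= created_h))
  expect_true(all(diff(created_h) >= 0))
  # growth phase: threefold by hour 6, then decline only
  expect_equal(unname(created_h[["6"]] / created_h[["0"]]), 3, tolerance = 0.01)
  expect_true(all(diff(alive_h[as.character(6:12)]) <= 0))
  # one-way alive transitions per particle
  for (pid in sample(unique(tr$particle_id), 40)) {
    a <- tr$alive[tr$particle_id == pid]
    expect_true(all(diff(as.integer(a)) <= 0))
  }
  # reproducibility of a full event
  tr2 <- run_event(ev, f, cfg)
  expect_identical(tr, tr2)
})

test_that("uniform flow displaces the ensemble mean at the flow speed", {
  f <- make_uniform_field(u = 0.5, v = 0, temp = 12, hours = 8)
  ev <- make_event(f, "no_decay")
  cfg <- simulation_config(n_particles = 300L, tracking_horizon_h = 6,
                           seed = 2L)
  tr <- run_event(ev, f, cfg)
  h6 <- tr[tr$hour == 6 & tr$alive, ]
  com <- center_of_mass(h6$lon, h6$lat)
  d <- mean_distance(c(ev$release_lon, ev$release_lat), com)
  expect_equal(d, 0.5 * 6 * 3.6, tolerance = 0.02)  # v t = 10.8 km
})

test_that("transport is statistically independent of decay (position law)", {
  f <- make_uniform_field(u = 0.3, v = 0.1, temp = 12, hours = 13,
                          half_span_km = 25)
  cfg <- simulation_config(n_particles = 10000L, tracking_horizon_h = 12,
                           seed = 8L)
  tr_nd <- run_event(make_event(f, "no_decay"), f, cfg)
  tr_ex <- run_event(make_event(f, "exponential"), f, cfg)
  a <- tr_nd[tr_nd$hour == 12 & tr_nd$alive, ]
  b <- tr_ex[tr_ex$hour == 12 & tr_ex$alive, ]
  expect_gt(nrow(b), 1000)
  ks_lon <- suppressWarnings(stats::ks.test(a$lon, b$lon)$statistic)
  ks_lat <- suppressWarnings(stats::ks.test(a$lat, b$lat)$statistic)
  expect_lt(unname(ks_lon), 0.05)
  expect_lt(unname(ks_lat), 0.05)
})
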