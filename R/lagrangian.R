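# 2-D surface particle tracking: RK4 advection on gridded flow, random-walk
# diffusion, and the four per-particle decay scenario engines.

#' Simulation configuration
#'
#' @param diffusivity_K Horizontal diffusivity (m^2/s, default 1), matched to
#'   a ~500 m grid.
#' @param timestep Integration time step (seconds, default 180 = 3 min); must
#'   divide the record cadence.
#' @param tracking_horizon_h Tracking horizon (hours, default 24).
#' @param n_particles Particles per release (default 10000).
#' @param record_cadence_h Hours between recorded positions (default 1).
#' @param seed Master seed; per-event child seeds are derived from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(diffusivity_K = 1, timestep = 180,
                              tracking_horizon_h = 24, n_particles = 10000L,
                              record_cadence_h = 1, seed = 1L) {
  stopifnot(diffusivity_K >= 0, timestep > 0, n_particles >= 1)
  nsub <- record_cadence_h * 3600 / timestep
  if (abs(nsub - round(nsub)) > 1e-9)
    stop("timestep must divide the record cadence")
  structure(list(diffusivity_K = diffusivity_K, timestep = timestep,
                 tracking_horizon_h = tracking_horizon_h,
                 n_particles = as.integer(n_particles),
                 record_cadence_h = record_cadence_h, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Decay scenario specification
#'
#' The four per-particle decay scenarios:
#' * `exponential` - each particle survives every step with probability
#'   `exp(-k(T) dt)`, `k(T)` from the temperature-decay law;
#' * `biphasic` - particles are split once into a fast group (fraction 0.7 at
#'   0.50 per hour) and a slow group (0.3 at 0.013 per hour), each keeping a
#'   constant rate for the whole simulation;
#' * `delayed` - during the first 6 h after release no decay is drawn and 20%
#'   of the alive particles are duplicated in place each hour (about a
#'   threefold increase by hour 6); afterwards identical to `exponential`;
#' * `no_decay` - all particles persist.
#'
#' @param kind One of `"exponential"`, `"biphasic"`, `"delayed"`, `"no_decay"`.
#' @param law [temperature_decay_law()] used by the exponential scenario and
#'   the delayed scenario's decline phase.
#' @param biphasic_fractions Group fractions (must sum to 1).
#' @param biphasic_rates Group decay rates (per hour).
#' @param division_fraction_per_h Fraction of alive particles duplicated per
#'   hour during the delayed growth phase (default 0.20).
#' @param division_duration_h Length of the growth phase (hours, default 6).
#' @return An object of class `decay_scenario`.
#' @export
decay_scenario <- function(kind = c("exponential", "biphasic", "delayed", "no_decay"),
                           law = temperature_decay_law(),
                           biphasic_fractions = c(0.7, 0.3),
                           biphasic_rates = c(0.50, 0.013),
                           division_fraction_per_h = 0.20,
                           division_duration_h = 6) {
  kind <- match.arg(kind)
  if (abs(sum(biphasic_fractions) - 1) > 1e-9)
    stop("biphasic_fractions must sum to 1")
  if (any(biphasic_rates < 0)) stop("rates must be non-negative")
  if (division_fraction_per_h < 0 || division_fraction_per_h > 1)
    stop("division_fraction_per_h must be in [0, 1]")
  structure(list(kind = kind, law = law,
                 biphasic_fractions = biphasic_fractions,
                 biphasic_rates = biphasic_rates,
                 division_fraction_per_h = division_fraction_per_h,
                 division_duration_h = division_duration_h),
            class = "decay_scenario")
}

#' Expected survival curve of a decay scenario
#'
#' Expected alive-particle fraction (relative to the released number) at time
#' `t` after release, used as the closed-form reference for the stochastic
#' engines. For the delayed scenario the growth phase multiplies the count by
#' `(1 + division fraction)` at each completed hour.
#'
#' @param scenario A [decay_scenario()].
#' @param t Hours since release (vectorized).
#' @param temperature Water temperature (degrees C) for the
#'   temperature-dependent scenarios.
#' @return Expected alive fraction (may exceed 1 for the delayed scenario).
#' @export
scenario_survival <- function(scenario, t, temperature = 12) {
  stopifnot(inherits(scenario, "decay_scenario"))
  k <- temperature_decay_rate(scenario$law, temperature)
  switch(scenario$kind,
    no_decay = rep(1, length(t)),
    exponential = exp(-k * t),
    biphasic = {
      f <- scenario$biphasic_fractions
      r <- scenario$biphasic_rates
      f[1] * exp(-r[1] * t) + f[2] * exp(-r[2] * t)
    },
    delayed = {
      g <- (1 + scenario$division_fraction_per_h) ^
        pmin(floor(t), scenario$division_duration_h)
      g * exp(-k * pmax(t - scenario$division_duration_h, 0))
    })
}

#' @rdname half_life
#' @export
half_life.decay_scenario <- function(model, temperature = 12, ...) {
  if (model$kind == "no_decay") return(Inf)
  .half_life_bisect(function(t) scenario_survival(model, t, temperature))
}

#' Build a release schedule
#'
#' One release event per (time, site, scenario), at a fixed cadence covering
#' each listed month completely. With a 2-hour cadence over January and
#' September of one year this gives 372 + 360 = 732 events per
#' (site, scenario) combination.
#'
#' @param months List of `c(year, month)` pairs (or a 2-column matrix).
#' @param cadence_h Release cadence in hours; must divide 24.
#' @param sites List of [site_profile()] objects (or a single one).
#' @param scenarios Character vector of scenario kinds or list of
#'   [decay_scenario()] objects.
#' @return Data frame with columns `event_id`, `release_id` (shared by the
#'   scenarios of one release occasion), `site`, `release_lon`,
#'   `release_lat`, `release_time`, `scenario`.
#' @export
build_release_schedule <- function(months, cadence_h = 2, sites, scenarios) {
  if (24 %% cadence_h != 0) stop("cadence_h must divide 24")
  if (inherits(sites, "site_profile")) sites <- list(sites)
  if (inherits(scenarios, "decay_scenario")) scenarios <- list(scenarios)
  scen_names <- vapply(scenarios, function(s)
    if (is.character(s)) s else s$kind, character(1))
  if (is.matrix(months)) months <- asplit(months, 1)
  times <- do.call(c, lapply(months, function(ym) {
    y <- ym[1]; mo <- ym[2]
    if (mo < 1 || mo > 12) stop("unknown month: ", mo)
    start <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", y, mo), tz = "UTC")
    nxt <- if (mo == 12) as.POSIXct(sprintf("%04d-01-01", y + 1), tz = "UTC")
           else as.POSIXct(sprintf("%04d-%02d-01", y, mo + 1), tz = "UTC")
    seq(start, nxt - 1, by = cadence_h * 3600)
  }))
  rows <- expand.grid(time_i = seq_along(times),
                      site_i = seq_along(sites),
                      scen_i = seq_along(scen_names),
                      KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(
    event_id = seq_len(nrow(rows)),
    # release_id identifies the shared release occasion (site x time): the
    # same occasion simulated under different scenarios keeps one release_id,
    # which is the blocking unit of the variance decomposition
    release_id = rows$time_i + (rows$site_i - 1L) * length(times),
    site = vapply(sites, `[[`, character(1), "name")[rows$site_i],
    release_lon = vapply(sites, `[[`, numeric(1), "center_lon")[rows$site_i],
    release_lat = vapply(sites, `[[`, numeric(1), "center_lat")[rows$site_i],
    release_time = times[rows$time_i],
    scenario = scen_names[rows$scen_i],
    stringsAsFactors = FALSE)
  df
}

#' Interpolate velocity (and temperature) in a flow field
#'
#' Bilinear interpolation in space and linear interpolation in time, applied
#' to `u` and `v` independently; exact at grid nodes and stored time slices.
#' Queries outside the grid (or time span) return `NA`, which callers treat
#' as the particle having exited the domain.
#'
#' @param field A `flow_field`.
#' @param lon,lat Query positions (degrees, vectorized).
#' @param time_h Scalar query time in hours since the field's first slice.
#' @return `interpolate_velocity`: 2 x n matrix (rows `u`, `v`, m/s);
#'   `interpolate_temperature`: numeric vector (degrees C).
#' @export
interpolate_velocity <- function(field, lon, lat, time_h) {
  pr <- .interp_prepare(field, lon, lat, time_h)
  rbind(u = .interp_apply(field$u, pr), v = .interp_apply(field$v, pr))
}

#' @rdname interpolate_velocity
#' @export
interpolate_temperature <- function(field, lon, lat, time_h) {
  .interp_apply(field$temp, .interp_prepare(field, lon, lat, time_h))
}

# fractional-index bookkeeping shared by u/v/temp lookups; scalar time
.interp_prepare <- function(field, lon, lat, time_h) {
  nx <- length(field$lon); ny <- length(field$lat); nt <- length(field$time_h)
  fx <- (lon - field$lon[1]) / (field$lon[2] - field$lon[1]) + 1
  fy <- (lat - field$lat[1]) / (field$lat[2] - field$lat[1]) + 1
  # a single-slice field is stationary: no time bound applies
  dt_h <- if (nt > 1) field$time_h[2] - field$time_h[1] else 1
  ft <- if (nt > 1) time_h / dt_h + 1 else 1
  bad <- fx < 1 | fx > nx | fy < 1 | fy > ny |
    (nt > 1 & (ft < 1 - 1e-9 | ft > nt + 1e-9))
  ix <- pmin(pmax(floor(fx), 1), nx - 1)
  iy <- pmin(pmax(floor(fy), 1), ny - 1)
  it <- min(max(floor(ft), 1), max(nt - 1, 1))
  wx <- fx - ix; wy <- fy - iy
  wt <- if (nt > 1) min(max(ft - it, 0), 1) else 0
  # linear indices of the (ix, iy) corner in time slices it and it+1
  base <- ix + (iy - 1) * nx
  list(nx = nx, base0 = base + (it - 1) * nx * ny,
       base1 = base + (min(it + 1, nt) - 1) * nx * ny,
       wx = wx, wy = wy, wt = wt, bad = bad, two_slices = nt > 1)
}

# bilinear in space, linear in time, from precomputed indices
.interp_apply <- function(arr, pr) {
  nx <- pr$nx; wx <- pr$wx; wy <- pr$wy
  bil <- function(b) {
    (1 - wx) * (1 - wy) * arr[b] + wx * (1 - wy) * arr[b + 1] +
      (1 - wx) * wy * arr[b + nx] + wx * wy * arr[b + nx + 1]
  }
  out <- if (pr$two_slices && pr$wt > 0)
    (1 - pr$wt) * bil(pr$base0) + pr$wt * bil(pr$base1)
  else bil(pr$base0)
  out[pr$bad] <- NA_real_
  out
}

#' One fourth-order Runge-Kutta advection step
#'
#' Integrates `dx/dt = u`, `dy/dt = v` over `dt` seconds with the classical
#' RK4 scheme, converting metres to degrees with a local equirectangular
#' scaling (`cos(latitude)`, Earth radius 6371 km) at each stage's latitude.
#' Positions whose stages leave the grid come back as `NA` (exited).
#'
#' @param lon,lat Current positions (degrees, vectorized).
#' @param field A `flow_field`.
#' @param time_h Scalar time (hours since field start) at the step's start.
#' @param dt Step length (seconds).
#' @return 2-column matrix of new `lon`, `lat` (NA rows = exited).
#' @export
rk4_step <- function(lon, lat, field, time_h, dt) {
  stopifnot(dt > 0)
  dt_h <- dt / 3600
  vel_deg <- function(lo, la, th) {
    uv <- interpolate_velocity(field, lo, la, th)
    dlon <- uv["u", ] / (.M_PER_DEG * cos(la * pi / 180))
    dlat <- uv["v", ] / .M_PER_DEG
    rbind(dlon, dlat)  # degrees per second
  }
  k1 <- vel_deg(lon, lat, time_h)
  k2 <- vel_deg(lon + k1[1, ] * dt / 2, lat + k1[2, ] * dt / 2, time_h + dt_h / 2)
  k3 <- vel_deg(lon + k2[1, ] * dt / 2, lat + k2[2, ] * dt / 2, time_h + dt_h / 2)
  k4 <- vel_deg(lon + k3[1, ] * dt, lat + k3[2, ] * dt, time_h + dt_h)
  new_lon <- lon + dt / 6 * (k1[1, ] + 2 * k2[1, ] + 2 * k3[1, ] + k4[1, ])
  new_lat <- lat + dt / 6 * (k1[2, ] + 2 * k2[2, ] + 2 * k3[2, ] + k4[2, ])
  cbind(lon = new_lon, lat = new_lat)
}

#' One random-walk diffusion step
#'
#' Independent Gaussian displacement on each horizontal axis with standard
#' deviation `sqrt(2 K dt)` metres, converted to degrees at each particle's
#' latitude. The 2-D mean squared displacement grows as `4 K t`.
#'
#' @param lon,lat Positions (degrees, vectorized).
#' @param K Horizontal diffusivity (m^2/s), >= 0.
#' @param dt Step length (seconds).
#' @return 2-column matrix of displaced `lon`, `lat`.
#' @export
diffusion_step <- function(lon, lat, K, dt) {
  stopifnot(K >= 0)
  if (K == 0) return(cbind(lon = lon, lat = lat))
  n <- length(lon)
  sd_m <- sqrt(2 * K * dt)
  dx <- stats::rnorm(n, 0, sd_m)
  dy <- stats::rnorm(n, 0, sd_m)
  cbind(lon = lon + dx / (.M_PER_DEG * cos(lat * pi / 180)),
        lat = lat + dy / .M_PER_DEG)
}

#' Per-step survival probability under first-order decay
#'
#' `exp(-k dt)`: the Bernoulli survival probability per step that is
#' consistent with continuous first-order decay at rate `k` (survival
#' composes exactly across steps).
#'
#' @param k Decay rate (per hour), >= 0.
#' @param dt Step length (hours), > 0.
#' @return Survival probability in (0, 1].
#' @export
survival_probability <- function(k, dt) {
  stopifnot(all(k >= 0), dt > 0)
  exp(-k * dt)
}

#' Assign biphasic decay groups
#'
#' Exact-count split: `round(fraction_fast * N)` particles get the fast rate,
#' the remainder the slow rate, with randomized membership. Each particle
#' keeps its group for the whole simulation.
#'
#' @param n Number of particles.
#' @param fractions Length-2 group fractions summing to 1 (fast, slow).
#' @param rates Length-2 decay rates (per hour).
#' @return Numeric vector of per-particle decay rates (length `n`).
#' @export
assign_biphasic_groups <- function(n, fractions = c(0.7, 0.3),
                                   rates = c(0.50, 0.013)) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_fast <- round(fractions[1] * n)
  grp <- rep(rates[2], n)
  grp[sample.int(n, n_fast)] <- rates[1]
  grp
}

#' Apply one decay step to a set of particles
#'
#' Draws per-particle Bernoulli survival for one time step according to the
#' scenario: `no_decay` keeps everything; `exponential` uses the
#' temperature-dependent rate; `biphasic` uses each particle's assigned group
#' rate; `delayed` draws nothing during the growth phase (first
#' `division_duration_h` hours) and behaves like `exponential` afterwards.
#' Dead particles stay dead.
#'
#' @param alive Logical vector of current alive states.
#' @param scenario A [decay_scenario()].
#' @param temperature Per-particle water temperature (degrees C; scalar or
#'   vector).
#' @param dt_h Step length in hours.
#' @param hours_since_release Elapsed time since release (hours) at the end
#'   of this step.
#' @param group_rates Per-particle rates from [assign_biphasic_groups()]
#'   (required for `biphasic`).
#' @return Updated logical alive vector.
#' @export
apply_decay_step <- function(alive, scenario, temperature, dt_h,
                             hours_since_release = Inf, group_rates = NULL) {
  stopifnot(inherits(scenario, "decay_scenario"))
  if (scenario$kind == "no_decay") return(alive)
  if (scenario$kind == "delayed" &&
      hours_since_release <= scenario$division_duration_h + 1e-9)
    return(alive)
  idx <- which(alive)
  if (!length(idx)) return(alive)
  k <- if (scenario$kind == "biphasic") {
    if (is.null(group_rates)) stop("biphasic scenario requires group_rates")
    group_rates[idx]
  } else {
    tk <- temperature_decay_rate(scenario$law, temperature)
    if (length(tk) == 1L) rep(tk, length(idx)) else tk[idx]
  }
  p <- survival_probability(k, dt_h)
  alive[idx] <- stats::runif(length(idx)) < p
  alive
}

#' Apply one hour of delayed-scenario particle division
#'
#' During the growth phase, `round(fraction * N_alive)` alive particles are
#' chosen uniformly without replacement and duplicated at their exact
#' positions (children get fresh ids, `parent_id` set, and the same future
#' dynamics). After `duration_h` hours the call is a no-op. Six hourly
#' divisions at the default 20% multiply the population by
#' `1.2^6 = 2.986`.
#'
#' @param particles List with vectors `lon`, `lat`, `alive`, `id`,
#'   `parent_id`, `group_rates` (the tracker's state).
#' @param hours_since_release Whole hours elapsed since release (>= 1).
#' @param fraction Fraction duplicated per hour (default 0.20).
#' @param duration_h Growth-phase length (hours, default 6).
#' @return Updated particle state list.
#' @export
apply_delayed_division <- function(particles, hours_since_release,
                                   fraction = 0.20, duration_h = 6) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  stopifnot(hours_since_release >= 1)
  if (hours_since_release > duration_h) return(particles)
  idx <- which(particles$alive)
  n_new <- round(fraction * length(idx))
  if (n_new == 0) return(particles)
  chosen <- idx[sample.int(length(idx), n_new)]
  next_id <- max(particles$id) + seq_len(n_new)
  particles$lon <- c(particles$lon, particles$lon[chosen])
  particles$lat <- c(particles$lat, particles$lat[chosen])
  particles$alive <- c(particles$alive, rep(TRUE, n_new))
  particles$parent_id <- c(particles$parent_id, particles$id[chosen])
  particles$id <- c(particles$id, next_id)
  particles$group_rates <- c(particles$group_rates, particles$group_rates[chosen])
  particles$birth_hour <- c(particles$birth_hour,
                            rep(hours_since_release, n_new))
  particles
}

#' Run one release event
#'
#' Releases `n_particles` at the event's location and tracks them for the
#' configured horizon: per 3-minute step, RK4 advection then random-walk
#' diffusion then a decay draw (rate scaled to the step length); particle
#' division (delayed scenario) on whole-hour boundaries; positions and alive
#' flags recorded hourly. Particles leaving the grid are marked dead and
#' never resurrect. The event's RNG stream is derived from
#' `(cfg$seed, event_id)`, so events are individually reproducible.
#'
#' @param event One row of a [build_release_schedule()] data frame (or a list
#'   with the same fields).
#' @param field A `flow_field` covering the event's release point and time
#'   span.
#' @param cfg A [simulation_config()].
#' @param scenario A [decay_scenario()]; default built from
#'   `event$scenario`.
#' @return Trajectory data frame with columns `event_id`, `scenario`,
#'   `particle_id`, `parent_id`, `decay_group`, `hour`, `lon`, `lat`,
#'   `alive`.
#' @export
run_event <- function(event, field, cfg, scenario = NULL) {
  stopifnot(inherits(field, "flow_field"), inherits(cfg, "simulation_config"))
  if (is.null(scenario)) scenario <- decay_scenario(event$scenario)
  release_time <- as.POSIXct(event$release_time, tz = "UTC")
  t0_h <- as.numeric(difftime(release_time, field$time[1], units = "hours"))
  horizon <- cfg$tracking_horizon_h
  if (t0_h < -1e-9 ||
      t0_h + horizon > field$time_h[length(field$time_h)] + 1e-9)
    stop("flow field does not cover the event's tracking window")
  if (event$release_lon < min(field$lon) || event$release_lon > max(field$lon) ||
      event$release_lat < min(field$lat) || event$release_lat > max(field$lat))
    stop("release point outside the flow-field grid")

  set.seed((cfg$seed %% 1000003L) * 2011L + as.integer(event$event_id))
  n0 <- cfg$n_particles
  st <- list(lon = rep(event$release_lon, n0),
             lat = rep(event$release_lat, n0),
             alive = rep(TRUE, n0),
             id = seq_len(n0),
             parent_id = rep(NA_integer_, n0),
             group_rates = if (scenario$kind == "biphasic")
               assign_biphasic_groups(n0, scenario$biphasic_fractions,
                                      scenario$biphasic_rates)
             else rep(NA_real_, n0),
             birth_hour = rep(0, n0))

  dt_s <- cfg$timestep
  dt_h <- dt_s / 3600
  n_sub <- round(cfg$record_cadence_h * 3600 / dt_s)
  n_hours <- round(horizon / cfg$record_cadence_h)

  rec <- vector("list", n_hours + 1L)
  snap <- function(hour, st) {
    data.frame(event_id = event$event_id, scenario = scenario$kind,
               particle_id = st$id, parent_id = st$parent_id,
               decay_group = st$group_rates, hour = hour,
               lon = st$lon, lat = st$lat, alive = st$alive,
               stringsAsFactors = FALSE)
  }
  rec[[1]] <- snap(0, st)

  for (h in seq_len(n_hours)) {
    for (s in seq_len(n_sub)) {
      t_cur <- t0_h + (h - 1) * cfg$record_cadence_h + (s - 1) * dt_h
      elapsed_end <- (h - 1) * cfg$record_cadence_h + s * dt_h
      idx <- which(st$alive)
      if (length(idx)) {
        np <- rk4_step(st$lon[idx], st$lat[idx], field, t_cur, dt_s)
        exited <- !is.finite(np[, 1]) | !is.finite(np[, 2])
        keep <- idx[!exited]
        st$alive[idx[exited]] <- FALSE
        if (length(keep)) {
          st$lon[keep] <- np[!exited, 1]
          st$lat[keep] <- np[!exited, 2]
          dp <- diffusion_step(st$lon[keep], st$lat[keep], cfg$diffusivity_K, dt_s)
          out <- dp[, 1] < min(field$lon) | dp[, 1] > max(field$lon) |
                 dp[, 2] < min(field$lat) | dp[, 2] > max(field$lat)
          st$lon[keep] <- dp[, 1]
          st$lat[keep] <- dp[, 2]
          st$alive[keep[out]] <- FALSE
        }
      }
      in_growth <- scenario$kind == "delayed" &&
        elapsed_end <= scenario$division_duration_h + 1e-9
      if (scenario$kind %in% c("exponential", "delayed", "biphasic") &&
          !in_growth) {
        tempv <- if (scenario$kind == "biphasic") NA_real_ else {
          tt <- interpolate_temperature(field, st$lon, st$lat,
                                        t0_h + elapsed_end)
          tt[!is.finite(tt)] <- 12
          tt
        }
        st$alive <- apply_decay_step(st$alive, scenario, tempv, dt_h,
                                     hours_since_release = elapsed_end,
                                     group_rates = st$group_rates)
      }
    }
    if (scenario$kind == "delayed" &&
        h * cfg$record_cadence_h <= scenario$division_duration_h)
      st <- apply_delayed_division(st, h * cfg$record_cadence_h,
                                   scenario$division_fraction_per_h,
                                   scenario$division_duration_h)
    rec[[h + 1L]] <- snap(h * cfg$record_cadence_h, st)
  }
  do.call(rbind, rec)
}
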