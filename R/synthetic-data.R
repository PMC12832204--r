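# Synthetic hydrodynamic forcing and tank-experiment style concentration series.

# metres per degree of latitude on a sphere of radius 6371 km
.M_PER_DEG <- 6371000 * pi / 180
.TIDAL_PERIOD_H <- 12.42      # semidiurnal (M2) period
.SPRINGNEAP_PERIOD_H <- 14.77 * 24  # spring-neap cycle, circa 14.8 days

#' Site profile for synthetic tidal forcing
#'
#' Statistical description of the surface currents at a release site: a
#' rotating semidiurnal tidal ellipse (period 12.42 h) whose amplitude is
#' modulated by a spring-neap envelope (period ~14.8 days), on top of a weak
#' residual flow. Speed at the site centre then sweeps
#' `[neap amplitude - residual, spring amplitude + residual]`, which must lie
#' inside the declared `speed_envelope`.
#'
#' @param name Site label, `"dynamic"` or `"quiet"`.
#' @param center_lon,center_lat Release point (degrees).
#' @param tidal_amplitude Spring tidal current amplitude (m/s), >= 0.
#' @param residual_speed Residual (non-tidal) flow speed (m/s), >= 0.
#' @param springneap_modulation Fraction in `[0, 1]`; neap amplitude is
#'   `tidal_amplitude * (1 - springneap_modulation)`.
#' @param temperature_mean Annual-mean surface temperature (degrees C).
#' @param temperature_seasonal_offset Seasonal half-range (degrees C); the
#'   field is `mean + offset * cos(2 pi (month - 9) / 12)`, monthly constant.
#' @param speed_envelope Length-2 declared `[min, max]` speed range (m/s).
#' @return An object of class `site_profile`.
#' @seealso [dynamic_site_profile()], [quiet_site_profile()]
#' @export
site_profile <- function(name, center_lon, center_lat,
                         tidal_amplitude, residual_speed,
                         springneap_modulation,
                         temperature_mean = 14, temperature_seasonal_offset = 4,
                         speed_envelope = c(0, Inf)) {
  stopifnot(tidal_amplitude >= 0, residual_speed >= 0,
            springneap_modulation >= 0, springneap_modulation <= 1,
            length(speed_envelope) == 2L)
  structure(list(name = name, center_lon = center_lon, center_lat = center_lat,
                 tidal_amplitude = tidal_amplitude,
                 residual_speed = residual_speed,
                 springneap_modulation = springneap_modulation,
                 temperature_mean = temperature_mean,
                 temperature_seasonal_offset = temperature_seasonal_offset,
                 speed_envelope = speed_envelope),
            class = "site_profile")
}

#' Preset site profiles
#'
#' `dynamic_site_profile()` emulates a macrotidal site at the tip of Brittany
#' (48.05 N, 5.05 W) with speeds spanning roughly 0.05-2.3 m/s inside a
#' declared 0.01-2.4 m/s envelope; `quiet_site_profile()` emulates a weaker
#' site (47.68 N, 4.51 W) inside a 0.01-0.6 m/s envelope.
#'
#' @return A [site_profile()] object.
#' @export
dynamic_site_profile <- function() {
  site_profile("dynamic", center_lon = -5.05, center_lat = 48.05,
               tidal_amplitude = 2.25, residual_speed = 0.05,
               springneap_modulation = 1 - 0.10 / 2.25,
               speed_envelope = c(0.01, 2.4))
}

#' @rdname dynamic_site_profile
#' @export
quiet_site_profile <- function() {
  site_profile("quiet", center_lon = -4.51, center_lat = 47.68,
               tidal_amplitude = 0.52, residual_speed = 0.04,
               springneap_modulation = 1 - 0.08 / 0.52,
               speed_envelope = c(0.01, 0.6))
}

#' Regular lon/lat grid specification for a flow field
#'
#' @param lon0,lat0 Grid origin (south-west corner, degrees).
#' @param nx,ny Node counts along longitude and latitude (>= 2).
#' @param spacing_m Node spacing in metres (target about 500 m).
#' @param time_start,time_end POSIXct span (inclusive).
#' @param cadence_h Temporal cadence in hours (default 1).
#' @return An object of class `field_grid_spec`.
#' @export
field_grid_spec <- function(lon0, lat0, nx, ny, spacing_m = 500,
                            time_start, time_end, cadence_h = 1) {
  stopifnot(nx >= 2, ny >= 2)
  if (spacing_m <= 0) stop("spacing_m must be positive")
  time_start <- as.POSIXct(time_start, tz = "UTC")
  time_end <- as.POSIXct(time_end, tz = "UTC")
  span_h <- as.numeric(difftime(time_end, time_start, units = "hours"))
  if (span_h <= 0) stop("time_end must be after time_start")
  if (abs(span_h / cadence_h - round(span_h / cadence_h)) > 1e-9)
    stop("cadence_h must divide the time span")
  structure(list(lon0 = lon0, lat0 = lat0, nx = as.integer(nx),
                 ny = as.integer(ny), spacing_m = spacing_m,
                 time_start = time_start, time_end = time_end,
                 cadence_h = cadence_h),
            class = "field_grid_spec")
}

#' Grid centred on a site
#'
#' Convenience constructor: a square grid centred on the profile's release
#' point with the given half-span. The release point sits exactly at the grid
#' centre, where the spatial flow perturbation vanishes by construction, so
#' the site's speed envelope holds exactly at the release point.
#'
#' @param profile A [site_profile()].
#' @param half_span_km Half-width of the grid (km, default 30).
#' @param spacing_m Node spacing (m, default 500).
#' @param time_start,time_end,cadence_h Passed to [field_grid_spec()].
#' @return A `field_grid_spec`.
#' @export
site_grid <- function(profile, half_span_km = 30, spacing_m = 500,
                      time_start, time_end, cadence_h = 1) {
  n_half <- ceiling(half_span_km * 1000 / spacing_m)
  nx <- 2L * n_half + 1L
  dlat <- spacing_m / .M_PER_DEG
  dlon <- spacing_m / (.M_PER_DEG * cos(profile$center_lat * pi / 180))
  field_grid_spec(lon0 = profile$center_lon - n_half * dlon,
                  lat0 = profile$center_lat - n_half * dlat,
                  nx = nx, ny = nx, spacing_m = spacing_m,
                  time_start = time_start, time_end = time_end,
                  cadence_h = cadence_h)
}

# monthly-constant uniform temperature for a profile
.profile_temperature <- function(profile, times) {
  month <- as.integer(format(times, "%m"))
  profile$temperature_mean +
    profile$temperature_seasonal_offset * cos(2 * pi * (month - 9) / 12)
}

#' Generate a gridded hourly flow and temperature field
#'
#' Builds hourly eastward (`u`) and northward (`v`) surface velocity and
#' temperature on a regular lon/lat grid. The velocity is the sum of
#' * a spatially uniform residual flow of speed `residual_speed` in a random
#'   (seeded) direction,
#' * a spatially uniform rotating semidiurnal tidal component (period
#'   12.42 h) whose amplitude follows a spring-neap envelope
#'   (`a(t) = A (1 - m sin^2(pi t / T_sn + phi))`, period ~14.8 d), and
#' * a weak stationary divergence-free spatial perturbation derived from a
#'   sinusoidal streamfunction spanning the grid (correlation length of the
#'   order of the grid extent), which vanishes at the grid centre.
#'
#' Because the rotating tide and the residual are spatially uniform and the
#' perturbation comes from a streamfunction, the analytic divergence of the
#' velocity field is zero. Temperature is spatially uniform and monthly
#' constant. Identical `seed` gives a bit-identical field.
#'
#' @param profile A [site_profile()].
#' @param grid A [field_grid_spec()].
#' @param seed Integer seed (fixes the tidal/residual/spring-neap phases).
#' @param perturbation_speed Peak speed of the spatial perturbation (m/s,
#'   default 0.02).
#' @param require_span_km When set, error if the grid spans less than this
#'   many km in either direction — a guard for production runs, where the
#'   grid must cover the dispersal footprint (the tidal excursion of the
#'   dynamic site alone is ~16 km each way, so ~30 km half-spans are
#'   typical). Unset by default so that reduced test fields can be built.
#' @return An object of class `flow_field`: list with `lon`, `lat`, `time`
#'   (POSIXct), `time_h` (hours since start), arrays `u`, `v`, `temp` of
#'   dimension `(nx, ny, nt)`, and `spacing_m`.
#' @export
generate_flow_field <- function(profile, grid, seed = 1L,
                                perturbation_speed = 0.02,
                                require_span_km = NULL) {
  stopifnot(inherits(profile, "site_profile"), inherits(grid, "field_grid_spec"))
  if (!is.null(require_span_km)) {
    span_km <- (min(grid$nx, grid$ny) - 1L) * grid$spacing_m / 1000
    if (span_km < require_span_km)
      stop("grid span (", round(span_km, 1), " km) is smaller than the ",
           "required dispersal footprint (", require_span_km, " km)")
  }
  set.seed(seed)
  phase_tide <- stats::runif(1, 0, 2 * pi)
  phase_sn <- stats::runif(1, 0, 2 * pi)
  dir_res <- stats::runif(1, 0, 2 * pi)

  nx <- grid$nx; ny <- grid$ny
  dlat <- grid$spacing_m / .M_PER_DEG
  dlon <- grid$spacing_m / (.M_PER_DEG * cos(grid$lat0 * pi / 180))
  lon <- grid$lon0 + (seq_len(nx) - 1L) * dlon
  lat <- grid$lat0 + (seq_len(ny) - 1L) * dlat
  times <- seq(grid$time_start, grid$time_end, by = grid$cadence_h * 3600)
  nt <- length(times)
  time_h <- as.numeric(difftime(times, times[1], units = "hours"))
  # absolute tidal clock so different spans of the same seed agree in phase
  t_abs <- as.numeric(times) / 3600

  A <- profile$tidal_amplitude
  m <- profile$springneap_modulation
  a_t <- A * (1 - m * sin(pi * t_abs / .SPRINGNEAP_PERIOD_H + phase_sn)^2)
  ang <- 2 * pi * t_abs / .TIDAL_PERIOD_H + phase_tide
  u_t <- profile$residual_speed * cos(dir_res) + a_t * cos(ang)
  v_t <- profile$residual_speed * sin(dir_res) + a_t * sin(ang)

  # stationary streamfunction perturbation, zero at the grid centre
  xm <- ((seq_len(nx) - 1L) - (nx - 1L) / 2) * grid$spacing_m
  ym <- ((seq_len(ny) - 1L) - (ny - 1L) / 2) * grid$spacing_m
  Lx <- max((nx - 1L) * grid$spacing_m, grid$spacing_m)
  Ly <- max((ny - 1L) * grid$spacing_m, grid$spacing_m)
  # psi = P sin(2 pi X / Lx) sin(2 pi Y / Ly); u' = -dpsi/dY, v' = dpsi/dX
  P <- perturbation_speed * Ly / (2 * pi)
  up <- -P * (2 * pi / Ly) * outer(sin(2 * pi * xm / Lx), cos(2 * pi * ym / Ly))
  vp <- P * (2 * pi / Lx) * outer(cos(2 * pi * xm / Lx), sin(2 * pi * ym / Ly))
  if (A == 0 && profile$residual_speed == 0) {
    up[] <- 0
    vp[] <- 0
  }

  u <- array(0, dim = c(nx, ny, nt))
  v <- array(0, dim = c(nx, ny, nt))
  for (k in seq_len(nt)) {
    u[, , k] <- u_t[k] + up
    v[, , k] <- v_t[k] + vp
  }
  tempv <- .profile_temperature(profile, times)
  temp <- array(rep(tempv, each = nx * ny), dim = c(nx, ny, nt))

  structure(list(lon = lon, lat = lat, time = times, time_h = time_h,
                 u = u, v = v, temp = temp, spacing_m = grid$spacing_m,
                 site = profile$name),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Gridded flow field (%s): %d x %d nodes, %d hourly steps\n",
              x$site %||% "custom", length(x$lon), length(x$lat), length(x$time)))
  cat(sprintf("  lon [%.3f, %.3f], lat [%.3f, %.3f], spacing %.0f m\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat), x$spacing_m))
  cat(sprintf("  %s to %s\n", format(x$time[1]), format(x$time[length(x$time)])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Speed series at a point of a flow field
#'
#' Hourly speed magnitude at a fixed location, read off the stored slices
#' (used to verify a site's speed envelope).
#'
#' @param field A `flow_field`.
#' @param lon,lat Query point (defaults to the grid centre).
#' @return Numeric vector of speeds (m/s), one per stored time.
#' @export
speed_at_point <- function(field, lon = NULL, lat = NULL) {
  if (is.null(lon)) lon <- field$lon[(length(field$lon) + 1L) %/% 2L]
  if (is.null(lat)) lat <- field$lat[(length(field$lat) + 1L) %/% 2L]
  uv <- vapply(field$time_h, function(th)
    interpolate_velocity(field, lon, lat, th), numeric(2))
  sqrt(uv[1, ]^2 + uv[2, ]^2)
}

#' Write / read a flow field as plain text
#'
#' Long-format CSV with columns `time`, `lat`, `lon`, `u`, `v`, `temp` and a
#' `#`-prefixed header line recording the node spacing in metres. Intended
#' for small fields and interchange; large fields are cheaper to regenerate
#' from their seed.
#'
#' @param field A `flow_field`.
#' @param path File path.
#' @return `write_flow_field` returns `path` invisibly; `read_flow_field`
#'   returns a `flow_field`.
#' @export
write_flow_field <- function(field, path) {
  nx <- length(field$lon); ny <- length(field$lat); nt <- length(field$time)
  df <- data.frame(
    time = rep(format(field$time, "%Y-%m-%dT%H:%M:%SZ"), each = nx * ny),
    lat = rep(rep(field$lat, each = nx), times = nt),
    lon = rep(field$lon, times = ny * nt),
    u = as.vector(field$u), v = as.vector(field$v),
    temp = as.vector(field$temp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flow_field spacing_m=%g site=%s",
                     field$spacing_m, field$site %||% "custom"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  spacing <- as.numeric(sub(".*spacing_m=([0-9.eE+-]+).*", "\\1", hdr))
  site <- sub(".*site=([^ ]+).*", "\\1", hdr)
  df <- utils::read.csv(path, comment.char = "#")
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  times <- as.POSIXct(sort(unique(df$time)), tz = "UTC",
                      format = "%Y-%m-%dT%H:%M:%SZ")
  nx <- length(lon); ny <- length(lat); nt <- length(times)
  ord <- order(match(df$time, format(times, "%Y-%m-%dT%H:%M:%SZ")),
               match(df$lat, lat), match(df$lon, lon))
  df <- df[ord, ]
  shape <- c(nx, ny, nt)
  structure(list(lon = lon, lat = lat, time = times,
                 time_h = as.numeric(difftime(times, times[1], units = "hours")),
                 u = array(df$u, shape), v = array(df$v, shape),
                 temp = array(df$temp, shape), spacing_m = spacing,
                 site = site),
            class = "flow_field")
}

#' Design of a tank decay experiment
#'
#' Describes the sampling layout of a temperature-crossed tank experiment:
#' three temperature treatments, two biological replicates (tanks A and B),
#' eight sampling times over 26 h and three technical (ddPCR) replicates per
#' filter, plus the generative truth used to simulate concentrations.
#'
#' @param temperatures Treatment temperatures (degrees C).
#' @param n_bio_replicates Number of tanks per temperature (default 2).
#' @param n_tech_replicates Technical replicates per sample (default 3).
#' @param sample_times_h Sampling times (hours), strictly increasing from 0.
#' @param replicate_offset Multiplicative factor by which tank A exceeds
#'   tank B in expectation (default 2); applied symmetrically
#'   (`sqrt(offset)` up for A, down for B) so the geometric mean across
#'   tanks follows the truth curve.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.3).
#' @param truth Either a decay-parameter object ([first_order_params()] or
#'   [second_order_params()]) used at every temperature, or a function of
#'   temperature returning one. Default: [delayed_decay_truth()].
#' @return An object of class `decay_series_design`.
#' @export
decay_series_design <- function(temperatures = c(13, 20, 27),
                                n_bio_replicates = 2L,
                                n_tech_replicates = 3L,
                                sample_times_h = c(0, 0.5, 1, 2, 4, 6, 23, 26),
                                replicate_offset = 2,
                                noise_cv = 0.3,
                                truth = delayed_decay_truth()) {
  stopifnot(length(sample_times_h) >= 2, sample_times_h[1] == 0,
            all(diff(sample_times_h) > 0), noise_cv >= 0,
            replicate_offset > 0, n_bio_replicates >= 1, n_tech_replicates >= 1)
  structure(list(temperatures = temperatures,
                 n_bio_replicates = as.integer(n_bio_replicates),
                 n_tech_replicates = as.integer(n_tech_replicates),
                 sample_times_h = sample_times_h,
                 replicate_offset = replicate_offset,
                 noise_cv = noise_cv, truth = truth),
            class = "decay_series_design")
}

#' Default delayed-decay generative truth
#'
#' Two-component truth with a fast negative component (release of initially
#' undetectable intracellular DNA) and a temperature-dependent slow phase:
#' `C(T; t) = (C0 + B) exp(-k(T) t) - B exp(-k1 t)` with `C0 = 100`
#' copies/uL, `B = 250`, `k1 = 1` per hour and `k(T)` from the
#' temperature-decay law. At 13 and 20 degrees C the curve more than doubles
#' over the first hours and is still above `C0` at 6 h before declining; at
#' 27 degrees C the fast slow-phase rate erodes the rise, so the shape is
#' much closer to a single exponential.
#'
#' @param law A [temperature_decay_law()].
#' @param C0 Initial concentration (copies/uL).
#' @param rise_amplitude Magnitude `B` of the negative fast component.
#' @param k1 Fast-component rate (per hour).
#' @return A function of temperature returning a [second_order_params()].
#' @export
delayed_decay_truth <- function(law = temperature_decay_law(), C0 = 100,
                                rise_amplitude = 250, k1 = 1) {
  force(law); force(C0); force(rise_amplitude); force(k1)
  function(temperature) {
    k2 <- temperature_decay_rate(law, temperature)
    second_order_params(C01 = -rise_amplitude, k1 = k1,
                        C02 = C0 + rise_amplitude, k2 = k2)
  }
}

.eval_truth <- function(truth, temperature, t) {
  p <- if (is.function(truth)) truth(temperature) else truth
  if (inherits(p, "first_order_params")) return(eval_first_order(p, t))
  if (inherits(p, "second_order_params")) return(eval_second_order(p, t))
  stop("truth must be first_order_params, second_order_params, or a function returning one")
}

#' Generate a synthetic eDNA concentration series
#'
#' Simulates the tank experiment described by a [decay_series_design()]: one
#' concentration per (temperature, tank, technical replicate, time). The
#' expected trajectory follows the design's truth model; tank A exceeds tank
#' B by `replicate_offset` in expectation; measurement noise is
#' multiplicative lognormal with the stated coefficient of variation
#' (mean-one correction applied). With `noise_cv = 0` and
#' `replicate_offset = 1` the output is an exact evaluation of the truth.
#'
#' @param design A [decay_series_design()].
#' @param seed Integer seed.
#' @return Data frame with columns `temperature_C`, `bio_replicate`,
#'   `tech_replicate`, `time_h`, `concentration_copies_per_uL`.
#' @export
generate_decay_series <- function(design, seed = 1L) {
  stopifnot(inherits(design, "decay_series_design"))
  set.seed(seed)
  tanks <- LETTERS[seq_len(design$n_bio_replicates)]
  # symmetric tank multipliers: ratio of consecutive tanks = replicate_offset
  lo <- log(design$replicate_offset)
  tank_mult <- exp(lo * (rev(seq_along(tanks)) - (length(tanks) + 1) / 2))
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  grid <- expand.grid(temperature_C = design$temperatures,
                      bio_replicate = tanks,
                      tech_replicate = seq_len(design$n_tech_replicates),
                      time_h = design$sample_times_h,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$temperature_C, grid$bio_replicate,
                     grid$time_h, grid$tech_replicate), ]
  rownames(grid) <- NULL
  mu <- numeric(nrow(grid))
  for (T in design$temperatures) {
    idx <- grid$temperature_C == T
    vals <- .eval_truth(design$truth, T, grid$time_h[idx])
    if (any(vals < 0))
      stop("truth model is negative at sample times for temperature ", T)
    mu[idx] <- vals
  }
  mu <- mu * tank_mult[match(grid$bio_replicate, tanks)]
  noise <- if (design$noise_cv > 0)
    exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog)) else 1
  grid$concentration_copies_per_uL <- mu * noise
  grid
}

#' Write / read a decay series CSV
#'
#' @param series Data frame from [generate_decay_series()].
#' @param path File path.
#' @export
write_decay_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_series
#' @export
read_decay_series <- function(path) {
  .validate_series(utils::read.csv(path))
}
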