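# Fixture builders: small analytic flow fields assembled in code.

M_PER_DEG <- 6371000 * pi / 180

# stationary field with prescribed uniform u, v (m/s) and temperature
make_uniform_field <- function(u = 0, v = 0, temp = 12,
                               lon0 = -4.6, lat0 = 47.6,
                               half_span_km = 15, spacing_m = 1000,
                               hours = 25) {
  nh <- ceiling(half_span_km * 1000 / spacing_m)
  n <- 2L * nh + 1L
  dlat <- spacing_m / M_PER_DEG
  dlon <- spacing_m / (M_PER_DEG * cos(lat0 * pi / 180))
  times <- as.POSIXct("2018-01-01", tz = "UTC") + 3600 * (seq_len(hours) - 1)
  structure(list(
    lon = lon0 + (seq_len(n) - 1L - nh) * dlon,
    lat = lat0 + (seq_len(n) - 1L - nh) * dlat,
    time = times,
    time_h = as.numeric(difftime(times, times[1], units = "hours")),
    u = array(u, c(n, n, hours)), v = array(v, c(n, n, hours)),
    temp = array(temp, c(n, n, hours)), spacing_m = spacing_m,
    site = "uniform"), class = "flow_field")
}

# stationary solid-body rotation about (lon0, lat0) with angular rate omega
# (rad/s); single time slice
make_rotation_field <- function(omega, lon0 = 0, lat0 = 45,
                                half_deg = 0.2, n = 41) {
  lons <- seq(lon0 - half_deg, lon0 + half_deg, length.out = n)
  lats <- seq(lat0 - half_deg, lat0 + half_deg, length.out = n)
  xm <- outer((lons - lon0) * M_PER_DEG * cos(lat0 * pi / 180), rep(1, n))
  ym <- outer(rep(1, n), (lats - lat0) * M_PER_DEG)
  structure(list(
    lon = lons, lat = lats,
    time = as.POSIXct("2018-01-01", tz = "UTC"), time_h = 0,
    u = array(-omega * ym, c(n, n, 1)), v = array(omega * xm, c(n, n, 1)),
    temp = array(12, c(n, n, 1)), spacing_m = 1), class = "flow_field")
}

# single release event at the centre of a field
make_event <- function(field, scenario = "no_decay", event_id = 1L,
                       release_time = field$time[1]) {
  ic <- (length(field$lon) + 1L) %/% 2L
  data.frame(event_id = event_id, release_id = event_id, site = "uniform",
             release_lon = field$lon[ic], release_lat = field$lat[ic],
             release_time = release_time, scenario = scenario,
             stringsAsFactors = FALSE)
}

# independent haversine implementation (test oracle, no geosphere)
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  dp <- p2 - p1
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(sqrt(a), 1))
}
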