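# Event-based dispersal metrics: alive counts, centre of mass, mean
# displacement, dispersion, convex-hull area and within-hull density.

#' Great-circle (haversine) distance in kilometres
#'
#' Standard haversine distance on a sphere of radius 6371 km (via
#' [geosphere::distHaversine]).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees (vectorized).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Centre of mass of particle positions
#'
#' The arithmetic mean of longitudes and latitudes, taken separately (a
#' planar mean, not a spherical centroid - adequate for plume footprints of
#' a few tens of km).
#'
#' @param lon,lat Particle positions (degrees).
#' @return Named numeric `c(lon =, lat =)`; `NA`s if no positions.
#' @export
center_of_mass <- function(lon, lat) {
  if (!length(lon)) return(c(lon = NA_real_, lat = NA_real_))
  c(lon = mean(lon), lat = mean(lat))
}

#' Mean displacement of a plume from its release point
#'
#' Haversine distance between the release location and the plume's centre of
#' mass.
#'
#' @param release Named numeric `c(lon, lat)` of the release point.
#' @param com Centre of mass from [center_of_mass()].
#' @return Distance in km (`NA` if the centre of mass is undefined).
#' @export
mean_distance <- function(release, com) {
  if (any(!is.finite(com))) return(NA_real_)
  haversine_km(release[[1]], release[[2]], com[[1]], com[[2]])
}

#' Dispersion of particles about their centre of mass
#'
#' Mean squared haversine distance (km^2) of the particles from the centre
#' of mass: `D = (1/N) sum r_i^2`. Zero iff all particles coincide.
#'
#' @param lon,lat Particle positions (degrees).
#' @param com Optional precomputed centre of mass.
#' @return Dispersion in km^2 (`NA` if no particles).
#' @export
dispersion <- function(lon, lat, com = center_of_mass(lon, lat)) {
  if (!length(lon) || any(!is.finite(com))) return(NA_real_)
  r <- haversine_km(lon, lat, com[[1]], com[[2]])
  mean(r^2)
}

# project to a local tangent plane (km) about a reference point
.project_km <- function(lon, lat, ref_lon, ref_lat) {
  kx <- (pi / 180) * 6371 * cos(ref_lat * pi / 180)
  ky <- (pi / 180) * 6371
  cbind(x = (lon - ref_lon) * kx, y = (lat - ref_lat) * ky)
}

#' Convex-hull area of a particle cloud
#'
#' Positions are projected onto a local tangent plane about their centre of
#' mass (equirectangular, cos-latitude scaled, km units); the hull vertices
#' are found with [grDevices::chull] and the polygon area computed with the
#' shoelace (triangle-fan) formula. Fewer than three non-collinear points
#' give area 0.
#'
#' @param lon,lat Particle positions (degrees).
#' @return Hull area in km^2.
#' @export
convex_hull_area <- function(lon, lat) {
  if (length(lon) < 3) return(0)
  com <- center_of_mass(lon, lat)
  xy <- .project_km(lon, lat, com[[1]], com[[2]])
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3) return(0)
  x <- xy[h, 1]; y <- xy[h, 2]
  j <- c(seq_along(h)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Particle density within the convex hull
#'
#' `n_alive / hull_area`; undefined (`NA`) when the hull area is zero.
#'
#' @param n_alive Number of alive particles.
#' @param hull_area_km2 Convex-hull area (km^2).
#' @return Density in particles per km^2, or `NA`.
#' @export
particle_density <- function(n_alive, hull_area_km2) {
  stopifnot(n_alive >= 0)
  ifelse(hull_area_km2 > 0, n_alive / hull_area_km2, NA_real_)
}

#' Compute the dispersal metrics table
#'
#' One row per (scenario, event, hour) with the six event-based metrics,
#' computed from the alive particles only: alive count, centre of mass, mean
#' displacement from the release point, dispersion about the centre of mass,
#' convex-hull area and within-hull density. Hours with zero alive particles
#' keep their row with `NA` sentinels rather than being dropped. An event
#' whose recorded hours have gaps raises an error.
#'
#' @param trajectories Trajectory data frame from [run_event()] (possibly
#'   several events row-bound together).
#' @param release_points Data frame with columns `event_id`, `release_lon`,
#'   `release_lat` and optionally `site` and `release_id` (e.g. the schedule
#'   from [build_release_schedule()]).
#' @return Data frame with columns `site` and `release_id` (when supplied),
#'   `scenario`, `event_id`, `hour`, `n_alive`, `com_lon`, `com_lat`,
#'   `mean_distance_km`, `dispersion_km2`, `hull_area_km2`,
#'   `density_per_km2`.
#' @export
compute_metrics_table <- function(trajectories, release_points) {
  need <- c("event_id", "scenario", "hour", "lon", "lat", "alive")
  miss <- setdiff(need, names(trajectories))
  if (length(miss)) stop("trajectories missing columns: ",
                         paste(miss, collapse = ", "))
  rp <- release_points
  if (!all(c("event_id", "release_lon", "release_lat") %in% names(rp)))
    stop("release_points needs event_id, release_lon, release_lat")
  keys <- unique(trajectories[, c("scenario", "event_id")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    tr <- trajectories[trajectories$scenario == keys$scenario[i] &
                       trajectories$event_id == keys$event_id[i], ]
    hours <- sort(unique(tr$hour))
    if (!identical(as.numeric(hours),
                   as.numeric(seq(min(hours), max(hours), by = 1))))
      stop("missing hours in event ", keys$event_id[i])
    ri <- match(keys$event_id[i], rp$event_id)
    if (is.na(ri)) stop("no release point for event ", keys$event_id[i])
    release <- c(rp$release_lon[ri], rp$release_lat[ri])
    rows <- lapply(hours, function(h) {
      sl <- tr[tr$hour == h & tr$alive, ]
      n <- nrow(sl)
      com <- center_of_mass(sl$lon, sl$lat)
      hull <- if (n) convex_hull_area(sl$lon, sl$lat) else NA_real_
      data.frame(
        scenario = keys$scenario[i], event_id = keys$event_id[i], hour = h,
        n_alive = n, com_lon = com[["lon"]], com_lat = com[["lat"]],
        mean_distance_km = mean_distance(release, com),
        dispersion_km2 = dispersion(sl$lon, sl$lat, com),
        hull_area_km2 = hull,
        density_per_km2 = if (n) particle_density(n, hull) else NA_real_,
        stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if ("release_id" %in% names(rp))
    res <- cbind(release_id = rp$release_id[match(res$event_id, rp$event_id)],
                 res)
  if ("site" %in% names(rp))
    res <- cbind(site = rp$site[match(res$event_id, rp$event_id)], res)
  rownames(res) <- NULL
  res
}

#' Relative density of a scenario against a reference scenario
#'
#' For each hour, every event's within-hull density under `scenario` is
#' divided by the across-event median density of `reference_scenario` at
#' that hour; the per-hour median and 20%-80% percentile band of those
#' ratios are returned. Hours where the reference median is zero or
#' undefined carry `NA`.
#'
#' @param metrics A metrics table from [compute_metrics_table()] containing
#'   both scenarios over the same release schedule.
#' @param scenario,reference_scenario Scenario labels.
#' @return Data frame with columns `hour`, `median`, `p20`, `p80`, `n_events`.
#' @export
relative_density <- function(metrics, scenario, reference_scenario) {
  a <- metrics[metrics$scenario == scenario, ]
  b <- metrics[metrics$scenario == reference_scenario, ]
  if (!nrow(a) || !nrow(b)) stop("scenario not present in metrics table")
  hours <- sort(unique(a$hour))
  rows <- lapply(hours, function(h) {
    ref <- stats::median(b$density_per_km2[b$hour == h], na.rm = TRUE)
    dens <- a$density_per_km2[a$hour == h]
    if (!is.finite(ref) || ref <= 0) {
      return(data.frame(hour = h, median = NA_real_, p20 = NA_real_,
                        p80 = NA_real_, n_events = sum(is.finite(dens))))
    }
    ratio <- dens / ref
    qs <- stats::quantile(ratio, c(0.2, 0.5, 0.8), na.rm = TRUE, names = FALSE)
    data.frame(hour = h, median = qs[2], p20 = qs[1], p80 = qs[3],
               n_events = sum(is.finite(ratio)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
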