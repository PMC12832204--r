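# End-to-end orchestration: synthetic forcing -> particle tracking ->
# metrics -> variance decomposition, plus the decay-series fitting branch.

#' Pipeline configuration
#'
#' Bundles everything one run needs. The defaults are deliberately small (a
#' few events, modest particle counts) so a full pipeline completes in
#' seconds; scale `months`, `max_events_per_combo` and `sim` up towards the
#' full study design (2-hourly releases over two months, 10,000 particles)
#' as compute allows.
#'
#' @param sites List of [site_profile()] objects.
#' @param scenarios Character vector of scenario kinds.
#' @param months List of `c(year, month)` pairs.
#' @param cadence_h Release cadence (hours).
#' @param max_events_per_combo Cap on release times kept per (site,
#'   scenario); `Inf` keeps the complete schedule. Times are thinned evenly
#'   across the span so tidal phases stay represented.
#' @param sim A [simulation_config()].
#' @param decay_design A [decay_series_design()].
#' @param grouping Standardization grouping (see [standardize_metrics()]).
#' @param seed Master seed; stage and event seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sites = list(quiet_site_profile()),
                            scenarios = c("exponential", "biphasic",
                                          "delayed", "no_decay"),
                            months = list(c(2018, 1)),
                            cadence_h = 2,
                            max_events_per_combo = 6,
                            sim = simulation_config(n_particles = 500L,
                                                    tracking_horizon_h = 24),
                            decay_design = decay_series_design(),
                            grouping = "metric_site",
                            seed = 1L) {
  site_names <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(site_names)) stop("duplicate site names")
  if (anyDuplicated(scenarios)) stop("duplicate scenarios")
  structure(list(sites = sites, scenarios = scenarios, months = months,
                 cadence_h = cadence_h,
                 max_events_per_combo = max_events_per_combo,
                 sim = sim, decay_design = decay_design,
                 grouping = grouping, seed = as.integer(seed)),
            class = "pipeline_config")
}

# thin a vector of indices evenly to at most n
.thin_evenly <- function(idx, n) {
  if (length(idx) <= n) return(idx)
  idx[unique(round(seq(1, length(idx), length.out = n)))]
}

#' Run the full analysis pipeline
#'
#' Executes, per site: synthetic flow-field generation, particle tracking
#' for every (release time, scenario) event, hourly dispersal metrics,
#' standardization, and the variance decomposition; and, independently:
#' synthetic decay-series generation, first- and second-order model fits,
#' and decay-pattern classification. A manifest records seeds and per-stage
#' row counts. Re-running with the same config reproduces all outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-event progress lines.
#' @return List of class `edna_pipeline` with elements `metrics`,
#'   `standardized`, `anova` (per site), `relative_density` (per scenario vs
#'   the exponential reference, per site), `decay_fits`, `classification`,
#'   `schedule` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  horizon <- config$sim$tracking_horizon_h

  schedule <- build_release_schedule(config$months, config$cadence_h,
                                     config$sites, config$scenarios)
  if (is.finite(config$max_events_per_combo)) {
    keep <- unlist(lapply(split(seq_len(nrow(schedule)),
                                list(schedule$site, schedule$scenario)),
                          function(ix) .thin_evenly(ix, config$max_events_per_combo)))
    schedule <- schedule[sort(keep), ]
    schedule$event_id <- seq_len(nrow(schedule))
  }

  metrics_list <- list()
  for (si in seq_along(config$sites)) {
    profile <- config$sites[[si]]
    sched_s <- schedule[schedule$site == profile$name, ]
    if (!nrow(sched_s)) next
    tmin <- min(sched_s$release_time)
    tmax <- max(sched_s$release_time) + horizon * 3600
    grid <- site_grid(profile,
                      half_span_km = if (profile$name == "dynamic") 30 else 15,
                      time_start = tmin, time_end = tmax)
    field <- generate_flow_field(profile, grid,
                                 seed = config$seed + 101L * si)
    for (ei in seq_len(nrow(sched_s))) {
      ev <- sched_s[ei, ]
      traj <- run_event(ev, field, config$sim)
      metrics_list[[length(metrics_list) + 1L]] <-
        compute_metrics_table(traj, sched_s)
      if (!quiet) {
        al <- tapply(traj$alive, traj$hour, sum)
        gv <- function(h) if (as.character(h) %in% names(al))
          al[[as.character(h)]] else NA
        message(sprintf(
          "event %d (%s, %s): alive h0=%s h6=%s h12=%s h%d=%s",
          ev$event_id, ev$site, ev$scenario, gv(0), gv(6), gv(12),
          horizon, gv(horizon)))
      }
    }
  }
  metrics <- do.call(rbind, metrics_list)

  standardized <- list()
  anova_tables <- list()
  reldens <- list()
  for (profile in config$sites) {
    sn <- profile$name
    ms <- metrics[metrics$site == sn, ]
    if (!nrow(ms)) next
    z <- standardize_metrics(ms, grouping = config$grouping)
    standardized[[sn]] <- z
    # hour 0 metrics are degenerate (zero hull, undefined density)
    anova_tables[[sn]] <- decompose_variance(z[z$hour >= 1, ])
    ref <- "exponential"
    if (ref %in% ms$scenario) {
      other <- setdiff(unique(ms$scenario), ref)
      reldens[[sn]] <- lapply(stats::setNames(other, other),
                              function(s) relative_density(ms, s, ref))
    }
  }

  series <- generate_decay_series(config$decay_design,
                                  seed = config$seed + 77L)
  fit1 <- fit_decay_models(series, "first", seed = config$seed)
  fit2 <- fit_decay_models(series, "second", seed = config$seed)
  classification <- classify_decay_pattern(series)

  manifest <- list(
    seed = config$seed,
    n_events = nrow(schedule),
    n_particles_per_event = config$sim$n_particles,
    n_metric_rows = nrow(metrics),
    n_series_rows = nrow(series),
    scenarios = config$scenarios,
    sites = vapply(config$sites, `[[`, character(1), "name"),
    grouping = config$grouping,
    aic = c(first = fit1$AIC, second = fit2$AIC),
    classification = classification,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  structure(list(metrics = metrics, standardized = standardized,
                 anova = anova_tables, relative_density = reldens,
                 decay_fits = list(first = fit1, second = fit2),
                 classification = classification,
                 schedule = schedule, manifest = manifest),
            class = "edna_pipeline")
}

#' @export
print.edna_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("eDNA decay/dispersal pipeline run\n")
  cat(sprintf("  %d events x %d particles -> %d metric rows\n",
              m$n_events, m$n_particles_per_event, m$n_metric_rows))
  cat(sprintf("  decay fit AIC: first %.1f, second %.1f; pattern: %s\n",
              m$aic[["first"]], m$aic[["second"]], m$classification))
  for (sn in names(x$anova)) {
    top <- x$anova[[sn]]
    top <- top[top$term != "Residuals", ]
    top <- top[order(-top$partial_eta2), ][1, ]
    cat(sprintf("  %s site: largest effect %s (partial eta2 = %.2f)\n",
                sn, top$term, top$partial_eta2))
  }
  invisible(x)
}
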