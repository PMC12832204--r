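# Standardization of dispersal metrics and ANOVA-based variance
# decomposition with Type III tests and partial eta-squared effect sizes.

.METRIC_COLS <- c(mean_distance = "mean_distance_km",
                  dispersion = "dispersion_km2",
                  hull_area = "hull_area_km2",
                  density = "density_per_km2")

#' Standardize dispersal metrics to z-scores
#'
#' Reshapes a metrics table to long format (one row per metric value) and
#' centres/scales each value within its standardization group. Two grouping
#' conventions are supported: `"metric_site"` (the default; scenario
#' differences survive standardization and can show up as a scenario main
#' effect) and `"metric_site_scenario"` (scenario means are removed too).
#' Missing metric values (`NA` sentinels) propagate as missing. A constant
#' group standardizes to all zeros and is flagged in the `constant_group`
#' column rather than raising an error.
#'
#' @param metrics Metrics table from [compute_metrics_table()]; needs a
#'   `site` column (use a schedule with sites as `release_points`).
#' @param grouping `"metric_site"` or `"metric_site_scenario"`.
#' @return Long data frame with columns `site`, `scenario`, `metric`,
#'   `event_id`, `release_id`, `hour`, `z_value`, `constant_group`; the
#'   grouping used is recorded in `attr(, "grouping")`.
#' @export
standardize_metrics <- function(metrics,
                                grouping = c("metric_site",
                                             "metric_site_scenario")) {
  grouping <- match.arg(grouping)
  if (!"site" %in% names(metrics)) {
    metrics <- cbind(site = "site", metrics)
  }
  long <- do.call(rbind, lapply(names(.METRIC_COLS), function(mn) {
    data.frame(site = metrics$site, scenario = metrics$scenario,
               metric = mn, event_id = metrics$event_id,
               release_id = if ("release_id" %in% names(metrics))
                 metrics$release_id else metrics$event_id,
               hour = metrics$hour,
               value = metrics[[.METRIC_COLS[[mn]]]],
               stringsAsFactors = FALSE)
  }))
  key <- if (grouping == "metric_site")
    interaction(long$metric, long$site, drop = TRUE)
  else
    interaction(long$metric, long$site, long$scenario, drop = TRUE)
  long$z_value <- NA_real_
  long$constant_group <- FALSE
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- long$value[idx]
    ok <- is.finite(v)
    if (sum(ok) < 2) stop("standardization group '", g,
                          "' has fewer than 2 non-missing values")
    s <- stats::sd(v[ok])
    if (s == 0) {
      long$z_value[idx][ok] <- 0
      long$constant_group[idx] <- TRUE
      warning("constant standardization group '", g, "' set to zeros")
    } else {
      long$z_value[idx][ok] <- (v[ok] - mean(v[ok])) / s
    }
  }
  out <- long[, c("site", "scenario", "metric", "event_id", "release_id",
                  "hour", "z_value", "constant_group")]
  attr(out, "grouping") <- grouping
  out
}

#' Decompose variance of standardized metrics
#'
#' Fits a linear model with fixed effects for decay scenario, dispersal
#' metric and hour since release (as an unordered factor), all two- and
#' three-way interactions, and release event as a fixed blocking term
#' (deterministic stand-in for a random intercept), using sum-to-zero
#' contrasts. Type III sums of squares are obtained via [car::Anova] and the
#' partial eta-squared of each term is `SS_term / (SS_term + SS_residual)`.
#' Factors with a single level are dropped from the formula, so degenerate
#' fixtures collapse to lower-way ANOVAs. Missing `z_value`s are dropped;
#' a factor-level combination with no data raises an error naming the empty
#' cells.
#'
#' @param table Long table from [standardize_metrics()] (one site at a
#'   time).
#' @return Data frame with columns `term`, `sum_sq`, `df`, `F`, `p`,
#'   `partial_eta2`.
#' @export
decompose_variance <- function(table) {
  d <- table[is.finite(table$z_value), , drop = FALSE]
  if (length(unique(d$site)) > 1)
    stop("decompose_variance expects a single site; split the table by site")
  d$scenario <- factor(d$scenario)
  d$metric <- factor(d$metric)
  d$hour <- factor(d$hour)
  # the blocking unit is the shared release occasion, crossed with scenario
  d$event <- factor(if ("release_id" %in% names(d)) d$release_id else d$event_id)
  fixed <- c("scenario", "metric", "hour")
  fixed <- fixed[vapply(fixed, function(f) nlevels(d[[f]]) > 1, logical(1))]
  if (!length(fixed)) stop("no factor with more than one level")
  if (length(fixed) > 1) {
    cells <- table(d[fixed])
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)
      lab <- apply(empty, 1, function(r)
        paste(mapply(function(f, i) paste0(f, "=", dimnames(cells)[[f]][i]),
                     fixed, r), collapse = ", "))
      stop("empty design cells: ", paste(utils::head(lab, 5), collapse = "; "))
    }
  }
  rhs <- paste(fixed, collapse = " * ")
  if (nlevels(d$event) > 1) rhs <- paste(rhs, "+ event")
  fml <- stats::as.formula(paste("z_value ~", rhs))
  contr <- lapply(c(fixed, if (nlevels(d$event) > 1) "event"),
                  function(f) "contr.sum")
  names(contr) <- c(fixed, if (nlevels(d$event) > 1) "event")
  fit <- stats::lm(fml, data = d, contrasts = contr)
  a3 <- car::Anova(fit, type = "III")
  tab <- as.data.frame(a3)
  tab <- tab[!rownames(tab) %in% "(Intercept)", , drop = FALSE]
  ss_res <- tab["Residuals", "Sum Sq"]
  terms <- rownames(tab)
  out <- data.frame(
    term = terms,
    sum_sq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    F = if ("F value" %in% names(tab)) tab[["F value"]] else NA_real_,
    p = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]] else NA_real_,
    stringsAsFactors = FALSE)
  out$partial_eta2 <- ifelse(out$term == "Residuals", NA_real_,
                             out$sum_sq / (out$sum_sq + ss_res))
  rownames(out) <- NULL
  out
}
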