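# Decay functional forms, half-lives, model fitting and pattern classification.

#' First-order exponential decay parameters
#'
#' Container for a single-phase exponential decay model
#' \eqn{C(t) = C_{00} e^{-k t}}, the default assumption of most eDNA decay
#' studies.
#'
#' @param C00 Initial concentration (copies per microlitre), non-negative.
#' @param k Decay rate constant (per hour), non-negative.
#' @return An object of class `first_order_params`.
#' @examples
#' p <- first_order_params(C00 = 100, k = log(2) / 6.4)
#' eval_first_order(p, 6.4)   # half the initial concentration
#' @export
first_order_params <- function(C00, k) {
  stopifnot(is.numeric(C00), length(C00) == 1L, is.numeric(k), length(k) == 1L)
  if (C00 < 0) stop("C00 must be non-negative")
  if (k < 0) stop("k must be non-negative")
  structure(list(C00 = C00, k = k), class = "first_order_params")
}

#' Two-component exponential decay parameters
#'
#' Container for the two-exponential mixture
#' \eqn{C(t) = C_{01} e^{-k_1 t} + C_{02} e^{-k_2 t}}. With both amplitudes
#' positive the curve is biphasic (fast phase then slow phase); with one
#' negative amplitude it rises first and then declines (delayed decay). The
#' initial concentration \eqn{C_{01} + C_{02}} must be non-negative.
#'
#' @param C01,C02 Component amplitudes (copies per microlitre); `C01` may be
#'   negative to encode a delayed rise.
#' @param k1,k2 Component rate constants (per hour), non-negative.
#' @return An object of class `second_order_params`.
#' @examples
#' biphasic <- second_order_params(0.7, 0.5, 0.3, 0.013)
#' delayed  <- second_order_params(-150, 1.0, 250, 0.1)
#' @export
second_order_params <- function(C01, k1, C02, k2) {
  stopifnot(is.numeric(C01), is.numeric(k1), is.numeric(C02), is.numeric(k2))
  if (k1 < 0 || k2 < 0) stop("rate constants must be non-negative")
  if (C01 + C02 < 0) stop("C01 + C02 (initial concentration) must be non-negative")
  structure(list(C01 = C01, k1 = k1, C02 = C02, k2 = k2),
            class = "second_order_params")
}

#' Temperature-dependent decay-rate law
#'
#' Exponential dependence of the first-order decay rate on water temperature,
#' \eqn{k(T) = a e^{bT}}. The default coefficients reproduce the median
#' decay-temperature relationship for teleost fish eDNA used by the decay
#' scenarios: `a = 0.0419` per hour at 0 degrees C and `b = 0.0776` per
#' degree C.
#'
#' @param a Rate at 0 degrees C (per hour), positive.
#' @param b Temperature coefficient (per degree C).
#' @return An object of class `temperature_decay_law`.
#' @export
temperature_decay_law <- function(a = 0.0419, b = 0.0776) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a <= 0) stop("a must be positive")
  structure(list(a = a, b = b), class = "temperature_decay_law")
}

#' Evaluate a first-order decay curve
#'
#' @param p A [first_order_params()] object.
#' @param t Time since shedding (hours), non-negative; vectorized.
#' @return Concentration at `t` (same units as `C00`).
#' @export
eval_first_order <- function(p, t) {
  stopifnot(inherits(p, "first_order_params"))
  if (any(t < 0)) stop("t must be non-negative")
  p$C00 * exp(-p$k * t)
}

#' Evaluate a two-component decay curve
#'
#' Reduces to a single exponential when `k1 == k2` or when one amplitude is
#' zero. Negative values at the requested times are flagged with a warning:
#' they indicate a parameterization that is invalid for concentrations.
#'
#' @param p A [second_order_params()] object.
#' @param t Time since shedding (hours), non-negative; vectorized.
#' @return Concentration at `t`.
#' @export
eval_second_order <- function(p, t) {
  stopifnot(inherits(p, "second_order_params"))
  if (any(t < 0)) stop("t must be non-negative")
  ct <- p$C01 * exp(-p$k1 * t) + p$C02 * exp(-p$k2 * t)
  if (any(ct < 0))
    warning("curve is negative at some requested times; invalid for concentrations")
  ct
}

#' Decay rate at a given water temperature
#'
#' @param law A [temperature_decay_law()] object.
#' @param temperature Water temperature (degrees C), within -2 to 35; vectorized.
#' @return Decay rate (per hour).
#' @examples
#' temperature_decay_rate(temperature_decay_law(), 0)    # the 0-degree rate a
#' temperature_decay_rate(temperature_decay_law(), 12)
#' @export
temperature_decay_rate <- function(law = temperature_decay_law(), temperature) {
  stopifnot(inherits(law, "temperature_decay_law"))
  if (any(temperature < -2 | temperature > 35))
    stop("temperature outside the supported range [-2, 35] degrees C")
  law$a * exp(law$b * temperature)
}

#' Half-life of a decay model or scenario
#'
#' Smallest time at which the expected concentration (or expected alive
#' fraction, for particle scenarios) drops to half its initial value, found
#' by bracket scanning plus bisection to an absolute tolerance of 1e-6 h.
#' Returns `Inf` when the curve never reaches half (e.g. `k = 0` or the
#' no-decay scenario).
#'
#' @param model A [first_order_params()], [second_order_params()] or
#'   [decay_scenario()] object.
#' @param ... Passed to methods; `decay_scenario` accepts `temperature` and
#'   `law` for its temperature-dependent phases.
#' @return Half-life in hours (possibly `Inf`).
#' @export
half_life <- function(model, ...) UseMethod("half_life")

# bracket + bisection on f(t) - C(0)/2; f must start at C(0) and be
# continuous except for jump-free evaluation on [0, t_max]
.half_life_bisect <- function(f, t_max = 1e4, tol = 1e-6) {
  c0 <- f(0)
  if (c0 <= 0) return(Inf)
  target <- c0 / 2
  # geometric scan for a bracket
  lo <- 0
  hi <- 1
  while (f(hi) > target && hi < t_max) {
    lo <- hi
    hi <- hi * 2
  }
  if (f(hi) > target) return(Inf)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @rdname half_life
#' @export
half_life.first_order_params <- function(model, ...) {
  if (model$k == 0 || model$C00 == 0) return(Inf)
  .half_life_bisect(function(t) eval_first_order(model, t))
}

#' @rdname half_life
#' @export
half_life.second_order_params <- function(model, ...) {
  f <- function(t) model$C01 * exp(-model$k1 * t) + model$C02 * exp(-model$k2 * t)
  if (model$k1 == 0 && model$k2 == 0) return(Inf)
  .half_life_bisect(f)
}

#' Fit decay models to a concentration series
#'
#' Fits the first-order or two-component decay model to replicate-level
#' concentration data, with temperature as a grouping for all model
#' parameters (each temperature gets its own parameter set) and a
#' per-(temperature x biological replicate) offset on log-amplitude,
#' constrained to sum to zero within each temperature. Fitting is nonlinear
#' least squares ([minpack.lm::nlsLM]) with a multi-start strategy over
#' log-spaced rate grids; the Akaike Information Criterion is computed from
#' the Gaussian likelihood of the pooled residuals, and R-squared is
#' 1 - SSR/SST on the pooled observations.
#'
#' @param series Data frame with columns `temperature_C`, `bio_replicate`,
#'   `tech_replicate`, `time_h`, `concentration_copies_per_uL` (the layout
#'   produced by [generate_decay_series()]).
#' @param form `"first"` or `"second"`.
#' @param exclude_times Numeric vector of time points (hours) to remove
#'   before fitting (explicit outlier handling; no automatic detection).
#' @param n_starts Minimum number of multi-start initializations per
#'   temperature (default 12).
#' @param seed Integer seed controlling start-point jitter.
#' @return An object of class `decay_fit`: list with `form`, `estimates`
#'   (data frame temperature x parameter), `offsets` (per temperature and
#'   biological replicate log-amplitude offsets), `AIC`, `logLik`, `R2`,
#'   `n_obs`, `n_par`, `excluded_times`, `rss` and a `predict` closure.
#' @export
fit_decay_models <- function(series, form = c("first", "second"),
                             exclude_times = numeric(0), n_starts = 12L,
                             seed = 1L) {
  form <- match.arg(form)
  series <- .validate_series(series)
  if (length(exclude_times)) {
    keep <- !vapply(series$time_h,
                    function(t) any(abs(t - exclude_times) < 1e-8), logical(1))
    series <- series[keep, , drop = FALSE]
  }
  if (any(series$concentration_copies_per_uL < 0))
    stop("concentrations must be non-negative")
  temps <- sort(unique(series$temperature_C))
  for (T in temps) {
    nt <- length(unique(series$time_h[series$temperature_C == T]))
    if (nt < 4) stop("need >= 4 distinct time points per temperature after exclusions")
  }

  fits <- lapply(temps, function(T) {
    d <- series[series$temperature_C == T, , drop = FALSE]
    .fit_one_temperature(d, form, n_starts = n_starts, seed = seed)
  })
  names(fits) <- as.character(temps)

  rss <- sum(vapply(fits, `[[`, numeric(1), "rss"))
  n <- nrow(series)
  n_fixed <- if (form == "first") 2L * length(temps) else 4L * length(temps)
  n_offsets <- sum(vapply(fits, function(f) length(f$offsets) - 1L, integer(1)))
  p <- n_fixed + n_offsets
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  aic <- -2 * loglik + 2 * (p + 1)  # +1 for the residual variance
  y <- series$concentration_copies_per_uL
  r2 <- 1 - rss / sum((y - mean(y))^2)

  estimates <- do.call(rbind, lapply(names(fits), function(Tn) {
    est <- fits[[Tn]]$par
    data.frame(temperature_C = as.numeric(Tn),
               parameter = names(est), estimate = unname(est),
               row.names = NULL)
  }))
  offsets <- do.call(rbind, lapply(names(fits), function(Tn) {
    off <- fits[[Tn]]$offsets
    data.frame(temperature_C = as.numeric(Tn),
               bio_replicate = names(off), log_offset = unname(off),
               row.names = NULL)
  }))

  predict_fun <- function(temperature, t, bio_replicate = NULL) {
    Tn <- as.character(temperature)
    if (!Tn %in% names(fits)) stop("no fit for temperature ", temperature)
    f <- fits[[Tn]]
    u <- if (is.null(bio_replicate)) 0 else f$offsets[[bio_replicate]]
    exp(u) * f$curve(t)
  }

  structure(list(form = form, estimates = estimates, offsets = offsets,
                 AIC = aic, logLik = loglik, R2 = r2, n_obs = n, n_par = p,
                 rss = rss, excluded_times = exclude_times,
                 predict = predict_fun),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay model fit (%s order)\n", x$form))
  cat(sprintf("  n = %d observations, %d parameters\n", x$n_obs, x$n_par))
  cat(sprintf("  AIC = %.2f, R2 = %.3f\n", x$AIC, x$R2))
  if (length(x$excluded_times))
    cat("  excluded time points:", paste(x$excluded_times, collapse = ", "), "h\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

.validate_series <- function(series) {
  need <- c("temperature_C", "bio_replicate", "tech_replicate", "time_h",
            "concentration_copies_per_uL")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("series is missing columns: ", paste(miss, collapse = ", "))
  series <- series[stats::complete.cases(series[, need]), , drop = FALSE]
  series
}

# Fit one temperature's data with tank log-amplitude offsets (sum-to-zero).
# The offsets are profiled out: for a fixed curve the least-squares
# multiplier of each tank has a closed form, so the fit alternates between
# an nlsLM step on the curve parameters (with offset-corrected responses)
# and the exact offset update. Each block step weakly decreases the RSS.
.fit_one_temperature <- function(d, form, n_starts = 12L, seed = 1L) {
  t <- d$time_h
  y <- d$concentration_copies_per_uL
  tanks <- sort(unique(as.character(d$bio_replicate)))
  m <- length(tanks)
  tank_idx <- match(as.character(d$bio_replicate), tanks)

  gm <- tapply(y, t, mean)
  tt <- as.numeric(names(gm))
  c0_guess <- max(gm[which.min(tt)], 1e-8)
  # crude rate from log-linear decline over the later half
  late <- tt >= stats::median(tt)
  k_guess <- if (sum(late) >= 2 && all(gm[late] > 0)) {
    sl <- -stats::coef(stats::lm(log(gm[late]) ~ tt[late]))[2]
    max(min(sl, 5), 1e-3)
  } else 0.1

  # exact per-tank multiplicative offsets for a fixed curve, normalized so
  # the offsets sum to zero in log space (the geometric-mean shift is
  # absorbed into the curve amplitude via `scale`)
  update_offsets <- function(pred_curve) {
    u <- vapply(seq_len(m), function(j) {
      sel <- tank_idx == j
      num <- sum(pred_curve[sel] * y[sel])
      den <- sum(pred_curve[sel]^2)
      if (den <= 0 || num <= 0) 0 else log(num / den)
    }, numeric(1))
    mshift <- mean(u)
    list(u = u - mshift, scale = exp(mshift))
  }

  fit_curve <- function(fml, start, lower) {
    u <- rep(0, m)
    scale_acc <- 1
    best_inner <- NULL
    for (iter in 1:6) {
      yadj <- y / exp(u[tank_idx])
      fit <- try(suppressWarnings(minpack.lm::nlsLM(
        fml, data = list(y = yadj, t = t),
        start = start, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      cf <- as.list(stats::coef(fit))
      curve_pred <- eval(fml[[3]], c(cf, list(t = t)))
      upd <- update_offsets(curve_pred)
      u_new <- upd$u
      # fold the geometric-mean shift into the amplitude parameters
      cf_scaled <- cf
      for (nm in intersect(names(cf), c("A1", "A2"))) cf_scaled[[nm]] <- cf[[nm]] * upd$scale
      if ("lc" %in% names(cf)) cf_scaled[["lc"]] <- cf[["lc"]] + log(upd$scale)
      pred_full <- eval(fml[[3]], c(cf_scaled, list(t = t))) * exp(u_new[tank_idx])
      rssi <- sum((y - pred_full)^2)
      if (!is.null(best_inner) && rssi > best_inner$rss - 1e-12 * (1 + best_inner$rss)) {
        break
      }
      best_inner <- list(rss = rssi, coef = cf_scaled, u = u_new)
      if (max(abs(u_new - u)) < 1e-10) break
      u <- u_new
      start <- cf_scaled
    }
    best_inner
  }

  set.seed(seed)
  best <- NULL
  if (form == "first") {
    fml <- stats::as.formula("y ~ exp(lc) * exp(-k * t)")
    lower <- c(-Inf, 0)
    starts <- lapply(c(0.25, 1, 4), function(f)
      list(lc = log(c0_guess), k = max(k_guess * f, 1e-4)))
    while (length(starts) < n_starts) {
      s <- starts[[1 + (length(starts) %% 3)]]
      s$k <- s$k * exp(stats::rnorm(1, 0, 0.7))
      s$lc <- s$lc + stats::rnorm(1, 0, 0.3)
      starts <- c(starts, list(s))
    }
    for (s in starts) {
      r <- fit_curve(fml, s, lower)
      if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
    }
    if (is.null(best)) stop("decay fit did not converge for any start (first order)")
    cf <- best$coef
    par <- c(C00 = exp(cf[["lc"]]), k = cf[["k"]])
    offs <- stats::setNames(best$u, tanks)
    curve <- function(tt) par[["C00"]] * exp(-par[["k"]] * tt)
    return(list(par = par, offsets = offs, rss = best$rss, curve = curve))
  }

  # second order: amplitudes free in sign, rates bounded below by zero
  fml <- stats::as.formula("y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t)")
  lower <- c(-Inf, -Inf, 0, 0)
  starts <- list()
  for (k1s in c(0.1, 0.3, 0.8, 2)) for (k2s in c(0.01, 0.05, 0.15)) {
    # amplitudes by linear least squares at the candidate rates
    X <- cbind(exp(-k1s * t), exp(-k2s * t))
    ab <- try(stats::lm.fit(X, y)$coefficients, silent = TRUE)
    if (inherits(ab, "try-error") || any(!is.finite(ab)))
      ab <- c(c0_guess / 2, c0_guess / 2)
    starts <- c(starts, list(list(A1 = ab[[1]], A2 = ab[[2]], k1 = k1s, k2 = k2s)))
  }
  # delayed-shape starts: negative fast amplitude
  for (k1s in c(0.5, 1)) {
    starts <- c(starts, list(list(A1 = -c0_guess, A2 = 2 * c0_guess,
                                  k1 = k1s, k2 = max(k_guess, 0.02))))
  }
  for (s in starts) {
    r <- fit_curve(fml, s, lower)
    if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
  }
  if (is.null(best)) stop("decay fit did not converge for any start (second order)")
  cf <- best$coef
  # order components so k1 >= k2 (fast phase first)
  A1 <- cf[["A1"]]; A2 <- cf[["A2"]]; k1 <- cf[["k1"]]; k2 <- cf[["k2"]]
  if (k1 < k2) { tmp <- A1; A1 <- A2; A2 <- tmp; tmp <- k1; k1 <- k2; k2 <- tmp }
  par <- c(C01 = A1, k1 = k1, C02 = A2, k2 = k2)
  offs <- stats::setNames(best$u, tanks)
  curve <- function(tt) par[["C01"]] * exp(-par[["k1"]] * tt) +
    par[["C02"]] * exp(-par[["k2"]] * tt)
  list(par = par, offsets = offs, rss = best$rss, curve = curve)
}

#' Classify the decay pattern of a concentration series
#'
#' Rule-based classification into `"delayed"`, `"biphasic"` or
#' `"exponential"`:
#' * **delayed** if the group-mean concentration inside the early window
#'   rises above `(1 + rise_threshold)` times the mean at `t = 0`;
#' * otherwise **biphasic** if a two-component fit with both amplitudes
#'   positive (each at least 1% of the initial concentration) has
#'   `k1 / k2 >= rate_ratio_threshold` and beats the first-order fit by AIC;
#' * otherwise **exponential**.
#'
#' A series with fewer than two distinct sampling times inside the early
#' window is `"unclassifiable"` (early-phase sampling is required to see
#' non-exponential behaviour at all).
#'
#' @param series A concentration series data frame (one experimental
#'   condition; if several temperatures are present the group means pool them).
#' @param early_window_h Width of the early window (hours, default 6).
#' @param rise_threshold Fractional rise over `C(0)` that signals delayed
#'   decay (default 0.25).
#' @param rate_ratio_threshold Minimum fast/slow rate ratio for the biphasic
#'   call (default 5).
#' @return One of `"delayed"`, `"biphasic"`, `"exponential"`,
#'   `"unclassifiable"`.
#' @export
classify_decay_pattern <- function(series, early_window_h = 6,
                                   rise_threshold = 0.25,
                                   rate_ratio_threshold = 5) {
  series <- .validate_series(series)
  tms <- sort(unique(series$time_h))
  early <- tms[tms <= early_window_h]
  if (length(early) < 2) return("unclassifiable")
  gm <- tapply(series$concentration_copies_per_uL, series$time_h, mean)
  m0 <- gm[[as.character(min(tms))]]
  early_means <- gm[as.character(early[early > min(tms)])]
  if (length(early_means) && m0 > 0 &&
      max(early_means) > (1 + rise_threshold) * m0)
    return("delayed")
  fit1 <- fit_decay_models(series, "first")
  fit2 <- try(fit_decay_models(series, "second"), silent = TRUE)
  if (inherits(fit2, "try-error")) return("exponential")
  # pool the per-temperature second-order estimates; biphasic needs every
  # temperature's fit to satisfy the amplitude and rate-ratio clauses
  est <- fit2$estimates
  ok <- TRUE
  for (T in unique(est$temperature_C)) {
    e <- est[est$temperature_C == T, ]
    a1 <- e$estimate[e$parameter == "C01"]
    a2 <- e$estimate[e$parameter == "C02"]
    k1 <- e$estimate[e$parameter == "k1"]
    k2 <- e$estimate[e$parameter == "k2"]
    c0 <- a1 + a2
    if (!(a1 > 0.01 * c0 && a2 > 0.01 * c0 && k2 > 0 &&
          k1 / k2 >= rate_ratio_threshold)) ok <- FALSE
  }
  if (ok && fit2$AIC < fit1$AIC) "biphasic" else "exponential"
}

#' Summarize a decay-pattern literature screen
#'
#' Given counts of studies categorized by decay pattern among those with
#' early-phase (< 12 h) sampling, report each category's share: the
#' exponential share is taken over all early-sampling studies, while the
#' delayed and biphasic shares are taken over the non-exponential studies
#' that were assigned one of the two alternative patterns.
#'
#' @param n_exponential,n_delayed,n_biphasic Study counts per category.
#' @param n_early Total number of studies with early-phase sampling
#'   (default `n_exponential + n_delayed + n_biphasic` if `NULL`).
#' @return Data frame with columns `category`, `n`, `denominator`, `percent`.
#' @examples
#' summarize_decay_review(13, 13, 8, n_early = 36)
#' @export
summarize_decay_review <- function(n_exponential, n_delayed, n_biphasic,
                                   n_early = NULL) {
  stopifnot(n_exponential >= 0, n_delayed >= 0, n_biphasic >= 0)
  if (is.null(n_early)) n_early <- n_exponential + n_delayed + n_biphasic
  n_alt <- n_delayed + n_biphasic
  data.frame(
    category = c("exponential", "delayed", "biphasic"),
    n = c(n_exponential, n_delayed, n_biphasic),
    denominator = c(n_early, n_alt, n_alt),
    percent = 100 * c(n_exponential / n_early,
                      if (n_alt > 0) n_delayed / n_alt else NA_real_,
                      if (n_alt > 0) n_biphasic / n_alt else NA_real_)
  )
}
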