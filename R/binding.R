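## Hill-model fitting of droplet-count titrations and one-site
## dissociation-constant fitting of binding isotherms, with bootstrap
## uncertainties.

#' Hill-model parameters
#'
#' Parameters of the sigmoidal count-vs-concentration model
#' `nc(c) = nc_min + (nc_max - nc_min) / (1 + (kd / c)^n)`.
#'
#' @param nc_min,nc_max Baseline and saturating counts
#'   (`nc_max >= nc_min >= 0`).
#' @param kd_uM Concentration of half-maximal effect (uM, > 0).
#' @param n_hill Hill (cooperativity) coefficient (> 0).
#' @return A `hill_params` list.
#' @export
hill_params <- function(nc_min = 0, nc_max = 40, kd_uM = 420, n_hill = 4) {
  stopifnot(nc_min >= 0, nc_max >= nc_min, kd_uM > 0, n_hill > 0)
  structure(list(nc_min = nc_min, nc_max = nc_max, kd_uM = kd_uM,
                 n_hill = n_hill), class = "hill_params")
}

#' Expected count from the Hill model
#'
#' Evaluates `nc_min + (nc_max - nc_min) / (1 + (kd / c)^n)`. The
#' printed form is singular at `c = 0`; the value there is defined by
#' continuity as `nc_min`. At `c = kd` the value is the midpoint
#' `(nc_min + nc_max) / 2` for any Hill coefficient, and the model is
#' monotone non-decreasing in `c`.
#'
#' @param conc_uM Concentrations (uM, >= 0); vectorized.
#' @param params A [hill_params()] object.
#' @return Expected counts, same length as `conc_uM`.
#' @export
hill_model <- function(conc_uM, params) {
  stopifnot(inherits(params, "hill_params"), all(conc_uM >= 0))
  out <- rep(params$nc_min, length(conc_uM))
  pos <- conc_uM > 0
  out[pos] <- params$nc_min + (params$nc_max - params$nc_min) /
    (1 + (params$kd_uM / conc_uM[pos])^params$n_hill)
  out
}

mean_counts <- function(series) {
  agg <- stats::aggregate(count ~ conc_uM, data = series, FUN = mean)
  agg[order(agg$conc_uM), ]
}

#' Fit the Hill model to per-field droplet counts
#'
#' Nonlinear least squares on the individual per-field counts (not
#' per-concentration means), all fields weighted equally by default.
#' `nc_min` can be fixed (e.g. at 0 when no droplets form below the
#' transition). The Hill coefficient is constrained to (0.3, 12]; a fit
#' pinned at that boundary triggers a warning. Initial values: `nc_min`
#' and `nc_max` from the extreme per-concentration means, `kd` from the
#' concentration whose mean count is closest to the midpoint, `n = 2`.
#'
#' @param series A `titration_series` data frame (`conc_uM`, `field_id`,
#'   `count`) as from [sim_titration()] or read from CSV.
#' @param fix_nc_min Optional fixed value for `nc_min` (commonly 0).
#' @param weights `"equal"` or `"poisson"` (weights `1 / max(mean, 1)`
#'   per concentration).
#' @return A `hill_fit`: list with `params` ([hill_params()]), `se`,
#'   `rss`, `n_points`, `extrapolated` (kd outside the tested range),
#'   and the underlying `nls` fit.
#' @export
fit_hill <- function(series, fix_nc_min = NULL,
                     weights = c("equal", "poisson")) {
  weights <- match.arg(weights)
  stopifnot(all(c("conc_uM", "count") %in% names(series)))
  if (length(unique(series$conc_uM)) < 4)
    stop("need at least 4 distinct concentrations")
  if (all(series$count == 0)) stop("no transition observed: all counts zero")
  mc <- mean_counts(series)
  nc_min0 <- min(mc$count); nc_max0 <- max(mc$count)
  mid <- (nc_min0 + nc_max0) / 2
  kd0 <- mc$conc_uM[which.min(abs(mc$count - mid))]
  if (kd0 <= 0) kd0 <- min(mc$conc_uM[mc$conc_uM > 0])
  dat <- series[, c("conc_uM", "count")]
  w <- rep(1, nrow(dat))
  if (weights == "poisson") {
    mu_by_conc <- setNames(pmax(mc$count, 1), mc$conc_uM)
    w <- 1 / mu_by_conc[as.character(dat$conc_uM)]
  }
  hill_fun <- function(conc, nc_min, nc_max, kd, n) {
    out <- rep(nc_min, length(conc))
    pos <- conc > 0
    out[pos] <- nc_min + (nc_max - nc_min) / (1 + (kd / conc[pos])^n)
    out
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  fit <- tryCatch({
    if (is.null(fix_nc_min)) {
      minpack.lm::nlsLM(
        count ~ hill_fun(conc_uM, nc_min, nc_max, kd, n), data = dat,
        start = list(nc_min = nc_min0, nc_max = max(nc_max0, nc_min0 + 1),
                     kd = kd0, n = 2),
        lower = c(0, 0, 1e-6, 0.3), upper = c(Inf, Inf, Inf, 12),
        weights = w, control = ctl)
    } else {
      minpack.lm::nlsLM(
        count ~ hill_fun(conc_uM, fix_nc_min, nc_max, kd, n), data = dat,
        start = list(nc_max = max(nc_max0, fix_nc_min + 1), kd = kd0, n = 2),
        lower = c(0, 1e-6, 0.3), upper = c(Inf, Inf, 12),
        weights = w, control = ctl)
    }
  }, error = function(e)
    stop(sprintf("Hill fit did not converge (start nc_max=%.3g kd=%.3g n=2): %s",
                 nc_max0, kd0, conditionMessage(e))))
  cf <- coef(fit)
  if (is.null(fix_nc_min) && cf[["nc_min"]] < 1e-6) {
    ## the free fit landed on the nc_min = 0 boundary, where the bounded
    ## LM steps can stall; re-optimize the remaining parameters there
    refit <- tryCatch(
      minpack.lm::nlsLM(
        count ~ hill_fun(conc_uM, 0, nc_max, kd, n), data = dat,
        start = list(nc_max = cf[["nc_max"]], kd = cf[["kd"]],
                     n = cf[["n"]]),
        lower = c(0, 1e-6, 0.3), upper = c(Inf, Inf, 12),
        weights = w, control = ctl),
      error = function(e) NULL)
    if (!is.null(refit) &&
        sum(stats::residuals(refit)^2) < sum(stats::residuals(fit)^2)) {
      fit <- refit
      cf <- c(nc_min = 0, coef(fit))
    }
  }
  if (!is.null(fix_nc_min)) cf <- c(nc_min = fix_nc_min, cf)
  if (cf[["n"]] <= 0.3 + 1e-6 || cf[["n"]] >= 12 - 1e-6)
    warning("Hill coefficient pinned at its allowed boundary (0.3, 12]")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(coef(fit))))
  rng <- range(series$conc_uM[series$conc_uM > 0])
  structure(list(
    params = hill_params(nc_min = cf[["nc_min"]], nc_max = cf[["nc_max"]],
                         kd_uM = cf[["kd"]], n_hill = cf[["n"]]),
    se = se, rss = sum(stats::residuals(fit)^2), n_points = nrow(dat),
    extrapolated = cf[["kd"]] < rng[1] || cf[["kd"]] > rng[2],
    fit = fit), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<hill_fit> kd = %.4g uM, n = %.3g, nc_min = %.3g, nc_max = %.3g%s\n",
    p$kd_uM, p$n_hill, p$nc_min, p$nc_max,
    if (x$extrapolated) " [kd extrapolated]" else ""))
  invisible(x)
}

#' Exact one-site bound fraction
#'
#' Fraction of the labeled partner bound at total titrant concentration
#' `titrant_uM`, from the quadratic solution in total concentrations:
#' `f_b = (L + T + Kd - sqrt((L + T + Kd)^2 - 4 L T)) / (2 L)`.
#' It reduces to the hyperbola `T / (T + Kd)` in the limit of vanishing
#' labeled concentration and is always >= that approximation.
#'
#' @param titrant_uM Total titrant concentrations (uM, >= 0).
#' @param labeled_uM Total labeled-partner concentration (uM, > 0).
#' @param kd_uM Dissociation constant (uM, > 0).
#' @return Bound fractions in `[0, 1]`.
#' @export
one_site_bound_fraction <- function(titrant_uM, labeled_uM, kd_uM) {
  stopifnot(all(titrant_uM >= 0), labeled_uM > 0, kd_uM > 0)
  s <- labeled_uM + titrant_uM + kd_uM
  pmin(1, pmax(0, (s - sqrt(s^2 - 4 * labeled_uM * titrant_uM)) /
                 (2 * labeled_uM)))
}

#' Fit a one-site binding isotherm
#'
#' Least squares of `response = free + (bound - free) * f_b` with the
#' exact one-site bound fraction in total concentrations. The fitted
#' `kd` is flagged `extrapolated` when it falls outside the tested
#' titrant range, and `stoichiometric` when the labeled concentration
#' exceeds the fitted `kd` (titration regime; `kd` poorly determined).
#'
#' @param isotherm Data frame with columns `conc_uM` (titrant) and
#'   `response`, e.g. from [sim_isotherm()].
#' @param labeled_conc_uM Labeled-partner concentration (uM).
#' @return A `one_site_fit`: list with `kd_uM`, `response_free`,
#'   `response_bound`, `se`, `rss`, `extrapolated`, `stoichiometric`,
#'   and the underlying `nls` fit.
#' @export
fit_one_site <- function(isotherm, labeled_conc_uM) {
  stopifnot(all(c("conc_uM", "response") %in% names(isotherm)),
            labeled_conc_uM > 0)
  if (length(unique(isotherm$conc_uM)) < 6)
    stop("need at least 6 titrant concentrations")
  dat <- isotherm[, c("conc_uM", "response")]
  r_free0 <- mean(dat$response[dat$conc_uM <= quantile(dat$conc_uM, 0.2)])
  r_bound0 <- mean(dat$response[dat$conc_uM >= quantile(dat$conc_uM, 0.8)])
  pos <- dat$conc_uM[dat$conc_uM > 0]
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  ## multi-start over kd: the response surface flattens in kd for
  ## stoichiometric titrations, where a single start can stall
  kd_starts <- unique(c(exp(mean(log(range(pos)))), median(pos),
                        labeled_conc_uM, labeled_conc_uM / 10,
                        min(pos), min(pos) / 10))
  fit <- NULL; last_err <- NULL
  for (kd0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ rf + (rb - rf) *
          one_site_bound_fraction(conc_uM, labeled_conc_uM, kd),
        data = dat, start = list(rf = r_free0, rb = r_bound0, kd = kd0),
        lower = c(-Inf, -Inf, 1e-9), control = ctl),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(sprintf("one-site fit did not converge (kd starts tried: %s): %s",
                 paste(signif(kd_starts, 3), collapse = ", "), last_err))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  rng <- range(pos)
  structure(list(kd_uM = cf[["kd"]], response_free = cf[["rf"]],
                 response_bound = cf[["rb"]], se = se,
                 rss = sum(stats::residuals(fit)^2),
                 n_points = nrow(dat),
                 extrapolated = cf[["kd"]] < rng[1] || cf[["kd"]] > rng[2],
                 stoichiometric = labeled_conc_uM > cf[["kd"]],
                 fit = fit), class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> kd = %.4g uM%s%s\n", x$kd_uM,
              if (x$extrapolated) " [extrapolated]" else "",
              if (x$stoichiometric) " [stoichiometric regime]" else ""))
  invisible(x)
}

#' Case-resampling bootstrap confidence intervals for a fit
#'
#' Resamples rows of `data` (optionally stratified, e.g. fields within
#' each concentration of a titration), refits with `fit_fun`, and
#' returns percentile confidence intervals per parameter. Errors if more
#' than 20% of resample fits fail.
#'
#' @param data Data frame of observations.
#' @param fit_fun Function `data -> named numeric vector` of parameter
#'   estimates.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer RNG seed.
#' @param strata Optional column name to stratify resampling on.
#' @param level Confidence level.
#' @return A matrix with one row per parameter and columns `lower`,
#'   `upper`, plus attribute `n_failed`.
#' @export
bootstrap_ci <- function(data, fit_fun, n_boot = 1000, seed = 1L,
                         strata = NULL, level = 0.95) {
  stopifnot(n_boot >= 200, is.function(fit_fun))
  resample <- function() {
    if (is.null(strata)) {
      data[sample(nrow(data), replace = TRUE), , drop = FALSE]
    } else {
      parts <- split(seq_len(nrow(data)), data[[strata]])
      idx <- unlist(lapply(parts, function(i)
        sample(i, length(i), replace = TRUE)))
      data[idx, , drop = FALSE]
    }
  }
  with_seed(seed, {
    draws <- vector("list", n_boot)
    n_failed <- 0L
    for (b in seq_len(n_boot)) {
      est <- tryCatch(fit_fun(resample()), error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else draws[[b]] <- est
    }
    if (n_failed > 0.2 * n_boot)
      stop(sprintf("bootstrap unstable: %d of %d resample fits failed",
                   n_failed, n_boot))
    m <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
    alpha <- (1 - level) / 2
    ci <- t(apply(m, 2, quantile, probs = c(alpha, 1 - alpha)))
    colnames(ci) <- c("lower", "upper")
    attr(ci, "n_failed") <- n_failed
    ci
  })
}
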