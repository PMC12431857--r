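## FRAP trace handling: normalization, single/double-exponential
## recovery fits, and conversion of half-times to apparent diffusion
## coefficients.

#' FRAP trace container
#'
#' @param time_s Strictly increasing per-frame acquisition times (s).
#' @param roi ROI mean intensities, one per frame (a.u.).
#' @param background Background intensities, one per frame or a scalar.
#' @param reference Optional reference-region intensities (for double
#'   normalization against acquisition bleaching).
#' @param bleach_frame 1-based index of the first postbleach frame; at
#'   least one prebleach frame must precede it.
#' @return A `frap_trace` data frame with attribute `bleach_frame`.
#' @export
frap_trace <- function(time_s, roi, background = 0, reference = NULL,
                       bleach_frame) {
  n <- length(time_s)
  stopifnot(length(roi) == n, all(diff(time_s) > 0),
            bleach_frame >= 2, bleach_frame <= n)
  background <- rep_len(background, n)
  df <- data.frame(time_s = time_s, roi = roi, background = background)
  if (!is.null(reference)) {
    stopifnot(length(reference) == n)
    df$reference <- reference
  }
  structure(df, class = c("frap_trace", "data.frame"),
            bleach_frame = as.integer(bleach_frame))
}

#' Normalize a FRAP trace
#'
#' The background is subtracted framewise, then:
#' \describe{
#'   \item{`prebleach_relative`}{divide by the mean prebleach intensity,
#'     so the prebleach plateau averages exactly 1;}
#'   \item{`percent_recovery`}{map the first postbleach point to 0 and
#'     the prebleach mean to 100;}
#'   \item{`double`}{additionally divide by the (prebleach-normalized)
#'     reference-region series to correct acquisition bleaching, then
#'     scale as `prebleach_relative`.}
#' }
#'
#' @param trace A [frap_trace()].
#' @param mode One of `"prebleach_relative"`, `"percent_recovery"`,
#'   `"double"`.
#' @return A `frap_trace` with normalized `roi` (background zeroed) and
#'   attribute `normalization`.
#' @export
normalize_frap <- function(trace,
                           mode = c("prebleach_relative",
                                    "percent_recovery", "double")) {
  stopifnot(inherits(trace, "frap_trace"))
  mode <- match.arg(mode)
  bf <- attr(trace, "bleach_frame")
  v <- trace$roi - trace$background
  pre <- seq_len(bf - 1)
  if (mode == "double") {
    if (is.null(trace$reference))
      stop("double normalization requested but no reference series present")
    ref <- trace$reference - trace$background
    if (any(ref <= 0)) stop("reference series must stay positive")
    v <- v / (ref / mean(ref[pre]))
  }
  v <- switch(mode,
    prebleach_relative = ,
    double = v / mean(v[pre]),
    percent_recovery = 100 * (v - v[bf]) / (mean(v[pre]) - v[bf]))
  out <- frap_trace(trace$time_s, v, background = 0,
                    reference = trace$reference, bleach_frame = bf)
  attr(out, "normalization") <- mode
  out
}

#' Fit exchange-limited FRAP recovery
#'
#' Least-squares fit of `I(t) = I0 + A * (1 - exp(-k * t))` (or a
#' two-term sum for `double_exp`) to the postbleach portion of a
#' normalized trace, with `t = 0` at the first postbleach frame. The
#' half-time is `ln(2) / k`, taken on the dominant-amplitude term for
#' the two-phase model, and the mobile fraction is
#' `A_total / (prebleach - I0)`. Rate initialization comes from a
#' log-linear regression of `plateau - I(t)`; the plateau guess is the
#' mean of the last 10% of frames. Traces with no measurable recovery
#' amplitude are flagged `immobile` and reported with `t_half_s = NA`.
#'
#' @param trace A normalized [frap_trace()] (see [normalize_frap()]).
#' @param model `"single_exp"` or `"double_exp"`.
#' @param bleach_radius_um Optional bleach-spot radius; if given, an
#'   apparent diffusion coefficient is attached via
#'   [diffusion_from_halftime()].
#' @param gamma Geometry factor for the diffusion conversion.
#' @return A `frap_fit`: list with `t_half_s`, `rate_k_per_s`,
#'   `mobile_fraction`, `plateau`, `params`, `se`, `rss`, `model`,
#'   `immobile`, and optionally `d_um2_per_s`.
#' @export
fit_recovery <- function(trace, model = c("single_exp", "double_exp"),
                         bleach_radius_um = NULL, gamma = 0.224) {
  stopifnot(inherits(trace, "frap_trace"))
  model <- match.arg(model)
  bf <- attr(trace, "bleach_frame")
  post <- trace[bf:nrow(trace), ]
  if (nrow(post) < 8) stop("need at least 8 postbleach frames")
  t <- post$time_s - post$time_s[1]
  y <- post$roi
  pre_level <- mean(trace$roi[seq_len(bf - 1)])
  n_tail <- max(3L, ceiling(0.1 * length(y)))
  plateau0 <- mean(tail(y, n_tail))
  a0 <- plateau0 - y[1]
  amp_floor <- 0.02 * max(abs(pre_level - y[1]), .Machine$double.eps)
  if (abs(a0) < amp_floor) {
    return(structure(list(t_half_s = NA_real_, rate_k_per_s = NA_real_,
                          mobile_fraction = 0, plateau = plateau0,
                          params = NULL, se = NULL, rss = sum((y - mean(y))^2),
                          model = model, immobile = TRUE),
                     class = "frap_fit"))
  }
  resid0 <- pmax(plateau0 - y, .Machine$double.eps)
  sel <- seq_len(max(5L, floor(0.8 * length(t))))
  k0 <- max(-coef(lm(log(resid0[sel]) ~ t[sel]))[2], 1e-4)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  if (model == "single_exp") {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ I0 + A * (1 - exp(-k * t)),
                        start = list(I0 = y[1], A = a0, k = k0),
                        lower = c(-Inf, 0, 1e-8), control = ctl),
      error = function(e)
        stop(sprintf(
          "recovery fit did not converge (start I0=%.3g A=%.3g k=%.3g): %s",
          y[1], a0, k0, conditionMessage(e))))
    cf <- coef(fit)
    k <- cf[["k"]]; a_tot <- cf[["A"]]; i0 <- cf[["I0"]]
    dominant_k <- k
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ I0 + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)),
        start = list(I0 = y[1], A1 = a0 / 2, k1 = 5 * k0,
                     A2 = a0 / 2, k2 = k0 / 2),
        lower = c(-Inf, 0, 1e-8, 0, 1e-8), control = ctl),
      error = function(e)
        stop(sprintf(
          "recovery fit did not converge (start k1=%.3g k2=%.3g): %s",
          5 * k0, k0 / 2, conditionMessage(e))))
    cf <- coef(fit)
    a_tot <- cf[["A1"]] + cf[["A2"]]
    i0 <- cf[["I0"]]
    dominant_k <- if (cf[["A1"]] >= cf[["A2"]]) cf[["k1"]] else cf[["k2"]]
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  res <- structure(list(
    t_half_s = log(2) / dominant_k,
    rate_k_per_s = dominant_k,
    mobile_fraction = a_tot / (pre_level - i0),
    plateau = i0 + a_tot,
    params = cf, se = se,
    rss = sum(stats::residuals(fit)^2),
    model = model, immobile = FALSE), class = "frap_fit")
  if (!is.null(bleach_radius_um)) {
    res$bleach_radius_um <- bleach_radius_um
    res$d_um2_per_s <- diffusion_from_halftime(res$t_half_s,
                                               bleach_radius_um, gamma)
  }
  res
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$immobile) {
    cat("<frap_fit> no measurable recovery (immobile)\n")
  } else {
    cat(sprintf(
      "<frap_fit> %s: t1/2 = %.3g s, k = %.3g /s, mobile fraction = %.3g\n",
      x$model, x$t_half_s, x$rate_k_per_s, x$mobile_fraction))
    if (!is.null(x$d_um2_per_s))
      cat(sprintf("  D = %.3g um2/s (w = %.3g um)\n", x$d_um2_per_s,
                  x$bleach_radius_um))
  }
  invisible(x)
}

#' Apparent diffusion coefficient from a FRAP half-time
#'
#' Uniform-disk spot-photobleaching approximation
#' `D = gamma * w^2 / t_half` with the standard geometry factor
#' `gamma = 0.224` for a circular bleach spot of radius `w`.
#'
#' @param t_half_s Recovery half-time (s, > 0).
#' @param bleach_radius_um Bleach-spot radius (um, > 0).
#' @param gamma Dimensionless geometry factor.
#' @return Apparent diffusion coefficient in um2/s.
#' @examples
#' diffusion_from_halftime(78, 1.18)  # ~4e-3 um2/s
#' @export
diffusion_from_halftime <- function(t_half_s, bleach_radius_um,
                                    gamma = 0.224) {
  if (any(c(t_half_s, bleach_radius_um, gamma) <= 0))
    stop("all inputs must be positive")
  gamma * bleach_radius_um^2 / t_half_s
}
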