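# Growth kinetics: maximum specific growth rate estimation from OD600 time
# series and the IIE / RSGR solvent-tolerance statistics with replicate
# t-tests.

#' Estimate the maximum specific growth rate from an OD time series
#'
#' After blank subtraction, readings above `min_od` enter the fit. The
#' default (`method = "spline"`) smooths `ln(OD)` with a cross-validated
#' smoothing spline weighted by OD^2 (the inverse variance of `ln(OD)`
#' under additive OD noise) and takes the maximum slope over sliding
#' windows of `window_points` consecutive readings on the smoothed curve.
#' `method = "window"` fits the sliding-window log-linear regressions on
#' the raw readings instead; it is exact on noise-free data but the
#' maximum over many noisy short-window slopes is biased upward on real
#' plate-reader noise, which is why the smoothed variant is the default.
#'
#' @param curve a `growth_curve` data.frame (`time_h`, `od600`), or a
#'   numeric vector of OD values when `times` is supplied.
#' @param times sampling times in hours (when `curve` is a bare vector).
#' @param window_points readings per sliding window (default 5).
#' @param min_od minimum blanked OD entering the fit (default 0.02).
#' @param blank blank OD subtracted from all readings (default 0).
#' @param method `"spline"` (default) or `"window"`.
#' @return object of class `growth_fit`: list with `mu_max` (1/h),
#'   `window` (`t_start`, `t_end` of the winning window), `r_squared` of
#'   the winning log-linear fit on the raw readings, `n_points` used, and
#'   `flat` (TRUE when no window shows positive growth, in which case
#'   `mu_max` is 0).
#' @export
fit_mu_max <- function(curve, times = NULL, window_points = 5,
                       min_od = 0.02, blank = 0,
                       method = c("spline", "window")) {
  method <- match.arg(method)
  if (is.data.frame(curve)) {
    od <- curve$od600; tt <- curve$time_h
  } else {
    od <- as.numeric(curve); tt <- times
  }
  if (is.null(tt) || length(tt) != length(od))
    stop("times must accompany the OD readings")
  od <- od - blank
  keep <- is.finite(od) & od > min_od
  n <- sum(keep)
  if (n < window_points)
    stop("only ", n, " readings above min_od = ", min_od,
         "; need at least window_points = ", window_points)
  t_u <- tt[keep]
  y_raw <- log(od[keep])
  w <- window_points

  y_fit <- y_raw
  if (method == "spline" && length(unique(t_u)) >= 4) {
    sp <- tryCatch(
      stats::smooth.spline(t_u, y_raw, w = od[keep]^2),
      error = function(e) NULL)
    if (!is.null(sp)) y_fit <- stats::predict(sp, t_u)$y
  }

  # vectorized sliding-window slopes on y_fit
  slopes <- .window_slopes(t_u, y_fit, w)
  best <- which.max(slopes)
  mu <- slopes[best]
  # slopes below numerical noise on the smoothed curve count as no growth
  flat <- !is.finite(mu) || mu <= 1e-9
  if (flat) mu <- 0
  idx <- best:(best + w - 1)
  r2 <- if (flat) 0 else {
    r <- suppressWarnings(stats::cor(t_u[idx], y_raw[idx]))
    if (is.na(r)) 0 else max(0, min(1, r^2))
  }
  structure(list(mu_max = mu,
                 window = c(t_start = t_u[idx[1]], t_end = t_u[idx[w]]),
                 r_squared = r2, n_points = n, flat = flat,
                 method = method),
            class = "growth_fit")
}

# slopes of OLS lines over all windows of w consecutive points (rolling sums)
.window_slopes <- function(t, y, w) {
  n <- length(t)
  m <- n - w + 1
  cs_t <- cumsum(c(0, t)); cs_y <- cumsum(c(0, y))
  cs_tt <- cumsum(c(0, t * t)); cs_ty <- cumsum(c(0, t * y))
  i <- seq_len(m)
  St <- cs_t[i + w] - cs_t[i]
  Sy <- cs_y[i + w] - cs_y[i]
  Stt <- cs_tt[i + w] - cs_tt[i]
  Sty <- cs_ty[i + w] - cs_ty[i]
  (w * Sty - St * Sy) / (w * Stt - St * St)
}

#' Tolerance ratio of a strain
#'
#' The ratio of the maximum specific growth rate in the presence of the
#' solvent to the rate in its absence, `T = mu_butanol / mu_0`.
#'
#' @param mu_at_butanol,mu_at_zero growth rates (1/h); `mu_at_zero` must be
#'   positive.
#' @return dimensionless ratio.
#' @export
tolerance_ratio <- function(mu_at_butanol, mu_at_zero) {
  if (any(mu_at_zero <= 0)) stop("mu_at_zero must be positive")
  mu_at_butanol / mu_at_zero
}

#' Improvement in the Inhibitory Effect (IIE)
#'
#' Percent increase of a strain's tolerance ratio over the wild type:
#' `IIE = (T_clone / T_wt - 1) * 100`. Positive values mean the clone
#' tolerates the solvent better than the wild type.
#'
#' @param t_clone,t_wt tolerance ratios; `t_wt` must be positive.
#' @return percent.
#' @export
compute_iie <- function(t_clone, t_wt) {
  if (any(t_wt <= 0)) stop("wild-type tolerance ratio must be positive")
  (t_clone / t_wt - 1) * 100
}

#' Reduction of Specific Growth Rate in the absence of the solvent (RSGR)
#'
#' Percent change of the clone's solvent-free growth rate relative to the
#' wild type: `RSGR = (mu_clone_0 / mu_wt_0 - 1) * 100`. Negative values
#' mean the genetic modification carries a growth penalty at 0% solvent
#' (signed-change convention).
#'
#' @param mu_clone_0,mu_wt_0 solvent-free growth rates (1/h); `mu_wt_0`
#'   must be positive.
#' @return percent.
#' @export
compute_rsgr <- function(mu_clone_0, mu_wt_0) {
  if (any(mu_wt_0 <= 0)) stop("wild-type mu at 0% must be positive")
  (mu_clone_0 / mu_wt_0 - 1) * 100
}

#' Score one candidate gene from replicated growth curves
#'
#' Fits `mu_max` for every replicate of clone and wild type at the solvent
#' and solvent-free conditions, pairs replicate r of the clone with
#' replicate r of the wild type, and reports IIE and RSGR as mean +/- sd of
#' the per-replicate values. The p-value is a two-sample two-sided
#' Student's t-test of the per-replicate tolerance ratios (clone vs wild
#' type). With unequal replicate counts the pairing falls back to
#' comparing every replicate against the other strain's mean (with a
#' warning).
#'
#' @param growth long data.frame `strain_id`, `condition`, `replicate`,
#'   `time_h`, `od600`.
#' @param clone_id,wt_id strain identifiers in `growth`.
#' @param butanol_conc,zero_conc the two conditions (% v/v; defaults 0.5
#'   and 0).
#' @param alpha significance level (default 0.05).
#' @param mode `"overexpression"` or `"deletion"`, carried in the result.
#' @param ... passed to [fit_mu_max()].
#' @return one-row data.frame of class `tolerance_result`: `gene_id`,
#'   `mode`, `iie`, `iie_sd`, `rsgr`, `rsgr_sd`, `p_value`, `significant`,
#'   `n_replicates`.
#' @export
screen_gene <- function(growth, clone_id, wt_id = "WT", butanol_conc = 0.5,
                        zero_conc = 0, alpha = 0.05,
                        mode = c("overexpression", "deletion"), ...) {
  mode <- match.arg(mode)
  fit_set <- function(strain, cond) {
    d <- growth[growth$strain_id == strain & growth$condition == cond, ,
                drop = FALSE]
    if (nrow(d) == 0)
      stop("no growth data for strain '", strain, "' at ", cond, "% v/v")
    reps <- sort(unique(d$replicate))
    vapply(reps, function(r) {
      dd <- d[d$replicate == r, , drop = FALSE]
      fit_mu_max(dd$od600, times = dd$time_h, ...)$mu_max
    }, numeric(1))
  }
  mu_cb <- fit_set(clone_id, butanol_conc)
  mu_c0 <- fit_set(clone_id, zero_conc)
  mu_wb <- fit_set(wt_id, butanol_conc)
  mu_w0 <- fit_set(wt_id, zero_conc)

  paired <- length(mu_cb) == length(mu_c0) &&
    length(mu_wb) == length(mu_w0) && length(mu_cb) == length(mu_wb)
  if (!paired) {
    warning("unequal replicate counts; pairing each replicate against the ",
            "other strain's mean")
    t_clone <- tolerance_ratio(mu_cb, mean(mu_c0))
    t_wt <- tolerance_ratio(mu_wb, mean(mu_w0))
    iie_r <- compute_iie(t_clone, mean(t_wt))
    rsgr_r <- compute_rsgr(mu_c0, mean(mu_w0))
  } else {
    t_clone <- tolerance_ratio(mu_cb, mu_c0)
    t_wt <- tolerance_ratio(mu_wb, mu_w0)
    iie_r <- compute_iie(t_clone, t_wt)
    rsgr_r <- compute_rsgr(mu_c0, mu_w0)
  }
  p <- .safe_t_test(t_clone, t_wt)
  out <- data.frame(gene_id = clone_id, mode = mode,
                    iie = mean(iie_r), iie_sd = stats::sd(iie_r),
                    rsgr = mean(rsgr_r), rsgr_sd = stats::sd(rsgr_r),
                    p_value = p, significant = p < alpha,
                    n_replicates = length(t_clone),
                    stringsAsFactors = FALSE)
  class(out) <- c("tolerance_result", "data.frame")
  out
}

# two-sample two-sided t; degenerate (zero-variance) inputs resolved by
# whether the means differ
.safe_t_test <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) {
    if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  })
}

#' Simulate one tolerance screen with known ground truth
#'
#' Generates 4-replicate lagged-logistic growth curves for a clone and the
#' wild type at 0% and 0.5% (v/v) n-butanol under the stated true growth
#' rates, then scores the clone with [screen_gene()]. The defaults encode
#' the screen's reference conditions: wild-type `mu_max` 0.6 1/h at 0%,
#' tolerance ratio 0.5 at 0.5% butanol, OD noise sd 0.005.
#'
#' @param true_ratio_clone clone's true tolerance ratio.
#' @param true_ratio_wt wild type's true tolerance ratio (default 0.5).
#' @param mu_wt0 wild-type growth rate at 0% butanol (1/h).
#' @param mu_clone0 clone growth rate at 0% butanol (defaults to `mu_wt0`,
#'   i.e. true RSGR 0).
#' @param n_replicates biological replicates (default 4).
#' @param noise_sd additive OD noise sd (default 0.005).
#' @param butanol_conc solvent condition (% v/v, default 0.5).
#' @param alpha significance level for the replicate t-test.
#' @param ... passed to [simulate_growth_set()] / [simulate_growth()].
#' @return a `tolerance_result` (see [screen_gene()]) with attribute
#'   `true_iie`.
#' @export
simulate_tolerance_screen <- function(true_ratio_clone, true_ratio_wt = 0.5,
                                      mu_wt0 = 0.6, mu_clone0 = mu_wt0,
                                      n_replicates = 4, noise_sd = 0.005,
                                      butanol_conc = 0.5, alpha = 0.05, ...) {
  design <- data.frame(
    strain_id = c("clone", "clone", "WT", "WT"),
    condition = c(0, butanol_conc, 0, butanol_conc),
    mu_max = c(mu_clone0, mu_clone0 * true_ratio_clone,
               mu_wt0, mu_wt0 * true_ratio_wt),
    stringsAsFactors = FALSE)
  growth <- simulate_growth_set(design, n_replicates = n_replicates,
                                noise_sd = noise_sd, ...)
  res <- screen_gene(growth, clone_id = "clone", wt_id = "WT",
                     butanol_conc = butanol_conc, alpha = alpha)
  attr(res, "true_iie") <- compute_iie(true_ratio_clone, true_ratio_wt)
  res
}

#' Recover a known IIE over repeated simulated screens
#'
#' Runs [simulate_tolerance_screen()] `n_screens` times with the clone's
#' true tolerance ratio chosen so its true IIE equals `true_iie`, and
#' summarizes the recovered statistic. This is the package's calibration
#' experiment: the mean recovered IIE should sit within a few percentage
#' points of the encoded truth.
#'
#' @param true_iie target IIE in percent.
#' @param n_screens independent 4-replicate screens to average over.
#' @param true_ratio_wt wild-type true tolerance ratio (default 0.5).
#' @param ... passed to [simulate_tolerance_screen()].
#' @return list with `mean_iie`, `sd_iie`, `median_p`,
#'   `significant_fraction`, `true_iie`, `n_screens` and the per-screen
#'   `results` data.frame.
#' @export
recover_iie <- function(true_iie, n_screens = 100, true_ratio_wt = 0.5, ...) {
  ratio_clone <- true_ratio_wt * (1 + true_iie / 100)
  res <- do.call(rbind, lapply(seq_len(n_screens), function(i)
    simulate_tolerance_screen(true_ratio_clone = ratio_clone,
                              true_ratio_wt = true_ratio_wt, ...)))
  list(mean_iie = mean(res$iie), sd_iie = stats::sd(res$iie),
       median_p = stats::median(res$p_value),
       significant_fraction = mean(res$significant),
       true_iie = true_iie, n_screens = n_screens, results = res)
}
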