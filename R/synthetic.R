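#' Generate a synthetic seed lot
#'
#' Draws seed archetypes around the in-paper central values: husk volume
#' fraction 0.10, husk/kernel density ratio 1.5, husk THC 300 mg/kg, kernel
#' THC 2 mg/kg. Spreads are repository conventions (the study reports central
#' values only). All draws are truncated to physically admissible ranges;
#' zero variances reproduce the central values exactly. Output is
#' bit-reproducible for a given seed.
#'
#' @param n number of seeds.
#' @param seed RNG seed.
#' @param f_H_mean,f_H_sd husk volume fraction, truncated to (0.02, 0.75).
#' @param rho_ratio_mean,rho_ratio_sd husk/kernel density ratio, truncated
#'   to be > 1.
#' @param C_H_mean,C_H_sd husk THC (mg/kg), truncated positive.
#' @param C_C_mean,C_C_sd kernel THC (mg/kg), truncated positive and below
#'   the husk value.
#' @return data.frame with columns `f_H`, `rho_ratio`, `C_H`, `C_C` (one row
#'   per seed).
#' @export
gen_seed_lot <- function(n, seed = 1,
                         f_H_mean = 0.10, f_H_sd = 0.01,
                         rho_ratio_mean = 1.5, rho_ratio_sd = 0.05,
                         C_H_mean = 300, C_H_sd = 20,
                         C_C_mean = 2, C_C_sd = 0.2) {
  stopifnot(n >= 0, f_H_sd >= 0, rho_ratio_sd >= 0, C_H_sd >= 0, C_C_sd >= 0,
            f_H_mean > 0.02, f_H_mean < 0.75, rho_ratio_mean > 1,
            C_H_mean > 0, C_C_mean > 0, C_C_mean < C_H_mean)
  if (n == 0L) {
    return(data.frame(f_H = numeric(), rho_ratio = numeric(),
                      C_H = numeric(), C_C = numeric()))
  }
  rtrunc <- function(n, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out <= lo | out >= hi)
    while (length(bad)) {  # rejection sampling keeps the shape inside bounds
      out[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[out[bad] <= lo | out[bad] >= hi]
    }
    out
  }
  with_rng(seed, {
    lot <- data.frame(
      f_H = rtrunc(n, f_H_mean, f_H_sd, 0.02, 0.75),
      rho_ratio = rtrunc(n, rho_ratio_mean, rho_ratio_sd, 1, Inf),
      C_H = rtrunc(n, C_H_mean, C_H_sd, 0, Inf),
      C_C = rtrunc(n, C_C_mean, C_C_sd, 0, Inf)
    )
    lot$C_C <- pmin(lot$C_C, lot$C_H)
    lot
  })
}

#' Generate a noisy peeling series
#'
#' Evaluates the remainder-concentration model on a removal grid and adds
#' Gaussian measurement noise: `C_obs = C_remain(x) + N(0, noise_sd)`.
#'
#' @param seed_model list with `f_H`, `C_H`, `C_C`
#'   (default [hemp_seed_archetype()]).
#' @param x_grid removed fractions, all within `[0, f_H]`.
#' @param noise_sd measurement noise SD (mg/kg); 0 gives the exact curve.
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `C` (observed, mg/kg) and `C_true`.
#' @export
gen_peeling_series <- function(seed_model = hemp_seed_archetype(),
                               x_grid = seq(0, 0.09, length.out = 10),
                               noise_sd = 1, seed = 1) {
  stopifnot(noise_sd >= 0)
  if (any(x_grid < 0) || any(x_grid > seed_model$f_H)) {
    stop("`x_grid` must lie within [0, f_H]", call. = FALSE)
  }
  C_true <- remainder_concentration(seed_model$f_H, seed_model$C_H,
                                    seed_model$C_C, x_grid)
  C_obs <- if (noise_sd == 0) C_true else {
    with_rng(seed, C_true + stats::rnorm(length(x_grid), 0, noise_sd))
  }
  data.frame(x = x_grid, C = C_obs, C_true = C_true)
}

#' Generate a synthetic chromatogram with known ground truth
#'
#' Builds a detector trace from Gaussian peaks centred in each analyte's
#' retention window (SD `peak_sd` minutes), with peak area equal to
#' `response_factor x concentration`, plus an early impurity/solvent front
#' before 2 min, additive Gaussian baseline noise, and a slow sinusoidal
#' drift. The generating truth is attached as attribute `"truth"` so
#' closed-loop accuracy tests are possible.
#'
#' @param truth named numeric vector, analyte -> concentration (mg/L);
#'   analytes must exist in the method's window table. May be empty.
#' @param method `"PK16"` or `"AOA"`.
#' @param noise_sd additive baseline noise SD (signal units, default 0.3).
#' @param drift_amplitude amplitude of the slow baseline drift (default 0.5).
#' @param seed RNG seed.
#' @param span_min trace length, minutes (default 12).
#' @param sampling_rate points per minute (default 100).
#' @param response_factor peak area per mg/L (default 12.5).
#' @param peak_sd chromatographic peak SD, minutes (default 0.08).
#' @param impurity_area area of the impurity front at 1.0 min (default 200;
#'   0 disables it).
#' @return a [chromatogram()] with attribute `"truth"`.
#' @examples
#' chrom <- gen_chromatogram(c(`delta9-THC` = 50), seed = 7)
#' @export
gen_chromatogram <- function(truth = numeric(), method = c("PK16", "AOA"),
                             noise_sd = 0.3, drift_amplitude = 0.5, seed = 1,
                             span_min = 12, sampling_rate = 100,
                             response_factor = 12.5, peak_sd = 0.08,
                             impurity_area = 200) {
  method <- match.arg(method)
  stopifnot(all(truth >= 0), noise_sd >= 0, drift_amplitude >= 0,
            span_min > 0, sampling_rate > 1, response_factor > 0,
            peak_sd > 0, impurity_area >= 0)
  windows <- method_windows(method)
  if (length(truth)) {
    unknown <- setdiff(names(truth), windows$analyte)
    if (length(unknown)) {
      stop("unknown analyte(s) for method ", method, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  t <- seq(0, span_min, by = 1 / sampling_rate)
  gauss <- function(center, area) {
    area / (peak_sd * sqrt(2 * pi)) * exp(-(t - center)^2 / (2 * peak_sd^2))
  }
  y <- numeric(length(t))
  for (a in names(truth)) {
    if (truth[[a]] <= 0) next
    center <- windows$center[windows$analyte == a]
    y <- y + gauss(center, response_factor * truth[[a]])
  }
  if (impurity_area > 0) {
    # broader, asymmetric-ish front well before the 2 min cutoff
    y <- y + impurity_area / (0.15 * sqrt(2 * pi)) *
      exp(-(t - 1.0)^2 / (2 * 0.15^2))
  }
  y <- y + drift_amplitude * sin(2 * pi * t / (2 * span_min))
  if (noise_sd > 0) {
    y <- with_rng(seed, y + stats::rnorm(length(t), 0, noise_sd))
  }
  chrom <- chromatogram(t, y, method = method)
  attr(chrom, "truth") <- truth
  chrom
}

#' Generate a multi-level calibration set
#'
#' Serial dilution from a stock standard mixture: levels `top / d^i`,
#' `i = 0 .. n_levels - 1` (default the 8-level twofold ladder from 50 mg/L),
#' with areas `response_factor x level` perturbed by multiplicative Gaussian
#' noise of coefficient of variation `noise_cv`.
#'
#' @param top_level_mg_L stock concentration (default 50).
#' @param n_levels number of levels, at least 2 (default 8).
#' @param dilution_factor serial dilution factor (default 2).
#' @param noise_cv multiplicative area noise CV (default 0).
#' @param analytes character vector of analyte labels (default
#'   `"delta9-THC"`).
#' @param response_factor area per mg/L (default 12.5).
#' @param seed RNG seed.
#' @return data.frame with columns `analyte`, `level_mg_per_L`, `area` and
#'   `area_true`.
#' @export
gen_calibration_set <- function(top_level_mg_L = 50, n_levels = 8,
                                dilution_factor = 2, noise_cv = 0,
                                analytes = "delta9-THC",
                                response_factor = 12.5, seed = 1) {
  stopifnot(top_level_mg_L > 0, n_levels >= 2, dilution_factor > 1,
            noise_cv >= 0, response_factor > 0)
  levels <- top_level_mg_L / dilution_factor^(seq_len(n_levels) - 1)
  out <- expand.grid(analyte = analytes, level_mg_per_L = levels,
                     stringsAsFactors = FALSE)
  out <- out[order(out$analyte, -out$level_mg_per_L), , drop = FALSE]
  out$area_true <- response_factor * out$level_mg_per_L
  out$area <- if (noise_cv == 0) out$area_true else {
    with_rng(seed,
             out$area_true * (1 + stats::rnorm(nrow(out), 0, noise_cv)))
  }
  rownames(out) <- NULL
  out
}
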