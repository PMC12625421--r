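#' Chromatogram container
#'
#' A detector trace: strictly increasing time (min) and detector response
#' (absorbance units at 220 nm). The isocratic PK16 method is designed so all
#' sixteen analytes elute within 10 min; a PK16 chromatogram must span at
#' least that window.
#'
#' @param time time axis, minutes, strictly increasing.
#' @param signal detector response, same length.
#' @param method `"PK16"` or `"AOA"`.
#' @return object of class `chromatogram`: list with `time`, `signal`,
#'   `sampling_rate` (points/min) and `method`.
#' @export
chromatogram <- function(time, signal, method = c("PK16", "AOA")) {
  method <- match.arg(method)
  stopifnot(is.numeric(time), is.numeric(signal))
  if (length(time) == 0L) stop("empty chromatogram", call. = FALSE)
  if (length(time) != length(signal)) {
    stop("`time` and `signal` must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing",
                                 call. = FALSE)
  span <- time[length(time)] - time[1]
  if (method == "PK16" && span < 10) {
    stop("a PK16 chromatogram must span at least 10 min", call. = FALSE)
  }
  structure(list(time = time, signal = signal,
                 sampling_rate = (length(time) - 1) / span,
                 method = method),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("%s chromatogram: %d points, %.2f-%.2f min, %.0f pts/min\n",
              x$method, length(x$time), x$time[1], x$time[length(x$time)],
              x$sampling_rate))
  invisible(x)
}

#' Read / write a chromatogram CSV
#'
#' The on-disk format is a two-column CSV with header `time_min, signal_au`.
#' The method is carried in a JSON sidecar `<path>.json` when present,
#' otherwise taken from the `method` argument.
#'
#' @param path CSV file path.
#' @param method fallback method if no sidecar exists.
#' @return a [chromatogram()].
#' @export
read_chromatogram_csv <- function(path, method = "PK16") {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "signal_au") %in% names(d))) {
    stop("chromatogram CSV needs columns `time_min` and `signal_au`",
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    method <- jsonlite::read_json(sidecar)$method
  }
  chromatogram(d$time_min, d$signal_au, method = method)
}

#' @rdname read_chromatogram_csv
#' @param chrom a [chromatogram()] to write.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(data.frame(time_min = chrom$time,
                              signal_au = chrom$signal),
                   path, row.names = FALSE)
  jsonlite::write_json(list(method = chrom$method), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

running_mean <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  pad <- (k - 1L) %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[n], pad))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2))[(pad + 1):(pad + n)]
}

trapz_area <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Detect and integrate peaks in a chromatogram
#'
#' Local maxima of a lightly smoothed trace above a height threshold are
#' retained if their topographic prominence exceeds `min_prominence`; maxima
#' closer together than `merge_within` minutes are merged (tallest kept).
#' Each peak is integrated by the trapezoidal rule over a region bounded
#' either at the midpoint to the neighbouring peak or at `region_halfwidth`
#' minutes, after subtracting a linear baseline interpolated between the
#' region endpoints (endpoint levels estimated from the smoothed trace, which
#' also absorbs slow drift).
#'
#' @param chrom a [chromatogram()].
#' @param min_height minimum peak height (signal units).
#' @param min_prominence minimum prominence above the surrounding baseline.
#' @param merge_within resolution window, minutes (default 0.1).
#' @param region_halfwidth maximum integration half-width, minutes
#'   (default 0.45).
#' @return a `peak_table`: data.frame with columns `retention_time`, `height`,
#'   `area`, `t_start`, `t_end` and `assignment` (`NA` until
#'   [assign_peaks()]), ordered by retention time. The chromatogram's method
#'   is kept as attribute `"method"`.
#' @export
detect_peaks <- function(chrom, min_height = 1, min_prominence = 0.5,
                         merge_within = 0.1, region_halfwidth = 0.45) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time
  y <- chrom$signal
  n <- length(y)
  empty <- data.frame(retention_time = numeric(), height = numeric(),
                      area = numeric(), t_start = numeric(),
                      t_end = numeric(), assignment = character())
  k <- max(3L, 2L * floor(chrom$sampling_rate * 0.02) + 1L)
  s <- running_mean(y, k)

  cand <- which(diff(sign(diff(s))) < 0) + 1L
  cand <- cand[s[cand] >= min_height]
  if (!length(cand)) return(structure(empty, method = chrom$method,
                                      class = c("peak_table", "data.frame")))

  prominence <- vapply(cand, function(p) {
    h <- s[p]
    left <- p
    while (left > 1L && s[left] <= h) left <- left - 1L
    lmin <- min(s[left:p])
    right <- p
    while (right < n && s[right] <= h) right <- right + 1L
    rmin <- min(s[p:right])
    h - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prominence >= min_prominence]
  if (!length(cand)) return(structure(empty, method = chrom$method,
                                      class = c("peak_table", "data.frame")))

  # merge peaks closer than the resolution window, tallest first
  keep <- integer()
  for (p in cand[order(s[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(t[p] - t[keep]) >= merge_within)) {
      keep <- c(keep, p)
    }
  }
  keep <- sort(keep)

  lo_all <- vapply(seq_along(keep), function(i) {
    lo <- if (i > 1L) (t[keep[i]] + t[keep[i - 1L]]) / 2 else t[1]
    max(lo, t[keep[i]] - region_halfwidth)
  }, numeric(1))
  hi_all <- vapply(seq_along(keep), function(i) {
    hi <- if (i < length(keep)) (t[keep[i]] + t[keep[i + 1L]]) / 2 else t[n]
    min(hi, t[keep[i]] + region_halfwidth)
  }, numeric(1))

  # baseline level at a region endpoint: average the smoothed trace over a
  # flanking window on the side away from the peak (up to 0.35 min of clean
  # baseline), falling back to a short window at the endpoint itself when a
  # neighbouring peak region leaves no room
  flank_level <- function(at_t, from_t, to_t) {
    span_ok <- to_t - from_t >= 0.05
    if (!span_ok) {
      idx <- which(t >= at_t - 0.02 & t <= at_t + 0.02)
    } else {
      idx <- which(t >= from_t & t <= to_t)
    }
    mean(s[idx])
  }

  rows <- lapply(seq_along(keep), function(i) {
    p <- keep[i]
    lo_t <- lo_all[i]
    hi_t <- hi_all[i]
    i0 <- which.min(abs(t - lo_t))
    i1 <- which.min(abs(t - hi_t))
    if (i1 - i0 < 2L) return(NULL)
    left_limit <- max(t[1], lo_t - 0.35,
                      if (i > 1L) hi_all[i - 1L] else t[1])
    right_limit <- min(t[n], hi_t + 0.35,
                       if (i < length(keep)) lo_all[i + 1L] else t[n])
    bl0 <- flank_level(lo_t, left_limit, lo_t)
    bl1 <- flank_level(hi_t, hi_t, right_limit)
    idx <- i0:i1
    baseline <- bl0 + (bl1 - bl0) * (t[idx] - t[i0]) / (t[i1] - t[i0])
    area <- trapz_area(t[idx], y[idx] - baseline)
    # apex from the raw trace near the smoothed maximum
    w <- max(1L, p - 2L):min(n, p + 2L)
    apex <- w[which.max(y[w])]
    data.frame(retention_time = t[apex], height = y[apex], area = area,
               t_start = t[i0], t_end = t[i1],
               assignment = NA_character_)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  out <- out[out$area > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, method = chrom$method,
            class = c("peak_table", "data.frame"))
}

#' PK16 retention-window table
#'
#' The anchored windows are: solvent/impurity front below 2 min, CBD
#' 2.7-3.3 min, delta8-THC 4.0-5.0 min, delta9-THC 5.0-6.0 min. The remaining
#' thirteen analyte windows are non-overlapping repository conventions placed
#' within the 2-10 min design window (the full instrument table is not
#' public); they are used consistently by the synthetic generator and the
#' assigner.
#'
#' @return data.frame with columns `analyte`, `rt_min`, `rt_max`, `center`.
#' @export
pk16_windows <- function() {
  w <- data.frame(
    analyte = c("CBDVA", "CBDV", "CBD", "CBDA", "CBGA", "CBG",
                "delta8-THC", "delta9-THC", "CBN", "CBNA", "CBL", "CBC",
                "CBCA", "THCV", "THCVA", "THCA-A"),
    rt_min = c(2.0, 2.4, 2.7, 3.3, 3.6, 3.8, 4.0, 5.0, 6.0, 6.5, 7.0, 7.5,
               8.0, 8.5, 9.0, 9.5),
    rt_max = c(2.4, 2.7, 3.3, 3.6, 3.8, 4.0, 5.0, 6.0, 6.5, 7.0, 7.5, 8.0,
               8.5, 9.0, 9.5, 10.0)
  )
  w$center <- (w$rt_min + w$rt_max) / 2
  w
}

#' AOA retention-window table
#'
#' The slower operating condition; only the anchored delta9-THC window
#' (6.5-7.5 min, eluting near 7 min) is defined.
#'
#' @return data.frame as in [pk16_windows()].
#' @export
aoa_windows <- function() {
  data.frame(analyte = "delta9-THC", rt_min = 6.5, rt_max = 7.5, center = 7.0)
}

method_windows <- function(method) {
  switch(method, PK16 = pk16_windows(), AOA = aoa_windows(),
         stop("unknown method: ", method, call. = FALSE))
}

#' Assign detected peaks to analytes by retention window
#'
#' Peaks eluting before 2 min are the PK0-driven impurity/solvent front and
#' are labelled `"impurity_front"` (excluded from potency). Other peaks get
#' the analyte of the window containing their retention time, or
#' `"unassigned"`. Assignment is deterministic and order-independent.
#'
#' @param peaks a `peak_table` from [detect_peaks()].
#' @param method `"PK16"` or `"AOA"`; default from the peak table's attribute.
#' @param windows optional user window table (`analyte`, `rt_min`, `rt_max`);
#'   overlapping windows are a configuration error.
#' @return the peak table with `assignment` filled in.
#' @export
assign_peaks <- function(peaks, method = NULL, windows = NULL) {
  stopifnot(inherits(peaks, "peak_table") || is.data.frame(peaks))
  if (is.null(method)) method <- attr(peaks, "method")
  if (is.null(windows)) windows <- method_windows(method)
  windows <- windows[order(windows$rt_min), , drop = FALSE]
  if (nrow(windows) > 1L &&
      any(windows$rt_min[-1] < windows$rt_max[-nrow(windows)] - 1e-12)) {
    stop("retention windows overlap: configuration error", call. = FALSE)
  }
  assign_one <- function(rt) {
    if (rt < 2) return("impurity_front")
    hit <- which(rt >= windows$rt_min & rt < windows$rt_max)
    if (length(hit)) windows$analyte[hit[1]] else "unassigned"
  }
  peaks$assignment <- vapply(peaks$retention_time, assign_one, character(1))
  peaks
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on concentration, per analyte, not
#' forced through the origin. The standard design is an 8-level twofold
#' serial dilution of a 50 mg/L stock standard mixture.
#'
#' @param levels data.frame with columns `level_mg_per_L` (alias
#'   `concentration`) and `area`; at least two distinct concentrations.
#' @param analyte label carried into quantification (default from a
#'   `analyte` column if present).
#' @return object of class `calibration_curve`: `analyte`, `slope`,
#'   `intercept`, `r_squared`, `top_level`, `levels`.
#' @export
fit_calibration <- function(levels, analyte = NULL) {
  stopifnot(is.data.frame(levels))
  conc_col <- intersect(c("level_mg_per_L", "concentration"), names(levels))
  if (!length(conc_col) || !"area" %in% names(levels)) {
    stop("`levels` needs columns `level_mg_per_L` (or `concentration`) and `area`",
         call. = FALSE)
  }
  conc <- levels[[conc_col[1]]]
  if (is.null(analyte)) {
    analyte <- if ("analyte" %in% names(levels)) levels$analyte[1] else "analyte"
  }
  if (length(unique(conc)) < 2L) {
    stop("singular fit: need at least 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(levels$area ~ conc)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((levels$area - mean(levels$area))^2)
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 top_level = max(conc),
                 levels = data.frame(level_mg_per_L = conc,
                                     area = levels$area)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration [%s]: area = %.4f x conc %+.4f, r^2 = %.6f (%d levels, top %.4g mg/L)\n",
              x$analyte, x$slope, x$intercept, x$r_squared,
              nrow(x$levels), x$top_level))
  invisible(x)
}

#' Read a calibration CSV
#'
#' Columns: `analyte`, `level_mg_per_L`, `area`.
#'
#' @param path CSV file path.
#' @return data.frame (one row per analyte x level).
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("analyte", "level_mg_per_L", "area") %in% names(d))) {
    stop("calibration CSV needs columns `analyte`, `level_mg_per_L`, `area`",
         call. = FALSE)
  }
  d
}

#' Compose a dilution chain into a single factor
#'
#' A dilution "a:b" is read as `a` parts diluent to `b` parts sample, i.e. a
#' factor of `(a + b) / b`; factors of a chain multiply. The standard
#' pretreatment chain `4:1, 1:1, 1:1` composes to a factor of 20.
#'
#' @param chain character vector of `"a:b"` ratios.
#' @return the composed dilution factor.
#' @examples
#' dilution_chain_factor(c("4:1", "1:1", "1:1"))  # 20
#' @export
dilution_chain_factor <- function(chain) {
  f <- vapply(chain, function(s) {
    ab <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(ab) != 2L || any(is.na(ab)) || ab[2] <= 0) {
      stop("malformed dilution ratio: ", s, call. = FALSE)
    }
    (ab[1] + ab[2]) / ab[2]
  }, numeric(1))
  prod(f)
}

#' Quantify a peak against a calibration curve
#'
#' `concentration = (area - intercept) / slope`, clipped at zero. The injected
#' solution value is multiplied by the composed dilution factor; if the
#' extraction volume and sample mass are supplied the result is also
#' back-calculated to a matrix concentration (mg/kg). Quantification refuses
#' to extrapolate beyond 1.5x the top calibration level.
#'
#' @param area peak area (signal x min), or a single `peak_table` row.
#' @param cal a [calibration_curve()].
#' @param dilution_factor composed dilution factor (default 1); see
#'   [dilution_chain_factor()].
#' @param extract_volume_mL,sample_mass_g optional matrix back-calculation:
#'   `mg/kg = mg/L x dilution x volume(L) / mass(kg)`.
#' @return object of class `quant_result`: `analyte`, `concentration`
#'   (mg/L injected), `dilution_factor`, `concentration_in_solution`
#'   (mg/L before dilution), `concentration_in_sample` (mg/kg, NA without
#'   matrix info).
#' @export
quantify <- function(area, cal, dilution_factor = 1,
                     extract_volume_mL = NULL, sample_mass_g = NULL) {
  stopifnot(inherits(cal, "calibration_curve"), dilution_factor >= 1)
  if (is.data.frame(area)) {
    stopifnot(nrow(area) == 1L)
    area <- area$area
  }
  if (cal$slope <= 0) stop("calibration error: non-positive slope",
                           call. = FALSE)
  conc <- max(0, (area - cal$intercept) / cal$slope)
  if (conc > 1.5 * cal$top_level) {
    stop(sprintf("refusing to extrapolate: %.3g mg/L exceeds 1.5x top level (%.3g mg/L)",
                 conc, cal$top_level), call. = FALSE)
  }
  in_solution <- conc * dilution_factor
  in_sample <- if (!is.null(extract_volume_mL) && !is.null(sample_mass_g)) {
    in_solution * (extract_volume_mL / 1000) / (sample_mass_g / 1000)
  } else NA_real_
  structure(list(analyte = cal$analyte, concentration = conc,
                 dilution_factor = dilution_factor,
                 concentration_in_solution = in_solution,
                 concentration_in_sample = in_sample),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("%s: %.4g mg/L injected (x%g dilution -> %.4g mg/L in solution",
              x$analyte, x$concentration, x$dilution_factor,
              x$concentration_in_solution))
  if (!is.na(x$concentration_in_sample)) {
    cat(sprintf("; %.4g mg/kg in sample", x$concentration_in_sample))
  }
  cat(")\n")
  invisible(x)
}

#' Quantify all assigned peaks of a chromatogram
#'
#' Convenience wrapper applying [quantify()] to every assigned analyte peak
#' with a matching calibration curve (front and unassigned peaks skipped).
#'
#' @param peaks an assigned `peak_table`.
#' @param calibrations named list of [calibration_curve()]s, keyed by analyte.
#' @param ... passed to [quantify()].
#' @return data.frame with one row per quantified analyte.
#' @export
quantify_peaks <- function(peaks, calibrations, ...) {
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    a <- peaks$assignment[i]
    if (is.na(a) || !a %in% names(calibrations)) return(NULL)
    q <- quantify(peaks$area[i], calibrations[[a]], ...)
    data.frame(analyte = q$analyte,
               retention_time = peaks$retention_time[i],
               area = peaks$area[i],
               concentration_mg_L = q$concentration,
               concentration_in_solution = q$concentration_in_solution,
               concentration_in_sample = q$concentration_in_sample)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(analyte = character(), retention_time = numeric(),
                      area = numeric(), concentration_mg_L = numeric(),
                      concentration_in_solution = numeric(),
                      concentration_in_sample = numeric())
  }
  out
}

#' Total-THC compliance verdict
#'
#' Total THC is the sum of the neutral delta8-THC and delta9-THC isomers
#' (absent analytes count as zero). Acid forms (THCA-A, THCVA) are reported
#' separately, not totalled, since no decarboxylation weighting is defined.
#' The comparison is inclusive (a total exactly at the ceiling passes).
#'
#' @param results a named numeric vector of matrix concentrations (mg/kg), or
#'   the data.frame from [quantify_peaks()] (uses `concentration_in_sample`).
#' @param limit a [regulatory_limit()] or numeric ceiling (mg/kg).
#' @return object of class `thc_verdict`: `total`, `pass`, `components`,
#'   `acids` (reported separately), `limit`.
#' @examples
#' total_thc_verdict(c(`delta9-THC` = 3.0, `delta8-THC` = 0.3),
#'                   korea_limits("seed"))
#' @export
total_thc_verdict <- function(results, limit) {
  lim <- as_limit_value(limit)
  if (is.data.frame(results)) {
    vals <- stats::setNames(results$concentration_in_sample, results$analyte)
  } else {
    vals <- results
  }
  stopifnot(is.numeric(vals))
  neutral <- c("delta8-THC", "delta9-THC")
  acid <- c("THCA-A", "THCVA")
  components <- vals[names(vals) %in% neutral]
  total <- sum(components, na.rm = TRUE)
  structure(list(total = total, pass = total <= lim,
                 components = components,
                 acids = vals[names(vals) %in% acid],
                 limit = lim),
            class = "thc_verdict")
}

#' @export
print.thc_verdict <- function(x, ...) {
  cat(sprintf("Total THC (delta8 + delta9): %.4g mg/kg vs limit %.4g mg/kg: %s\n",
              x$total, x$limit, if (x$pass) "PASS" else "FAIL"))
  if (length(x$acids)) {
    cat("  acid forms (reported, not totalled):",
        paste(sprintf("%s %.4g", names(x$acids), x$acids), collapse = ", "),
        "\n")
  }
  invisible(x)
}
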