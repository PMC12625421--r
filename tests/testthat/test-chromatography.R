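test_that("chromatogram constructor validates its trace", {
  expect_error(chromatogram(numeric(), numeric()), "empty")
  expect_error(chromatogram(c(0, 1), c(0, 0, 0)), "equal length")
  expect_error(chromatogram(c(0, 1, 1), c(0, 0, 0), method = "AOA"),
               "strictly increasing")
  expect_error(chromatogram(seq(0, 5, 0.01), rep(0, 501), method = "PK16"),
               "10 min")
})

test_that("a flat trace yields no peaks; a synthetic Gaussian is located and integrated", {
  t <- seq(0, 12, by = 0.01)
  flat <- chromatogram(t, rep(0, length(t)))
  expect_equal(nrow(detect_peaks(flat)), 0)

  g <- 100 / (0.08 * sqrt(2 * pi)) * exp(-(t - 5.5)^2 / (2 * 0.08^2))
  pk <- detect_peaks(chromatogram(t, g))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$retention_time, 5.5, tolerance = 0.011)
  expect_equal(pk$area, 100, tolerance = 0.01 * 100)

  g2 <- g + 40 / (0.08 * sqrt(2 * pi)) * exp(-(t - 3.0)^2 / (2 * 0.08^2))
  pk2 <- detect_peaks(chromatogram(t, g2))
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$retention_time, c(3.0, 5.5), tolerance = 0.011)
  expect_equal(pk2$area, c(40, 100), tolerance = 0.01)
})

test_that("integration is linear: doubling the amplitude doubles the area", {
  t <- seq(0, 12, by = 0.01)
  g <- 50 / (0.08 * sqrt(2 * pi)) * exp(-(t - 5.5)^2 / (2 * 0.08^2))
  a1 <- detect_peaks(chromatogram(t, g))$area
  a2 <- detect_peaks(chromatogram(t, 2 * g))$area
  expect_equal(a2 / a1, 2, tolerance = 1e-3)
})

test_that("noise-only traces produce nothing above threshold", {
  ch <- gen_chromatogram(numeric(), impurity_area = 0, seed = 5)
  pk <- detect_peaks(ch, min_height = 1, min_prominence = 0.5)
  expect_equal(nrow(pk), 0)
})

test_that("peaks are assigned by retention window, with the front excluded", {
  pk <- data.frame(retention_time = c(1.0, 3.0, 4.5, 5.5, 11.0),
                   height = 1, area = 1,
                   t_start = 0, t_end = 0, assignment = NA_character_)
  class(pk) <- c("peak_table", "data.frame")
  attr(pk, "method") <- "PK16"
  out <- assign_peaks(pk)
  expect_equal(out$assignment,
               c("impurity_front", "CBD", "delta8-THC", "delta9-THC",
                 "unassigned"))
  # AOA: delta9-THC elutes near 7 min
  out_aoa <- assign_peaks(pk[4, ], method = "AOA")
  expect_equal(out_aoa$assignment, "unassigned")
  pk7 <- pk[1, ]; pk7$retention_time <- 7.2
  expect_equal(assign_peaks(pk7, method = "AOA")$assignment, "delta9-THC")
  # assignment is order-independent
  shuffled <- assign_peaks(pk[c(4, 1, 5, 2, 3), ], method = "PK16")
  expect_equal(shuffled$assignment[order(shuffled$retention_time)],
               out$assignment)
})

test_that("the PK16 window table is complete, non-overlapping and inside 2-10 min", {
  w <- pk16_windows()
  expect_equal(nrow(w), 16)
  expect_setequal(c("CBC", "CBCA", "CBD", "CBG", "CBN", "CBDA", "CBGA",
                    "CBNA", "CBL", "CBDV", "CBDVA", "delta8-THC",
                    "delta9-THC", "THCA-A", "THCV", "THCVA"), w$analyte)
  w <- w[order(w$rt_min), ]
  expect_true(all(w$rt_min[-1] >= w$rt_max[-nrow(w)]))
  expect_true(all(w$rt_min >= 2) && all(w$rt_max <= 10))
  # user-supplied overlapping windows are a configuration error
  bad <- data.frame(analyte = c("a", "b"), rt_min = c(3, 3.5),
                    rt_max = c(4, 4.5))
  pk <- data.frame(retention_time = 3.2, height = 1, area = 1,
                   t_start = 0, t_end = 0, assignment = NA_character_)
  expect_error(assign_peaks(pk, method = "PK16", windows = bad), "overlap")
})

test_that("calibration fitting: exact line, noisy slope, degenerate input", {
  cal_df <- gen_calibration_set(noise_cv = 0)
  expect_equal(cal_df$level_mg_per_L,
               50 / 2^(0:7))
  cal <- fit_calibration(cal_df, analyte = "delta9-THC")
  expect_equal(cal$slope, 12.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  noisy <- gen_calibration_set(noise_cv = 0.01, seed = 3)
  cal_n <- fit_calibration(noisy)
  expect_equal(cal_n$slope, 12.5, tolerance = 0.02 * 12.5)

  one <- data.frame(level_mg_per_L = c(5, 5), area = c(60, 61))
  expect_error(fit_calibration(one), "singular")
})

test_that("quantification inverts the calibration with dilution scaling", {
  cal <- fit_calibration(gen_calibration_set(noise_cv = 0))
  expect_equal(quantify(cal$intercept, cal)$concentration, 0)
  q1 <- quantify(12.5 * 2, cal, dilution_factor = 1)
  q4 <- quantify(12.5 * 2, cal, dilution_factor = 4)
  expect_equal(q1$concentration_in_solution, 2)
  expect_equal(q4$concentration_in_solution, 8)
  expect_error(quantify(12.5 * 100, cal), "extrapolate")

  bad <- cal; bad$slope <- -1
  expect_error(quantify(10, bad), "slope")

  # matrix back-calculation: mg/L x L / kg
  qm <- quantify(12.5 * 2, cal, dilution_factor = 1,
                 extract_volume_mL = 20, sample_mass_g = 5)
  expect_equal(qm$concentration_in_sample, 2 * 0.02 / 0.005)
})

test_that("dilution chains compose multiplicatively", {
  expect_equal(dilution_chain_factor(c("4:1", "1:1", "1:1")), 20)
  expect_equal(dilution_chain_factor("1:1"), 2)
  expect_error(dilution_chain_factor("4"), "malformed")
})

test_that("generated chromatograms round-trip through the quantification pipeline", {
  cal <- fit_calibration(gen_calibration_set(noise_cv = 0))
  ch <- gen_chromatogram(c(`delta9-THC` = 50), seed = 7)
  pk <- assign_peaks(detect_peaks(ch))
  expect_true("delta9-THC" %in% pk$assignment)
  thc <- pk[pk$assignment == "delta9-THC", ]
  expect_gte(thc$retention_time, 5)
  expect_lte(thc$retention_time, 6)
  q <- quantify(thc$area, cal)
  expect_equal(q$concentration, 50, tolerance = 0.02 * 50)
})

test_that("total-THC verdict sums neutral isomers and reports acids separately", {
  lim <- korea_limits("seed")
  expect_true(total_thc_verdict(c(`delta9-THC` = 2.0), lim)$pass)
  v <- total_thc_verdict(c(`delta9-THC` = 3.0, `delta8-THC` = 0.3), lim)
  expect_equal(v$total, 3.3)
  expect_true(v$pass)
  expect_false(total_thc_verdict(c(`delta9-THC` = 6), lim)$pass)
  va <- total_thc_verdict(c(`delta9-THC` = 3, `THCA-A` = 40), lim)
  expect_equal(va$total, 3)
  expect_true(va$pass)
  expect_equal(unname(va$acids["THCA-A"]), 40)
})

test_that("chromatogram CSV round-trips with its method sidecar", {
  tmp <- file.path(tempdir(), "chrom.csv")
  ch <- gen_chromatogram(c(CBD = 10), seed = 2)
  write_chromatogram_csv(ch, tmp)
  back <- read_chromatogram_csv(tmp)
  expect_equal(back$time, ch$time)
  expect_equal(back$signal, ch$signal)
  expect_equal(back$method, "PK16")
  unlink(c(tmp, paste0(tmp, ".json")))
})
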