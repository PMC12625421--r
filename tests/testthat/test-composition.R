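test_that("remainder density reproduces the printed interval endpoints", {
  # unprocessed 10% husk at 1.5x kernel density -> 1.05 rho_c
  expect_equal(remainder_density(0.10, 1, 1.5, x = 0), 1.05,
               tolerance = 1e-15)
  # complete husk removal -> kernel density
  expect_equal(remainder_density(0.10, 1, 1.5, x = 0.10), 1)
  # partial removal, frozen from the explicit volume bookkeeping oracle
  expect_equal(remainder_density(0.10, 1, 1.5, x = 0.05),
               remainder_by_volumes(1.5, 1, 0.10, 0.05),
               tolerance = 1e-12)
  expect_equal(remainder_density(0.10, 1, 1.5, x = 0.05), 1.0263158,
               tolerance = 1e-6)
})

test_that("remainder density stays inside [rho_c, 1.05 rho_c] and is continuous", {
  x <- seq(0, 0.10, length.out = 1001)
  rho <- remainder_density(0.10, 1, 1.5, x)
  expect_true(all(rho >= 1 - 1e-12))
  expect_true(all(rho <= 1.05 + 1e-12))
  expect_true(all(diff(rho) < 0))
  # continuity across the exact-husk boundary into the kernel-only branch
  eps <- 1e-9
  expect_equal(remainder_density(0.10, 1, 1.5, 0.10 - eps),
               remainder_density(0.10, 1, 1.5, 0.10 + eps),
               tolerance = 1e-6)
  expect_error(remainder_density(0.10, 1, 1.5, 1.2), "\\[0, 1\\]")
})

test_that("remainder concentration hits the whole-seed, threshold and kernel values", {
  p <- ref_seed
  expect_equal(remainder_concentration(p$f_H, p$C_H, p$C_C, 0), 31.8)
  expect_equal(remainder_concentration(p$f_H, p$C_H, p$C_C, p$f_H), 2)
  # x = 0.09085 sits within rounding of the 5 mg/kg crossing
  expect_equal(remainder_concentration(p$f_H, p$C_H, p$C_C, 0.09085), 5.0,
               tolerance = 1e-3)
  expect_error(remainder_concentration(p$f_H, p$C_H, p$C_C, 1), "\\[0, 1\\)")
})

test_that("density and concentration share one mixing kernel (rho -> C substitution)", {
  set.seed(11)
  for (i in 1:200) {
    f_H <- runif(1, 0.01, 0.6)
    hi <- runif(1, 10, 500)
    lo <- runif(1, 0, hi)
    x <- runif(1, 0, f_H)
    expect_identical(remainder_density(f_H, lo, hi, x),
                     remainder_concentration(f_H, hi, lo, x))
    expect_equal(remainder_concentration(f_H, hi, lo, x),
                 remainder_by_volumes(hi, lo, f_H, x),
                 tolerance = 1e-12)
  }
})

test_that("concentration is bounded by the kernel and husk values", {
  set.seed(12)
  for (i in 1:200) {
    f_H <- runif(1, 0.01, 0.7)
    C_H <- runif(1, 10, 1000)
    C_C <- runif(1, 0, C_H)
    x <- runif(1, 0, 0.999)
    C <- remainder_concentration(f_H, C_H, C_C, x)
    expect_gte(C, C_C - 1e-12)
    expect_lte(C, C_H + 1e-12)
  }
})

test_that("minimal removal threshold: closed form, bisection and edge cases", {
  p <- ref_seed
  thr <- min_removal_for_limit(p$f_H, p$C_H, p$C_C, korea_limits("seed"))
  expect_true(thr$feasible)
  expect_equal(round(100 * thr$x_star, 1), 9.1)
  expect_equal(remainder_concentration(p$f_H, p$C_H, p$C_C, thr$x_star), 5,
               tolerance = 1e-9)

  bis <- min_removal_for_limit(p$f_H, p$C_H, p$C_C, 5, method = "bisection")
  expect_equal(thr$x_star, bis$x_star, tolerance = 1e-10)

  # already compliant at the whole-seed mixture value
  expect_equal(min_removal_for_limit(p$f_H, p$C_H, p$C_C, 31.8)$x_star, 0)
  # limit at the kernel floor: the entire husk must go
  expect_equal(min_removal_for_limit(p$f_H, p$C_H, p$C_C, 2)$x_star, p$f_H,
               tolerance = 1e-12)
  # below the kernel floor: infeasible
  inf <- min_removal_for_limit(p$f_H, p$C_H, p$C_C, 1)
  expect_false(inf$feasible)
  expect_true(is.na(inf$x_star))
})

test_that("closed form and bisection agree across random parameter draws", {
  set.seed(13)
  for (i in 1:10000) {
    f_H <- runif(1, 0.02, 0.6)
    C_H <- runif(1, 50, 1000)
    C_C <- runif(1, 0, 10)
    ws <- f_H * C_H + (1 - f_H) * C_C
    lim <- runif(1, C_C + 0.1, ws - 0.1)
    if (lim <= 0) next
    a <- min_removal_for_limit(f_H, C_H, C_C, lim)$x_star
    b <- min_removal_for_limit(f_H, C_H, C_C, lim,
                               method = "bisection")$x_star
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("whole-seed concentration: volume canonical, mass-weighted variant", {
  p <- ref_seed
  expect_equal(whole_seed_concentration(p$f_H, p$C_H, p$C_C), 31.8)
  expect_equal(whole_seed_concentration(0, 300, 2), 2)
  both <- whole_seed_concentration(p$f_H, p$C_H, p$C_C,
                                   rho_c = 1, rho_H = 1.5)
  expect_equal(unname(both["volume_weighted"]), 31.8)
  # (0.1*1.5*300 + 0.9*1*2)/(0.1*1.5 + 0.9*1) = 46.8/1.05, by hand
  expect_equal(unname(both["mass_weighted"]), 46.8 / 1.05,
               tolerance = 1e-12)
})

test_that("simulated removal curve is strictly decreasing with correct endpoints", {
  p <- ref_seed
  expect_equal(simulate_removal_curve(p$f_H, p$C_H, p$C_C,
                                      x_grid = 0)$C_remain, 31.8)
  expect_equal(simulate_removal_curve(p$f_H, p$C_H, p$C_C,
                                      x_grid = p$f_H)$C_remain, 2)
  curve <- simulate_removal_curve(p$f_H, p$C_H, p$C_C)
  expect_true(all(diff(curve$C_remain) < 0))
  expect_equal(curve$C_remain[1],
               whole_seed_concentration(p$f_H, p$C_H, p$C_C))
  # the 5 mg/kg crossing lies between x = 0.090 and 0.091
  lo <- remainder_concentration(p$f_H, p$C_H, p$C_C, 0.090)
  hi <- remainder_concentration(p$f_H, p$C_H, p$C_C, 0.091)
  expect_true(lo > 5 && hi < 5)
  expect_error(simulate_removal_curve(p$f_H, p$C_H, p$C_C, x_grid = 0.2),
               "within")
})

test_that("compliance check is inclusive at the boundary", {
  lim <- korea_limits("seed")
  expect_true(compliance_check(2, lim)$pass)
  expect_true(compliance_check(5.0, lim)$pass)
  expect_false(compliance_check(31.8, lim)$pass)
  expect_equal(compliance_check(2, lim)$margin, 3)
  expect_equal(korea_limits("oil")$limit, 10)
})

test_that("archetype reporting: husk carries two orders of magnitude more THC", {
  expect_equal(husk_kernel_ratio(), 150)
  expect_gte(husk_kernel_ratio(), 100)
})

test_that("mg/L converts to mg/kg through the density", {
  expect_equal(mg_per_L_to_mg_per_kg(10, 1), 10)
  expect_equal(mg_per_L_to_mg_per_kg(9.2, 0.92), 10)
})
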