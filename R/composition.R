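#' Shared remainder mixture kernel
#'
#' Both the remainder density and the remainder THC concentration obey the
#' same spherical-shell mixing law: with a husk-borne value `high`, a
#' kernel-borne value `low`, husk volume fraction `f_H` and removed volume
#' fraction `x <= f_H`,
#' `value(x) = high - (high - low) * (1 - f_H) / (1 - x)`.
#' For `x > f_H` only kernel remains and the kernel value is returned.
#'
#' @noRd
shell_remainder_value <- function(high, low, f_H, x) {
  out <- ifelse(x <= f_H,
                high - (high - low) * (1 - f_H) / (1 - x),
                low)
  # guard against FP undershoot at the exact-husk boundary
  pmin(pmax(out, pmin(low, high)), pmax(low, high))
}

check_fraction <- function(v, name, upper_open = TRUE) {
  if (any(!is.finite(v)) || any(v < 0) ||
      (upper_open && any(v >= 1)) || (!upper_open && any(v > 1))) {
    stop(sprintf("`%s` must lie in [0, 1%s", name,
                 if (upper_open) ")" else "]"), call. = FALSE)
  }
  invisible(v)
}

#' Removal regime classification
#'
#' @param f_H husk volume fraction.
#' @param x removed volume fraction. Vectorised.
#' @return character: `"partial_husk"` (`x < f_H`), `"exact_husk"`
#'   (`x == f_H` to within 1e-12), or `"over_extracted"`.
#' @export
removal_regime <- function(f_H, x) {
  ifelse(abs(x - f_H) <= 1e-12, "exact_husk",
         ifelse(x < f_H, "partial_husk", "over_extracted"))
}

#' Density of the remaining material under partial husk removal
#'
#' While some husk remains (`x <= f_H`) the remainder is a husk/kernel mixture
#' with density `rho_H - (rho_H - rho_c) * V_C.max / V_r`, which in removed-
#' fraction form is `rho_H - (rho_H - rho_c) * (1 - f_H) / (1 - x)`. Once the
#' husk is gone (`x > f_H`) only kernel remains and the density is `rho_c`.
#' With a 10% husk at 1.5 times kernel density, the unprocessed seed sits at
#' `1.05 * rho_c` and processing moves it down to `rho_c`.
#'
#' @param f_H husk volume fraction, in `[0, 1)`.
#' @param rho_c kernel density (any unit; ratios matter).
#' @param rho_H husk density, same unit; must be `>= rho_c`.
#' @param x removed volume fraction, in `[0, 1]`. Vectorised.
#' @return remainder density, same unit as `rho_c`; always in
#'   `[rho_c, rho_H]`.
#' @examples
#' remainder_density(f_H = 0.10, rho_c = 1, rho_H = 1.5, x = 0)     # 1.05
#' remainder_density(f_H = 0.10, rho_c = 1, rho_H = 1.5, x = 0.10)  # 1 (kernel)
#' @export
remainder_density <- function(f_H, rho_c, rho_H, x) {
  stopifnot(is.numeric(f_H), is.numeric(rho_c), is.numeric(rho_H),
            is.numeric(x), rho_c > 0, rho_H > 0, rho_H >= rho_c)
  check_fraction(f_H, "f_H")
  check_fraction(x, "x", upper_open = FALSE)
  shell_remainder_value(rho_H, rho_c, f_H, x)
}

#' THC concentration of the remaining material under partial husk removal
#'
#' The density mixing law extends to any conserved component carried at
#' different levels by husk and kernel. With husk THC concentration `C_H` and
#' kernel concentration `C_C` (mg/kg), the remainder concentration is
#' `C_H - (C_H - C_C) * (1 - f_H) / (1 - x)` while husk remains, and `C_C`
#' once removal exceeds the husk fraction. It is strictly decreasing in `x`
#' on `[0, f_H]`, from the whole-seed mixture value down to the kernel value.
#'
#' @param f_H husk volume fraction, in `[0, 1)`.
#' @param C_H husk THC concentration (mg/kg).
#' @param C_C kernel THC concentration (mg/kg); `C_H >= C_C >= 0`.
#' @param x removed volume fraction, in `[0, 1)` (at `x = 1` nothing remains).
#'   Vectorised.
#' @return remainder THC concentration (mg/kg), in `[C_C, C_H]`.
#' @examples
#' remainder_concentration(0.10, 300, 2, x = 0)     # 31.8 mg/kg whole seed
#' remainder_concentration(0.10, 300, 2, x = 0.10)  # 2 mg/kg, kernel only
#' @export
remainder_concentration <- function(f_H, C_H, C_C, x) {
  stopifnot(is.numeric(f_H), is.numeric(C_H), is.numeric(C_C), is.numeric(x),
            C_C >= 0, C_H >= C_C)
  check_fraction(f_H, "f_H")
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 1)) {
    stop("`x` must lie in [0, 1): at x = 1 nothing remains", call. = FALSE)
  }
  shell_remainder_value(C_H, C_C, f_H, x)
}

#' Whole-seed THC concentration
#'
#' The `x = 0` evaluation of the remainder model: the volume-weighted mixture
#' `f_H * C_H + (1 - f_H) * C_C`. This volume weighting is the canonical model
#' (it treats concentration like density, with unit compatibility assumed);
#' when husk and kernel densities are supplied a mass-weighted variant
#' `(f_H rho_H C_H + (1-f_H) rho_c C_C) / (f_H rho_H + (1-f_H) rho_c)` is
#' returned alongside, clearly labelled non-canonical.
#'
#' @param f_H husk volume fraction.
#' @param C_H,C_C husk and kernel THC concentrations (mg/kg).
#' @param rho_c,rho_H optional densities enabling the mass-weighted variant.
#' @return If densities are omitted, the volume-weighted value (numeric).
#'   Otherwise a named numeric vector with `volume_weighted` (canonical) and
#'   `mass_weighted` elements.
#' @examples
#' whole_seed_concentration(0.10, 300, 2)                       # 31.8
#' whole_seed_concentration(0.10, 300, 2, rho_c = 1, rho_H = 1.5)
#' @export
whole_seed_concentration <- function(f_H, C_H, C_C, rho_c = NULL,
                                     rho_H = NULL) {
  check_fraction(f_H, "f_H")
  stopifnot(C_C >= 0, C_H >= C_C)
  vw <- f_H * C_H + (1 - f_H) * C_C
  if (is.null(rho_c) && is.null(rho_H)) return(vw)
  stopifnot(!is.null(rho_c), !is.null(rho_H), rho_c > 0, rho_H > 0)
  mw <- (f_H * rho_H * C_H + (1 - f_H) * rho_c * C_C) /
    (f_H * rho_H + (1 - f_H) * rho_c)
  c(volume_weighted = vw, mass_weighted = mw)
}

#' Regulatory THC limit
#'
#' Constructor for a jurisdiction/product THC ceiling. The two limits the
#' package bundles (see [korea_limits()]) are Korea's: 5 mg/kg for seeds and
#' 10 mg/kg for hemp seed oil. Other jurisdictions are user-supplied, not
#' guessed.
#'
#' @param jurisdiction label, e.g. `"Korea"`.
#' @param product `"seed"` or `"oil"`.
#' @param limit THC ceiling in mg/kg, positive.
#' @return object of class `regulatory_limit`.
#' @export
regulatory_limit <- function(jurisdiction, product = c("seed", "oil"), limit) {
  product <- match.arg(product)
  stopifnot(is.character(jurisdiction), length(jurisdiction) == 1L,
            is.numeric(limit), length(limit) == 1L, limit > 0)
  structure(list(jurisdiction = jurisdiction, product = product,
                 limit = limit),
            class = "regulatory_limit")
}

#' Bundled Korean THC limits
#'
#' @param product `"seed"` (5 mg/kg) or `"oil"` (10 mg/kg).
#' @return a [regulatory_limit()].
#' @export
korea_limits <- function(product = c("seed", "oil")) {
  product <- match.arg(product)
  regulatory_limit("Korea", product,
                   limit = if (product == "seed") 5 else 10)
}

#' @export
print.regulatory_limit <- function(x, ...) {
  cat(sprintf("Regulatory THC limit: %s %s, %.3g mg/kg (inclusive)\n",
              x$jurisdiction, x$product, x$limit))
  invisible(x)
}

as_limit_value <- function(limit) {
  if (inherits(limit, "regulatory_limit")) limit$limit
  else {
    stopifnot(is.numeric(limit), length(limit) == 1L, limit > 0)
    limit
  }
}

#' Minimal removed volume fraction to meet a THC limit
#'
#' Solves `remainder_concentration(f_H, C_H, C_C, x) = limit` for the smallest
#' removed fraction `x*`. The closed form is
#' `x* = 1 - (C_H - C_C) (1 - f_H) / (C_H - limit)`; a bisection solver on the
#' same equation is available as an independent cross-check. With the in-paper
#' parameters (10% husk, 300/2 mg/kg) and Korea's 5 mg/kg seed ceiling,
#' `x*` is about 0.0908, i.e. removing just over 9.1% of the seed volume
#' (essentially the husk alone) is sufficient.
#'
#' @param f_H husk volume fraction.
#' @param C_H,C_C husk and kernel THC concentrations (mg/kg).
#' @param limit a [regulatory_limit()] or a numeric ceiling (mg/kg).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return object of class `removal_threshold`: list with `x_star` (NA when
#'   infeasible), `feasible`, `limit`, `achieved` (remainder concentration at
#'   `x_star`) and `method`.
#' @examples
#' min_removal_for_limit(0.10, 300, 2, korea_limits("seed"))
#' @export
min_removal_for_limit <- function(f_H, C_H, C_C, limit,
                                  method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  lim <- as_limit_value(limit)
  check_fraction(f_H, "f_H")
  stopifnot(C_C >= 0, C_H >= C_C)
  feasible <- lim >= C_C
  if (!feasible) {
    x_star <- NA_real_
  } else if (lim >= whole_seed_concentration(f_H, C_H, C_C)) {
    x_star <- 0
  } else if (method == "closed_form") {
    x_star <- 1 - (C_H - C_C) * (1 - f_H) / (C_H - lim)
  } else {
    f <- function(x) remainder_concentration(f_H, C_H, C_C, x) - lim
    x_star <- stats::uniroot(f, interval = c(0, f_H),
                             tol = .Machine$double.eps / 4)$root
  }
  achieved <- if (feasible && !is.na(x_star)) {
    remainder_concentration(f_H, C_H, C_C, x_star)
  } else NA_real_
  structure(list(x_star = x_star, feasible = feasible, limit = lim,
                 achieved = achieved, method = method,
                 params = list(f_H = f_H, C_H = C_H, C_C = C_C)),
            class = "removal_threshold")
}

#' @export
print.removal_threshold <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf(
      "Infeasible: even the pure kernel exceeds the %.3g mg/kg limit\n",
      x$limit))
  } else {
    cat(sprintf(
      "Minimal removal x* = %.5f (%.1f%% of seed volume) for limit %.3g mg/kg [%s]\n",
      x$x_star, 100 * x$x_star, x$limit, x$method))
    cat(sprintf("  remainder THC at x*: %.6g mg/kg\n", x$achieved))
  }
  invisible(x)
}

#' Simulate the removal curve (remainder THC vs removed fraction)
#'
#' Evaluates the remainder-concentration model on a grid of removed fractions
#' within `[0, f_H]`, reproducing the standard simulation figure: the curve
#' starts at the whole-seed mixture value, decreases strictly, and reaches the
#' kernel value at complete husk removal.
#'
#' @param f_H husk volume fraction.
#' @param C_H,C_C husk and kernel THC concentrations (mg/kg).
#' @param x_grid removed fractions, all in `[0, f_H]`; default 101 points.
#' @return data.frame with columns `x` and `C_remain` (mg/kg).
#' @examples
#' head(simulate_removal_curve(0.10, 300, 2))
#' @export
simulate_removal_curve <- function(f_H, C_H, C_C,
                                   x_grid = seq(0, f_H, length.out = 101)) {
  check_fraction(f_H, "f_H")
  if (any(x_grid < 0) || any(x_grid > f_H)) {
    stop("`x_grid` must lie within [0, f_H]", call. = FALSE)
  }
  data.frame(x = x_grid,
             C_remain = remainder_concentration(f_H, C_H, C_C, x_grid))
}

#' Compliance check of a THC concentration against a limit
#'
#' The boundary is inclusive: a value exactly at the ceiling passes (the
#' regulation is phrased as "at or below").
#'
#' @param C measured THC concentration (mg/kg), non-negative.
#' @param limit a [regulatory_limit()] or numeric ceiling (mg/kg).
#' @return object of class `compliance_report`: list with `pass`, `value`,
#'   `limit`, `margin` (limit - value), `jurisdiction`, `product`.
#' @examples
#' compliance_check(2, korea_limits("seed"))
#' @export
compliance_check <- function(C, limit) {
  stopifnot(is.numeric(C), length(C) == 1L, C >= 0)
  lim <- as_limit_value(limit)
  jur <- if (inherits(limit, "regulatory_limit")) limit$jurisdiction else NA
  prod <- if (inherits(limit, "regulatory_limit")) limit$product else NA
  structure(list(pass = C <= lim, value = C, limit = lim,
                 margin = lim - C, jurisdiction = jur, product = prod),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("THC %.4g mg/kg vs limit %.4g mg/kg (%s, %s): %s (margin %.4g)\n",
              x$value, x$limit,
              ifelse(is.na(x$jurisdiction), "user", x$jurisdiction),
              ifelse(is.na(x$product), "-", x$product),
              if (x$pass) "PASS" else "FAIL", x$margin))
  invisible(x)
}

#' The in-paper hemp seed archetype
#'
#' The parameter set the model analysis is carried out with: husk occupying
#' 10% of the seed volume at 1.5 times the kernel density, husk THC
#' 300 mg/kg, kernel THC 2 mg/kg.
#'
#' @return list with `f_H`, `rho_ratio` (`rho_H / rho_c`), `C_H` and `C_C`.
#' @export
hemp_seed_archetype <- function() {
  list(f_H = 0.10, rho_ratio = 1.5, C_H = 300, C_C = 2)
}

#' Husk-to-kernel THC concentration ratio
#'
#' Reporting helper: how many times more THC the husk carries than the kernel.
#' For the bundled archetype this is 150 (the husk exceeds the kernel by more
#' than two orders of magnitude).
#'
#' @param seed a list with `C_H` and `C_C`, e.g. [hemp_seed_archetype()].
#' @return numeric ratio `C_H / C_C`.
#' @export
husk_kernel_ratio <- function(seed = hemp_seed_archetype()) {
  stopifnot(is.numeric(seed$C_H), is.numeric(seed$C_C), seed$C_C > 0)
  seed$C_H / seed$C_C
}
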