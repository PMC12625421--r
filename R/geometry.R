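#' Spherical seed geometry
#'
#' A hemp seed is modelled as a sphere of outer radius `R` whose outer shell of
#' thickness `t_H` is husk and whose inner ball of radius `r_c_max = R - t_H`
#' is the nut kernel. Exactly one of `t_H` or the husk volume fraction `f_H`
#' must be given; the other is derived from the spherical shell relation
#' `f_H = 1 - (1 - t_H/R)^3`.
#'
#' @param R outer radius (mm), positive.
#' @param t_H husk thickness (mm), in `[0, R)`.
#' @param f_H husk volume fraction, in `[0, 1)`.
#' @return An object of class `seed_geometry`: a list with fields `R`, `t_H`,
#'   `r_c_max` and `f_H`.
#' @examples
#' seed_geometry(R = 1, f_H = 0.10)
#' @export
seed_geometry <- function(R, t_H = NULL, f_H = NULL) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R > 0)
  if (is.null(t_H) == is.null(f_H)) {
    stop("supply exactly one of `t_H` or `f_H`", call. = FALSE)
  }
  if (is.null(t_H)) {
    t_H <- R * thickness_from_husk_fraction(f_H)
  } else {
    stopifnot(is.numeric(t_H), length(t_H) == 1L, t_H >= 0, t_H < R)
    f_H <- husk_fraction_from_thickness(t_H / R)
  }
  structure(
    list(R = R, t_H = t_H, r_c_max = R - t_H, f_H = f_H),
    class = "seed_geometry"
  )
}

#' @export
print.seed_geometry <- function(x, ...) {
  cat("Spherical seed geometry\n")
  cat(sprintf("  outer radius R      : %.4f mm\n", x$R))
  cat(sprintf("  husk thickness t_H  : %.4f mm (t_H/R = %.4f)\n",
              x$t_H, x$t_H / x$R))
  cat(sprintf("  max kernel radius   : %.4f mm\n", x$r_c_max))
  cat(sprintf("  husk volume fraction: %.4f\n", x$f_H))
  invisible(x)
}

#' Volume of a spherical shell
#'
#' Volume removed when a sphere of radius `R` is pared down to radius `r_c`:
#' `(4 pi / 3) (R^3 - r_c^3)`, i.e. the integral of `4 pi r^2` from `r_c` to
#' `R`.
#'
#' @param R outer radius (mm).
#' @param r_c inner radius (mm), `0 <= r_c <= R`. Vectorised over `r_c`.
#' @return shell volume (mm^3); zero iff `r_c == R`.
#' @examples
#' sphere_shell_volume(1, 0)            # full sphere, 4*pi/3
#' sphere_shell_volume(1, 0.9^(1/3))    # 10% of the seed volume
#' @export
sphere_shell_volume <- function(R, r_c) {
  stopifnot(is.numeric(R), is.numeric(r_c), all(is.finite(R)),
            all(is.finite(r_c)))
  if (any(R < 0) || any(r_c < 0)) stop("radii must be non-negative",
                                       call. = FALSE)
  if (any(r_c > R)) stop("`r_c` must not exceed `R`", call. = FALSE)
  (4 * pi / 3) * (R^3 - r_c^3)
}

#' Relative husk thickness from husk volume fraction
#'
#' Solves `f_H = 1 - (1 - t/R)^3` for `t/R`: the shell thickness (relative to
#' the seed radius) that makes the husk occupy a fraction `f_H` of the seed
#' volume.
#'
#' @param f_H husk volume fraction, in `[0, 1)`. Vectorised.
#' @return relative thickness `t_H / R`, strictly increasing in `f_H`.
#' @examples
#' thickness_from_husk_fraction(0.10)  # ~0.0345: a 10% husk is a thin shell
#' @export
thickness_from_husk_fraction <- function(f_H) {
  stopifnot(is.numeric(f_H))
  if (any(!is.finite(f_H)) || any(f_H < 0) || any(f_H >= 1)) {
    stop("`f_H` must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - f_H)^(1 / 3)
}

#' Husk volume fraction from relative thickness
#'
#' Exact inverse of [thickness_from_husk_fraction()].
#'
#' @param t_rel relative husk thickness `t_H / R`, in `[0, 1)`. Vectorised.
#' @return husk volume fraction.
#' @export
husk_fraction_from_thickness <- function(t_rel) {
  stopifnot(is.numeric(t_rel))
  if (any(!is.finite(t_rel)) || any(t_rel < 0) || any(t_rel >= 1)) {
    stop("`t_rel` must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - t_rel)^3
}

#' Removal state and volume breakdown for a removed volume fraction
#'
#' Given a seed geometry and the fraction `x` of whole-seed volume removed
#' (from the outside in), computes the current core radius
#' `r_c = R (1 - x)^(1/3)`, the over-extraction thickness
#' `t_OE = max(0, R - r_c - t_H)` (kernel depth lost beyond the husk), and the
#' full volume breakdown. `x` equal to the husk fraction means perfect
#' dehulling (`t_OE = 0`); `x = 1` removes everything (`r_c = 0`,
#' `t_OE = R - t_H`).
#'
#' @param geom a [seed_geometry()].
#' @param x removed volume fraction, in `[0, 1]`.
#' @return An object of class `removal_state`: list with `r_c`, `x`, `t_OE`,
#'   `regime` (one of `"partial_husk"`, `"exact_husk"`, `"over_extracted"`)
#'   and `volumes`, a list with `V_R`, `V_H`, `V_C_max`, `V_r`, `V_red`,
#'   `V_OE` (mm^3) satisfying `V_R = V_H + V_C_max` and, whenever
#'   `r_c <= r_c_max`, `V_red = V_H + V_OE`.
#' @examples
#' g <- seed_geometry(R = 1, f_H = 0.10)
#' removal_state(g, x = 0.10)  # husk exactly removed: t_OE = 0
#' @export
removal_state <- function(geom, x) {
  stopifnot(inherits(geom, "seed_geometry"), is.numeric(x), length(x) == 1L)
  if (!is.finite(x) || x < 0 || x > 1) stop("`x` must lie in [0, 1]",
                                            call. = FALSE)
  R <- geom$R
  r_c <- R * (1 - x)^(1 / 3)
  t_OE <- max(0, R - r_c - geom$t_H)
  V_R <- sphere_shell_volume(R, 0)
  V_C_max <- sphere_shell_volume(geom$r_c_max, 0)
  V_H <- V_R - V_C_max
  V_r <- sphere_shell_volume(r_c, 0)
  V_red <- V_R - V_r
  V_OE <- if (r_c <= geom$r_c_max) V_C_max - V_r else 0
  regime <- removal_regime(geom$f_H, x)
  structure(
    list(r_c = r_c, x = x, t_OE = t_OE, regime = regime,
         volumes = list(V_R = V_R, V_H = V_H, V_C_max = V_C_max,
                        V_r = V_r, V_red = V_red, V_OE = V_OE)),
    class = "removal_state"
  )
}

#' @export
print.removal_state <- function(x, ...) {
  v <- x$volumes
  cat(sprintf("Removal state: x = %.4f (%s)\n", x$x, x$regime))
  cat(sprintf("  core radius r_c = %.5f mm, over-extraction t_OE = %.5f mm\n",
              x$r_c, x$t_OE))
  cat(sprintf("  V_R = %.4f, V_H = %.4f, V_r = %.4f, V_red = %.4f, V_OE = %.4f mm^3\n",
              v$V_R, v$V_H, v$V_r, v$V_red, v$V_OE))
  invisible(x)
}
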