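# Independent oracles used to freeze expected values.

# shell volume by numerical quadrature of 4*pi*r^2
quad_shell_volume <- function(R, r_c) {
  stats::integrate(function(r) 4 * pi * r^2, lower = r_c, upper = R,
                   rel.tol = 1e-12)$value
}

# invert f_H = 1 - (1 - t)^3 numerically (oracle for the closed form)
thickness_by_root <- function(f_H) {
  stats::uniroot(function(t) 1 - (1 - t)^3 - f_H, c(0, 1 - 1e-12),
                 tol = 1e-14)$root
}

# remainder value by explicit volume bookkeeping (independent of the
# removed-fraction form used in the package kernel)
remainder_by_volumes <- function(high, low, f_H, x, V_R = 1) {
  V_H <- f_H * V_R
  V_C_max <- V_R - V_H
  V_r <- (1 - x) * V_R
  (high * V_r - (high - low) * V_C_max) / V_r
}

ref_seed <- list(f_H = 0.10, C_H = 300, C_C = 2)
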