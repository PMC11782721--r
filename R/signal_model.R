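# Steady-state MP2RAGE signal model.
#
# Every stage of one MP2RAGE cycle (inversion, free relaxation, FLASH
# excitation trains) acts on the longitudinal magnetization Mz as an affine
# map Mz -> a*Mz + b. Composing the stages gives the whole cycle as a single
# affine map whose fixed point is the steady-state magnetization; the two
# gradient-echo signals are read out at the k-space-centre excitation of each
# block. Transverse magnetization is assumed perfectly spoiled between
# excitations and the inversion is instantaneous.

# compose g after f: (g o f)(m) = g$a*(f$a*m + f$b) + g$b
.aff_compose <- function(f, g) {
  list(a = g$a * f$a, b = g$a * f$b + g$b)
}

# free relaxation for time t (vectorized over r1)
.aff_relax <- function(t, r1, m0) {
  e <- exp(-t * r1)
  list(a = e, b = m0 * (1 - e))
}

# one FLASH repetition: excitation (Mz -> Mz*cos(alpha)) then relaxation
# over tr_flash
.aff_rep <- function(alpha, tr_flash, r1, m0) {
  e <- exp(-tr_flash * r1)
  list(a = cos(alpha) * e, b = m0 * (1 - e))
}

# k-fold self-composition of an affine map (geometric series in closed form);
# the a == 1 branch only arises in degenerate limits kept for completeness
.aff_pow <- function(f, k) {
  if (k == 0) return(list(a = rep(1, length(f$a)), b = rep(0, length(f$a))))
  a <- f$a^k
  b <- ifelse(abs(1 - f$a) < .Machine$double.eps,
              k * f$b,
              f$b * (1 - a) / (1 - f$a))
  list(a = a, b = b)
}

# Internal workhorse: cycle map plus the pre-readout maps of both blocks,
# vectorized elementwise over r1 and b1 (recycled to common length).
.cycle_maps <- function(protocol, r1, b1 = protocol$b1_scale) {
  p <- protocol
  n <- max(length(r1), length(b1))
  r1 <- rep_len(r1, n)
  b1 <- rep_len(b1, n)
  kc <- floor(p$n_exc / 2)
  a1 <- b1 * p$fa1 * pi / 180
  a2 <- b1 * p$fa2 * pi / 180
  ta <- p$ti1 - kc * p$tr_flash
  tb <- p$ti2 - p$ti1 - p$n_exc * p$tr_flash
  tc <- p$tr_mp2rage - p$ti2 - (p$n_exc - kc) * p$tr_flash

  rep1 <- .aff_rep(a1, p$tr_flash, r1, p$m0)
  rep2 <- .aff_rep(a2, p$tr_flash, r1, p$m0)

  cyc <- list(a = rep(-p$inv_eff, n), b = rep(0, n))     # inversion
  cyc <- .aff_compose(cyc, .aff_relax(ta, r1, p$m0))     # delay TA
  pre1 <- .aff_compose(cyc, .aff_pow(rep1, kc))          # up to centre of block 1
  cyc <- .aff_compose(cyc, .aff_pow(rep1, p$n_exc))      # full block 1
  cyc <- .aff_compose(cyc, .aff_relax(tb, r1, p$m0))     # delay TB
  pre2 <- .aff_compose(cyc, .aff_pow(rep2, kc))          # up to centre of block 2
  cyc <- .aff_compose(cyc, .aff_pow(rep2, p$n_exc))      # full block 2
  cyc <- .aff_compose(cyc, .aff_relax(tc, r1, p$m0))     # delay TC
  list(cycle = cyc, pre1 = pre1, pre2 = pre2, sin1 = sin(a1), sin2 = sin(a2))
}

.check_r1 <- function(r1) {
  if (!is.numeric(r1) || length(r1) == 0 || any(!is.finite(r1)) ||
      any(r1 <= 0)) {
    rlang::abort("`r1` must be finite, positive relaxation rates (s^-1).",
                 class = "r1lut_input_error")
  }
}

#' Affine map of one MP2RAGE cycle
#'
#' Composes the stages of one MP2RAGE cycle -- inversion, delay, first FLASH
#' block, delay, second FLASH block, delay -- into a single affine map
#' `Mz_end = a * Mz_start + b` acting on the longitudinal magnetization at the
#' start of the cycle. Because the inversion flips the magnetization, `a` is
#' negative whenever `inv_eff > 0`; `|a| < 1` always holds for positive `r1`,
#' which guarantees a unique steady state.
#'
#' @param protocol An [mp2rage_protocol()].
#' @param r1 Longitudinal relaxation rate(s), s^-1, positive. Vectorized.
#' @return A list with numeric vectors `a` (slope) and `b` (intercept),
#'   one element per `r1`.
#' @export
affine_cycle <- function(protocol, r1) {
  validate_protocol(protocol)
  .check_r1(r1)
  m <- .cycle_maps(protocol, r1)
  list(a = m$cycle$a, b = m$cycle$b)
}

#' Steady-state longitudinal magnetization of the MP2RAGE cycle
#'
#' Returns the unique fixed point `Mz* = b / (1 - a)` of the cycle map
#' from [affine_cycle()].
#'
#' @inheritParams affine_cycle
#' @return Numeric vector of steady-state `Mz` values (same units as `m0`).
#' @export
steady_state_mz <- function(protocol, r1) {
  cyc <- affine_cycle(protocol, r1)
  if (any(abs(cyc$a) >= 1)) {
    rlang::abort("Cycle map is not a contraction (|a| >= 1); no steady state.",
                 class = "r1lut_degenerate_error")
  }
  cyc$b / (1 - cyc$a)
}

#' Simulate the steady-state MP2RAGE signal pair
#'
#' Propagates the steady-state magnetization through the cycle and reads the
#' two gradient-echo signals at the k-space-centre excitation of each block
#' (excitation index `floor(n_exc/2)`, 0-based, linear encoding):
#' `s_i = sin(b1 * fa_i) * Mz` just before that excitation. Signals are
#' signed; `s1` is negative for long T1 at typical first inversion times.
#'
#' @inheritParams affine_cycle
#' @param b1 Optional B1+ scale factor(s) overriding `protocol$b1_scale`;
#'   recycled against `r1`. Applied to the excitation flip angles only.
#' @return A tibble with columns `r1`, `s1`, `s2`.
#' @examples
#' simulate_signals(protocol_lessbias(), c(0.25, 0.75, 1.25))
#' @export
simulate_signals <- function(protocol, r1, b1 = NULL) {
  validate_protocol(protocol)
  .check_r1(r1)
  if (is.null(b1)) b1 <- protocol$b1_scale
  if (!is.numeric(b1) || any(!is.finite(b1)) || any(b1 <= 0)) {
    rlang::abort("`b1` must be finite positive scale factor(s).",
                 class = "r1lut_input_error")
  }
  m <- .cycle_maps(protocol, r1, b1)
  if (any(abs(m$cycle$a) >= 1)) {
    rlang::abort("Cycle map is not a contraction (|a| >= 1); no steady state.",
                 class = "r1lut_degenerate_error")
  }
  mzss <- m$cycle$b / (1 - m$cycle$a)
  n <- length(mzss)
  tibble::tibble(
    r1 = rep_len(r1, n),
    s1 = m$sin1 * (m$pre1$a * mzss + m$pre1$b),
    s2 = m$sin2 * (m$pre2$a * mzss + m$pre2$b)
  )
}

#' Simulate signals over an R1 grid
#'
#' Validated vectorized wrapper around [simulate_signals()] for a strictly
#' increasing grid of relaxation rates.
#'
#' @inheritParams affine_cycle
#' @param r1_grid Strictly increasing vector of positive rates, s^-1.
#' @return A tibble with columns `r1`, `s1`, `s2`, one row per grid point.
#' @export
simulate_signal_grid <- function(protocol, r1_grid) {
  if (!is.numeric(r1_grid) || length(r1_grid) == 0) {
    rlang::abort("`r1_grid` must be a non-empty numeric vector.",
                 class = "r1lut_input_error")
  }
  if (length(r1_grid) > 1 && any(diff(r1_grid) <= 0)) {
    rlang::abort("`r1_grid` must be strictly increasing.",
                 class = "r1lut_input_error")
  }
  simulate_signals(protocol, r1_grid)
}
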