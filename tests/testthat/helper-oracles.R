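# Independent oracles used across the suite.
#
# event_simulate() walks the MP2RAGE cycle event by event (explicit per-pulse
# loop, relaxation written as m0 + (mz - m0)*exp(-t*r1)), deliberately NOT
# sharing code or algebra with the package's composed-affine implementation.

event_simulate <- function(protocol, r1, mz0, b1 = protocol$b1_scale) {
  p <- protocol
  kc <- floor(p$n_exc / 2)
  a1 <- b1 * p$fa1 * pi / 180
  a2 <- b1 * p$fa2 * pi / 180
  relax <- function(mz, t) p$m0 + (mz - p$m0) * exp(-t * r1)

  mz <- -p$inv_eff * mz0
  mz <- relax(mz, p$ti1 - kc * p$tr_flash)
  pre1 <- NA_real_
  for (i in seq_len(p$n_exc)) {
    if (i == kc + 1) pre1 <- mz
    mz <- relax(mz * cos(a1), p$tr_flash)
  }
  mz <- relax(mz, p$ti2 - p$ti1 - p$n_exc * p$tr_flash)
  pre2 <- NA_real_
  for (i in seq_len(p$n_exc)) {
    if (i == kc + 1) pre2 <- mz
    mz <- relax(mz * cos(a2), p$tr_flash)
  }
  mz <- relax(mz, p$tr_mp2rage - p$ti2 - (p$n_exc - kc) * p$tr_flash)
  list(mz_end = mz, s1 = sin(a1) * pre1, s2 = sin(a2) * pre2)
}

# slope/intercept of the cycle map, estimated from two event-simulated runs
# (an affine map is determined exactly by its values at 0 and 1)
oracle_affine <- function(protocol, r1, b1 = protocol$b1_scale) {
  b <- event_simulate(protocol, r1, 0, b1)$mz_end
  ab <- event_simulate(protocol, r1, 1, b1)$mz_end
  list(a = ab - b, b = b)
}

# steady-state signals by iterating the event simulation to convergence
oracle_signals <- function(protocol, r1, b1 = protocol$b1_scale,
                           n_cycles = 300) {
  mz <- protocol$m0
  for (k in seq_len(n_cycles)) {
    mz <- event_simulate(protocol, r1, mz, b1)$mz_end
  }
  event_simulate(protocol, r1, mz, b1)
}

# exhaustive R-side argmin, written term for term like the C++ search
brute_invert <- function(uni, dsr, table, weight) {
  d2 <- (weight * (uni - table$uni))^2 + (dsr - table$dsr)^2
  i <- which.min(d2)  # which.min takes the first (lowest) index on ties
  list(index = i, r1 = table$r1[i], distance = sqrt(d2[i]))
}

# random feasible protocol within the type invariants
draw_protocol <- function() {
  tr_flash <- stats::runif(1, 0.005, 0.009)
  n_exc <- 2L * sample(30:70, 1)
  kc <- n_exc / 2
  ti1 <- kc * tr_flash + stats::runif(1, 0.01, 0.4)
  ti2 <- ti1 + n_exc * tr_flash + stats::runif(1, 0.05, 0.8)
  tr <- ti2 + kc * tr_flash + stats::runif(1, 0.2, 1.5)
  mp2rage_protocol(tr, tr_flash, ti1, ti2,
                   fa1 = stats::runif(1, 1, 8), fa2 = stats::runif(1, 1, 8),
                   n_exc = n_exc, inv_eff = stats::runif(1, 0.85, 1),
                   b1_scale = stats::runif(1, 0.6, 1.4))
}

# small helper: (uni, dsr) of simulated signals at given rates
contrast_pair <- function(protocol, r1, b1 = NULL) {
  sig <- simulate_signals(protocol, r1, b1 = b1)
  list(uni = compute_uni(sig$s1, sig$s2),
       dsr = compute_dsr(abs(sig$s1), abs(sig$s2)))
}
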