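# Digital MP2RAGE phantom.
#
# Nested-ellipsoid geometry with three brain compartments (CSF shell, GM
# shell, WM core) over a noise-only background, a smooth low-order
# multiplicative B1+ field, and Rician magnitude noise from a complex
# Gaussian channel. Geometry is analytic so the ground truth is exact and
# generation is instant; anatomy, coil sensitivities and k-space effects are
# deliberately out of scope.

#' Specify a digital MP2RAGE phantom
#'
#' @param shape Integer vector of 3 voxel counts.
#' @param tissue_r1 Named rates (s^-1) for `csf`, `gm`, `wm`. The defaults
#'   (0.25 / 0.75 / 1.25) are package conventions placed inside the usual
#'   R1 window of interest, with GM inside the common display window
#'   0.65-0.85 s^-1; they are not literature tissue values.
#' @param semi_axes Named list of length-3 fractional semi-axes (of the half
#'   field of view) for the nested `csf`, `gm`, `wm` ellipsoids; must nest.
#' @param b1_center Centre value of the multiplicative B1+ field.
#' @param b1_amplitude Half-range of the field. The field is a low-order
#'   surface (linear gradient along the third axis plus a transverse
#'   quadratic term), normalized to span exactly
#'   `b1_center +/- b1_amplitude` and clipped to `[0.6, 1.4]`. The default
#'   0.4 reproduces the +/-40% transmit-field stress range.
#' @param noise_sigma Standard deviation of each complex Gaussian noise
#'   channel, relative to `m0`. Because the steady-state gradient-echo
#'   signals are only a few percent of `m0`, the default 0.0007 puts the
#'   phantom in the SNR regime of real 3 T acquisitions (SNR of about
#'   70-75 under the max-intensity / background-mean definition of
#'   [compute_snr()]).
#' @param seed Integer RNG seed; identical spec and seed give bit-identical
#'   phantoms.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         tissue_r1 = c(csf = 0.25, gm = 0.75, wm = 1.25),
                         semi_axes = list(csf = c(0.90, 0.88, 0.90),
                                          gm = c(0.76, 0.74, 0.76),
                                          wm = c(0.52, 0.50, 0.52)),
                         b1_center = 1,
                         b1_amplitude = 0.4,
                         noise_sigma = 0.0007,
                         seed = 1L) {
  fail <- function(field, msg) {
    rlang::abort(sprintf("Invalid phantom spec field `%s`: %s", field, msg),
                 class = "r1lut_input_error")
  }
  if (length(shape) != 3 || any(shape < 8) || any(shape != round(shape))) {
    fail("shape", "need 3 integer extents >= 8")
  }
  if (!all(c("csf", "gm", "wm") %in% names(tissue_r1))) {
    fail("tissue_r1", "need named rates for csf, gm, wm")
  }
  if (any(tissue_r1 <= 0.01) || any(tissue_r1 >= 20)) {
    fail("tissue_r1", "rates must lie within (0.01, 20) s^-1")
  }
  for (t in c("csf", "gm", "wm")) {
    ax <- semi_axes[[t]]
    if (is.null(ax) || length(ax) != 3 || any(ax <= 0) || any(ax > 1)) {
      fail("semi_axes", paste0("need 3 fractional semi-axes in (0, 1] for ", t))
    }
  }
  if (!all(semi_axes$wm < semi_axes$gm) || !all(semi_axes$gm < semi_axes$csf)) {
    fail("semi_axes", "shells must nest: wm < gm < csf")
  }
  if (noise_sigma < 0) fail("noise_sigma", "must be >= 0")
  if (b1_amplitude < 0) fail("b1_amplitude", "must be >= 0")
  structure(
    list(shape = as.integer(shape), tissue_r1 = tissue_r1,
         semi_axes = semi_axes, b1_center = b1_center,
         b1_amplitude = b1_amplitude, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# normalized voxel-centre coordinates in [-1, 1] per axis
.norm_coords <- function(shape) {
  lapply(shape, function(n) {
    if (n == 1) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  })
}

# label array: 0 background, 1 CSF, 2 GM, 3 WM (deterministic in the geometry)
.phantom_labels <- function(spec) {
  co <- .norm_coords(spec$shape)
  xs <- co[[1]]; ys <- co[[2]]; zs <- co[[3]]
  lab <- array(0L, dim = spec$shape)
  inside <- function(ax) {
    q <- outer(outer((xs / ax[1])^2, (ys / ax[2])^2, "+"), (zs / ax[3])^2, "+")
    q <= 1
  }
  lab[inside(spec$semi_axes$csf)] <- 1L
  lab[inside(spec$semi_axes$gm)] <- 2L
  lab[inside(spec$semi_axes$wm)] <- 3L
  lab
}

# smooth multiplicative B1+ field spanning b1_center +/- b1_amplitude,
# clipped to [0.6, 1.4]
.phantom_b1 <- function(spec) {
  co <- .norm_coords(spec$shape)
  xs <- co[[1]]; ys <- co[[2]]; zs <- co[[3]]
  u <- outer(outer(0.25 * xs^2, 0.25 * ys^2, "+"), zs, "+") - 0.125
  rng <- range(u)
  u <- if (diff(rng) > 0) 2 * (u - rng[1]) / diff(rng) - 1 else 0 * u
  b1 <- spec$b1_center + spec$b1_amplitude * u
  pmin(pmax(b1, 0.6), 1.4)
}

#' Generate a synthetic MP2RAGE acquisition
#'
#' Builds the labelled geometry, the ground-truth R1 and B1+ volumes, then
#' simulates the steady-state signal pair per voxel at the local B1+ scale
#' and corrupts it through a complex Gaussian channel:
#' `z_i = s_i + N(0, sigma) + 1i * N(0, sigma)`. Magnitudes `m1`, `m2` are
#' `|z_i|` (Rician), and the measured UNI is computed from the same noisy
#' complex pair as `Re(z1 * Conj(z2)) / (|z1|^2 + |z2|^2)`, so signal and
#' noise enter numerator and denominator consistently. Background voxels
#' carry noise only.
#'
#' @param spec A [phantom_spec()].
#' @param protocol An [mp2rage_protocol()].
#' @return An `mp2rage_phantom`: list of arrays `labels` (0 = background,
#'   1 = CSF, 2 = GM, 3 = WM), `r1_truth`, `b1_truth`, `m1`, `m2`, `uni`,
#'   plus the generating `spec` and `protocol`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16)),
#'                        protocol_lessbias())
#' table(ph$labels)
#' @export
generate_phantom <- function(spec, protocol) {
  if (!inherits(spec, "phantom_spec")) {
    rlang::abort("`spec` must be a `phantom_spec`.",
                 class = "r1lut_input_error")
  }
  validate_protocol(protocol)
  labels <- .phantom_labels(spec)
  b1 <- .phantom_b1(spec)
  r1 <- array(NA_real_, dim = spec$shape)
  r1[labels == 1L] <- spec$tissue_r1[["csf"]]
  r1[labels == 2L] <- spec$tissue_r1[["gm"]]
  r1[labels == 3L] <- spec$tissue_r1[["wm"]]

  s1 <- array(0, dim = spec$shape)
  s2 <- array(0, dim = spec$shape)
  fg <- which(labels > 0L)
  sig <- simulate_signals(protocol, r1[fg], b1 = b1[fg])
  s1[fg] <- sig$s1
  s2[fg] <- sig$s2

  n <- prod(spec$shape)
  withr::with_seed(spec$seed, {
    z1 <- complex(real = s1 + stats::rnorm(n, 0, spec$noise_sigma),
                  imaginary = stats::rnorm(n, 0, spec$noise_sigma))
    z2 <- complex(real = s2 + stats::rnorm(n, 0, spec$noise_sigma),
                  imaginary = stats::rnorm(n, 0, spec$noise_sigma))
  })
  if (spec$noise_sigma == 0) {
    z1 <- complex(real = s1, imaginary = 0)
    z2 <- complex(real = s2, imaginary = 0)
  }
  m1 <- array(Mod(z1), dim = spec$shape)
  m2 <- array(Mod(z2), dim = spec$shape)
  denom <- Mod(z1)^2 + Mod(z2)^2
  uni <- array(Re(z1 * Conj(z2)) / ifelse(denom == 0, NA_real_, denom),
               dim = spec$shape)
  structure(
    list(labels = labels, r1_truth = r1, b1_truth = b1,
         m1 = m1, m2 = m2, uni = uni, spec = spec, protocol = protocol),
    class = "mp2rage_phantom"
  )
}

#' @export
print.mp2rage_phantom <- function(x, ...) {
  cat(sprintf(
    "<mp2rage_phantom> %s voxels | noise sigma %.3g | seed %d\n",
    paste(x$spec$shape, collapse = "x"), x$spec$noise_sigma, x$spec$seed))
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "csf", "gm", "wm")))
  print(tab)
  invisible(x)
}

#' Generate replicate phantom acquisitions
#'
#' Replicates share the truth volumes (geometry, R1, B1+) and differ only in
#' their noise stream; replicate `i` is seeded `base_seed + i - 1`.
#'
#' @inheritParams generate_phantom
#' @param n Number of replicates (>= 1).
#' @param base_seed Seed of the first replicate (defaults to `spec$seed`).
#' @return A list of `n` `mp2rage_phantom` objects.
#' @export
make_replicates <- function(spec, protocol, n, base_seed = spec$seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer.",
                 class = "r1lut_input_error")
  }
  purrr::map(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(base_seed + i - 1)
    generate_phantom(sp, protocol)
  })
}

#' Write a phantom as a BIDS-flavoured NIfTI file set
#'
#' Writes `sub-phantom_inv-1_mag.nii.gz`, `sub-phantom_inv-2_mag.nii.gz` and
#' `sub-phantom_UNI.nii.gz` under `dir`, the truth volumes (labels, R1, B1)
#' under `dir/derivatives/`, and a JSON manifest recording spec, protocol and
#' seed.
#'
#' @param phantom An `mp2rage_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "mp2rage_phantom")) {
    rlang::abort("`phantom` must be an `mp2rage_phantom`.",
                 class = "r1lut_input_error")
  }
  dir.create(file.path(dir, "derivatives"), recursive = TRUE,
             showWarnings = FALSE)
  wv <- function(data, path) RNifti::writeNifti(RNifti::asNifti(data), path)
  wv(phantom$m1, file.path(dir, "sub-phantom_inv-1_mag.nii.gz"))
  wv(phantom$m2, file.path(dir, "sub-phantom_inv-2_mag.nii.gz"))
  wv(phantom$uni, file.path(dir, "sub-phantom_UNI.nii.gz"))
  wv(phantom$labels, file.path(dir, "derivatives", "sub-phantom_labels.nii.gz"))
  r1 <- phantom$r1_truth
  r1[is.na(r1)] <- 0
  wv(r1, file.path(dir, "derivatives", "sub-phantom_R1truth.nii.gz"))
  wv(phantom$b1_truth, file.path(dir, "derivatives", "sub-phantom_B1truth.nii.gz"))
  sp <- phantom$spec
  jsonlite::write_json(
    list(
      spec = list(shape = sp$shape, tissue_r1 = as.list(sp$tissue_r1),
                  semi_axes = sp$semi_axes, b1_center = sp$b1_center,
                  b1_amplitude = sp$b1_amplitude,
                  noise_sigma = sp$noise_sigma, seed = sp$seed),
      protocol = stats::setNames(phantom$protocol[.protocol_file_keys],
                                 names(.protocol_file_keys)),
      generator = paste0("r1lut ", utils::packageVersion("r1lut"))
    ),
    file.path(dir, "sub-phantom_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
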