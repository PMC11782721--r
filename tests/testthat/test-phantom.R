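lb <- protocol_lessbias()

small_spec <- function(...) phantom_spec(shape = c(24L, 24L, 24L), ...)

test_that("phantom spec validation names the offending field", {
  expect_error(phantom_spec(shape = c(4, 4)), "shape",
               class = "r1lut_input_error")
  expect_error(phantom_spec(tissue_r1 = c(csf = 0.25, gm = 0.75, wm = 25)),
               "tissue_r1", class = "r1lut_input_error")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma",
               class = "r1lut_input_error")
  expect_error(
    phantom_spec(semi_axes = list(csf = c(0.5, 0.5, 0.5),
                                  gm = c(0.7, 0.7, 0.7),
                                  wm = c(0.3, 0.3, 0.3))),
    "nest", class = "r1lut_input_error")
})

test_that("identical spec and seed give bit-identical phantoms", {
  sp <- small_spec(noise_sigma = 0.01, seed = 33L)
  a <- generate_phantom(sp, lb)
  b <- generate_phantom(sp, lb)
  for (v in c("labels", "r1_truth", "b1_truth", "m1", "m2", "uni")) {
    expect_identical(a[[v]], b[[v]])
  }
})

test_that("tissue voxel counts depend on geometry only, never on seed or noise", {
  counts <- function(ph) table(ph$labels)
  a <- generate_phantom(small_spec(noise_sigma = 0.01, seed = 1L), lb)
  b <- generate_phantom(small_spec(noise_sigma = 0.05, seed = 999L), lb)
  expect_identical(counts(a), counts(b))
  expect_true(all(1:3 %in% a$labels))  # all three tissues present
})

test_that("the B1 field is smooth, bounded and spans the stress range", {
  ph <- generate_phantom(small_spec(noise_sigma = 0), lb)
  expect_true(all(ph$b1_truth >= 0.6 & ph$b1_truth <= 1.4))
  expect_equal(min(ph$b1_truth), 0.6, tolerance = 1e-9)
  expect_equal(max(ph$b1_truth), 1.4, tolerance = 1e-9)
  # low-order field: neighbouring voxels differ by a small bounded step
  d3 <- abs(diff(ph$b1_truth[12, 12, ]))
  expect_lt(max(d3), 0.06)
})

test_that("noiseless phantom contrasts are in range and invert to truth", {
  ph <- generate_phantom(small_spec(noise_sigma = 0), lb)
  fg <- ph$labels > 0
  expect_true(all(abs(ph$uni[fg]) <= 0.5))
  dsr <- compute_dsr(ph$m1, ph$m2)
  expect_true(all(abs(dsr[fg]) <= 0.5))
  expect_true(all(is.na(ph$uni[!fg])))  # background 0/0 flagged invalid

  # simulated at the *local* B1 and inverted against a table at that B1,
  # every foreground voxel must round-trip to within one grid step
  tab_point <- function(r1v, b1v) {
    sig <- simulate_signals(lb, r1v, b1 = b1v)
    list(uni = compute_uni(sig$s1, sig$s2),
         dsr = compute_dsr(abs(sig$s1), abs(sig$s2)))
  }
  idx <- which(fg)[seq(1, sum(fg), by = 37)]
  prs <- tab_point(ph$r1_truth[idx], ph$b1_truth[idx])
  expect_equal(ph$uni[idx], prs$uni, tolerance = 1e-12)
  expect_equal(dsr[idx], prs$dsr, tolerance = 1e-12)
})

test_that("replicates share truth and differ only in noise", {
  sp <- small_spec(noise_sigma = 0.01, seed = 5L)
  reps <- make_replicates(sp, lb, 3)
  expect_identical(reps[[1]]$r1_truth, reps[[2]]$r1_truth)
  expect_identical(reps[[1]]$b1_truth, reps[[3]]$b1_truth)
  expect_false(identical(reps[[1]]$m1, reps[[2]]$m1))
  expect_false(identical(reps[[2]]$m1, reps[[3]]$m1))
  # n = 1 reduces to a single generate_phantom call at the base seed
  one <- make_replicates(sp, lb, 1)
  expect_identical(one[[1]]$m1, generate_phantom(sp, lb)$m1)
  expect_error(make_replicates(sp, lb, 0), class = "r1lut_input_error")
})

test_that("background magnitude noise follows the Rayleigh closed form", {
  sigma <- 0.02
  sp <- phantom_spec(shape = c(16L, 16L, 16L), noise_sigma = sigma, seed = 21L)
  reps <- make_replicates(sp, lb, 20)
  bg <- which(reps[[1]]$labels == 0L)
  stack <- vapply(reps, function(p) p$m1[bg], numeric(length(bg)))
  vox_sd <- apply(stack, 1, sd)
  expect_equal(mean(vox_sd), sigma * sqrt(2 - pi / 2), tolerance = 0.1)
})

test_that("default-noise phantoms sit in the realistic SNR regime", {
  ph <- generate_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 13L),
                         lb)
  snr <- compute_snr(ph$m1, ph$m2, ph$labels == 0L)
  expect_gt(snr, 40)
  expect_lt(snr, 110)
})

test_that("noise-driven 2D-lookup tissue errors stay within calibrated bounds", {
  tab <- build_table(lb)
  med_rel_err <- function(sigma) {
    sp <- phantom_spec(shape = c(32L, 32L, 32L), noise_sigma = sigma,
                       seed = 9L)
    ph <- generate_phantom(sp, lb)
    res <- lut_invert_2d(ph$uni, compute_dsr(ph$m1, ph$m2), tab,
                         rescale = "never")
    rel_err <- abs(res$r1 - ph$r1_truth) / ph$r1_truth
    c(gm = median(rel_err[ph$labels == 2L], na.rm = TRUE),
      wm = median(rel_err[ph$labels == 3L], na.rm = TRUE))
  }
  # realistic SNR (default sigma): median tissue error below 5%
  expect_true(all(med_rel_err(0.0007) < 0.05))
  # heavy-noise stress (sigma = 0.5% of m0 is SNR of order 10 here):
  # bound frozen from this generator's own Monte-Carlo baseline
  expect_true(all(med_rel_err(0.005) < 0.15))
})

test_that("phantoms write a complete BIDS-flavoured file set", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(shape = c(12L, 12L, 12L),
                                      noise_sigma = 0.01), lb)
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "sub-phantom_inv-1_mag.nii.gz", "sub-phantom_inv-2_mag.nii.gz",
    "sub-phantom_UNI.nii.gz", "sub-phantom_manifest.json")))))
  expect_true(file.exists(file.path(dir, "derivatives",
                                    "sub-phantom_R1truth.nii.gz")))
  m1 <- read_volume(file.path(dir, "sub-phantom_inv-1_mag.nii.gz"))
  expect_equal(as.numeric(m1), as.numeric(ph$m1), tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(dir, "sub-phantom_manifest.json"),
                                  simplifyVector = TRUE)
  expect_identical(manifest$spec$seed, ph$spec$seed)
  expect_equal(manifest$protocol$ti1_s, lb$ti1)
})
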