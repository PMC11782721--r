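lb_tab <- build_table(protocol_lessbias())     # full default grid
std_tab <- build_table(protocol_standard())

# hand-built table for contract tests
toy_table <- function(uni, dsr = rep(0, length(uni)),
                      r1 = seq_along(uni) / 10) {
  r1lut:::new_transfer_table(
    tibble::tibble(r1 = r1, uni = uni, dsr = dsr),
    protocol = protocol_lessbias()
  )
}

test_that("table construction honours the grid contract", {
  expect_identical(nrow(lb_tab), 19991L)
  expect_equal(lb_tab$r1[1], 0.01)
  expect_equal(lb_tab$r1[2] - lb_tab$r1[1], 0.001)
  expect_true(all(lb_tab$uni >= -0.5 & lb_tab$uni <= 0.5))
  expect_true(all(lb_tab$dsr >= -0.5 & lb_tab$dsr <= 0.5))

  single <- build_table(protocol_lessbias(), 0.7, 0.7005, 0.001)
  expect_identical(nrow(single), 1L)
  sig <- simulate_signals(protocol_lessbias(), 0.7)
  expect_identical(single$uni, compute_uni(sig$s1, sig$s2))
  expect_identical(single$dsr, compute_dsr(abs(sig$s1), abs(sig$s2)))

  expect_error(build_table(protocol_lessbias(), 2, 1, 0.01),
               class = "r1lut_input_error")
})

test_that("transfer tables round-trip losslessly through CSV + sidecar", {
  tab <- build_table(protocol_lessbias(), 0.2, 1, 0.01)
  f <- withr::local_tempfile(fileext = ".csv")
  write_transfer_table(tab, f)
  hdr <- readLines(f, n = 1)
  expect_identical(hdr, "r1_s-1,uni,dsr")
  back <- read_transfer_table(f)
  expect_true(max(abs(back$r1 - tab$r1)) < 1e-12)
  expect_true(max(abs(back$uni - tab$uni)) < 1e-12)
  expect_true(max(abs(back$dsr - tab$dsr)) < 1e-12)
  expect_equal(unclass(attr(back, "protocol")),
               unclass(attr(tab, "protocol")), tolerance = 1e-12)
})

test_that("1D inversion is the identity on a monotone table's own references", {
  sub <- build_table(protocol_standard(), 0.5, 3, 0.01)
  expect_true(all(diff(sub$uni) > 0) || all(diff(sub$uni) < 0))
  res <- lut_invert_1d(sub$uni, sub)
  expect_identical(res$r1, sub$r1)
  expect_true(all(res$distance == 0))
  expect_identical(sum(res$truncated), 2L)  # exactly the two end points
})

test_that("1D ties resolve to the lowest grid index", {
  tab <- toy_table(uni = c(0.1, 0.2, 0.2, 0.4))
  # exact duplicate: both rows at distance 0, lowest index wins
  expect_equal(lut_invert_1d(0.2, tab)$r1, tab$r1[2])
  # midway between two references: lower index wins
  expect_equal(lut_invert_1d(0.15, tab)$r1, tab$r1[1])
  expect_equal(lut_invert_1d(0.3, tab)$r1, tab$r1[2])
})

test_that("1D inversion collapses fold-ambiguous UNI values to the lower branch", {
  fold <- find_folds(lb_tab)$folds[1]
  below <- which(lb_tab$r1 < fold - 0.002 & lb_tab$r1 > 0.2)
  above <- which(lb_tab$r1 > fold + 0.002 & lb_tab$r1 < 5)
  # find a sub-fold reference whose UNI is nearly attained on the upper branch
  gap <- vapply(below, function(i) min(abs(lb_tab$uni[i] - lb_tab$uni[above])),
                numeric(1))
  i <- below[which.min(gap)]
  expect_lt(min(gap), 1e-6)  # >= 2 grid entries within eps of this UNI value
  res <- lut_invert_1d(lb_tab$uni[i], lb_tab)
  expect_identical(res$r1, lb_tab$r1[i])  # exact match on the lower branch
  expect_lt(res$r1, fold)
})

test_that("2D inversion recovers exact table rows with zero distance", {
  withr::with_seed(5, {
    ks <- sample(nrow(lb_tab), 25)
    res <- lut_invert_2d(lb_tab$uni[ks], lb_tab$dsr[ks], lb_tab)
    expect_identical(res$r1, lb_tab$r1[ks])
    expect_true(all(res$distance == 0))
  })
})

test_that("noiseless forward simulation inverts to within one grid step", {
  pr <- contrast_pair(protocol_lessbias(), 0.7)
  res <- lut_invert_2d(pr$uni, pr$dsr, lb_tab)
  expect_lt(abs(res$r1 - 0.7), 0.001 + 1e-12)

  withr::with_seed(6, {
    r1s <- runif(200, 0.2, 5)
    for (p in list(protocol_lessbias(), protocol_standard())) {
      tab <- if (identical(p$ti1, 0.5)) lb_tab else std_tab
      pr <- contrast_pair(p, r1s)
      res <- lut_invert_2d(pr$uni, pr$dsr, tab)
      expect_lt(max(abs(res$r1 - r1s)), 0.001 + 1e-12)
    }
  })
})

test_that("DSR disambiguates UNI values shared across the fold", {
  fold <- find_folds(lb_tab)$folds[1]
  below <- which(lb_tab$r1 < fold - 0.002 & lb_tab$r1 > 0.2)
  above <- which(lb_tab$r1 > fold + 0.002 & lb_tab$r1 < 5)
  pairs <- expand.grid(i = below, j = above)
  pairs$duni <- abs(lb_tab$uni[pairs$i] - lb_tab$uni[pairs$j])
  best <- pairs[which.min(pairs$duni), ]
  expect_lt(best$duni, 1e-4)
  res <- lut_invert_2d(lb_tab$uni[c(best$i, best$j)],
                       lb_tab$dsr[c(best$i, best$j)], lb_tab)
  expect_lt(res$r1[1], fold)
  expect_gt(res$r1[2], fold)
  expect_identical(res$r1, lb_tab$r1[c(best$i, best$j)])
})

test_that("accelerated lookup equals the exhaustive argmin exactly", {
  withr::with_seed(8, {
    n <- 1000
    uni <- runif(n, -0.5, 0.5)
    dsr <- runif(n, -0.5, 0.5)
    res <- lut_invert_2d(uni, dsr, lb_tab, weight = 100)
    for (k in seq_len(n)) {
      bf <- brute_invert(uni[k], dsr[k], lb_tab, weight = 100)
      if (bf$r1 != res$r1[k]) {
        fail(sprintf("argmin mismatch at voxel %d: %g vs %g",
                     k, res$r1[k], bf$r1))
      }
    }
    succeed()
  })
})

test_that("invalid voxels propagate as NA without aborting volumes", {
  uni <- c(0.1, NA, 0.3)
  dsr <- c(0, 0.1, NA)
  res <- lut_invert_2d(uni, dsr, lb_tab)
  expect_identical(res$invalid, c(FALSE, TRUE, TRUE))
  expect_identical(is.na(res$r1), c(FALSE, TRUE, TRUE))
  expect_error(lut_invert_2d(c(0.1, 0.2), 0.1, lb_tab),
               class = "r1lut_input_error")
  expect_error(lut_invert_2d(0.1, 0.1, lb_tab, weight = -1),
               class = "r1lut_input_error")
})

test_that("large UNI weights degenerate the 2D lookup to the 1D lookup", {
  sub <- build_table(protocol_standard(), 0.5, 3, 0.005)  # bijective window
  withr::with_seed(9, {
    uni <- runif(200, min(sub$uni), max(sub$uni))
    dsr <- runif(200, -0.5, 0.5)
    r2d <- lut_invert_2d(uni, dsr, sub, weight = 1e9)
    r1d <- lut_invert_1d(uni, sub)
    expect_identical(r2d$r1, r1d$r1)
  })
})

test_that("fold detection is exact on synthetic curves and honest on real ones", {
  mono <- toy_table(uni = seq(-0.4, 0.4, length.out = 50),
                    r1 = seq(0.1, 6, length.out = 50))
  fr <- find_folds(mono, window = c(0.2, 5))
  expect_true(fr$bijective)
  expect_length(fr$folds, 0)

  # single triangular fold, vertex exactly at a grid point
  vee <- toy_table(uni = c(seq(0.4, 0, by = -0.05), seq(0.05, 0.4, by = 0.05)),
                   r1 = seq(0.5, 2.1, by = 0.1))
  fr <- find_folds(vee, window = c(0.5, 2.1))
  expect_length(fr$folds, 1)
  expect_equal(fr$folds, 1.3, tolerance = 0.05)

  # LessBias: one fold in the window, at the R1 where s1 = -s2
  fr <- find_folds(lb_tab)
  expect_length(fr$folds, 1)
  root <- uniroot(function(r) {
    s <- simulate_signals(protocol_lessbias(), r)
    s$s1 + s$s2
  }, c(0.3, 0.6))$root
  expect_equal(fr$folds[1], root, tolerance = 0.002)

  # Standard: the curve touches -0.5 just above 0.2 s^-1 (a shallow fold),
  # again exactly where s1 = -s2
  fr_std <- find_folds(std_tab)
  root_std <- uniroot(function(r) {
    s <- simulate_signals(protocol_standard(), r)
    s$s1 + s$s2
  }, c(0.15, 0.3))$root
  expect_length(fr_std$folds, 1)
  expect_equal(fr_std$folds[1], root_std, tolerance = 0.002)

  expect_error(find_folds(lb_tab, window = c(0.001, 5)),
               class = "r1lut_input_error")
})

test_that("B1-informed 1D inversion uses the local transmit scale", {
  grid <- list(r1_min = 0.2, r1_max = 5, dr1 = 0.005)
  # b1 = 1 everywhere reduces to the nominal 1D inversion
  withr::with_seed(10, uni <- runif(50, -0.45, 0.45))
  nominal <- build_table(protocol_standard(), grid$r1_min, grid$r1_max,
                         grid$dr1)
  fam <- c(0.6, 0.8, 1, 1.2, 1.4)
  res_b1 <- lut_invert_1d_b1(uni, rep(1, 50), protocol_standard(),
                             grid$r1_min, grid$r1_max, grid$dr1,
                             b1_family = fam)
  res_1d <- lut_invert_1d(uni, nominal)
  expect_identical(res_b1$r1, res_1d$r1)

  # data simulated at b1 = 0.8 with the true map: round trip within one step
  r1s <- seq(0.6, 2.5, by = 0.1)
  pr <- contrast_pair(protocol_standard(), r1s, b1 = 0.8)
  res <- lut_invert_1d_b1(pr$uni, rep(0.8, length(r1s)), protocol_standard(),
                          grid$r1_min, grid$r1_max, grid$dr1,
                          b1_family = fam)
  expect_lt(max(abs(res$r1 - r1s)), grid$dr1 + 1e-12)

  # a wrong (all-nominal) map degenerates to the plain biased 1D estimate
  pr6 <- contrast_pair(protocol_standard(), r1s, b1 = 0.6)
  res_wrong <- lut_invert_1d_b1(pr6$uni, rep(1, length(r1s)),
                                protocol_standard(),
                                grid$r1_min, grid$r1_max, grid$dr1,
                                b1_family = fam)
  plain <- lut_invert_1d(pr6$uni, nominal)
  expect_identical(res_wrong$r1, plain$r1)

  # out-of-family values are clamped with a warning and flagged
  expect_warning(
    res_cl <- lut_invert_1d_b1(pr$uni[1:2], c(0.3, 1), protocol_standard(),
                               grid$r1_min, grid$r1_max, grid$dr1,
                               b1_family = fam),
    "clamped")
  expect_identical(res_cl$b1_clamped, c(TRUE, FALSE))
})
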