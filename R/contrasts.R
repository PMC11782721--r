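# UNI and DSR contrasts.
#
# UNI combines the two gradient-echo images voxel by voxel into a unified,
# M0/T2*/B1(-)-insensitive image bounded in [-0.5, 0.5]. DSR, the
# difference-sum-ratio of the two magnitudes, shares the bound and the
# nuisance cancellation but peaks where UNI is flat and vice versa, which is
# what makes the pair suitable for disambiguating non-bijective UNI curves.

.both_zero_guard <- function(bad, what) {
  if (any(bad, na.rm = TRUE)) {
    if (length(bad) == 1) {
      rlang::abort(paste0(what, " is undefined when both inputs are zero."),
                   class = "r1lut_domain_error")
    }
  }
}

#' Unified MP2RAGE contrast (UNI)
#'
#' Computes `uni = s1 * s2 / (s1^2 + s2^2)` from the signed gradient-echo
#' signals (the real part of the conjugate product for real-valued signals).
#' The result is bounded in `[-0.5, 0.5]` and equals exactly +0.5 or -0.5 when
#' `s1 = s2` or `s1 = -s2` (nonzero). Multiplicative factors common to both
#' signals cancel.
#'
#' For a length-1 input with `s1 = s2 = 0` a domain error is raised; on longer
#' inputs such voxels yield `NA`, to be carried as an invalid-voxel flag by
#' volume-level callers.
#'
#' @param s1,s2 Signed signal amplitudes (numeric, recycled to common length;
#'   arrays keep their dimensions).
#' @return UNI values in `[-0.5, 0.5]` (`NA` where both inputs are zero).
#' @examples
#' compute_uni(0.3, 0.3)   # +0.5
#' compute_uni(-0.2, 0.2)  # -0.5
#' compute_uni(3, 1)       # 0.3
#' @export
compute_uni <- function(s1, s2) {
  denom <- s1^2 + s2^2
  bad <- denom == 0
  .both_zero_guard(bad & !is.na(bad), "UNI")
  out <- s1 * s2 / denom
  out[bad] <- NA_real_
  out
}

#' Difference-sum-ratio contrast (DSR)
#'
#' Computes `dsr = (m1 - m2) / (2 * (m1 + m2))` from the two gradient-echo
#' magnitudes. The factor 2 in the denominator puts DSR on the same
#' `[-0.5, 0.5]` scale as UNI. DSR equals +0.5 iff `m2 = 0`, -0.5 iff
#' `m1 = 0`, and 0 where the magnitudes are equal -- the extremes occur
#' exactly where UNI is uninformative, which is why the pair disambiguates.
#'
#' @param m1,m2 Non-negative magnitudes (recycled; arrays keep dimensions).
#' @return DSR values in `[-0.5, 0.5]` (`NA` where both inputs are zero).
#' @examples
#' compute_dsr(1, 0)     # +0.5
#' compute_dsr(0.7, 0.7) # 0
#' compute_dsr(1, 3)     # -0.25
#' @export
compute_dsr <- function(m1, m2) {
  if (any(m1 < 0, na.rm = TRUE) || any(m2 < 0, na.rm = TRUE)) {
    rlang::abort("DSR inputs are magnitudes and must be non-negative.",
                 class = "r1lut_input_error")
  }
  s <- m1 + m2
  bad <- s == 0
  .both_zero_guard(bad & !is.na(bad), "DSR")
  out <- (m1 - m2) / (2 * s)
  out[bad] <- NA_real_
  out
}

#' Signal-to-noise ratio of an MP2RAGE acquisition
#'
#' SNR is defined as the maximum intensity across both gradient-echo
#' magnitude images divided by the mean intensity of the first magnitude
#' image within a background mask.
#'
#' @param m1,m2 Magnitude volumes/arrays of identical shape.
#' @param background_mask Logical array of the same shape selecting
#'   noise-only voxels.
#' @return A positive scalar.
#' @export
compute_snr <- function(m1, m2, background_mask) {
  if (!identical(dim2(m1), dim2(m2)) ||
      !identical(dim2(m1), dim2(background_mask))) {
    rlang::abort("`m1`, `m2` and `background_mask` must share a shape.",
                 class = "r1lut_input_error")
  }
  mask <- as.logical(background_mask)
  if (!any(mask, na.rm = TRUE)) {
    rlang::abort("Background mask selects no voxels.",
                 class = "r1lut_computation_error")
  }
  bg_mean <- mean(m1[which(mask)], na.rm = TRUE)
  if (!is.finite(bg_mean) || bg_mean <= 0) {
    rlang::abort("Background mean of |I1| is zero or undefined.",
                 class = "r1lut_computation_error")
  }
  max(c(m1, m2), na.rm = TRUE) / bg_mean
}

# dim() that treats plain vectors as 1-d shapes
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Detect and undo scanner-style integer UNI storage
#'
#' Vendors commonly store the UNI image as integers in `[0, 4095]`.
#' `looks_like_scanner_uni()` reports whether a volume matches that dialect
#' (integer-valued, within `[0, 4095]`, exceeding the native `[-0.5, 0.5]`
#' range); `rescale_scanner_uni()` maps such values to the native scale via
#' `x / 4095 - 0.5`.
#'
#' @param x Numeric vector or array of UNI values.
#' @return `looks_like_scanner_uni()`: a logical scalar.
#'   `rescale_scanner_uni()`: `x` rescaled to `[-0.5, 0.5]`.
#' @export
looks_like_scanner_uni <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) == 0) return(FALSE)
  all(v >= 0) && all(v <= 4095) && max(v) > 0.5 &&
    all(abs(v - round(v)) < 1e-8)
}

#' @rdname looks_like_scanner_uni
#' @export
rescale_scanner_uni <- function(x) {
  x / 4095 - 0.5
}

# Apply the scanner-UNI dialect according to a user policy; messages once.
.apply_uni_dialect <- function(uni, rescale = c("auto", "never", "always")) {
  rescale <- match.arg(rescale)
  do_it <- switch(rescale,
                  auto = looks_like_scanner_uni(uni),
                  never = FALSE,
                  always = TRUE)
  if (do_it) {
    message("UNI volume matches the scanner integer dialect [0, 4095]; ",
            "rescaling to [-0.5, 0.5] (use rescale = \"never\" to override).")
    uni <- rescale_scanner_uni(uni)
  }
  uni
}
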