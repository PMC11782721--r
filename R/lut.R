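# Transfer tables and lookup-table inversion.
#
# A transfer table samples the forward signal model on an equidistant R1 grid
# and stores the (UNI, DSR) reference pair of every grid point. Inversion is
# exact nearest-reference search: 1D on UNI alone (the classic procedure,
# valid only for bijective curves) or 2D on the weighted (UNI, DSR) pair,
# which resolves folds. Equidistant R1 spacing (rather than equidistant T1)
# concentrates resolution in the white-matter/gray-matter range.

#' Build a transfer table
#'
#' Simulates the steady-state signal pair on the grid
#' `seq(r1_min, r1_max, by = dr1)` and stores the UNI reference (from the
#' signed signals) and the DSR reference (from their magnitudes) per grid
#' point. The default grid (0.01 to 20 s^-1, step 0.001 s^-1, 19,991 rows)
#' is wide enough to avoid truncation effects in brain tissue.
#'
#' @param protocol An [mp2rage_protocol()]; its `b1_scale` is baked into the
#'   table.
#' @param r1_min,r1_max,dr1 Grid bounds and step, s^-1.
#' @return A `transfer_table`: a tibble with columns `r1`, `uni`, `dsr` and
#'   the generating protocol attached as an attribute.
#' @examples
#' tab <- build_table(protocol_lessbias(), 0.2, 5, 0.01)
#' tab
#' @export
build_table <- function(protocol, r1_min = 0.01, r1_max = 20, dr1 = 0.001) {
  if (!(is.numeric(r1_min) && is.numeric(r1_max) && is.numeric(dr1) &&
        r1_min > 0 && r1_max > r1_min && dr1 > 0)) {
    rlang::abort("Require 0 < r1_min < r1_max and dr1 > 0.",
                 class = "r1lut_input_error")
  }
  grid <- seq(r1_min, r1_max, by = dr1)
  sig <- simulate_signal_grid(protocol, grid)
  new_transfer_table(
    tibble::tibble(
      r1 = grid,
      uni = compute_uni(sig$s1, sig$s2),
      dsr = compute_dsr(abs(sig$s1), abs(sig$s2))
    ),
    protocol = protocol
  )
}

new_transfer_table <- function(df, protocol) {
  structure(
    df,
    protocol = protocol,
    class = c("transfer_table", class(tibble::tibble()))
  )
}

#' @export
print.transfer_table <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf(
    "<transfer_table> %d rows, R1 %.4g..%.4g s^-1, b1_scale %.3g\n",
    nrow(x), min(x$r1), max(x$r1), p$b1_scale))
  NextMethod()
}

.check_table <- function(table) {
  if (!inherits(table, "transfer_table") ||
      !all(c("r1", "uni", "dsr") %in% names(table))) {
    rlang::abort("`table` must be a `transfer_table` (see build_table()).",
                 class = "r1lut_input_error")
  }
}

# Shared finishing step for inversion results.
.finish_mapping <- function(res, shape, n_ref, grid, method, weight = NA_real_) {
  idx <- res$index
  invalid <- is.na(idx)
  r1 <- rep(NA_real_, length(idx))
  r1[!invalid] <- grid[idx[!invalid]]
  truncated <- !invalid & (idx == 1L | idx == n_ref)
  shape_it <- function(v) {
    if (length(shape) > 1) array(v, dim = shape) else v
  }
  structure(
    list(
      r1 = shape_it(r1),
      distance = shape_it(res$distance),
      truncated = shape_it(truncated),
      invalid = shape_it(invalid),
      method = method,
      weight = weight,
      grid_range = range(grid),
      n_ref = n_ref
    ),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf(
    "<mapping_result> method %s | %d voxels | %d invalid | %d truncated\n",
    x$method, length(x$r1), sum(x$invalid), sum(x$truncated, na.rm = TRUE)))
  cat(sprintf("  R1 grid [%.4g, %.4g] s^-1; median R1 %.4g s^-1\n",
              x$grid_range[1], x$grid_range[2],
              stats::median(x$r1, na.rm = TRUE)))
  invisible(x)
}

#' Invert a UNI volume to R1 with a 1D lookup
#'
#' Per voxel, returns the grid R1 whose reference UNI is nearest to the
#' measured UNI (`argmin |uni - uni_ref|`). Ties resolve to the lowest grid
#' index. This is the classic procedure; on a non-bijective transfer curve
#' distinct R1 values share a UNI value and the result silently collapses to
#' the lower branch -- use [lut_invert_2d()] there.
#'
#' @param uni Numeric vector or array of UNI values (native `[-0.5, 0.5]`
#'   scale; the scanner integer dialect is rescaled according to `rescale`).
#' @param table A `transfer_table`.
#' @param rescale Scanner-UNI dialect policy: `"auto"` (default), `"never"`,
#'   `"always"`. See [looks_like_scanner_uni()].
#' @return A `mapping_result`: list with `r1`, `distance`, `truncated` and
#'   `invalid` components shaped like `uni`.
#' @export
lut_invert_1d <- function(uni, table, rescale = "auto") {
  .check_table(table)
  shape <- dim2(uni)
  uni <- .apply_uni_dialect(as.numeric(uni), rescale)
  res <- nearest_ref_cpp(uni, rep(0, length(uni)),
                         table$uni, rep(0, nrow(table)), 1.0)
  .finish_mapping(res, shape, nrow(table), table$r1, method = "1d")
}

#' Invert (UNI, DSR) volumes to R1 with a weighted 2D lookup
#'
#' Per voxel, returns the grid R1 minimizing the Euclidean distance
#' `sqrt((weight * (uni - uni_ref))^2 + (dsr - dsr_ref)^2)`; the weight
#' multiplies the measured and reference UNI equally, so a large weight makes
#' UNI drive the estimate while DSR disambiguates between fold branches. The
#' default 100:1 weighting keeps the estimate UNI-driven, mirroring the 1D
#' procedure wherever the curve is bijective. Ties resolve to the lowest grid
#' index; boundary matches are flagged as truncated, not clamped silently.
#'
#' @inheritParams lut_invert_1d
#' @param dsr Numeric vector or array of DSR values, same shape as `uni`.
#' @param weight Positive UNI:DSR weight ratio (default 100).
#' @return A `mapping_result` (see [lut_invert_1d()]).
#' @examples
#' tab <- build_table(protocol_lessbias(), 0.2, 5, 0.01)
#' sig <- simulate_signals(protocol_lessbias(), 0.7)
#' m <- lut_invert_2d(compute_uni(sig$s1, sig$s2),
#'                    compute_dsr(abs(sig$s1), abs(sig$s2)), tab)
#' m$r1
#' @export
lut_invert_2d <- function(uni, dsr, table, weight = 100, rescale = "auto") {
  .check_table(table)
  if (!identical(dim2(uni), dim2(dsr))) {
    rlang::abort("`uni` and `dsr` must have identical shapes.",
                 class = "r1lut_input_error")
  }
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) ||
      weight <= 0) {
    rlang::abort("`weight` must be a positive scalar.",
                 class = "r1lut_input_error")
  }
  shape <- dim2(uni)
  uni <- .apply_uni_dialect(as.numeric(uni), rescale)
  res <- nearest_ref_cpp(uni, as.numeric(dsr), table$uni, table$dsr, weight)
  .finish_mapping(res, shape, nrow(table), table$r1, method = "2d",
                  weight = weight)
}

#' B1-informed 1D lookup inversion
#'
#' Comparator for the 2D lookup: uses a measured B1+ map to pick, per voxel,
#' a 1D transfer table built at that voxel's transmit scale. Tables are
#' precomputed over the family `b1_family` and each voxel snaps to the
#' nearest family member; voxels outside the family range are clamped to the
#' nearest end with a warning and flagged.
#'
#' @inheritParams lut_invert_1d
#' @param b1 Positive B1+ scale map, same shape as `uni`.
#' @param protocol An [mp2rage_protocol()] (nominal; its `b1_scale` is
#'   replaced by each family member).
#' @param r1_min,r1_max,dr1 Grid parameters passed to [build_table()].
#' @param b1_family B1 scales at which tables are precomputed.
#' @return A `mapping_result` with an extra logical component `b1_clamped`.
#' @export
lut_invert_1d_b1 <- function(uni, b1, protocol,
                             r1_min = 0.01, r1_max = 20, dr1 = 0.001,
                             b1_family = seq(0.5, 1.5, by = 0.05),
                             rescale = "auto") {
  if (!identical(dim2(uni), dim2(b1))) {
    rlang::abort("`uni` and `b1` must have identical shapes.",
                 class = "r1lut_input_error")
  }
  if (any(b1 <= 0, na.rm = TRUE)) {
    rlang::abort("`b1` must be positive.", class = "r1lut_input_error")
  }
  shape <- dim2(uni)
  uni <- .apply_uni_dialect(as.numeric(uni), rescale)
  b1v <- as.numeric(b1)
  clamped <- !is.na(b1v) & (b1v < min(b1_family) | b1v > max(b1_family))
  if (any(clamped)) {
    warning(sprintf(
      "%d voxel(s) have B1 outside [%.3g, %.3g]; clamped to the family range.",
      sum(clamped), min(b1_family), max(b1_family)))
  }
  fam_idx <- vapply(b1v, function(b) {
    if (is.na(b)) NA_integer_ else which.min(abs(b1_family - b))
  }, integer(1))

  grid <- seq(r1_min, r1_max, by = dr1)
  n <- length(uni)
  idx <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  for (k in sort(unique(fam_idx[!is.na(fam_idx)]))) {
    sel <- which(!is.na(fam_idx) & fam_idx == k)
    p <- protocol
    p$b1_scale <- b1_family[k]
    tab <- build_table(p, r1_min, r1_max, dr1)
    res <- nearest_ref_cpp(uni[sel], rep(0, length(sel)),
                           tab$uni, rep(0, nrow(tab)), 1.0)
    idx[sel] <- res$index
    dist[sel] <- res$distance
  }
  out <- .finish_mapping(list(index = idx, distance = dist), shape,
                         length(grid), grid, method = "1d-b1")
  out$b1_clamped <- if (length(shape) > 1) array(clamped, dim = shape) else clamped
  out
}

#' Locate folds of a transfer curve
#'
#' A fold is a local extremum of the UNI transfer curve -- the point where
#' `I1 = +/-I2` and the UNI-to-R1 mapping stops being injective. Folds are
#' detected as sign changes of the first difference of the UNI reference
#' inside `window`, and each location is refined by three-point parabolic
#' interpolation (reported to 0.001 s^-1). The table is bijective over the
#' window iff no fold is found.
#'
#' @param table A `transfer_table`.
#' @param window Length-2 numeric, the open R1 window of interest in s^-1
#'   (default `c(0.2, 5)`).
#' @return A `fold_report`: list with `folds` (refined R1 locations, s^-1),
#'   `bijective` (logical) and `window`.
#' @examples
#' find_folds(build_table(protocol_lessbias(), 0.2, 5, 0.005))
#' @export
find_folds <- function(table, window = c(0.2, 5)) {
  .check_table(table)
  if (!(is.numeric(window) && length(window) == 2 && window[1] < window[2])) {
    rlang::abort("`window` must be c(lo, hi) with lo < hi.",
                 class = "r1lut_input_error")
  }
  if (window[1] < min(table$r1) || window[2] > max(table$r1)) {
    rlang::abort("`window` must lie within the table's R1 grid.",
                 class = "r1lut_input_error")
  }
  r1 <- table$r1
  u <- table$uni
  d <- diff(u)
  # sign change between consecutive differences marks grid point i+1 as a
  # local extremum of the curve
  sc <- which(d[-length(d)] * d[-1] < 0) + 1L
  sc <- sc[r1[sc] > window[1] & r1[sc] < window[2]]
  folds <- vapply(sc, function(i) {
    # parabola through (r1, uni) at i-1, i, i+1; vertex refines the extremum
    x <- r1[(i - 1):(i + 1)]
    y <- u[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom == 0) return(x[2])
    x[2] - (x[2] - x[1]) * (y[3] - y[1]) / (2 * denom)
  }, numeric(1))
  folds <- round(folds, 3)
  structure(
    list(folds = folds, grid_index = sc, bijective = length(folds) == 0,
         window = window),
    class = "fold_report"
  )
}

#' @export
print.fold_report <- function(x, ...) {
  if (x$bijective) {
    cat(sprintf("<fold_report> bijective over (%.3g, %.3g) s^-1: no folds\n",
                x$window[1], x$window[2]))
  } else {
    cat(sprintf("<fold_report> %d fold(s) in (%.3g, %.3g) s^-1 at: %s\n",
                length(x$folds), x$window[1], x$window[2],
                paste(format(x$folds), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a transfer table
#'
#' Writes the table as CSV with header `r1_s-1,uni,dsr` at full double
#' precision, plus a JSON sidecar (same path with extension `.json`) carrying
#' the generating protocol. [read_transfer_table()] restores the object;
#' the round trip is lossless to better than 1e-12.
#'
#' @param table A `transfer_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transfer_table <- function(table, path) {
  .check_table(table)
  df <- data.frame(
    `r1_s-1` = sprintf("%.17g", table$r1),
    uni = sprintf("%.17g", table$uni),
    dsr = sprintf("%.17g", table$dsr),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  p <- attr(table, "protocol")
  jsonlite::write_json(
    list(
      protocol = stats::setNames(p[.protocol_file_keys],
                                 names(.protocol_file_keys)),
      n_rows = nrow(table)
    ),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a serialized transfer table
#'
#' @param path Path to a CSV written by [write_transfer_table()]; the JSON
#'   sidecar must sit next to it.
#' @return A `transfer_table`.
#' @export
read_transfer_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    rlang::abort(paste0("Missing protocol sidecar: ", sidecar),
                 class = "r1lut_input_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  proto <- do.call(
    mp2rage_protocol,
    stats::setNames(meta$protocol[names(.protocol_file_keys)],
                    .protocol_file_keys)
  )
  new_transfer_table(
    tibble::tibble(r1 = df[["r1_s-1"]], uni = df$uni, dsr = df$dsr),
    protocol = proto
  )
}
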