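# Transmit-field (B1+) sensitivity analyses.
#
# The workhorse experiment: simulate signals with the excitation amplitude
# scaled away from nominal, invert against the *nominal* table (as a scanner
# pipeline would), and record the R1 error. On phantoms the truth is known,
# so bias is reported against truth rather than against the nominal-scale
# estimate.

.tissue_levels <- c("background", "csf", "gm", "wm")

.labels_factor <- function(labels) {
  factor(.tissue_levels[as.integer(labels) + 1L], levels = .tissue_levels)
}

#' B1+ bias curves
#'
#' For each transmit scale and true R1: simulate the signal pair under
#' [scale_excitation()], compute (UNI, DSR), invert against the nominal
#' (scale = 1) transfer table with the requested method, and record
#' `bias = r1_est - r1_true`.
#'
#' @param protocol Nominal [mp2rage_protocol()].
#' @param b1_scales Positive transmit scale factors (default the +/-40%
#'   stress set `c(0.6, 1, 1.4)`).
#' @param r1_true True rates, s^-1, within the grid.
#' @param method `"2d"` (weighted UNI+DSR lookup) or `"1d"` (UNI only).
#' @param weight UNI:DSR weight for the 2D method.
#' @param r1_min,r1_max,dr1 Grid parameters for the nominal table.
#' @return A `bias_curve` tibble with columns `b1_scale`, `r1_true`,
#'   `r1_est`, `bias`, plus `method` and `protocol` attributes.
#' @examples
#' bc <- bias_curve(protocol_lessbias(), r1_true = c(0.75, 1.25),
#'                  r1_min = 0.2, r1_max = 5, dr1 = 0.005)
#' bc
#' @export
bias_curve <- function(protocol, b1_scales = c(0.6, 1, 1.4),
                       r1_true = seq(0.25, 2, by = 0.25),
                       method = c("2d", "1d"), weight = 100,
                       r1_min = 0.01, r1_max = 20, dr1 = 0.001) {
  method <- match.arg(method)
  if (any(b1_scales <= 0)) {
    rlang::abort("`b1_scales` must be positive.", class = "r1lut_input_error")
  }
  if (any(r1_true < r1_min) || any(r1_true > r1_max)) {
    rlang::abort("`r1_true` must lie within the grid.",
                 class = "r1lut_input_error")
  }
  nominal <- build_table(protocol, r1_min, r1_max, dr1)
  rows <- purrr::map(b1_scales, function(sc) {
    p <- scale_excitation(protocol, sc)
    sig <- simulate_signals(p, r1_true)
    uni <- compute_uni(sig$s1, sig$s2)
    dsr <- compute_dsr(abs(sig$s1), abs(sig$s2))
    m <- if (method == "2d") {
      lut_invert_2d(uni, dsr, nominal, weight = weight, rescale = "never")
    } else {
      lut_invert_1d(uni, nominal, rescale = "never")
    }
    tibble::tibble(b1_scale = sc, r1_true = r1_true, r1_est = m$r1,
                   bias = m$r1 - r1_true)
  })
  structure(
    dplyr::bind_rows(rows),
    method = method, weight = weight, protocol = protocol,
    class = c("bias_curve", class(tibble::tibble()))
  )
}

#' Cross-scaling mean and standard deviation
#'
#' Given R1 maps of the same object acquired (or simulated) at different
#' excitation-amplitude scalings, computes the voxelwise mean and sample
#' standard deviation across the maps and summarizes the standard-deviation
#' map per tissue.
#'
#' @param r1_maps List (length >= 2) of aligned R1 arrays or
#'   `mapping_result` objects.
#' @param labels Integer label array (0 = background, 1 = CSF, 2 = GM,
#'   3 = WM) of the same shape.
#' @return A `cross_scaling_stats`: list with arrays `mean` and `sd` and a
#'   tibble `tissue` of per-tissue means of R1 and of the voxelwise sd.
#' @export
cross_scaling_stats <- function(r1_maps, labels) {
  maps <- purrr::map(r1_maps, function(m) {
    if (inherits(m, "mapping_result")) m$r1 else m
  })
  if (length(maps) < 2) {
    rlang::abort("Need at least two aligned R1 maps.",
                 class = "r1lut_input_error")
  }
  shapes <- purrr::map(maps, dim2)
  if (!all(purrr::map_lgl(shapes, identical, shapes[[1]])) ||
      !identical(dim2(labels), shapes[[1]])) {
    rlang::abort("R1 maps and labels must share a shape.",
                 class = "r1lut_input_error")
  }
  stack <- do.call(cbind, purrr::map(maps, as.numeric))
  mu <- rowMeans(stack)
  sdv <- apply(stack, 1, stats::sd)
  shape <- dim2(maps[[1]])
  shape_it <- function(v) if (length(shape) > 1) array(v, dim = shape) else v
  tissue <- tibble::tibble(
    tissue = .labels_factor(labels),
    mean_r1 = mu,
    sd_r1 = sdv
  ) |>
    dplyr::filter(.data$tissue != "background") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      mean_r1 = mean(.data$mean_r1, na.rm = TRUE),
      mean_sd = mean(.data$sd_r1, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(mean = shape_it(mu), sd = shape_it(sdv), tissue = tissue,
         n_maps = length(maps)),
    class = "cross_scaling_stats"
  )
}

#' @export
print.cross_scaling_stats <- function(x, ...) {
  cat(sprintf("<cross_scaling_stats> across %d maps\n", x$n_maps))
  print(x$tissue)
  invisible(x)
}

#' Flip-angle manipulation variance study
#'
#' Separates noise-driven from bias-driven R1 variance. Takes exactly three
#' replicate acquisitions of the same object (same truth, independent noise).
#' For each manipulation step `k` percent, replicate A is mapped with the
#' nominal-flip-angle table, replicate B with a table built at
#' `fa * (1 - k/100)` and replicate C at `fa * (1 + k/100)`; the voxelwise
#' standard deviation across the three maps is summarized per tissue. At
#' `k = 0` the three tables coincide, so the variance is the noise floor;
#' growth with `k` measures the protocol's sensitivity to flip-angle
#' (transmit-field) error.
#'
#' @param replicates List of exactly 3 `mp2rage_phantom` objects (or lists
#'   with elements `uni`, `m1`, `m2`), sharing truth.
#' @param protocol Nominal [mp2rage_protocol()].
#' @param steps Manipulation percentages (default `seq(0, 90, by = 10)`).
#' @param labels Label array; defaults to the first replicate's labels.
#' @param method,weight,r1_min,r1_max,dr1 Passed to the lookup inversion.
#' @return A `variance_study`: list with tibble `tissue` (columns
#'   `manipulation_pct`, `tissue`, `mean_sd`) and `sd_maps` (one array per
#'   step).
#' @export
fa_manipulation_study <- function(replicates, protocol,
                                  steps = seq(0, 90, by = 10),
                                  labels = NULL,
                                  method = c("2d", "1d"), weight = 100,
                                  r1_min = 0.01, r1_max = 20, dr1 = 0.001) {
  method <- match.arg(method)
  if (length(replicates) != 3) {
    rlang::abort("Exactly 3 replicate image sets are required.",
                 class = "r1lut_input_error")
  }
  if (is.null(labels)) {
    labels <- replicates[[1]]$labels
    if (is.null(labels)) {
      rlang::abort("Provide `labels` when replicates carry none.",
                   class = "r1lut_input_error")
    }
  }
  if (any(steps < 0 | steps >= 100)) {
    rlang::abort("`steps` must be percentages in [0, 100).",
                 class = "r1lut_input_error")
  }

  invert_with <- function(rep_set, table) {
    uni <- rep_set$uni
    dsr <- compute_dsr(rep_set$m1, rep_set$m2)
    if (method == "2d") {
      lut_invert_2d(uni, dsr, table, weight = weight, rescale = "never")$r1
    } else {
      lut_invert_1d(uni, table, rescale = "never")$r1
    }
  }
  table_at <- function(factor) {
    build_table(scale_excitation(protocol, factor), r1_min, r1_max, dr1)
  }
  nominal <- table_at(1)
  tiss <- .labels_factor(labels)

  out <- purrr::map(steps, function(k) {
    tab_dn <- if (k == 0) nominal else table_at(1 - k / 100)
    tab_up <- if (k == 0) nominal else table_at(1 + k / 100)
    maps <- list(
      invert_with(replicates[[1]], nominal),
      invert_with(replicates[[2]], tab_dn),
      invert_with(replicates[[3]], tab_up)
    )
    stack <- do.call(cbind, purrr::map(maps, as.numeric))
    sdv <- apply(stack, 1, stats::sd)
    tissue <- tibble::tibble(tissue = tiss, sd_r1 = sdv) |>
      dplyr::filter(.data$tissue != "background") |>
      dplyr::group_by(.data$tissue) |>
      dplyr::summarise(mean_sd = mean(.data$sd_r1, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(manipulation_pct = k, .before = 1)
    shape <- dim2(labels)
    sd_map <- if (length(shape) > 1) array(sdv, dim = shape) else sdv
    list(tissue = tissue, sd_map = sd_map)
  })
  structure(
    list(
      tissue = dplyr::bind_rows(purrr::map(out, "tissue")),
      sd_maps = stats::setNames(purrr::map(out, "sd_map"),
                                paste0("pct_", steps)),
      steps = steps, method = method
    ),
    class = "variance_study"
  )
}

#' @export
print.variance_study <- function(x, ...) {
  cat(sprintf("<variance_study> method %s, %d manipulation steps\n",
              x$method, length(x$steps)))
  print(tidyr::pivot_wider(x$tissue, names_from = "tissue",
                           values_from = "mean_sd"))
  invisible(x)
}
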