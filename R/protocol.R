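#' Define an MP2RAGE protocol
#'
#' An MP2RAGE cycle consists of an adiabatic inversion followed by two rapid
#' gradient-echo (FLASH) readout blocks placed at inversion times `ti1` and
#' `ti2`, all within one repetition time `tr_mp2rage`. The protocol object
#' collects the timing, flip angles, readout train length and inversion
#' efficiency needed to simulate the steady-state signal pair.
#'
#' Inversion times are referenced to the k-space-centre excitation of each
#' block, taken as excitation index `floor(n_exc/2)` (0-based) under linear
#' encoding. Three free-relaxation delays follow from that convention and must
#' be non-negative:
#' \itemize{
#'   \item `ta = ti1 - floor(n_exc/2) * tr_flash` (inversion to block 1),
#'   \item `tb = ti2 - ti1 - n_exc * tr_flash` (between blocks),
#'   \item `tc = tr_mp2rage - ti2 - (n_exc - floor(n_exc/2)) * tr_flash`
#'     (block 2 to end of cycle).
#' }
#'
#' @param tr_mp2rage Cycle repetition time, seconds.
#' @param tr_flash Excitation repetition time within a readout block, seconds.
#' @param ti1,ti2 Inversion times of the two blocks, seconds (`ti1 < ti2`).
#' @param fa1,fa2 Nominal excitation flip angles of the two blocks, degrees,
#'   each in `[0, 90)`.
#' @param n_exc Number of excitations per readout block.
#' @param inv_eff Inversion efficiency in `[0, 1]`: the preparation pulse maps
#'   longitudinal magnetization `Mz` to `-inv_eff * Mz`, so 1 is a perfect
#'   inversion. Default 0.96 (the value commonly assumed at 3 T).
#' @param b1_scale Multiplicative transmit-field (B1+) factor applied to `fa1`
#'   and `fa2` only; the inversion is not scaled.
#' @param m0 Equilibrium magnetization, arbitrary units.
#'
#' @return An object of class `mp2rage_protocol` (a validated named list).
#' @examples
#' p <- mp2rage_protocol(
#'   tr_mp2rage = 5, tr_flash = 0.00718, ti1 = 0.5, ti2 = 1.9,
#'   fa1 = 3, fa2 = 5, n_exc = 138
#' )
#' p
#' @seealso [protocol_standard()], [protocol_lessbias()], [scale_excitation()]
#' @export
mp2rage_protocol <- function(tr_mp2rage, tr_flash, ti1, ti2, fa1, fa2,
                             n_exc = 138L, inv_eff = 0.96, b1_scale = 1,
                             m0 = 1) {
  p <- structure(
    list(
      tr_mp2rage = as.numeric(tr_mp2rage),
      tr_flash = as.numeric(tr_flash),
      ti1 = as.numeric(ti1),
      ti2 = as.numeric(ti2),
      fa1 = as.numeric(fa1),
      fa2 = as.numeric(fa2),
      n_exc = as.integer(n_exc),
      inv_eff = as.numeric(inv_eff),
      b1_scale = as.numeric(b1_scale),
      m0 = as.numeric(m0)
    ),
    class = "mp2rage_protocol"
  )
  validate_protocol(p)
  p
}

#' Validate an MP2RAGE protocol
#'
#' Checks ordering, ranges and the three timing-feasibility inequalities
#' (see [mp2rage_protocol()]). Errors name the violated constraint.
#'
#' @param protocol An `mp2rage_protocol`.
#' @return `protocol`, invisibly, if valid.
#' @export
validate_protocol <- function(protocol) {
  p <- protocol
  if (!inherits(p, "mp2rage_protocol")) {
    rlang::abort("`protocol` must be an `mp2rage_protocol` object.",
                 class = "r1lut_config_error")
  }
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    rlang::abort(
      paste0("Protocol fields must be finite scalars; offending: ",
             paste(names(p)[!num], collapse = ", ")),
      class = "r1lut_config_error"
    )
  }
  fail <- function(msg) rlang::abort(msg, class = "r1lut_config_error")
  if (!(p$ti1 > 0)) fail("timing: ti1 > 0 is violated")
  if (!(p$ti2 > p$ti1)) fail("timing: ti2 > ti1 is violated")
  if (!(p$tr_mp2rage > p$ti2)) fail("timing: tr_mp2rage > ti2 is violated")
  if (!(p$tr_flash > 0)) fail("timing: tr_flash > 0 is violated")
  if (!(p$n_exc >= 1)) fail("n_exc >= 1 is violated")
  kc <- floor(p$n_exc / 2)
  ta <- p$ti1 - kc * p$tr_flash
  tb <- p$ti2 - p$ti1 - p$n_exc * p$tr_flash
  tc <- p$tr_mp2rage - p$ti2 - (p$n_exc - kc) * p$tr_flash
  if (ta < 0) {
    fail(sprintf(
      "timing infeasibility: ti1 - floor(n_exc/2)*tr_flash >= 0 is violated (ta = %.6g s)",
      ta))
  }
  if (tb < 0) {
    fail(sprintf(
      "timing infeasibility: ti2 - ti1 - n_exc*tr_flash >= 0 is violated (tb = %.6g s)",
      tb))
  }
  if (tc < 0) {
    fail(sprintf(
      "timing infeasibility: tr_mp2rage - ti2 - (n_exc - floor(n_exc/2))*tr_flash >= 0 is violated (tc = %.6g s)",
      tc))
  }
  if (p$inv_eff < 0 || p$inv_eff > 1) fail("inv_eff must lie in [0, 1]")
  if (!(p$b1_scale > 0)) fail("b1_scale must be > 0")
  if (p$fa1 < 0 || p$fa1 >= 90) fail("fa1 must lie in [0, 90) degrees")
  if (p$fa2 < 0 || p$fa2 >= 90) fail("fa2 must lie in [0, 90) degrees")
  invisible(protocol)
}

#' @export
print.mp2rage_protocol <- function(x, ...) {
  cat("<mp2rage_protocol>\n")
  cat(sprintf("  TR_MP2RAGE %.4g s | TR_FLASH %.4g ms | TI %.4g / %.4g s\n",
              x$tr_mp2rage, 1000 * x$tr_flash, x$ti1, x$ti2))
  cat(sprintf("  FA %.3g / %.3g deg | n_exc %d | inv_eff %.3g | b1_scale %.3g | m0 %.3g\n",
              x$fa1, x$fa2, x$n_exc, x$inv_eff, x$b1_scale, x$m0))
  invisible(x)
}

# file keys <-> field names; files carry explicit units in the key names
.protocol_file_keys <- c(
  tr_mp2rage_s = "tr_mp2rage", tr_flash_s = "tr_flash",
  ti1_s = "ti1", ti2_s = "ti2", fa1_deg = "fa1", fa2_deg = "fa2",
  n_exc = "n_exc", inv_eff = "inv_eff", b1_scale = "b1_scale", m0 = "m0"
)

#' Read a protocol definition file
#'
#' Reads a JSON or YAML protocol file with keys `tr_mp2rage_s`, `tr_flash_s`,
#' `ti1_s`, `ti2_s`, `fa1_deg`, `fa2_deg`, `n_exc`, `inv_eff`, `b1_scale`
#' (and optionally `m0`). Times are in seconds, angles in degrees.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `mp2rage_protocol`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Protocol file not found: ", path),
                 class = "r1lut_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      rlang::abort(paste0("Cannot parse protocol file ", path, ": ",
                          conditionMessage(e)),
                   class = "r1lut_config_error")
    }
  )
  missing_keys <- setdiff(setdiff(names(.protocol_file_keys), "m0"), names(raw))
  if (length(missing_keys) > 0) {
    rlang::abort(
      paste0("Protocol file ", path, " is missing keys: ",
             paste(missing_keys, collapse = ", ")),
      class = "r1lut_config_error"
    )
  }
  args <- stats::setNames(
    raw[intersect(names(.protocol_file_keys), names(raw))],
    .protocol_file_keys[intersect(names(.protocol_file_keys), names(raw))]
  )
  do.call(mp2rage_protocol, args)
}

#' Write a protocol definition file
#'
#' @param protocol An `mp2rage_protocol`.
#' @param path Output path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  out <- stats::setNames(
    protocol[.protocol_file_keys],
    names(.protocol_file_keys)
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Bundled reference protocols
#'
#' `protocol_standard()` is a typical 3 T MP2RAGE protocol
#' (TR 5 s, TR_FLASH 7.18 ms, FA 4/5 degrees, TI 700/2500 ms);
#' `protocol_lessbias()` is the B1+-tolerant variant
#' (FA 3/5 degrees, TI 500/1900 ms) whose UNI transfer curve is
#' non-bijective in the R1 window of interest and therefore requires the
#' two-dimensional lookup. Both ship with `n_exc = 138` excitations per
#' block and 96% inversion efficiency.
#'
#' @return An `mp2rage_protocol`.
#' @export
protocol_standard <- function() {
  read_protocol(system.file("extdata", "protocols", "standard.json",
                            package = "r1lut", mustWork = TRUE))
}

#' @rdname protocol_standard
#' @export
protocol_lessbias <- function() {
  read_protocol(system.file("extdata", "protocols", "lessbias.json",
                            package = "r1lut", mustWork = TRUE))
}

#' Scale the excitation flip angles of a protocol
#'
#' Multiplies both excitation flip angles by `factor`, leaving every other
#' field (including the inversion) untouched. This emulates a transmit-field
#' (B1+) deviation or a deliberate excitation-amplitude rescaling on the
#' scanner, which is equivalent to using non-integer flip angles.
#'
#' @param protocol An `mp2rage_protocol`.
#' @param factor Positive scale factor (1 leaves the protocol unchanged).
#' @return A new `mp2rage_protocol`.
#' @examples
#' scale_excitation(protocol_standard(), 0.6) # FA 2.4 / 3 degrees
#' @export
scale_excitation <- function(protocol, factor) {
  validate_protocol(protocol)
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    rlang::abort("`factor` must be a positive finite scalar.",
                 class = "r1lut_input_error")
  }
  p <- protocol
  p$fa1 <- p$fa1 * factor
  p$fa2 <- p$fa2 * factor
  validate_protocol(p)
  p
}
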