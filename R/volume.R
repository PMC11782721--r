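# Thin NIfTI layer. Analysis functions work on plain arrays; NIfTI metadata
# enters and leaves only here, via RNifti.

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `niftiImage` array (usable as a plain array; carries its
#'   affine and header as attributes).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Volume not found: ", path),
                 class = "r1lut_input_error")
  }
  RNifti::readNifti(path)
}

#' Write a NIfTI volume
#'
#' Output volumes copy the template's geometry (affine, voxel sizes) and are
#' stored as float32 with `scl_slope`/`scl_inter` reset to 1/0.
#'
#' @param data Numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional `niftiImage` (or path) supplying the header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, template = NULL) {
  img <- if (is.null(template)) {
    RNifti::asNifti(data + 0)
  } else {
    RNifti::asNifti(data + 0, reference = template)
  }
  img$scl_slope <- 1
  img$scl_inter <- 0
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# Shapes and affines must agree before voxelwise work.
.check_aligned <- function(...) {
  vols <- list(...)
  shapes <- purrr::map(vols, dim2)
  if (!all(purrr::map_lgl(shapes, identical, shapes[[1]]))) {
    rlang::abort("Input volumes have mismatched shapes.",
                 class = "r1lut_input_error")
  }
  affines <- purrr::map(vols, function(v) {
    tryCatch(structure(RNifti::xform(v), class = NULL),
             error = function(e) NULL)
  })
  affines <- purrr::compact(affines)
  if (length(affines) > 1) {
    ok <- all(purrr::map_lgl(affines, function(a) {
      max(abs(a - affines[[1]])) < 1e-4
    }))
    if (!ok) {
      rlang::abort("Input volumes have mismatched affines.",
                   class = "r1lut_input_error")
    }
  }
  invisible(TRUE)
}
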