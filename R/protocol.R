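#' Define a 2D gradient-echo EPI protocol
#'
#' Fixed acquisition parameters of a single-shot 2D EPI protocol. Arguments are
#' given in the units conventionally quoted on the scanner console (ms, mm);
#' they are converted once here and stored in SI units (s, m).
#'
#' @param te0 nominal echo time, ms.
#' @param echo_spacing inter-echo spacing of the EPI readout train, ms.
#' @param matrix_pe acquired-lines base matrix size along phase encode.
#' @param matrix_ro number of readout samples.
#' @param res_ro readout resolution, mm.
#' @param res_pe phase-encode resolution, mm.
#' @param slice_thickness slice thickness, mm.
#' @param orientation slice orientation, one of `"transverse"`, `"sagittal"`,
#'   `"coronal"`.
#' @param grappa_factor integer parallel-imaging (GRAPPA) acceleration factor
#'   along PE, >= 1. Modelled as an effective echo spacing
#'   `echo_spacing / grappa_factor`, shortening the acquisition window.
#' @param pe_oversampling phase oversampling fraction >= 0; enters both the
#'   acquired line count and the acquired PE field of view.
#' @param t2star assumed effective transverse relaxation time, ms. Default 50
#'   (typical grey matter at 3 T).
#' @param partial_fourier must be `FALSE`; the dropout model assumes symmetric
#'   k-space sampling, so partial-Fourier protocols are rejected.
#'
#' @return An object of class `epi_protocol`: a list with the fields above in
#'   SI units plus `fov_pe` (acquired PE field of view, m).
#' @seealso [protocol_preset()] for the shipped reference protocols,
#'   [effective_readout()] for derived readout quantities.
#' @examples
#' p <- epi_protocol(te0 = 30, echo_spacing = 0.5, matrix_pe = 64,
#'                   matrix_ro = 64, res_ro = 3, res_pe = 3,
#'                   slice_thickness = 3)
#' effective_readout(p)$ta  # 0.032 s
#' @export
epi_protocol <- function(te0, echo_spacing, matrix_pe, matrix_ro,
                         res_ro, res_pe, slice_thickness,
                         orientation = c("transverse", "sagittal", "coronal"),
                         grappa_factor = 1L, pe_oversampling = 0,
                         t2star = 50, partial_fourier = FALSE) {
  orientation <- match.arg(orientation)
  if (isTRUE(partial_fourier)) {
    stop("partial-Fourier protocols are not supported: the dropout model ",
         "assumes symmetric k-space sampling", call. = FALSE)
  }
  num <- c(te0 = te0, echo_spacing = echo_spacing, matrix_pe = matrix_pe,
           matrix_ro = matrix_ro, res_ro = res_ro, res_pe = res_pe,
           slice_thickness = slice_thickness, t2star = t2star)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all protocol times, lengths and matrix sizes must be finite and ",
         "strictly positive", call. = FALSE)
  }
  if (grappa_factor < 1 || grappa_factor != round(grappa_factor)) {
    stop("grappa_factor must be an integer >= 1", call. = FALSE)
  }
  if (pe_oversampling < 0) stop("pe_oversampling must be >= 0", call. = FALSE)
  if (matrix_pe != round(matrix_pe) || matrix_ro != round(matrix_ro)) {
    stop("matrix sizes must be integers", call. = FALSE)
  }
  acquired_lines <- as.integer(round(matrix_pe * (1 + pe_oversampling)))
  p <- structure(list(
    te0 = ms_to_s(te0),
    echo_spacing = ms_to_s(echo_spacing),
    matrix_pe = as.integer(matrix_pe),
    matrix_ro = as.integer(matrix_ro),
    res_ro = mm_to_m(res_ro),
    res_pe = mm_to_m(res_pe),
    slice_thickness = mm_to_m(slice_thickness),
    fov_pe = acquired_lines * mm_to_m(res_pe),
    orientation = orientation,
    grappa_factor = as.integer(grappa_factor),
    pe_oversampling = pe_oversampling,
    t2star = ms_to_s(t2star)
  ), class = "epi_protocol")
  p
}

#' @export
print.epi_protocol <- function(x, ...) {
  er <- effective_readout(x)
  cat("<epi_protocol>\n")
  cat(sprintf("  TE0 %.4g ms | echo spacing %.4g ms (effective %.4g ms, GRAPPA %d)\n",
              x$te0 * 1e3, x$echo_spacing * 1e3,
              er$echo_spacing_eff * 1e3, x$grappa_factor))
  cat(sprintf("  matrix %d x %d | res %.3g x %.3g mm | slice %.3g mm | %s\n",
              x$matrix_ro, x$matrix_pe, x$res_ro * 1e3, x$res_pe * 1e3,
              x$slice_thickness * 1e3, x$orientation))
  cat(sprintf("  acquired lines %d (oversampling %.3g%%) | TA %.4g ms | FoV_PE %.4g mm\n",
              er$acquired_lines, x$pe_oversampling * 100, er$ta * 1e3,
              er$fov_pe * 1e3))
  cat(sprintf("  T2* %.4g ms\n", x$t2star * 1e3))
  invisible(x)
}

#' Reference EPI protocol presets
#'
#' Named acquisition protocols used throughout the package:
#' \describe{
#'   \item{"I"}{standard resolution: TE 30 ms, echo spacing 0.5 ms, 64 x 64,
#'     3 x 3 mm in plane, 3 mm slices, no acceleration.}
#'   \item{"II"}{high resolution: TE 30 ms, echo spacing 0.78 ms, 96 x 96,
#'     2 x 2 mm, 2 mm slices.}
#'   \item{"III"}{as "II" with GRAPPA factor 2 along PE.}
#'   \item{"invivo"}{as "I" with phase oversampling such that 74 k-space lines
#'     are acquired for the 64 base matrix (TA 37 ms).}
#'   \item{"comparison"}{TE 30 ms, echo spacing 0.33 ms, 64 x 64, 3 x 3 mm,
#'     2 mm slices — the configuration used for comparison against earlier
#'     atlas-based optimization work.}
#' }
#'
#' @param name preset name.
#' @param orientation slice orientation for the returned protocol.
#' @param ... further arguments passed to [epi_protocol()] to override preset
#'   defaults (e.g. `t2star`).
#' @return An [epi_protocol()] object.
#' @export
protocol_preset <- function(name = c("I", "II", "III", "invivo", "comparison"),
                            orientation = "transverse", ...) {
  name <- match.arg(name)
  args <- switch(name,
    "I" = list(te0 = 30, echo_spacing = 0.5, matrix_pe = 64, matrix_ro = 64,
               res_ro = 3, res_pe = 3, slice_thickness = 3),
    "II" = list(te0 = 30, echo_spacing = 0.78, matrix_pe = 96, matrix_ro = 96,
                res_ro = 2, res_pe = 2, slice_thickness = 2),
    "III" = list(te0 = 30, echo_spacing = 0.78, matrix_pe = 96, matrix_ro = 96,
                 res_ro = 2, res_pe = 2, slice_thickness = 2,
                 grappa_factor = 2L),
    ## the printed "13%" oversampling is inconsistent with the stated 74
    ## acquired lines; the line count is authoritative: 64*(1+10/64) = 74
    "invivo" = list(te0 = 30, echo_spacing = 0.5, matrix_pe = 64,
                    matrix_ro = 64, res_ro = 3, res_pe = 3,
                    slice_thickness = 3, pe_oversampling = 10 / 64),
    "comparison" = list(te0 = 30, echo_spacing = 0.33, matrix_pe = 64,
                        matrix_ro = 64, res_ro = 3, res_pe = 3,
                        slice_thickness = 2)
  )
  args$orientation <- orientation
  do.call(epi_protocol, utils::modifyList(args, list(...)))
}

#' Derived readout quantities of an EPI protocol
#'
#' Computes the quantities of the EPI readout train that the physics model
#' consumes: the acquired line count (base matrix inflated by phase
#' oversampling), the effective echo spacing (inter-echo spacing divided by the
#' GRAPPA factor), the total acquisition duration TA of the symmetric readout,
#' and the acquired PE field of view.
#'
#' @param protocol an [epi_protocol()].
#' @return A list with elements `acquired_lines`, `echo_spacing_eff` (s),
#'   `ta` (s) and `fov_pe` (m).
#' @export
effective_readout <- function(protocol) {
  stopifnot(inherits(protocol, "epi_protocol"))
  acquired_lines <- as.integer(round(protocol$matrix_pe *
                                       (1 + protocol$pe_oversampling)))
  dt_eff <- protocol$echo_spacing / protocol$grappa_factor
  ta <- acquired_lines * dt_eff
  fov_pe <- acquired_lines * protocol$res_pe
  out <- list(acquired_lines = acquired_lines, echo_spacing_eff = dt_eff,
              ta = ta, fov_pe = fov_pe)
  if (any(unlist(out) <= 0)) {
    stop("malformed protocol: non-positive derived readout quantity",
         call. = FALSE)
  }
  out
}

#' Adjustable acquisition parameters
#'
#' The three quantities the optimizer varies: the z-shim gradient moment
#' applied along the slice direction, the slice tilt (slice angulation for
#' transverse/coronal slices, in-plane rotation for sagittal slices), and the
#' polarity of the PE gradient.
#'
#' @param zshim z-shim gradient moment, mT/m*ms.
#' @param tilt slice tilt / in-plane rotation, degrees.
#' @param polarity `"positive"` or `"negative"` PE prewinder polarity.
#' @return An object of class `adjustable_params`.
#' @export
adjustable_params <- function(zshim = 0, tilt = 0,
                              polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(is.finite(zshim), is.finite(tilt))
  structure(list(zshim = zshim, tilt = tilt, polarity = polarity),
            class = "adjustable_params")
}

#' @export
print.adjustable_params <- function(x, ...) {
  cat(sprintf("<adjustable_params> zshim %.3g mT/m*ms | tilt %.3g deg | PE %s\n",
              x$zshim, x$tilt, x$polarity))
  invisible(x)
}

#' Build the grid of adjustable parameters
#'
#' Inclusive-endpoint grids over z-shim moment and slice tilt, crossed with the
#' PE polarities. Defaults reproduce the reference search space: tilt -45..45
#' degrees in steps of 5, z-shim -5..5 mT/m*ms in steps of 0.5, both
#' polarities (798 parameter sets). Every grid must contain the identity point
#' (zero moment, zero tilt) so the gain of the reference protocol is defined.
#'
#' @param zshim_range length-2 numeric, min and max z-shim moment, mT/m*ms.
#' @param zshim_step positive step, mT/m*ms.
#' @param tilt_range length-2 numeric, min and max tilt, degrees.
#' @param tilt_step positive step, degrees.
#' @param polarities character subset of `c("positive", "negative")`.
#' @return An object of class `param_grid` with fields `zshim_values`,
#'   `tilt_values`, `polarities`.
#' @export
build_grid <- function(zshim_range = c(-5, 5), zshim_step = 0.5,
                       tilt_range = c(-45, 45), tilt_step = 5,
                       polarities = c("positive", "negative")) {
  axis_values <- function(range, step, what) {
    if (length(range) != 2 || any(!is.finite(range)) || range[1] > range[2]) {
      stop("invalid ", what, " range", call. = FALSE)
    }
    if (range[1] > 0 || range[2] < 0) {
      stop(what, " range must bracket 0 (the identity point)", call. = FALSE)
    }
    if (range[1] == range[2]) return(range[1])
    if (!is.finite(step) || step <= 0) {
      stop(what, " step must be positive", call. = FALSE)
    }
    if (step > diff(range)) {
      stop(what, " step larger than range", call. = FALSE)
    }
    v <- seq(range[1], range[2], by = step)
    if (utils::tail(v, 1) < range[2] - 1e-9) v <- c(v, range[2])
    v <- round(v, 9)
    if (!any(abs(v) < 1e-9)) {
      stop(what, " grid does not contain 0; the identity point is required",
           call. = FALSE)
    }
    v
  }
  polarities <- match.arg(polarities, c("positive", "negative"),
                          several.ok = TRUE)
  structure(list(
    zshim_values = axis_values(zshim_range, zshim_step, "zshim"),
    tilt_values = axis_values(tilt_range, tilt_step, "tilt"),
    polarities = polarities
  ), class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("<param_grid> %d tilt x %d zshim x %d polarity = %d sets\n",
              length(x$tilt_values), length(x$zshim_values),
              length(x$polarities), n_param_sets(x)))
  invisible(x)
}

#' Number of parameter sets in a grid
#' @param grid a [build_grid()] object.
#' @return Integer count of parameter sets.
#' @export
n_param_sets <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  length(grid$zshim_values) * length(grid$tilt_values) * length(grid$polarities)
}

#' Enumerate a parameter grid in tie-break order
#'
#' Expands a [build_grid()] into one row per parameter set, ordered by the
#' deterministic tie-breaking rule used by the optimizer: smallest |zshim|
#' first, then smallest |tilt|, then positive before negative polarity; among
#' equal magnitudes the positive value precedes the negative one. Streaming
#' over rows in this order with a strict "greater than" comparison therefore
#' implements the tie-break for free.
#'
#' @param grid a [build_grid()] object.
#' @return data.frame with columns `zshim`, `tilt`, `polarity`.
#' @export
param_sets <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  d <- expand.grid(zshim = grid$zshim_values, tilt = grid$tilt_values,
                   polarity = grid$polarities,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- order(abs(d$zshim), abs(d$tilt),
               match(d$polarity, c("positive", "negative")),
               -d$zshim, -d$tilt)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Does a grid contain the reference point?
#' @param grid a [build_grid()] object.
#' @return `TRUE` if (zshim 0, tilt 0, positive polarity) is on the grid.
#' @export
has_reference_point <- function(grid) {
  any(abs(grid$zshim_values) < 1e-9) && any(abs(grid$tilt_values) < 1e-9) &&
    "positive" %in% grid$polarities
}
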