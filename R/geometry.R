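## Slice-frame geometry.
##
## Scanner axes: X = right-left, Y = posterior-anterior, Z = head-feet.
## Canonical frames (tilt 0), with the PE gradient pointing anterior->posterior
## for transverse and sagittal slices and feet->head for coronal slices:
##   transverse: e_RO = +X, e_PE = -Y, e_SL = +Z
##   sagittal:   e_RO = +Z, e_PE = -Y, e_SL = +X
##   coronal:    e_RO = +X, e_PE = +Z, e_SL = +Y
## Tilting rotates (e_PE, e_SL) about e_RO for transverse/coronal slices
## (slice angulation) and (e_RO, e_PE) about e_SL for sagittal slices
## (in-plane rotation). The rotation sense is fixed so that for transverse
## slices a positive angle tips the anterior slice edge towards the feet; the
## sagittal sense is chosen so that e_PE coincides with the transverse case at
## equal tilt, and the coronal sense follows the same signed-rotation table.
## These senses are a documented package convention where only pictorial
## definitions exist.

FRAME_TABLE <- list(
  transverse = list(e_ro = c(1, 0, 0), e_pe = c(0, -1, 0), e_sl = c(0, 0, 1),
                    tilt_axis = "e_ro", angle_sign = -1),
  sagittal = list(e_ro = c(0, 0, 1), e_pe = c(0, -1, 0), e_sl = c(1, 0, 0),
                  tilt_axis = "e_sl", angle_sign = -1),
  coronal = list(e_ro = c(1, 0, 0), e_pe = c(0, 0, 1), e_sl = c(0, 1, 0),
                 tilt_axis = "e_ro", angle_sign = -1)
)

#' Canonical slice frame for a principal orientation
#'
#' Returns the untilted acquisition frame (unit vectors `e_ro`, `e_pe`, `e_sl`
#' in the scanner frame) for a principal slice orientation.
#'
#' @param orientation `"transverse"`, `"sagittal"` or `"coronal"`.
#' @return An object of class `slice_frame` with fields `orientation`,
#'   `tilt`, `e_ro`, `e_pe`, `e_sl`.
#' @export
canonical_frame <- function(orientation = c("transverse", "sagittal",
                                            "coronal")) {
  orientation <- match.arg(orientation)
  f <- FRAME_TABLE[[orientation]]
  structure(list(orientation = orientation, tilt = 0,
                 e_ro = f$e_ro, e_pe = f$e_pe, e_sl = f$e_sl),
            class = "slice_frame")
}

#' @export
print.slice_frame <- function(x, ...) {
  cat(sprintf("<slice_frame> %s, tilt %.3g deg\n", x$orientation, x$tilt))
  cat(sprintf("  e_RO (%+.3f %+.3f %+.3f)\n", x$e_ro[1], x$e_ro[2], x$e_ro[3]))
  cat(sprintf("  e_PE (%+.3f %+.3f %+.3f)\n", x$e_pe[1], x$e_pe[2], x$e_pe[3]))
  cat(sprintf("  e_SL (%+.3f %+.3f %+.3f)\n", x$e_sl[1], x$e_sl[2], x$e_sl[3]))
  invisible(x)
}

rotation_matrix <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(a)
}

#' Tilt a slice frame
#'
#' Applies the slice angulation (transverse/coronal: rotation of the PE and SL
#' axes about the RO axis) or in-plane rotation (sagittal: rotation of the RO
#' and PE axes about the SL axis) to a canonical frame. A positive angle tips
#' the anterior edge of transverse slices towards the feet.
#'
#' @param frame a [canonical_frame()] (or previously tilted frame; tilts add).
#' @param tilt_deg rotation angle in degrees.
#' @return A `slice_frame` with updated unit vectors.
#' @export
tilt_frame <- function(frame, tilt_deg) {
  stopifnot(inherits(frame, "slice_frame"))
  f <- FRAME_TABLE[[frame$orientation]]
  axis <- frame[[f$tilt_axis]]
  R <- rotation_matrix(axis, f$angle_sign * tilt_deg * pi / 180)
  out <- frame
  out$tilt <- frame$tilt + tilt_deg
  if (f$tilt_axis == "e_ro") {
    out$e_pe <- as.numeric(R %*% frame$e_pe)
    out$e_sl <- as.numeric(R %*% frame$e_sl)
  } else {
    out$e_ro <- as.numeric(R %*% frame$e_ro)
    out$e_pe <- as.numeric(R %*% frame$e_pe)
  }
  out
}

#' Project a scanner-frame gradient vector into the slice frame
#'
#' Orthogonal projection of a susceptibility-gradient vector onto the RO, PE
#' and SL axes of an acquisition frame. The PE polarity does not alter the
#' projection; it selects the sign branch of the echo-shift factor downstream.
#'
#' @param grad numeric length-3 vector (uT/m, scanner frame), or an n x 3
#'   matrix of vectors.
#' @param frame a `slice_frame`.
#' @return For a single vector, named numeric `c(g_ro, g_pe, g_sl)`; for a
#'   matrix, an n x 3 matrix with columns `g_ro`, `g_pe`, `g_sl`.
#' @export
project_gradient <- function(grad, frame) {
  stopifnot(inherits(frame, "slice_frame"))
  B <- cbind(g_ro = frame$e_ro, g_pe = frame$e_pe, g_sl = frame$e_sl)
  if (is.matrix(grad)) {
    stopifnot(ncol(grad) == 3)
    grad %*% B
  } else {
    stopifnot(length(grad) == 3, all(is.finite(grad)))
    drop(grad %*% B)
  }
}
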