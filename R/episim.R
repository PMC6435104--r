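## Forward simulation of a 2D EPI acquisition from a field map.
##
## The readout is modelled per phase-encode column as a 1D acquisition: line m
## (m = -N/2 .. N/2-1 around the k-space centre) is sampled at time
## t_m = TE0 + m*dt_eff and encodes k_m = s*m*dk with dk = 2*pi/FoV_P and
## s = +1/-1 for positive/negative PE polarity. Off-resonance f(y) accrues
## phase exp(i*2*pi*f*t_m); T2* decay and through-plane dephasing (from the
## slice-direction gradient and the z-shim moment, evaluated at each sample
## time) attenuate the signal. Reconstruction is the nominal inverse DFT, so
## susceptibility-induced echo shifts, intensity scaling and geometric
## distortion emerge from the simulation rather than being imposed — the
## simulated data share no code path with the closed-form BS model.

#' Forward-simulate complex EPI data from a field map
#'
#' Generates magnitude and phase volumes of a single-shot EPI acquisition of a
#' uniform object (the field-map mask) in the presence of the map's
#' off-resonance field. Used to validate the phase-difference BS estimator
#' ([experimental_bs()]) against the closed-form model in a closed loop.
#' Only untilted acquisitions are supported; the lattice extent along the PE
#' axis must equal the protocol's acquired line count.
#'
#' @param fieldmap a [field_map()] in Hz; its mask (all voxels if unset)
#'   defines the object.
#' @param protocol an [epi_protocol()].
#' @param params an [adjustable_params()] with `tilt = 0`; the z-shim moment
#'   and PE polarity are applied.
#' @param config a [bs_config()] (profile constant of the through-plane
#'   dephasing term).
#' @param rho optional 3D array of object intensities overriding the mask.
#' @return List of class `epi_sim` with [field_map()] elements `magnitude`
#'   and `phase` (radians).
#' @export
simulate_epi_complex <- function(fieldmap, protocol,
                                 params = adjustable_params(),
                                 config = bs_config(), rho = NULL) {
  stopifnot(inherits(fieldmap, "field_map"))
  if (params$tilt != 0) {
    stop("the EPI forward simulator supports untilted acquisitions only",
         call. = FALSE)
  }
  er <- effective_readout(protocol)
  ax <- resolve_pe_axis(fieldmap, protocol)
  dims <- dim(fieldmap$values)
  n_pe <- dims[ax$axis]
  if (n_pe != er$acquired_lines) {
    stop("lattice extent along PE (", n_pe, ") must equal the acquired ",
         "line count (", er$acquired_lines, ")", call. = FALSE)
  }
  ## slice-direction gradient per voxel (uT/m) for through-plane dephasing
  frame <- canonical_frame(protocol$orientation)
  gf <- gradient_field(fieldmap)
  gsl <- gf$gx * frame$e_sl[1] + gf$gy * frame$e_sl[2] + gf$gz * frame$e_sl[3]

  rho <- rho %||% (fieldmap$mask %||% array(TRUE, dims)) * 1
  ## permute PE axis first, oriented along +PE
  perm <- c(ax$axis, setdiff(1:3, ax$axis))
  to_pe <- function(a) {
    a <- aperm(a, perm)
    if (ax$sign < 0) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    matrix(a, nrow = n_pe)
  }
  fmat <- to_pe(fieldmap$values)
  rmat <- to_pe(rho)
  gmat <- to_pe(gsl)

  m_idx <- seq_len(n_pe) - 1 - n_pe %/% 2
  t_m <- protocol$te0 + m_idx * er$echo_spacing_eff
  dk <- 2 * pi / er$fov_pe
  s_pol <- if (params$polarity == "positive") 1 else -1
  k_m <- s_pol * m_idx * dk
  y <- (seq_len(n_pe) - 1 - n_pe %/% 2) * protocol$res_pe
  enc <- exp(-1i * outer(k_m, y))              # n_pe x n_pe encoding
  rec <- Conj(t(enc)) / n_pe                   # nominal inverse DFT
  decay <- exp(-t_m / protocol$t2star)
  psi_scale <- config$gamma * protocol$slice_thickness /
    config$profile_constant
  m_shim <- moment_to_SI(params$zshim)

  img <- matrix(complex(real = 0), n_pe, ncol(fmat))
  for (c_ in seq_len(ncol(fmat))) {
    if (all(rmat[, c_] == 0)) next
    ## voxel x time phase evolution and attenuation
    ph <- exp(1i * 2 * pi * outer(fmat[, c_], t_m))          # n_y x n_t
    att <- exp(-(psi_scale *
                   (outer(uTm_to_Tm(gmat[, c_]), t_m) + m_shim))^2)
    E <- (rmat[, c_] * ph * att) * rep(decay, each = n_pe)
    S <- enc %*% E  # S[m, t]; acquisition takes the diagonal: line m at t_m
    img[, c_] <- rec %*% diag(S)
  }

  from_pe <- function(m) {
    a <- array(m, c(n_pe, dims[perm[2]], dims[perm[3]]))
    if (ax$sign < 0) a <- a[rev(seq_len(n_pe)), , , drop = FALSE]
    aperm(a, order(perm))
  }
  mk <- function(v) field_map(v, voxel_size = fieldmap$voxel_size,
                              axes = fieldmap$axes)
  structure(list(magnitude = mk(from_pe(Mod(img))),
                 phase = mk(from_pe(Arg(img)))),
            class = "epi_sim")
}
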