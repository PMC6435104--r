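#' BS model configuration
#'
#' Numerical constants and mode switches of the BOLD-sensitivity model.
#'
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @param profile_constant denominator constant of the Gaussian slice-profile
#'   dephasing term. Default `4*log(2)` as conventionally printed; the analytic
#'   constant for a Gaussian profile specified by its FWHM would be
#'   `4*sqrt(log(2))` — see the methods vignette.
#' @param dropout_te_mode `"local"` evaluates the readout-direction dropout
#'   bound at the locally shifted echo time (default); `"nominal"` uses the
#'   nominal TE.
#' @return An object of class `bs_config`.
#' @export
bs_config <- function(gamma = GAMMA_RAD, profile_constant = 4 * log(2),
                      dropout_te_mode = c("local", "nominal")) {
  stopifnot(gamma > 0, profile_constant > 0)
  structure(list(gamma = gamma, profile_constant = profile_constant,
                 dropout_te_mode = match.arg(dropout_te_mode)),
            class = "bs_config")
}

#' Echo-shift factor Q from a PE-direction gradient
#'
#' A susceptibility gradient along the phase-encode direction adds to the PE
#' blip gradients and shifts the echo in time:
#' `q = 1 -/+ (gamma/2pi) * dt_eff * FoV_P * G_PE`, with `-` for positive and
#' `+` for negative PE polarity. The local echo time is `TE0 / q` and the
#' initial intensity scales as `1/q`. `q <= 0` is not an error; it signals
#' total echo loss and is handled by the dropout check.
#'
#' @param g_pe PE-direction gradient component(s), uT/m. Vectorized.
#' @param protocol an [epi_protocol()].
#' @param polarity `"positive"` or `"negative"`.
#' @param config a [bs_config()].
#' @return Numeric vector of echo-shift factors.
#' @export
q_factor <- function(g_pe, protocol, polarity = "positive",
                     config = bs_config()) {
  er <- effective_readout(protocol)
  sgn <- if (polarity == "positive") -1 else 1
  gamma_bar <- config$gamma / (2 * pi)
  1 + sgn * gamma_bar * er$echo_spacing_eff * er$fov_pe * uTm_to_Tm(g_pe)
}

#' Through-plane dephasing attenuation
#'
#' Signal attenuation from through-plane dephasing across a Gaussian slice
#' profile of thickness `dz`:
#' `exp(-Psi^2)` with `Psi = gamma*dz/C * (G_SL*TE + M_shim)`.
#' A z-shim moment `M_shim = -G_SL*TE` compensates the dephasing exactly.
#'
#' @param g_sl slice-direction gradient component(s), uT/m. Vectorized.
#' @param zshim z-shim gradient moment, mT/m*ms.
#' @param protocol an [epi_protocol()].
#' @param local_te echo time entering the `G_SL*TE` product, s. Defaults to
#'   the protocol's nominal TE.
#' @param config a [bs_config()].
#' @return Attenuation factor(s) in `[0, 1]`.
#' @export
through_plane_attenuation <- function(g_sl, zshim, protocol,
                                      local_te = protocol$te0,
                                      config = bs_config()) {
  psi <- config$gamma * protocol$slice_thickness / config$profile_constant *
    (uTm_to_Tm(g_sl) * local_te + moment_to_SI(zshim))
  exp(-psi^2)
}

#' Complete-dropout test
#'
#' A voxel suffers complete signal loss when the echo leaves the acquisition
#' window: along PE when the local echo time falls outside
#' `[TE0 - TA/2, TE0 + TA/2]` for the symmetric readout of duration TA (or
#' when `q <= 0`), and along RO when the k-space shift
#' `|gamma * TE * G_RO|` exceeds `pi / dx`.
#'
#' @param g_pe,g_ro gradient components, uT/m. Vectorized.
#' @param protocol an [epi_protocol()].
#' @param polarity PE polarity.
#' @param config a [bs_config()]; `dropout_te_mode` selects whether the RO
#'   bound uses the local or the nominal TE.
#' @return Logical vector: `TRUE` where the voxel is dropped.
#' @export
dropout <- function(g_pe, g_ro, protocol, polarity = "positive",
                    config = bs_config()) {
  er <- effective_readout(protocol)
  q <- q_factor(g_pe, protocol, polarity, config)
  te0 <- protocol$te0
  local_te <- ifelse(q > 0, te0 / q, Inf)
  pe_drop <- q <= 0 | local_te < te0 - er$ta / 2 | local_te > te0 + er$ta / 2
  te_used <- if (config$dropout_te_mode == "local") local_te else te0
  ro_drop <- abs(config$gamma * te_used * uTm_to_Tm(g_ro)) >
    pi / protocol$res_ro
  pe_drop | ro_drop
}

#' Relative BOLD sensitivity of voxels (vectorized core)
#'
#' Evaluates the BS model for slice-frame gradient components:
#' `BS/BS0 = q^-2 * exp(-(TE_local - TE0)/T2*) * exp(-Psi^2)` inside the
#' acquisition window and exactly 0 where the dropout conditions hold. BS is
#' normalised so a well-shimmed voxel at reference settings has `bs = 1`.
#'
#' @param g_ro,g_pe,g_sl gradient components in the slice frame, uT/m
#'   (vectors of common length).
#' @param protocol an [epi_protocol()].
#' @param zshim z-shim moment, mT/m*ms.
#' @param polarity PE polarity.
#' @param config a [bs_config()].
#' @return List of vectors: `bs`, `local_te` (s, `NA` where the echo is lost),
#'   `q`, `attenuation_sl`, `dropped`.
#' @export
bs_relative <- function(g_ro, g_pe, g_sl, protocol, zshim = 0,
                        polarity = "positive", config = bs_config()) {
  q <- q_factor(g_pe, protocol, polarity, config)
  dropped <- dropout(g_pe, g_ro, protocol, polarity, config)
  local_te <- ifelse(q > 0, protocol$te0 / q, NA_real_)
  te_for_psi <- ifelse(is.na(local_te), protocol$te0, local_te)
  att <- through_plane_attenuation(g_sl, zshim, protocol, te_for_psi, config)
  bs <- ifelse(dropped, 0,
               q^-2 * exp(-(local_te - protocol$te0) / protocol$t2star) * att)
  bs[dropped] <- 0  # ensure exact zeros even where local_te is NA
  list(bs = bs, local_te = local_te, q = q, attenuation_sl = att,
       dropped = dropped)
}

#' Relative BS of a single voxel
#'
#' Scalar convenience wrapper around [bs_relative()] taking an
#' [adjustable_params()] set; the tilt is not applied here (gradients are
#' assumed to already be expressed in the tilted slice frame, see
#' [project_gradient()]).
#'
#' @param g_ro,g_pe,g_sl scalar slice-frame gradient components, uT/m.
#' @param protocol an [epi_protocol()].
#' @param params an [adjustable_params()].
#' @param config a [bs_config()].
#' @return An object of class `voxel_bs` with fields `bs_rel`, `local_te`,
#'   `q`, `attenuation_sl`, `dropped`.
#' @export
voxel_bs <- function(g_ro, g_pe, g_sl, protocol, params = adjustable_params(),
                     config = bs_config()) {
  r <- bs_relative(g_ro, g_pe, g_sl, protocol, zshim = params$zshim,
                   polarity = params$polarity, config = config)
  structure(list(bs_rel = r$bs, local_te = r$local_te, q = r$q,
                 attenuation_sl = r$attenuation_sl, dropped = r$dropped),
            class = "voxel_bs")
}

#' @export
print.voxel_bs <- function(x, ...) {
  cat(sprintf("<voxel_bs> bs %.4g | local TE %s ms | q %.4g | att %.4g%s\n",
              x$bs_rel,
              if (is.na(x$local_te)) "NA" else sprintf("%.4g", x$local_te * 1e3),
              x$q, x$attenuation_sl, if (x$dropped) " [dropped]" else ""))
  invisible(x)
}

#' BS loss in well-shimmed tissue
#'
#' The fractional BS loss a parameter set incurs in tissue with zero
#' susceptibility gradient, relative to the reference settings. With zero
#' gradients only the z-shim dephasing term contributes; tilt and polarity
#' leave the loss unchanged, and the loss is even in the shim moment. The
#' optimizer rejects parameter sets whose loss exceeds the configured bound
#' (default 15%).
#'
#' @param params an [adjustable_params()] (only `zshim` matters).
#' @param protocol an [epi_protocol()].
#' @param config a [bs_config()].
#' @return Loss fraction in `[0, 1]`.
#' @export
wellshimmed_loss <- function(params, protocol, config = bs_config()) {
  r <- bs_relative(0, 0, 0, protocol, zshim = params$zshim,
                   polarity = params$polarity, config = config)
  1 - r$bs
}

#' Symmetric percent BS gain
#'
#' `200 * (bs - bs_ref) / (bs + bs_ref)`, bounded in `[-200, 200]`.
#' Undefined (NA) where both inputs are zero.
#'
#' @param bs,bs_ref non-negative BS values (vectorized).
#' @return Percent gain.
#' @export
bs_gain <- function(bs, bs_ref) {
  out <- ifelse(bs + bs_ref > 0, 200 * (bs - bs_ref) / (bs + bs_ref),
                NA_real_)
  out
}

#' Experimental BS map from complex EPI data
#'
#' Estimates the local echo time voxel-wise from the phase difference between
#' adjacent voxels along the phase-encode direction: an echo shifted by `n`
#' lines in k-space manifests as an image phase ramp of `2*pi*n/N` per PE
#' voxel, so `n = dphi * N_acq / (2*pi)` (sign set by the PE polarity) and
#' `TE_local = TE0 + n * dt_eff`. The BS is then `TE_local * |I|`. Voxels with
#' negative estimated TE are set to `NA`.
#'
#' @param magnitude,phase [field_map()] objects holding the magnitude and
#'   phase (radians) of the complex EPI data, identical geometry.
#' @param protocol an [epi_protocol()]; its orientation identifies the PE
#'   direction via [canonical_frame()].
#' @param polarity PE polarity of the acquisition.
#' @param pe_axis optional override: lattice axis (1..3) along PE, negative to
#'   indicate that increasing index runs against the PE direction.
#' @return A list of class `experimental_bs` with [field_map()] elements
#'   `bs` (s * intensity units) and `local_te` (s).
#' @export
experimental_bs <- function(magnitude, phase, protocol, polarity = "positive",
                            pe_axis = NULL) {
  stopifnot(inherits(magnitude, "field_map"), inherits(phase, "field_map"))
  if (!same_geometry(magnitude, phase)) {
    stop("magnitude/phase geometry mismatch", call. = FALSE)
  }
  ax <- resolve_pe_axis(phase, protocol, pe_axis)
  er <- effective_readout(protocol)
  dphi <- forward_phase_diff(phase$values, ax$axis) * ax$sign
  n_lines <- dphi * er$acquired_lines / (2 * pi)
  if (polarity == "negative") n_lines <- -n_lines
  local_te <- protocol$te0 + n_lines * er$echo_spacing_eff
  local_te[local_te < 0] <- NA_real_
  bs <- local_te * magnitude$values
  mk <- function(v) field_map(v, voxel_size = phase$voxel_size,
                              axes = phase$axes)
  structure(list(bs = mk(bs), local_te = mk(local_te)),
            class = "experimental_bs")
}

## identify the lattice axis running along e_PE; returns axis index and the
## sign relating +index direction to +PE direction
resolve_pe_axis <- function(map, protocol, pe_axis = NULL) {
  if (!is.null(pe_axis)) {
    return(list(axis = abs(pe_axis), sign = sign(pe_axis)))
  }
  e_pe <- canonical_frame(protocol$orientation)$e_pe
  letters3 <- c(x = 1L, y = 2L, z = 3L)
  for (j in 1:3) {
    ax <- map$axes[j]
    sgn <- if (startsWith(ax, "-")) -1 else 1
    dir <- numeric(3)
    dir[letters3[[sub("^-", "", ax)]]] <- sgn
    d <- sum(dir * e_pe)
    if (abs(d) > 0.5) return(list(axis = j, sign = sign(d)))
  }
  stop("could not identify the PE axis from the volume orientation; ",
       "pass pe_axis explicitly", call. = FALSE)
}

## wrapped forward difference along a lattice axis, assigned to the leading
## voxel; the trailing edge repeats its neighbour's difference
forward_phase_diff <- function(values, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(values, perm)
  dims <- dim(a)
  n <- dims[1]
  m <- matrix(a, nrow = n)
  d <- matrix(NA_real_, n, ncol(m))
  d[1:(n - 1), ] <- wrap_phase(m[2:n, , drop = FALSE] -
                                 m[1:(n - 1), , drop = FALSE])
  d[n, ] <- d[n - 1, ]
  aperm(array(d, dims), order(perm))
}

#' Difference statistics between simulated and experimental BS-gain maps
#'
#' Voxel-wise difference `sim_gain - exp_gain`, summarised by its mean and
#' standard deviation within a mask, with histogram data for export.
#'
#' @param sim_gain,exp_gain co-registered gain maps: [field_map()] objects or
#'   bare arrays of identical dimension (percent units).
#' @param mask logical array; must select at least one voxel with finite
#'   values in both maps.
#' @param breaks passed to [graphics::hist()] binning via [base::cut()]-style
#'   `hist(plot = FALSE)`.
#' @return List with `mean`, `sd`, `n`, and `histogram` (data.frame with bin
#'   `mid` and `count`).
#' @export
bs_difference_stats <- function(sim_gain, exp_gain, mask, breaks = 50) {
  g1 <- if (inherits(sim_gain, "field_map")) sim_gain$values else sim_gain
  g2 <- if (inherits(exp_gain, "field_map")) exp_gain$values else exp_gain
  stopifnot(identical(dim(g1), dim(g2)), identical(dim(g1), dim(mask)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  d <- (g1 - g2)[mask]
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no finite differences inside mask", call. = FALSE)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(mean = mean(d), sd = stats::sd(d), n = length(d),
       histogram = data.frame(mid = h$mids, count = h$counts))
}
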