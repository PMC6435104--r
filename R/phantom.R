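#' Specify a synthetic head phantom
#'
#' Describes a synthetic field-map phantom: a lattice, a main field strength,
#' spherical air cavities (each a susceptibility difference to tissue that
#' perturbs the field as a magnetic dipole), an ellipsoidal brain mask, and
#' labelled ROI spheres. All positions are in mm relative to the volume
#' centre; scanner axes are X = right-left, Y = posterior-anterior,
#' Z = head-feet.
#'
#' @param shape lattice dimensions, length 3.
#' @param voxel_size voxel size, mm (scalar or length 3).
#' @param b0 main field strength, T.
#' @param cavities list of `list(centre = c(x,y,z) mm, radius = mm,
#'   dchi = ppm)`.
#' @param brain `list(centre, semiaxes)` of the ellipsoidal brain mask, mm.
#' @param rois list of `list(name, centres = list of c(x,y,z), radius)`; each
#'   entry becomes one label covering all its spheres (bilateral ROIs are a
#'   single label with two centres).
#' @param noise_sd additive Gaussian field noise, Hz.
#' @param seed integer seed making noise and cohort jitter reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size = 3, b0 = 3,
                         cavities = list(), brain = NULL, rois = list(),
                         noise_sd = 0, seed = 1L) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(shape) == 3, all(shape >= 2), all(voxel_size > 0), b0 > 0)
  half <- (shape - 1) / 2 * voxel_size
  for (cv in cavities) {
    stopifnot(cv$radius > 0)
    if (any(abs(cv$centre) + cv$radius > half + voxel_size)) {
      stop("cavity extends outside the volume", call. = FALSE)
    }
  }
  structure(list(shape = as.integer(shape), voxel_size = voxel_size, b0 = b0,
                 cavities = cavities, brain = brain, rois = rois,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_coords <- function(spec) {
  lapply(1:3, function(d) {
    (seq_len(spec$shape[d]) - (spec$shape[d] + 1) / 2) * spec$voxel_size[d]
  })
}

#' Analytic dipole field of a phantom
#'
#' Superposes the external field of each spherical cavity in a uniform main
#' field along Z: off-resonance in Hz at distance `r` and polar angle `theta`
#' from the cavity centre is
#' `(gamma/2pi) * B0 * (dchi/3) * (a/r)^3 * (3*cos(theta)^2 - 1)` for
#' `r >= a`, and 0 inside the cavity (the interior is air and is excluded
#' from the brain mask). Optional Gaussian noise is added with the spec's
#' seed. Overlapping cavities superpose with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return A [field_map()] in Hz with the brain mask attached (cavity
#'   interiors excluded).
#' @export
dipole_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  X <- array(co[[1]], spec$shape)
  Y <- aperm(array(co[[2]], spec$shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co[[3]], spec$shape[c(3, 1, 2)]), c(2, 3, 1))
  f <- array(0, spec$shape)
  inside_any <- array(FALSE, spec$shape)
  if (length(spec$cavities) >= 2) {
    ctr <- t(vapply(spec$cavities, `[[`, numeric(3), "centre"))
    rad <- vapply(spec$cavities, `[[`, numeric(1), "radius")
    dd <- as.matrix(stats::dist(ctr))
    sep <- outer(rad, rad, `+`)
    diag(dd) <- Inf
    if (any(dd < sep)) warning("overlapping cavities: fields superpose")
  }
  for (cv in spec$cavities) {
    dx <- X - cv$centre[1]; dy <- Y - cv$centre[2]; dz <- Z - cv$centre[3]
    r2 <- dx^2 + dy^2 + dz^2
    r2[r2 == 0] <- 1e-12
    cos2 <- dz^2 / r2
    amp <- GAMMA_BAR * spec$b0 * (cv$dchi * 1e-6) / 3
    contrib <- amp * (cv$radius^2 / r2)^1.5 * (3 * cos2 - 1)
    inside <- r2 < cv$radius^2
    contrib[inside] <- 0
    inside_any <- inside_any | inside
    f <- f + contrib
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    f <- f + array(stats::rnorm(prod(spec$shape), 0, spec$noise_sd),
                   spec$shape)
  }
  mask <- phantom_brain_mask(spec) & !inside_any
  field_map(f, voxel_size = spec$voxel_size, mask = mask)
}

#' Brain mask of a phantom
#' @param spec a [phantom_spec()].
#' @return Logical 3D array (ellipsoid; everything if no brain is specified).
#' @export
phantom_brain_mask <- function(spec) {
  if (is.null(spec$brain)) return(array(TRUE, spec$shape))
  co <- phantom_coords(spec)
  X <- array(co[[1]], spec$shape)
  Y <- aperm(array(co[[2]], spec$shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co[[3]], spec$shape[c(3, 1, 2)]), c(2, 3, 1))
  ctr <- spec$brain$centre; ax <- spec$brain$semiaxes
  ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
    ((Z - ctr[3]) / ax[3])^2 <= 1
}

#' ROI label volume of a phantom
#' @param spec a [phantom_spec()].
#' @return A [roi_set()] with consecutive labels in the order of `spec$rois`.
#' @export
phantom_rois <- function(spec) {
  stopifnot(length(spec$rois) >= 1)
  co <- phantom_coords(spec)
  X <- array(co[[1]], spec$shape)
  Y <- aperm(array(co[[2]], spec$shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co[[3]], spec$shape[c(3, 1, 2)]), c(2, 3, 1))
  labels <- array(0L, spec$shape)
  nm <- integer(0)
  for (i in seq_along(spec$rois)) {
    roi <- spec$rois[[i]]
    for (ctr in roi$centres) {
      sel <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= roi$radius^2
      labels[sel] <- i
    }
    nm[roi$name] <- i
  }
  roi_set(labels, nm)
}

#' Default head phantom
#'
#' A 64 x 64 x 48 lattice at 3 mm emulating the susceptibility field structure
#' of a human head at 3 T: two inferior-anterior air cavities (paranasal
#' sinuses) and two inferior-lateral cavities (ear canals / mastoids) with an
#' air-tissue susceptibility difference of 9.4 ppm, an ellipsoidal brain mask,
#' and five labelled ROIs in the orbitofrontal and temporal regions above the
#' cavities. Cavity geometry is chosen so the peak susceptibility-gradient
#' magnitude inside the mask is on the 100 uT/m scale observed over the
#' orbitofrontal and temporal cortex in vivo.
#'
#' @param noise_sd additive field noise, Hz (default 0).
#' @param seed reproducibility seed.
#' @return A [phantom_spec()].
#' @export
default_head_phantom <- function(noise_sd = 0, seed = 1L) {
  phantom_spec(
    shape = c(64, 64, 48), voxel_size = 3, b0 = 3,
    cavities = list(
      list(centre = c(-13, 62, -54), radius = 11, dchi = 9.4),
      list(centre = c(13, 62, -54), radius = 11, dchi = 9.4),
      list(centre = c(-70, -6, -48), radius = 10, dchi = 9.4),
      list(centre = c(70, -6, -48), radius = 10, dchi = 9.4)
    ),
    brain = list(centre = c(0, 2, 8), semiaxes = c(68, 82, 52)),
    rois = list(
      list(name = "mOFC", centres = list(c(0, 50, -22)), radius = 10),
      list(name = "inferior-temporal",
           centres = list(c(-46, -6, -18), c(46, -6, -18)), radius = 9),
      list(name = "temporal-pole",
           centres = list(c(-40, 28, -18), c(40, 28, -18)), radius = 8),
      list(name = "amygdala",
           centres = list(c(-22, 16, -16), c(22, 16, -16)), radius = 7),
      list(name = "hippocampus",
           centres = list(c(-28, -18, -16), c(28, -18, -16)), radius = 8)
    ),
    noise_sd = noise_sd, seed = seed
  )
}

#' Generate a cohort of jittered phantom field maps
#'
#' Stands in for a multi-subject field-map database: each subject's map is the
#' phantom with cavity centres and radii perturbed by seeded Gaussian jitter,
#' on identical (co-registered) geometry.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects, >= 1.
#' @param jitter relative perturbation scale (fraction of each radius for
#'   centres, of each radius for radii). `0` yields identical maps.
#' @return List of [field_map()] objects.
#' @export
make_cohort <- function(spec, n_subjects, jitter = 0.05) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1, jitter >= 0)
  set.seed(spec$seed)
  lapply(seq_len(n_subjects), function(s) {
    sp <- spec
    sp$cavities <- lapply(spec$cavities, function(cv) {
      cv$centre <- cv$centre + stats::rnorm(3, 0, jitter * cv$radius)
      cv$radius <- cv$radius * (1 + stats::rnorm(1, 0, jitter))
      cv
    })
    ## distinct (but spec-seeded) noise realisation per subject
    sp$seed <- spec$seed + s
    dipole_field(sp)
  })
}

#' Mirror a field map left-right
#'
#' Flips the volume along the lattice axis mapped to the scanner X axis
#' (right-left). Under this mirror the X component of the gradient field flips
#' sign voxel-wise while Y and Z components are preserved, which is the
#' transformation behind the left-right antisymmetry of sagittal z-shim
#' optima.
#'
#' @param map a [field_map()].
#' @return The mirrored [field_map()].
#' @export
mirror_lr <- function(map) {
  stopifnot(inherits(map, "field_map"))
  j <- which(sub("^-", "", map$axes) == "x")
  idx <- rep(list(quote(expr = )), 3)
  idx[[j]] <- rev(seq_len(dim(map$values)[j]))
  flip <- function(a) do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  out <- map
  out$values <- flip(map$values)
  if (!is.null(map$mask)) out$mask <- flip(map$mask)
  out
}

#' Synthetic validation field map for closed-loop EPI simulation
#'
#' Builds a field map designed for comparing simulated and
#' phase-difference-estimated BS: within each phase-encode column the field is
#' exactly linear, with the PE-direction slope varying smoothly across columns
#' and a small through-plane component. For a column-constant PE gradient the
#' EPI distortion is a uniform per-column stretch, so voxel-wise comparison of
#' gain maps is not confounded by misregistration. Labelled `synthetic`: this
#' is a constructed stand-in for in-vivo validation field maps.
#'
#' @param protocol an [epi_protocol()] (transverse); the PE-axis length of the
#'   lattice equals the protocol's acquired line count.
#' @param n_ro,n_sl lattice size along the readout and slice axes.
#' @param gpe_max peak PE-direction gradient magnitude, uT/m.
#' @param gsl_max peak slice-direction gradient magnitude, uT/m.
#' @return A [field_map()] with an interior object mask.
#' @export
validation_field_map <- function(protocol, n_ro = 32, n_sl = 12,
                                 gpe_max = 40, gsl_max = 15) {
  stopifnot(protocol$orientation == "transverse")
  er <- effective_readout(protocol)
  n_pe <- er$acquired_lines
  shape <- c(n_ro, n_pe, n_sl)  # lattice: x (RO), y (PE), z (SL)
  vox <- c(protocol$res_ro, protocol$res_pe, protocol$slice_thickness) * 1e3
  xs <- (seq_len(n_ro) - (n_ro + 1) / 2) * vox[1]
  ys <- (seq_len(n_pe) - (n_pe + 1) / 2) * vox[2]
  zs <- (seq_len(n_sl) - (n_sl + 1) / 2) * vox[3]
  ## slopes in Hz/mm: gpe_max uT/m corresponds to gpe_max / 23.49 Hz/mm.
  ## Triangle-wave profiles across readout columns keep the incidental
  ## readout-direction gradient (d2f/dxdy * y) small and constant, well below
  ## the echo-loss threshold: the 1D forward simulator does not encode RO, so
  ## the validation field must not trigger the model's RO dropout.
  to_hzmm <- function(g) g / hz_per_mm_to_uT_per_m(1)
  tri <- function(t) 4 * abs(t - floor(t) - 0.5) - 1
  tt <- (seq_len(n_ro) - 1) / n_ro
  a <- to_hzmm(gpe_max) * tri(tt)           # d f / dy per column
  b <- to_hzmm(gsl_max) * tri(tt + 0.25)    # d f / dz per column
  f <- array(0, shape)
  for (i in seq_len(n_ro)) {
    f[i, , ] <- outer(a[i] * ys, b[i] * zs, `+`)
  }
  ## the simulated object fills the PE field of view (the EPI encoding is
  ## periodic, so a full-FoV object has no edges to ring or to be displaced);
  ## the mask marks the interior region valid for voxel-wise comparison,
  ## keeping clear of the PE boundary where wrapped content carries the
  ## opposite edge's off-resonance
  margin <- max(8L, ceiling(n_pe / 6))
  mask <- array(FALSE, shape)
  mask[, (margin + 1):(n_pe - margin), ] <- TRUE
  field_map(f, voxel_size = vox, mask = mask)
}
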