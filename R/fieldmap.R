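#' Construct a B0 field map
#'
#' A scalar 3D lattice of off-resonance values in Hz together with its
#' geometry: voxel size in mm and the mapping of lattice axes to the scanner
#' frame (X = right-left, Y = posterior-anterior, Z = head-feet), given as a
#' signed permutation such as `c("x","y","z")` or `c("-y","x","z")`.
#'
#' @param values 3D numeric array, Hz.
#' @param voxel_size length-3 positive numeric, mm.
#' @param axes signed axis labels, a permutation of `"x"`, `"y"`, `"z"` with
#'   optional `"-"` prefixes.
#' @param mask optional logical array of the same dimension; values must be
#'   finite inside the mask.
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, voxel_size, axes = c("x", "y", "z"),
                      mask = NULL) {
  if (length(dim(values)) != 3) stop("values must be a 3D array", call. = FALSE)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be three positive numbers (mm)", call. = FALSE)
  }
  axes_matrix(axes, voxel_size)  # validates the signed permutation
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values))) {
      stop("mask geometry mismatch", call. = FALSE)
    }
    mask <- array(as.logical(mask), dim(mask))
    if (any(!is.finite(values[mask]))) {
      stop("non-finite field values inside mask", call. = FALSE)
    }
  }
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 axes = axes, mask = mask),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field_map> %d x %d x %d @ %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], paste(x$axes, collapse = ",")))
  v <- if (is.null(x$mask)) x$values else x$values[x$mask]
  cat(sprintf("  range %.4g .. %.4g Hz%s\n", min(v), max(v),
              if (is.null(x$mask)) "" else
                sprintf(" in mask (%d voxels)", sum(x$mask))))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$values %||% a$gx), dim(b$values %||% b$gx)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-9)) &&
    identical(a$axes, b$axes)
}

wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

## 3D region-growing phase unwrapping (6-connected BFS) of an already wrapped
## volume, started from `seed` (linear index). Each voxel is adjusted by the
## multiple of 2*pi that brings it within pi of the neighbour it was grown
## from. Pure R; intended for the modest volumes of field-map estimation.
unwrap_region_grow <- function(wrapped, mask, seed) {
  dims <- dim(wrapped)
  n <- prod(dims)
  out <- wrapped
  visited <- !mask          # never visit voxels outside the mask
  queue <- integer(n)
  head <- 1L; tail <- 1L
  queue[tail] <- seed; tail <- tail + 1L
  visited[seed] <- TRUE
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  while (head < tail) {
    cur <- queue[head]; head <- head + 1L
    k <- (cur - 1L) %/% (nx * ny)
    r <- (cur - 1L) %% (nx * ny)
    j <- r %/% nx
    i <- r %% nx
    val <- out[cur]
    for (d in 1:6) {
      ii <- i; jj <- j; kk <- k
      if (d == 1L) ii <- i - 1L else if (d == 2L) ii <- i + 1L
      else if (d == 3L) jj <- j - 1L else if (d == 4L) jj <- j + 1L
      else if (d == 5L) kk <- k - 1L else kk <- k + 1L
      if (ii < 0L || ii >= nx || jj < 0L || jj >= ny || kk < 0L || kk >= nz)
        next
      nb <- 1L + ii + nx * (jj + ny * kk)
      if (visited[nb]) next
      visited[nb] <- TRUE
      out[nb] <- out[nb] - 2 * pi * round((out[nb] - val) / (2 * pi))
      queue[tail] <- nb; tail <- tail + 1L
    }
  }
  out
}

#' Estimate a field map from double-echo phase data
#'
#' Computes the off-resonance field from two phase volumes acquired at
#' different echo times: the wrapped phase difference is spatially unwrapped by
#' 3D region growing (6-connected, breadth-first from the most reliable voxel)
#' and divided by `2*pi*(te_long - te_short)`. The unambiguous range before
#' unwrapping is `+/- 1/(2*dTE)` Hz.
#'
#' @param phase_short,phase_long [field_map()] objects holding phase volumes in
#'   radians at the short and long echo time; identical geometry required.
#' @param te_short,te_long echo times in seconds, `te_long > te_short`.
#' @param magnitude optional [field_map()] of signal magnitude; the unwrapping
#'   seed is its maximum inside the mask (defaulting to the mask centroid
#'   voxel otherwise).
#' @param mask optional logical array restricting the unwrapping region;
#'   defaults to the mask of `phase_short`, else the full volume.
#' @return A [field_map()] in Hz.
#' @export
fieldmap_from_double_echo <- function(phase_short, phase_long, te_short,
                                      te_long, magnitude = NULL, mask = NULL) {
  stopifnot(inherits(phase_short, "field_map"), inherits(phase_long, "field_map"))
  if (te_long <= te_short) stop("te_long must exceed te_short", call. = FALSE)
  if (!same_geometry(phase_short, phase_long)) {
    stop("phase volumes have mismatching geometry", call. = FALSE)
  }
  dte <- te_long - te_short
  d <- wrap_phase(phase_long$values - phase_short$values)
  mask <- mask %||% phase_short$mask %||% array(TRUE, dim(d))
  mask <- array(as.logical(mask), dim(d))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  seed <- if (!is.null(magnitude)) {
    which(mask & magnitude$values == max(magnitude$values[mask]))[1]
  } else {
    ## voxel of the mask closest to the mask centroid
    ind <- which(mask)
    sub <- arrayInd(ind, dim(d))
    ctr <- colMeans(sub)
    ind[which.min(rowSums(sweep(sub, 2, ctr)^2))]
  }
  unwrapped <- unwrap_region_grow(d, mask, seed)
  field_map(unwrapped / (2 * pi * dte), voxel_size = phase_short$voxel_size,
            axes = phase_short$axes, mask = phase_short$mask)
}

## derivative along the first array dimension, spacing h: central differences
## on the interior, one-sided at the two edges
diff_first_dim <- function(a, h) {
  dims <- dim(a)
  n <- dims[1]
  m <- matrix(a, nrow = n)
  res <- matrix(NA_real_, n, ncol(m))
  if (n >= 3) res[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                                     m[1:(n - 2), , drop = FALSE]) / (2 * h)
  res[1, ] <- (m[2, ] - m[1, ]) / h
  res[n, ] <- (m[n, ] - m[n - 1, ]) / h
  array(res, dims)
}

lattice_derivative <- function(values, voxel_size, axis) {
  if (dim(values)[axis] < 2) {
    stop("cannot differentiate along singleton dimension ", axis,
         call. = FALSE)
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(values, perm)
  d <- diff_first_dim(a, voxel_size[axis])
  aperm(d, order(perm))
}

#' Susceptibility gradient field from a field map
#'
#' Differentiates the off-resonance field numerically (spacing-aware central
#' differences on interior voxels, one-sided at edges) and converts the result
#' from Hz/mm to scanner-frame gradient components in uT/m via
#' `G = (2*pi/gamma) * df/dr` with `gamma = 2.6753e8 rad/s/T`.
#'
#' @param map a [field_map()] in Hz.
#' @param erode_mask if `TRUE` and the map carries a mask, the output mask is
#'   eroded by one voxel (6-neighbourhood) to flag the less reliable one-sided
#'   boundary estimates.
#' @return An object of class `gradient_field` with components `gx`, `gy`,
#'   `gz` (uT/m, scanner frame) sharing the map's geometry.
#' @export
gradient_field <- function(map, erode_mask = FALSE) {
  stopifnot(inherits(map, "field_map"))
  comp <- list(x = NULL, y = NULL, z = NULL)
  for (j in 1:3) {
    d <- lattice_derivative(map$values, map$voxel_size, j)  # Hz/mm
    ax <- map$axes[j]
    sgn <- if (startsWith(ax, "-")) -1 else 1
    letter <- sub("^-", "", ax)
    comp[[letter]] <- sgn * hz_per_mm_to_uT_per_m(d)
  }
  mask <- map$mask
  if (erode_mask && !is.null(mask)) mask <- erode3d(mask)
  structure(list(gx = comp$x, gy = comp$y, gz = comp$z,
                 voxel_size = map$voxel_size, axes = map$axes, mask = mask),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  d <- dim(x$gx)
  g <- sqrt(x$gx^2 + x$gy^2 + x$gz^2)
  if (!is.null(x$mask)) g <- g[x$mask]
  cat(sprintf("<gradient_field> %d x %d x %d @ %.3g mm | peak |G| %.4g uT/m\n",
              d[1], d[2], d[3], x$voxel_size[1], max(g)))
  invisible(x)
}

erode3d <- function(mask) {
  dims <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- dims[axis]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[axis]] <- src
    res <- do.call(`[`, c(list(m), idx, list(drop = FALSE)))
    ## out-of-range neighbours count as outside the mask
    edge <- rep(list(quote(expr = )), 3)
    edge[[axis]] <- if (by > 0) n else 1L
    res <- do.call(`[<-`, c(list(res), edge, list(value = FALSE)))
    res
  }
  for (axis in 1:3) {
    out <- out & shift(mask, axis, 1L) & shift(mask, axis, -1L)
  }
  out
}

#' Voxel-wise average of co-registered maps
#'
#' Arithmetic mean over a list of [field_map()] or [gradient_field()] objects
#' with identical geometry. Voxels where any input is non-finite are set to
#' `NA`; the output mask is the intersection of the input masks.
#'
#' @param maps non-empty list of maps of one class.
#' @return A map of the same class.
#' @export
average_maps <- function(maps) {
  if (!is.list(maps) || length(maps) < 1) stop("need >= 1 map", call. = FALSE)
  cls <- class(maps[[1]])[1]
  if (!all(vapply(maps, function(m) inherits(m, cls), logical(1)))) {
    stop("all maps must share one class", call. = FALSE)
  }
  for (m in maps[-1]) {
    if (!same_geometry(maps[[1]], m)) stop("geometry mismatch", call. = FALSE)
  }
  masks <- lapply(maps, `[[`, "mask")
  mask <- NULL
  if (any(!vapply(masks, is.null, logical(1)))) {
    mask <- Reduce(`&`, lapply(masks, function(m) {
      m %||% array(TRUE, dim(maps[[1]]$values %||% maps[[1]]$gx))
    }))
  }
  mean_arrays <- function(arrs) {
    s <- Reduce(`+`, arrs)
    ok <- Reduce(`&`, lapply(arrs, is.finite))
    s[!ok] <- NA_real_
    s / length(arrs)
  }
  if (cls == "field_map") {
    out <- field_map(mean_arrays(lapply(maps, `[[`, "values")),
                     voxel_size = maps[[1]]$voxel_size, axes = maps[[1]]$axes)
    out$mask <- mask
    out
  } else if (cls == "gradient_field") {
    structure(list(gx = mean_arrays(lapply(maps, `[[`, "gx")),
                   gy = mean_arrays(lapply(maps, `[[`, "gy")),
                   gz = mean_arrays(lapply(maps, `[[`, "gz")),
                   voxel_size = maps[[1]]$voxel_size, axes = maps[[1]]$axes,
                   mask = mask),
              class = "gradient_field")
  } else {
    stop("unsupported map class: ", cls, call. = FALSE)
  }
}
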