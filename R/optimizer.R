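#' Define a set of regions of interest
#'
#' An integer label volume co-registered to the gradient field plus a
#' label-to-name table.
#'
#' @param labels 3D array of non-negative integer labels (0 = background).
#' @param names named integer vector (`name = label`) or data.frame with
#'   columns `label`, `name`. Every named label must occur in the volume.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, names) {
  stopifnot(length(dim(labels)) == 3)
  labels <- array(as.integer(round(labels)), dim(labels))
  if (any(labels < 0, na.rm = TRUE)) stop("labels must be non-negative")
  if (is.data.frame(names)) {
    tab <- stats::setNames(as.integer(names$label), as.character(names$name))
  } else {
    tab <- stats::setNames(as.integer(names), base::names(names))
  }
  if (is.null(base::names(tab)) || any(base::names(tab) == "")) {
    stop("every ROI label needs a name")
  }
  present <- unique(as.vector(labels))
  missing <- tab[!tab %in% present]
  if (length(missing)) {
    stop("named labels absent from volume: ",
         paste(base::names(missing), collapse = ", "))
  }
  structure(list(labels = labels, names = tab), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs: %s\n", length(x$names),
              paste(base::names(x$names), collapse = ", ")))
  invisible(x)
}

## Internal: masked gradient vectors and a per-parameter-set BS evaluator with
## a per-tilt projection cache. The evaluator routes every computation through
## bs_relative() so streamed optimization is numerically identical to direct
## voxel_bs() calls.
make_bs_evaluator <- function(gradfield, protocol, config) {
  stopifnot(inherits(gradfield, "gradient_field"))
  finite <- is.finite(gradfield$gx) & is.finite(gradfield$gy) &
    is.finite(gradfield$gz)
  mask <- (gradfield$mask %||% array(TRUE, dim(gradfield$gx))) & finite
  idx <- which(mask)
  if (length(idx) == 0) stop("gradient field has no usable voxels")
  G <- cbind(gradfield$gx[idx], gradfield$gy[idx], gradfield$gz[idx])
  proj_cache <- new.env(parent = emptyenv())
  project <- function(tilt) {
    key <- format(tilt, digits = 12)
    p <- proj_cache[[key]]
    if (is.null(p)) {
      frame <- tilt_frame(canonical_frame(protocol$orientation), tilt)
      p <- project_gradient(G, frame)
      proj_cache[[key]] <- p
    }
    p
  }
  list(
    mask = mask, idx = idx, n = length(idx), dims = dim(gradfield$gx),
    bs = function(zshim, tilt, polarity) {
      p <- project(tilt)
      bs_relative(p[, "g_ro"], p[, "g_pe"], p[, "g_sl"], protocol,
                  zshim = zshim, polarity = polarity, config = config)$bs
    }
  )
}

feasible_sets <- function(sets, protocol, config, max_loss) {
  loss <- vapply(sets$zshim, function(m) {
    wellshimmed_loss(adjustable_params(zshim = m), protocol, config)
  }, numeric(1))
  sets$wellshimmed_loss <- loss
  sets[loss <= max_loss + 1e-12, , drop = FALSE]
}

#' Evaluate the BS over a full parameter grid
#'
#' Computes the relative BS of every masked voxel for every parameter set of
#' the grid (enumerated in the deterministic tie-break order of
#' [param_sets()]). For small problems the full stack is returned densely;
#' beyond `max_dense_elements` the result is lazy and rows are computed on
#' demand.
#'
#' @param gradfield a [gradient_field()].
#' @param protocol an [epi_protocol()].
#' @param grid a [build_grid()].
#' @param config a [bs_config()].
#' @param max_dense_elements memory guard: the dense matrix is only
#'   materialised when `n_sets * n_voxels` does not exceed this bound.
#' @return An object of class `bs_grid_eval`: list with `sets` (data.frame),
#'   `mask`, `eval(i)` returning the BS vector of set `i`, and `bs` (the dense
#'   `n_sets x n_voxels` matrix, or `NULL` when lazy).
#' @export
evaluate_grid <- function(gradfield, protocol, grid, config = bs_config(),
                          max_dense_elements = 2^24) {
  ev <- make_bs_evaluator(gradfield, protocol, config)
  sets <- param_sets(grid)
  eval_i <- function(i) {
    ev$bs(sets$zshim[i], sets$tilt[i], sets$polarity[i])
  }
  dense <- nrow(sets) * ev$n <= max_dense_elements
  bs <- NULL
  if (dense) {
    bs <- matrix(NA_real_, nrow(sets), ev$n)
    for (i in seq_len(nrow(sets))) bs[i, ] <- eval_i(i)
  }
  structure(list(sets = sets, mask = ev$mask, n_voxels = ev$n,
                 eval = eval_i, bs = bs, dense = dense),
            class = "bs_grid_eval")
}

fill_volume <- function(values, idx, dims) {
  v <- array(NA_real_, dims)
  v[idx] <- values
  v
}

#' Voxel-wise BS optimization
#'
#' Exhaustive search over the parameter grid for the set maximising the BS of
#' each voxel independently, restricted to parameter sets whose well-shimmed
#' BS loss does not exceed `max_loss` (the constraint depends only on the
#' z-shim moment, so infeasible sets are excluded up front). Ties are broken
#' deterministically: smallest |zshim|, then smallest |tilt|, then positive
#' polarity (positive values before negative at equal magnitude).
#'
#' @param gradfield a [gradient_field()].
#' @param protocol an [epi_protocol()].
#' @param grid a [build_grid()]; must contain the reference point
#'   (zshim 0, tilt 0, positive polarity).
#' @param config a [bs_config()].
#' @param max_loss well-shimmed loss bound, default 0.15.
#' @param display_gain_threshold optional percent threshold; when given, a
#'   logical `display_mask` marking voxels with gain at or above it is added
#'   (the conventional reporting mask is 20).
#' @return An object of class `bs_voxel_optimum`: list with 3D arrays
#'   `zshim`, `tilt`, `polarity` (+1 positive / -1 negative), `bs_opt`,
#'   `bs_ref`, `gain` (percent), optional `display_mask`, plus `mask`,
#'   `voxel_size`, `axes` and the feasible `sets`.
#' @export
optimize_voxelwise <- function(gradfield, protocol, grid,
                               config = bs_config(), max_loss = 0.15,
                               display_gain_threshold = NULL) {
  if (!has_reference_point(grid)) {
    stop("grid must contain the reference point (0, 0, positive)",
         call. = FALSE)
  }
  ev <- make_bs_evaluator(gradfield, protocol, config)
  sets <- feasible_sets(param_sets(grid), protocol, config, max_loss)
  stopifnot(nrow(sets) >= 1)  # reference point is always feasible
  best_bs <- rep(-Inf, ev$n)
  best_set <- rep(NA_integer_, ev$n)
  for (i in seq_len(nrow(sets))) {
    bs <- ev$bs(sets$zshim[i], sets$tilt[i], sets$polarity[i])
    upd <- bs > best_bs
    best_bs[upd] <- bs[upd]
    best_set[upd] <- i
  }
  bs_ref <- ev$bs(0, 0, "positive")
  gain <- bs_gain(best_bs, bs_ref)
  out <- list(
    zshim = fill_volume(sets$zshim[best_set], ev$idx, ev$dims),
    tilt = fill_volume(sets$tilt[best_set], ev$idx, ev$dims),
    polarity = fill_volume(ifelse(sets$polarity[best_set] == "positive",
                                  1, -1), ev$idx, ev$dims),
    bs_opt = fill_volume(best_bs, ev$idx, ev$dims),
    bs_ref = fill_volume(bs_ref, ev$idx, ev$dims),
    gain = fill_volume(gain, ev$idx, ev$dims),
    mask = ev$mask, voxel_size = gradfield$voxel_size, axes = gradfield$axes,
    sets = sets, max_loss = max_loss
  )
  if (!is.null(display_gain_threshold)) {
    dm <- array(FALSE, ev$dims)
    dm[ev$idx] <- !is.na(gain) & gain >= display_gain_threshold
    out$display_mask <- dm
  }
  structure(out, class = "bs_voxel_optimum")
}

#' @export
print.bs_voxel_optimum <- function(x, ...) {
  g <- x$gain[x$mask]
  cat(sprintf("<bs_voxel_optimum> %d voxels | %d feasible sets | gain %.3g .. %.3g%% (median %.3g%%)\n",
              sum(x$mask), nrow(x$sets), min(g, na.rm = TRUE),
              max(g, na.rm = TRUE), stats::median(g, na.rm = TRUE)))
  invisible(x)
}

roi_indices <- function(rois, mask, idx) {
  lab <- rois$labels[idx]
  lapply(rois$names, function(l) which(lab == l))
}

#' ROI-wise BS optimization
#'
#' For each region of interest, finds the feasible parameter set maximising
#' the mean voxel BS across the ROI (one parameter set per ROI, applied to all
#' slices). Tie-breaking as in [optimize_voxelwise()]. The full gain surface
#' over (tilt, zshim) per polarity is returned for each ROI; the argmax is
#' restricted to feasible sets, but surfaces cover the whole grid.
#'
#' @inheritParams optimize_voxelwise
#' @param rois a [roi_set()] co-registered to the gradient field. ROIs with no
#'   voxel inside the usable mask yield an `NA` row rather than an error.
#' @return An object of class `bs_roi_optimum`: list with `table`
#'   (data.frame: roi, zshim, tilt, polarity, gain, n_voxels,
#'   wellshimmed_loss), `surfaces` (per ROI, per polarity: matrix tilt x
#'   zshim of mean percent gain), `mean_bs` (matrix of mean BS, all grid sets
#'   x ROIs), `sets` (all sets with feasibility flag), and the grid.
#' @export
optimize_roi <- function(gradfield, protocol, grid, rois,
                         config = bs_config(), max_loss = 0.15) {
  stopifnot(inherits(rois, "roi_set"))
  if (!has_reference_point(grid)) {
    stop("grid must contain the reference point (0, 0, positive)",
         call. = FALSE)
  }
  ev <- make_bs_evaluator(gradfield, protocol, config)
  all_sets <- param_sets(grid)
  loss <- vapply(all_sets$zshim, function(m) {
    wellshimmed_loss(adjustable_params(zshim = m), protocol, config)
  }, numeric(1))
  all_sets$wellshimmed_loss <- loss
  all_sets$feasible <- loss <= max_loss + 1e-12
  ridx <- roi_indices(rois, ev$mask, ev$idx)
  n_roi <- length(ridx)
  mean_bs <- matrix(NA_real_, nrow(all_sets), n_roi,
                    dimnames = list(NULL, base::names(rois$names)))
  ref_row <- which(all_sets$zshim == 0 & all_sets$tilt == 0 &
                     all_sets$polarity == "positive")[1]
  for (i in seq_len(nrow(all_sets))) {
    bs <- ev$bs(all_sets$zshim[i], all_sets$tilt[i], all_sets$polarity[i])
    mean_bs[i, ] <- vapply(ridx, function(ix) {
      if (length(ix) == 0) NA_real_ else mean(bs[ix])
    }, numeric(1))
  }
  feas <- which(all_sets$feasible)
  rows <- lapply(seq_len(n_roi), function(r) {
    if (length(ridx[[r]]) == 0 || all(is.na(mean_bs[feas, r]))) {
      return(data.frame(roi = base::names(rois$names)[r], zshim = NA_real_,
                        tilt = NA_real_, polarity = NA_character_,
                        gain = NA_real_, n_voxels = 0L,
                        wellshimmed_loss = NA_real_))
    }
    ## which.max returns the first maximiser, i.e. the winner in tie-break
    ## order since feasible sets are enumerated in that order
    v <- mean_bs[feas, r]
    best <- feas[which.max(v)]
    data.frame(roi = base::names(rois$names)[r],
               zshim = all_sets$zshim[best], tilt = all_sets$tilt[best],
               polarity = all_sets$polarity[best],
               gain = bs_gain(mean_bs[best, r], mean_bs[ref_row, r]),
               n_voxels = length(ridx[[r]]),
               wellshimmed_loss = all_sets$wellshimmed_loss[best])
  })
  surfaces <- lapply(seq_len(n_roi), function(r) {
    lapply(stats::setNames(nm = grid$polarities), function(pol) {
      m <- matrix(NA_real_, length(grid$tilt_values),
                  length(grid$zshim_values),
                  dimnames = list(tilt = grid$tilt_values,
                                  zshim = grid$zshim_values))
      sel <- all_sets$polarity == pol
      ti <- match(all_sets$tilt[sel], grid$tilt_values)
      zi <- match(all_sets$zshim[sel], grid$zshim_values)
      m[cbind(ti, zi)] <- bs_gain(mean_bs[sel, r], mean_bs[ref_row, r])
      m
    })
  })
  base::names(surfaces) <- base::names(rois$names)
  structure(list(table = do.call(rbind, rows), surfaces = surfaces,
                 mean_bs = mean_bs, sets = all_sets, grid = grid,
                 max_loss = max_loss),
            class = "bs_roi_optimum")
}

#' @export
print.bs_roi_optimum <- function(x, ...) {
  cat("<bs_roi_optimum>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cross-ROI impact matrix
#'
#' Quantifies how optimizing the protocol for one ROI affects the BS of the
#' others: entry (i, j) is the mean voxel-wise percent BS gain in ROI j when
#' the parameter set optimal for ROI i is applied. Rows and columns include a
#' Whole-Brain pseudo-ROI (all usable voxels; row optimum maximises the
#' whole-brain mean BS) and a Well-Shimmed pseudo-ROI (a synthetic
#' zero-gradient voxel; its row optimum is the reference set, and its column
#' can lose at most the boundary-condition percentage).
#'
#' @inheritParams optimize_roi
#' @param roi_optima result of [optimize_roi()] on the same inputs.
#' @return Numeric matrix of mean percent gains, rows = optimized-for ROI,
#'   columns = evaluated-in ROI.
#' @export
cross_roi_impact <- function(gradfield, protocol, roi_optima, rois,
                             config = bs_config(), max_loss = 0.15) {
  stopifnot(inherits(roi_optima, "bs_roi_optimum"))
  ev <- make_bs_evaluator(gradfield, protocol, config)
  ridx <- roi_indices(rois, ev$mask, ev$idx)
  ridx$`Whole-Brain` <- seq_len(ev$n)
  ## whole-brain row optimum: maximise mean BS over all usable voxels
  all_sets <- roi_optima$sets
  feas <- which(all_sets$feasible)
  wb_mean <- vapply(feas, function(i) {
    mean(ev$bs(all_sets$zshim[i], all_sets$tilt[i], all_sets$polarity[i]))
  }, numeric(1))
  wb_best <- feas[which.max(wb_mean)]
  params <- rbind(
    roi_optima$table[, c("roi", "zshim", "tilt", "polarity")],
    data.frame(roi = "Whole-Brain", zshim = all_sets$zshim[wb_best],
               tilt = all_sets$tilt[wb_best],
               polarity = all_sets$polarity[wb_best]),
    data.frame(roi = "Well-Shimmed", zshim = 0, tilt = 0,
               polarity = "positive")
  )
  bs_ref <- ev$bs(0, 0, "positive")
  cols <- c(base::names(rois$names), "Whole-Brain", "Well-Shimmed")
  out <- matrix(NA_real_, nrow(params), length(cols),
                dimnames = list(params$roi, cols))
  for (i in seq_len(nrow(params))) {
    if (is.na(params$zshim[i])) next
    bs <- ev$bs(params$zshim[i], params$tilt[i], params$polarity[i])
    g <- bs_gain(bs, bs_ref)
    for (j in seq_along(ridx)) {
      ix <- ridx[[j]]
      out[i, base::names(ridx)[j]] <-
        if (length(ix)) mean(g[ix], na.rm = TRUE) else NA_real_
    }
    ## well-shimmed column: synthetic zero-gradient voxel
    ws <- bs_relative(0, 0, 0, protocol, zshim = params$zshim[i],
                      polarity = params$polarity[i], config = config)$bs
    ws_ref <- bs_relative(0, 0, 0, protocol, config = config)$bs
    out[i, "Well-Shimmed"] <- bs_gain(ws, ws_ref)
  }
  out
}

#' Per-subject optima and generalizability of the group optimum
#'
#' Runs the ROI optimization for each subject's gradient field separately and
#' summarises (a) how often each tilt value (split by PE polarity) and each
#' z-shim value (polarities combined) is optimal across subjects, and (b) the
#' per-subject percent gain achieved by the group-optimal parameter set,
#' reported as mean and standard deviation across subjects.
#'
#' @param gradfields list of co-registered [gradient_field()] objects, one per
#'   subject.
#' @inheritParams optimize_roi
#' @param group_optima optional [optimize_roi()] result providing the group
#'   parameter set per ROI; computed from the averaged gradient fields when
#'   omitted.
#' @return List of class `bs_subject_optima` with `histograms` (per ROI:
#'   data.frames `tilt` (tilt, polarity, count) and `zshim` (zshim, count)),
#'   `gain_table` (roi, zshim, tilt, polarity, gain_mean, gain_sd),
#'   `per_subject` (long data.frame of each subject's optimum per ROI).
#' @export
per_subject_optima <- function(gradfields, protocol, grid, rois,
                               config = bs_config(), max_loss = 0.15,
                               group_optima = NULL) {
  stopifnot(is.list(gradfields), length(gradfields) >= 1)
  if (is.null(group_optima)) {
    group_optima <- optimize_roi(average_maps(gradfields), protocol, grid,
                                 rois, config, max_loss)
  }
  n_sub <- length(gradfields)
  roi_names <- base::names(rois$names)
  per_sub <- vector("list", n_sub)
  gain_at_group <- matrix(NA_real_, n_sub, length(roi_names),
                          dimnames = list(NULL, roi_names))
  for (s in seq_len(n_sub)) {
    opt_s <- optimize_roi(gradfields[[s]], protocol, grid, rois, config,
                          max_loss)
    per_sub[[s]] <- cbind(subject = s, opt_s$table)
    ## gain of the group-optimal set evaluated on this subject
    ref_row <- which(opt_s$sets$zshim == 0 & opt_s$sets$tilt == 0 &
                       opt_s$sets$polarity == "positive")[1]
    for (r in seq_along(roi_names)) {
      gp <- group_optima$table[r, ]
      if (is.na(gp$zshim)) next
      row <- which(opt_s$sets$zshim == gp$zshim &
                     opt_s$sets$tilt == gp$tilt &
                     opt_s$sets$polarity == gp$polarity)[1]
      gain_at_group[s, r] <- bs_gain(opt_s$mean_bs[row, r],
                                     opt_s$mean_bs[ref_row, r])
    }
  }
  per_sub <- do.call(rbind, per_sub)
  histograms <- lapply(stats::setNames(nm = roi_names), function(rn) {
    d <- per_sub[per_sub$roi == rn & !is.na(per_sub$zshim), ]
    tilt_grid <- expand.grid(tilt = grid$tilt_values,
                             polarity = grid$polarities,
                             stringsAsFactors = FALSE)
    tilt_grid$count <- mapply(function(t, p) {
      sum(d$tilt == t & d$polarity == p)
    }, tilt_grid$tilt, tilt_grid$polarity)
    zs <- data.frame(zshim = grid$zshim_values)
    zs$count <- vapply(zs$zshim, function(z) sum(d$zshim == z), numeric(1))
    list(tilt = tilt_grid, zshim = zs)
  })
  gain_table <- data.frame(
    roi = roi_names,
    zshim = group_optima$table$zshim,
    tilt = group_optima$table$tilt,
    polarity = group_optima$table$polarity,
    gain_mean = colMeans(gain_at_group, na.rm = TRUE),
    gain_sd = apply(gain_at_group, 2, stats::sd, na.rm = TRUE)
  )
  rownames(gain_table) <- NULL
  structure(list(histograms = histograms, gain_table = gain_table,
                 per_subject = per_sub, gain_at_group = gain_at_group),
            class = "bs_subject_optima")
}
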