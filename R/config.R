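## Plain-text configuration files: one `key: value` pair per line, `#`
## comments. Units at this boundary are the conventional ones (ms, mm,
## mT/m*ms, degrees); they are converted once at parse time.

#' Read a key-value configuration file
#' @param path file path.
#' @return Named list; values parsed as numeric where possible.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln, call. = FALSE)
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Read an EPI protocol from a config file
#'
#' Recognised keys (units in brackets): `preset` (name, optionally combined
#' with overrides), `te0` \[ms\], `echo_spacing` \[ms\], `matrix_pe`,
#' `matrix_ro`, `res_ro` \[mm\], `res_pe` \[mm\], `slice_thickness` \[mm\],
#' `orientation`, `grappa_factor`, `pe_oversampling` (fraction),
#' `t2star` \[ms\], `partial_fourier` (rejected if true).
#'
#' @param path config file path.
#' @return An [epi_protocol()].
#' @export
read_protocol_config <- function(path) {
  cfg <- read_config(path)
  if (!is.null(cfg$partial_fourier) &&
      !cfg$partial_fourier %in% c("false", "no", 0)) {
    stop("partial-Fourier protocols are rejected (symmetric sampling assumed)",
         call. = FALSE)
  }
  cfg$partial_fourier <- NULL
  if (!is.null(cfg$preset)) {
    preset <- cfg$preset
    cfg$preset <- NULL
    return(do.call(protocol_preset, c(list(name = preset), cfg)))
  }
  do.call(epi_protocol, cfg)
}

#' Read a parameter grid from a config file
#'
#' Keys: `zshim_min`, `zshim_max`, `zshim_step` \[mT/m*ms\], `tilt_min`,
#' `tilt_max`, `tilt_step` \[degrees\], `polarities` (`both`, `positive` or
#' `negative`). Missing keys fall back to the default search space.
#'
#' @param path config file path.
#' @return A [build_grid()] object.
#' @export
read_grid_config <- function(path) {
  cfg <- read_config(path)
  pol <- switch(cfg$polarities %||% "both",
                both = c("positive", "negative"),
                positive = "positive", negative = "negative",
                stop("polarities must be both/positive/negative"))
  build_grid(
    zshim_range = c(cfg$zshim_min %||% -5, cfg$zshim_max %||% 5),
    zshim_step = cfg$zshim_step %||% 0.5,
    tilt_range = c(cfg$tilt_min %||% -45, cfg$tilt_max %||% 45),
    tilt_step = cfg$tilt_step %||% 5,
    polarities = pol
  )
}

resolve_protocol <- function(protocol, orientation = NULL) {
  if (inherits(protocol, "epi_protocol")) return(protocol)
  if (is.character(protocol) && file.exists(protocol)) {
    return(read_protocol_config(protocol))
  }
  if (is.character(protocol)) {
    if (is.null(orientation)) return(protocol_preset(protocol))
    return(protocol_preset(protocol, orientation = orientation))
  }
  stop("protocol must be an epi_protocol, a preset name or a config path",
       call. = FALSE)
}

resolve_grid <- function(grid) {
  if (is.null(grid)) return(build_grid())
  if (inherits(grid, "param_grid")) return(grid)
  if (is.character(grid) && file.exists(grid)) return(read_grid_config(grid))
  stop("grid must be a param_grid, a config path, or NULL for defaults",
       call. = FALSE)
}
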