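# Pressure post-processing.  "Pressure" is the hydrostatic part of the
# Cauchy stress with COMPRESSION POSITIVE: p = -tr(sigma)/3.  The opposite
# sign convention is also common; this one matches separate
# max-compression / max-traction reporting.  Internal stresses are MPa;
# reported pressures are converted to Pa exactly once, here.

MPA_TO_PA <- 1e6

#' Hydrostatic element pressure
#'
#' p = -(s11 + s22 + s33)/3; compression positive, traction negative.
#'
#' @param stress 3 x 3 stress tensor, or a Voigt row
#'   (xx, yy, zz, xy, yz, xz), or an n x 6 Voigt matrix (MPa).
#' @return Pressure (same units as the input stress).
#' @export
element_pressure <- function(stress) {
  if (is.matrix(stress) && ncol(stress) == 3L && nrow(stress) == 3L)
    return(-sum(diag(stress)) / 3)
  if (is.matrix(stress) && ncol(stress) == 6L)
    return(-(stress[, 1L] + stress[, 2L] + stress[, 3L]) / 3)
  if (length(stress) == 6L)
    return(-(stress[1L] + stress[2L] + stress[3L]) / 3)
  stop("stress must be a 3x3 tensor or Voigt-6 row(s)")
}

region_elements <- function(result, region) {
  mesh <- result$case$mesh
  if (is.character(region)) {
    sel <- which(mesh$part %in% region)
    if (!length(sel)) stop("no elements in region '", region, "'")
  } else {
    sel <- as.integer(region)
    if (!length(sel)) stop("empty element selection")
  }
  sel
}

#' Per-step pressure envelope and average over a region
#'
#' Minimum, maximum and volume-weighted mean element pressure over the
#' region at every converged step, in Pa.
#'
#' @param result A `field_result`.
#' @param region Part name(s) or element index vector.
#' @return A `pressure_curve_set`: data frame (step, min, mean, max) in Pa
#'   with the region name attached.
#' @export
region_envelope <- function(result, region) {
  sel <- region_elements(result, region)
  vols <- result$case$mesh$volumes[sel]
  rows <- lapply(seq_len(result$steps_completed), function(s) {
    p <- element_pressure(result$stress[[s]][sel, , drop = FALSE]) * MPA_TO_PA
    data.frame(step = s, min = min(p), mean = sum(p * vols) / sum(vols),
               max = max(p))
  })
  out <- do.call(rbind, rows)
  structure(out, region = if (is.character(region))
    paste(region, collapse = "+") else "custom",
    class = c("pressure_curve_set", "data.frame"))
}

#' Maximum compression and traction over a region
#'
#' Maximum positive pressure (compression) and maximum magnitude of
#' negative pressure (traction) over all steps and region elements.
#'
#' @param result A `field_result`.
#' @param region Part name(s) or element index vector.
#' @return Named numeric: `max_compression`, `max_traction` (Pa, both >= 0).
#' @export
max_compression_traction <- function(result, region) {
  sel <- region_elements(result, region)
  comp <- 0; trac <- 0
  for (s in seq_len(result$steps_completed)) {
    p <- element_pressure(result$stress[[s]][sel, , drop = FALSE]) * MPA_TO_PA
    comp <- max(comp, p)
    trac <- max(trac, -p)
  }
  c(max_compression = max(comp, 0), max_traction = max(trac, 0))
}

#' Write pressure curves as delimited text
#' @param curves A `pressure_curve_set`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_pressure_curves <- function(curves, file) {
  utils::write.table(as.data.frame(curves), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot a pressure envelope
#' @param x A `pressure_curve_set`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, x.
#' @export
plot.pressure_curve_set <- function(x, ...) {
  graphics::plot(x$step, x$max, type = "l", lty = 2,
                 ylim = range(c(x$min, x$max)),
                 xlab = "load step", ylab = "pressure (Pa)",
                 main = paste("Pressure envelope:", attr(x, "region")), ...)
  graphics::lines(x$step, x$min, lty = 2)
  graphics::lines(x$step, x$mean, lwd = 2)
  invisible(x)
}

#' Write a solved case as a VTU time series
#'
#' One file per converged step with displacement vectors, per-element
#' pressure (Pa) and part ids.
#'
#' @param result A `field_result`.
#' @param dir Output directory.
#' @param basename File prefix.
#' @return Invisibly, the written paths.
#' @export
write_result_series <- function(result, dir, basename = "step") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mesh <- result$case$mesh
  paths <- character(0)
  for (s in seq_len(result$steps_completed)) {
    p <- element_pressure(result$stress[[s]]) * MPA_TO_PA
    u <- matrix(result$u[[s]], ncol = 3L, byrow = TRUE)
    f <- file.path(dir, sprintf("%s_%03d.vtu", basename, s))
    write_vtu(mesh, f, cell_data = list(pressure_Pa = p),
              point_data = list(displacement_mm = u))
    paths <- c(paths, f)
  }
  invisible(paths)
}
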