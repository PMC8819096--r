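# Experimental SLIL stiffness: linear stiffness from uniaxial
# load-displacement curves, summary statistics, literature comparison, and
# a synthetic curve generator for testing the fitting procedure.

#' Load-displacement curve
#' @param displacement Strictly increasing displacement samples (mm).
#' @param force Force samples (N), same length.
#' @param id Sample identifier.
#' @param metadata Optional list (e.g. donor age/sex).
#' @return A `load_displacement_curve`.
#' @export
load_displacement_curve <- function(displacement, force, id = "sample",
                                    metadata = list()) {
  if (length(displacement) != length(force))
    stop("displacement and force must have the same length")
  if (any(diff(displacement) <= 0))
    stop("displacement must be strictly increasing")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force), id = id, metadata = metadata),
            class = "load_displacement_curve")
}

#' @export
print.load_displacement_curve <- function(x, ...) {
  cat(sprintf("load_displacement_curve '%s': %d samples, d in [%.3g, %.3g] mm\n",
              x$id, length(x$displacement), min(x$displacement),
              max(x$displacement)))
  invisible(x)
}

#' The six measured SLIL stiffness values
#'
#' Linear stiffness (N/mm) of the six tested cadaveric scapholunate
#' interosseous ligament samples.
#'
#' @return Numeric vector of length 6.
#' @export
slil_stiffness_samples <- function() c(111.38, 24.44, 114.12, 35.36, 90.29, 53.44)

#' Fit linear stiffness from a load-displacement curve
#'
#' Ordinary least-squares slope of force versus displacement over a window
#' of the displacement range.  The default window covers the upper 60% of
#' the range, skipping the nonlinear toe region.
#'
#' @param curve A `load_displacement_curve`.
#' @param window Numeric `c(lo, hi)` fractions of the displacement range
#'   (default `c(0.4, 1)`).
#' @return Stiffness k (N/mm).
#' @export
fit_linear_stiffness <- function(curve, window = c(0.4, 1)) {
  d <- curve$displacement; f <- curve$force
  lo <- min(d) + window[1L] * diff(range(d))
  hi <- min(d) + window[2L] * diff(range(d))
  sel <- d >= lo & d <= hi
  if (sum(sel) < 3L)
    stop("fit window selects fewer than 3 samples")
  unname(stats::coef(stats::lm(f[sel] ~ d[sel]))[2L])
}

#' Summarize per-sample stiffness values
#'
#' @param values Numeric vector of per-sample stiffnesses (N/mm), length >= 2.
#' @return A `stiffness_summary`: values, `mean`, `sd` (sample, n-1
#'   denominator), and the same rounded to 2 decimals for reporting.
#' @export
summarize_stiffness <- function(values) {
  if (length(values) < 2L) stop("need at least 2 stiffness values")
  m <- mean(values); s <- stats::sd(values)
  structure(list(values = values, mean = m, sd = s,
                 mean_report = round(m, 2), sd_report = round(s, 2)),
            class = "stiffness_summary")
}

#' @export
print.stiffness_summary <- function(x, ...) {
  cat(sprintf("stiffness_summary: n = %d, mean/sd = %.2f/%.2f N/mm\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Literature stiffness table
#'
#' Reported SLIL linear stiffness values or ranges (N/mm) from the
#' comparison literature, plus the pooled mean/sd printed alongside them
#' (65.50/34.70; consistent with the midpoint-of-ranges mean, stored as a
#' reference constant because its exact derivation is ambiguous).
#'
#' @return List: `table` (study, lo, hi), `pooled_mean`, `pooled_sd`.
#' @export
literature_stiffness <- function() {
  list(table = data.frame(
    study = c("Nikolopoulos", "Wayne and Tremols", "Eschweiler"),
    lo = c(25, 66, 50), hi = c(36, 66, 150)),
    pooled_mean = 65.50, pooled_sd = 34.70)
}

#' Compare a stiffness summary to literature ranges
#'
#' A point literature value is treated as a degenerate closed range, so a
#' mean equal to it counts as inside.
#'
#' @param summary A `stiffness_summary`.
#' @param literature From [literature_stiffness()].
#' @return Data frame: study, lo, hi, inside (closed-interval test for the
#'   experimental mean), with the pooled constants as attributes.
#' @export
compare_to_literature <- function(summary, literature = literature_stiffness()) {
  tab <- literature$table
  tab$inside <- summary$mean >= tab$lo & summary$mean <= tab$hi
  attr(tab, "pooled_mean") <- literature$pooled_mean
  attr(tab, "pooled_sd") <- literature$pooled_sd
  attr(tab, "experimental_mean") <- summary$mean
  tab
}

#' Synthesize a load-displacement curve with toe region and noise
#'
#' Deterministic for a fixed seed.  The noiseless curve is a smooth toe
#' (quadratic in displacement, C1-continuous into the linear branch) up to
#' `toe_extent`, then exactly linear with slope `k_true`:
#' F = k d^2 / (2 t) for d < t, F = k (d - t/2) beyond.
#'
#' @param k_true True linear-region slope (N/mm), positive.
#' @param noise_sd Gaussian force noise (N).
#' @param toe_extent Toe-region length (mm), >= 0.
#' @param n Number of samples (>= 10).
#' @param seed Integer seed.
#' @param d_max Maximum displacement (mm).
#' @return A `load_displacement_curve`.
#' @export
synthesize_curve <- function(k_true, noise_sd = 0, toe_extent = 0, n = 50L,
                             seed = 1L, d_max = 2) {
  if (!is.numeric(k_true) || k_true <= 0) stop("k_true must be positive")
  if (n < 10L) stop("need n >= 10 samples")
  if (noise_sd < 0 || toe_extent < 0) stop("invalid parameters")
  if (toe_extent >= d_max) stop("toe_extent must be below d_max")
  d <- seq(0, d_max, length.out = n)
  f0 <- ifelse(d < toe_extent & toe_extent > 0,
               k_true * d^2 / (2 * toe_extent),
               k_true * (d - toe_extent / 2))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  f <- f0 + stats::rnorm(n, 0, noise_sd)
  load_displacement_curve(d, f, id = sprintf("synthetic_k%.4g_seed%d", k_true,
                                             as.integer(seed)))
}

#' Read / write load-displacement curves as delimited text
#'
#' One-line header `displacement_mm<TAB>force_N`.
#'
#' @param curve A `load_displacement_curve`.
#' @param file Path.
#' @return `write_curve`: invisibly the path; `read_curve`: the curve.
#' @export
write_curve <- function(curve, file) {
  utils::write.table(data.frame(displacement_mm = curve$displacement,
                                force_N = curve$force),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_curve
#' @param id Sample id for the curve read back.
#' @export
read_curve <- function(file, id = basename(file)) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  load_displacement_curve(df$displacement_mm, df$force_N, id = id)
}
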