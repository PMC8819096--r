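# Pipeline plumbing: run configuration, stage orchestration, and the
# reproducibility manifest.

#' Build a run configuration
#'
#' @param stages Character subset of
#'   `c("anatomy", "mesh", "simulate", "postprocess", "stiffness")`.
#' @param seed Integer seed used by every stochastic stage.
#' @param output_dir Output directory.
#' @param shape Shape configuration from [default_shape_config()].
#' @param target_edge Mesh edge length (mm).
#' @param motion Motion name for simulate.
#' @param angle_policy Angle policy ("midpoint", "lower", "upper",
#'   "explicit").
#' @param angle Explicit angle (degrees) for `angle_policy = "explicit"`.
#' @param lever_arm_r Lever arm (mm).
#' @param steps Load steps for simulate.
#' @param motion_fraction Fraction of the full converted displacement
#'   applied (1 = full motion; small fractions give the stability probe).
#' @param include_slil Keep the SLIL block in the simulated mesh?
#' @param material_overrides Named list of `material` objects.
#' @param stiffness_values Stiffness values (N/mm) for the stiffness stage;
#'   defaults to the six measured SLIL samples.
#' @param solver [solver_settings()].
#' @return A `run_config`.
#' @export
run_config <- function(stages = c("anatomy", "mesh", "simulate", "postprocess"),
                       seed = 1L, output_dir = tempfile("carpalfem_run_"),
                       shape = default_shape_config(), target_edge = 3,
                       motion = "extension", angle_policy = "midpoint",
                       angle = NULL, lever_arm_r = NULL, steps = 5L,
                       motion_fraction = 0.01, include_slil = TRUE,
                       material_overrides = list(),
                       stiffness_values = slil_stiffness_samples(),
                       solver = solver_settings()) {
  known <- c("anatomy", "mesh", "simulate", "postprocess", "stiffness")
  if (length(bad <- setdiff(stages, known)))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(lever_arm_r)) lever_arm_r <- shape$lever_arm_r
  structure(list(stages = stages, seed = as.integer(seed),
                 output_dir = output_dir, shape = shape,
                 target_edge = target_edge, motion = motion,
                 angle_policy = angle_policy, angle = angle,
                 lever_arm_r = lever_arm_r, steps = as.integer(steps),
                 motion_fraction = motion_fraction,
                 include_slil = isTRUE(include_slil),
                 material_overrides = material_overrides,
                 stiffness_values = stiffness_values, solver = solver),
            class = "run_config")
}

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the modelling pipeline
#'
#' Executes the selected stages in order (anatomy generation, meshing,
#' motion simulation, pressure post-processing; or the stiffness analysis),
#' writing artifacts and a machine-readable manifest (config fingerprint,
#' seed, package version) to the output directory.  A divergent simulation
#' is reported in the summary, not raised as an error.
#'
#' @param config A `run_config`.
#' @return A `pipeline_summary` list with the stage products and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config)
  mats <- material_library(config$material_overrides)

  if (any(c("anatomy", "mesh", "simulate", "postprocess") %in% config$stages)) {
    model <- generate_reduced_wrist(config$shape, config$seed)
    out$model <- model
    if ("anatomy" %in% config$stages)
      write_anatomy(model, file.path(config$output_dir, "anatomy"))
  }

  if (any(c("mesh", "simulate", "postprocess") %in% config$stages)) {
    mesh <- mesh_anatomy(out$model, config$target_edge)
    if (!config$include_slil) {
      mesh <- remove_part(mesh, "slil")
      attr(mesh, "target_edge") <- config$target_edge
    }
    out$mesh <- mesh
    out$quality <- validate_mesh(mesh)
    if ("mesh" %in% config$stages)
      write_vtk(mesh, file.path(config$output_dir, "carpus.vtk"))
  }

  if (any(c("simulate", "postprocess") %in% config$stages)) {
    bcs <- build_bc_set(out$mesh, config$motion, steps = config$steps,
                        r_mm = config$lever_arm_r,
                        policy = config$angle_policy, angle = config$angle)
    bcs$target <- config$motion_fraction * bcs$target
    springs <- build_spring_set(out$model$landmarks, out$mesh)
    part_mat <- list(cortical = mats$cortical, cancellous = mats$cancellous,
                     scaphoid = mats$cortical, lunate = mats$cortical,
                     capitate = mats$cortical,
                     radius_cartilage = mats$cartilage,
                     scaphoid_cartilage = mats$cartilage,
                     lunate_cartilage = mats$cartilage,
                     capitate_cartilage = mats$cartilage,
                     slil = mats$slil)
    part_mat <- part_mat[intersect(names(part_mat),
                                   unique(c(out$mesh$part, out$mesh$region)))]
    case <- simulation_case(out$mesh, part_mat, springs = springs, bcs = bcs,
                            settings = config$solver)
    out$mechanism_modes <- as.integer(detect_mechanism(case))
    result <- newton_solve(case)
    out$result <- result
    utils::write.table(result$convergence,
                       file.path(config$output_dir, "convergence.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_spring_set(springs, file.path(config$output_dir, "springs.tsv"))
    if (result$steps_completed > 0)
      write_result_series(result, file.path(config$output_dir, "fields"))
    if ("postprocess" %in% config$stages && result$steps_completed > 0 &&
        config$include_slil) {
      env <- region_envelope(result, "slil")
      out$slil_envelope <- env
      out$slil_extremes <- max_compression_traction(result, "slil")
      write_pressure_curves(env, file.path(config$output_dir,
                                           "slil_pressure_curves.tsv"))
    }
  }

  if ("stiffness" %in% config$stages) {
    summ <- summarize_stiffness(config$stiffness_values)
    out$stiffness_summary <- summ
    out$literature <- compare_to_literature(summ)
    rep_lines <- c(
      sprintf("SLIL linear stiffness report (n = %d)", length(summ$values)),
      sprintf("per-sample k [N/mm]: %s", paste(sprintf("%.2f", summ$values),
                                               collapse = ", ")),
      sprintf("mean/sd: %.2f/%.2f N/mm", summ$mean_report, summ$sd_report),
      sprintf("literature: %s",
              paste(sprintf("%s [%g-%g] %s", out$literature$study,
                            out$literature$lo, out$literature$hi,
                            ifelse(out$literature$inside, "inside", "outside")),
                    collapse = "; ")))
    writeLines(rep_lines, file.path(config$output_dir, "stiffness_report.txt"))
  }

  manifest <- list(package = "carpalfem",
                   version = as.character(utils::packageVersion("carpalfem")),
                   seed = config$seed,
                   config_md5 = config_fingerprint(config),
                   stages = config$stages,
                   mechanism_modes = out$mechanism_modes,
                   diverged = if (!is.null(out$result)) out$result$diverged else NULL)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  out$manifest <- manifest
  class(out) <- "pipeline_summary"
  out
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("pipeline_summary\n")
  cat(" stages:", paste(x$config$stages, collapse = ", "), "\n")
  if (!is.null(x$mesh))
    cat(sprintf(" mesh: %d nodes, %d elements\n", nrow(x$mesh$nodes),
                nrow(x$mesh$tets)))
  if (!is.null(x$mechanism_modes))
    cat(" mechanism modes:", x$mechanism_modes, "\n")
  if (!is.null(x$result))
    cat(sprintf(" simulation: %d/%d steps%s\n", x$result$steps_completed,
                length(x$result$case$bcs$ramp),
                if (x$result$diverged) " (diverged)" else ""))
  if (!is.null(x$stiffness_summary))
    cat(sprintf(" stiffness mean/sd: %.2f/%.2f N/mm\n",
                x$stiffness_summary$mean_report, x$stiffness_summary$sd_report))
  invisible(x)
}
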