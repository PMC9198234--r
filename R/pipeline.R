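#' Configuration for a full segmentation-sensitivity run
#'
#' Bundles every knob of the generate - segment - mesh - solve - summarize -
#' compare chain. Defaults reproduce the standardized study conditions: a
#' 66 + 63 two-sided cohort, the four KI-based segmentation methods, bone
#' elasticity E = 16800 MPa / nu = 0.3 and the 1800 N compressive load case
#' with a fully fixed inferior surface.
#'
#' @param n_left,n_right Cohort sizes.
#' @param base_params [phantom_params()] template for the cohort.
#' @param methods Character vector of segmentation method names.
#' @param n_bins Histogram bins for KI thresholding.
#' @param material [fe_material()].
#' @param load_case [fe_load_case()].
#' @param load_cone_deg,load_top_fraction Load-face selection, see
#'   [tetrahedralize()].
#' @param stats_mode,alpha Group-comparison options, see [build_tables()].
#' @param base_seed Integer seed for the whole run.
#' @param out_dir Optional output directory; when given, summary and table
#'   CSVs (and per-specimen artifacts if `artifacts = "all"`) are written.
#' @param artifacts `"none"` or `"all"` (mask NIfTI, surface STL, tet/result
#'   VTK per specimen-method).
#' @param strict Abort on the first specimen failure (`TRUE`) or log and
#'   skip (`FALSE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_left = 66L, n_right = 63L,
                            base_params = phantom_params(),
                            methods = c("KI", "KI-99.0", "KI-97.5", "KI-95.0"),
                            n_bins = 256L,
                            material = fe_material(),
                            load_case = fe_load_case(),
                            load_cone_deg = 45, load_top_fraction = 0.2,
                            stats_mode = "welch", alpha = 0.05,
                            base_seed = 42L,
                            out_dir = NULL, artifacts = c("none", "all"),
                            strict = TRUE) {
  artifacts <- match.arg(artifacts)
  stopifnot(n_left >= 0, n_right >= 0,
            all(methods %in% c("KI", "KI-99.0", "KI-97.5", "KI-95.0")))
  structure(
    list(n_left = as.integer(n_left), n_right = as.integer(n_right),
         base_params = base_params, methods = methods,
         n_bins = as.integer(n_bins), material = material,
         load_case = load_case, load_cone_deg = load_cone_deg,
         load_top_fraction = load_top_fraction,
         stats_mode = stats_mode, alpha = alpha,
         base_seed = as.integer(base_seed), out_dir = out_dir,
         artifacts = artifacts, strict = strict),
    class = "pipeline_config")
}

#' Run one specimen through segmentation, meshing and FE analysis
#'
#' @param volume A [ct_volume()].
#' @param truth Ground truth carrying the head-neck junction plane (for real
#'   CT data, construct a minimal truth list with `junction_point` and
#'   `junction_normal`).
#' @param method A [seg_method()] or name.
#' @param config A [pipeline_config()].
#' @return A list with `summary` (one-row tibble), `mask`, `tet`, `result`.
#' @export
analyze_specimen <- function(volume, truth, method,
                             config = pipeline_config()) {
  if (is.character(method)) method <- seg_method(method)
  mask <- segment_volume(volume, method, n_bins = config$n_bins)
  cropped <- crop_and_orient(mask, truth$junction_point,
                             truth$junction_normal)
  tet <- tetrahedralize(cropped, load_cone_deg = config$load_cone_deg,
                        load_top_fraction = config$load_top_fraction)
  K <- assemble_stiffness(tet, config$material)
  loads <- build_load_and_constraints(tet, config$load_case)
  sol <- solve_displacements(K, loads)
  result <- compute_element_fields(tet, sol$u, config$material)
  summary <- summarize_specimen(
    result, provenance = list(specimen_id = volume$specimen_id,
                              side = volume$side, method = method$name))
  list(summary = summary, mask = mask, cropped = cropped, tet = tet,
       result = result, solution = sol)
}

#' Run the full segmentation-sensitivity pipeline
#'
#' Generates the synthetic cohort, segments every specimen with every
#' configured method, builds a cropped Z-oriented tetrahedral model, solves
#' the standardized compressive load case and aggregates the four
#' biomechanical measures into group-mean and comparison tables. One FE
#' model per (specimen, method). Identical `config` + seed reruns produce
#' identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-specimen progress lines?
#' @return A list of class `pipeline_run`: `summaries` (tibble, one row per
#'   specimen-method), `tables` ([build_tables()] result), `manifest`
#'   (seeds, counts, per-stage timings, errors), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  t0 <- Sys.time()
  cohort <- generate_population(config$n_left, config$n_right,
                                base_params = config$base_params,
                                base_seed = config$base_seed)
  rows <- list()
  errors <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (sp in cohort) {
    vol <- sp$volume; truth <- sp$truth
    for (mn in config$methods) {
      res <- tryCatch(
        analyze_specimen(vol, truth, mn, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        if (config$strict) {
          abort_femurfe(sprintf("Specimen %s, method %s failed: %s",
                                vol$specimen_id, mn, conditionMessage(res)),
                        "femurfe_pipeline_error")
        }
        errors[[length(errors) + 1L]] <- list(
          specimen_id = vol$specimen_id, method = mn,
          message = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- res$summary
      if (progress) {
        message(sprintf("%s %s: %d tets, mean stress %.3f MPa",
                        vol$specimen_id, mn, nrow(res$tet$elements),
                        res$summary$mean_stress))
      }
      if (!is.null(out_dir) && config$artifacts == "all") {
        stem <- file.path(out_dir, paste0(vol$specimen_id, "_",
                                          gsub("[^A-Za-z0-9]", "", mn)))
        write_nifti_volume(res$mask, paste0(stem, "_mask.nii.gz"))
        surf <- standardize_surface(extract_surface(res$cropped))
        write_stl(surf, paste0(stem, ".stl"))
        write_vtk(res$tet, paste0(stem, ".vtk"), res$result)
      }
    }
  }
  summaries <- dplyr::bind_rows(rows)
  tables <- if (nrow(summaries) > 0 &&
                length(unique(summaries$method)) == length(config$methods) &&
                length(unique(summaries$specimen_id)) >= 2) {
    tryCatch(build_tables(summaries, alpha = config$alpha,
                          mode = config$stats_mode,
                          methods = config$methods),
             error = function(e) NULL)
  } else NULL
  manifest <- list(
    base_seed = config$base_seed,
    n_left = config$n_left, n_right = config$n_right,
    methods = config$methods,
    n_models = nrow(summaries),
    n_errors = length(errors),
    errors = errors,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    if (!is.null(tables)) {
      utils::write.csv(tables$means, file.path(out_dir, "means_table.csv"),
                       row.names = FALSE)
      for (sd_ in unique(tables$comparisons$side)) {
        utils::write.csv(
          dplyr::filter(tables$comparisons, .data$side == sd_),
          file.path(out_dir, paste0("comparisons_", sd_, ".csv")),
          row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest[setdiff(names(manifest), "errors")],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(summaries = summaries, tables = tables, manifest = manifest,
                 config = config),
            class = "pipeline_run")
}

#' @exportS3Method base::print
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d FE models (%d specimens x %d methods), %d errors, %.1f s\n",
              x$manifest$n_models,
              length(unique(x$summaries$specimen_id)),
              length(x$config$methods), x$manifest$n_errors,
              x$manifest$elapsed_s))
  invisible(x)
}
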