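#' Study run configuration
#'
#' A single serializable object tying the pipeline stages together: fluid
#' properties, flow-rate presets, station count, landmark fractions, the
#' cohort specification, output directory and master seed. The defaults
#' reproduce the documented demo study end to end.
#'
#' @param fluid A [fluid_properties()].
#' @param flow_lpm Flow-rate presets (L/min).
#' @param n_stations Cross-section stations per subject state.
#' @param landmarks Named landmark fractions (see [place_landmarks()]).
#' @param cohort A [cohort_spec()].
#' @param out_dir Output directory (`NULL`: nothing is written).
#' @param seed Master seed; overrides `cohort$seed` so one number controls
#'   the whole run.
#' @param alpha Significance threshold for the cohort comparison.
#' @param mesh_demo_subject Subject index for which phantom meshes and an
#'   analytic field are additionally emitted when writing output (0 = none).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fluid = fluid_properties(), flow_lpm = c(15, 30),
                       n_stations = 61,
                       landmarks = c(NV = 0.12, AS = 0.18, V1 = 0.32,
                                     V2 = 0.45, V3 = 0.58, PS = 0.72),
                       cohort = cohort_spec(flow_lpm = flow_lpm),
                       out_dir = NULL, seed = 1L, alpha = 0.05,
                       mesh_demo_subject = 0L) {
  cohort$seed <- as.integer(seed)
  cohort$flow_lpm <- flow_lpm
  structure(
    list(fluid = fluid, flow_lpm = flow_lpm, n_stations = n_stations,
         landmarks = landmarks, cohort = cohort, out_dir = out_dir,
         seed = as.integer(seed), alpha = alpha,
         mesh_demo_subject = as.integer(mesh_demo_subject)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> seed %d, %d subjects, flow %s L/min, %d stations\n",
    x$seed, x$cohort$n_subjects, paste(x$flow_lpm, collapse = "/"),
    x$n_stations
  ))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' The round trip `read_config(write_config(cfg))` reproduces the
#' configuration exactly.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_config <- function(config, path) {
  x <- list(
    fluid = list(rho = config$fluid$rho, mu = config$fluid$mu),
    flow_lpm = config$flow_lpm,
    n_stations = config$n_stations,
    landmarks = as.list(config$landmarks),
    cohort = config$cohort[c("n_subjects", "csa_cv", "valve_cv", "length_cv",
                             "effect_ratio", "effect_cv", "noise_cv",
                             "resistance_effect")],
    out_dir = config$out_dir,
    seed = config$seed,
    alpha = config$alpha,
    mesh_demo_subject = config$mesh_demo_subject
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  co <- x$cohort
  run_config(
    fluid = fluid_properties(x$fluid$rho, x$fluid$mu),
    flow_lpm = unlist(x$flow_lpm),
    n_stations = x$n_stations,
    landmarks = unlist(x$landmarks),
    cohort = cohort_spec(
      n_subjects = co$n_subjects, csa_cv = co$csa_cv, valve_cv = co$valve_cv,
      length_cv = co$length_cv, effect_ratio = co$effect_ratio,
      effect_cv = co$effect_cv, noise_cv = co$noise_cv,
      resistance_effect = co$resistance_effect,
      flow_lpm = unlist(x$flow_lpm), seed = x$seed
    ),
    out_dir = x$out_dir, seed = x$seed, alpha = x$alpha,
    mesh_demo_subject = x$mesh_demo_subject %||% 0L
  )
}

#' Run the paper-style synthetic study end to end
#'
#' Simulates the paired cohort, evaluates the geometric and flow metrics for
#' every subject in both states at each flow-rate preset, and runs the
#' paired Wilcoxon comparison over all metric panels (SA, CV, SAVR whole and
#' per region, plateau CSA, total and anterior/posterior resistance per flow
#' rate). With an output directory set, writes the cohort table, the
#' comparison report, the configuration and a content-hash manifest; rerun
#' with the same configuration is bit-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A `study_report`: list with `config`, `cohort` (the generated
#'   cohort), `comparison` (a [compare_cohort()] result) and `manifest`
#'   (tibble of written files and their MD5 hashes, or `NULL`).
#' @export
run_study <- function(config = run_config(), quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  say("simulating cohort: %d subjects, seed %d",
      config$cohort$n_subjects, config$seed)
  cohort <- tryCatch(
    generate_cohort(config$cohort, n_stations = config$n_stations),
    error = function(e) abort(sprintf("stage 'simulate' failed: %s", conditionMessage(e)))
  )
  say("comparing %d metrics over %d subjects",
      length(unique(cohort$table$metric)), config$cohort$n_subjects)
  comparison <- tryCatch(
    compare_cohort(cohort$table, alpha = config$alpha),
    error = function(e) abort(sprintf("stage 'compare' failed: %s", conditionMessage(e)))
  )

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    p <- file.path(config$out_dir, "cohort_metrics.csv")
    readr::write_csv(cohort$table, p)
    paths <- c(paths, p)
    p <- file.path(config$out_dir, "comparison.json")
    jsonlite::write_json(
      list(alpha = config$alpha, tests = tidy(comparison)),
      p, digits = NA, pretty = TRUE
    )
    paths <- c(paths, p)
    p <- file.path(config$out_dir, "config.yaml")
    write_config(config, p)
    paths <- c(paths, p)
    if (config$mesh_demo_subject > 0) {
      i <- min(config$mesh_demo_subject, length(cohort$subject_specs))
      say("emitting demo meshes for subject %d", i)
      for (state_name in c("normal", "decongested")) {
        c_val <- if (state_name == "normal") 1 else 0
        surf <- make_phantom(cohort$subject_specs[[i]], congestion = c_val)
        p <- file.path(config$out_dir, sprintf("subject%02d_%s.vtk", i, state_name))
        write_surface(surf, p)
        paths <- c(paths, p)
      }
    }
    manifest <- tibble(
      file = basename(paths),
      md5 = unname(vapply(paths, function(f) {
        digest::digest(file = f, algo = "md5")
      }, character(1)))
    )
    readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"))
    say("wrote %d files to %s", length(paths) + 1, config$out_dir)
  }

  structure(
    list(config = config, cohort = cohort, comparison = comparison,
         manifest = manifest),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$config)
  print(x$comparison)
  invisible(x)
}

#' @rdname tidy.cohort_comparison
#' @export
tidy.study_report <- function(x, ...) tidy(x$comparison)

#' @rdname glance.cohort_comparison
#' @export
glance.study_report <- function(x, ...) glance(x$comparison)
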