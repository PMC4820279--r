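#' Read a schema-validated CSV table
#'
#' Plain-CSV table input with column validation: required columns must be
#' present with the declared types; extra columns are preserved with a
#' warning.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`, `"logical"`).
#' @return data frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, schema, where = path)
  extra <- setdiff(names(df), names(schema))
  if (length(extra)) {
    warning("extra columns preserved: ", paste(extra, collapse = ", "))
  }
  df
}

check_schema <- function(df, schema, where = "table") {
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop(where, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    ok <- switch(schema[[col]],
      numeric = is.numeric(df[[col]]),
      integer = is.numeric(df[[col]]) && all(df[[col]] == round(df[[col]]),
                                             na.rm = TRUE),
      character = is.character(df[[col]]) || is.factor(df[[col]]),
      logical = is.logical(df[[col]]),
      stop("unknown schema type: ", schema[[col]])
    )
    if (!ok) {
      stop(where, ": column '", col, "' is not of type ", schema[[col]])
    }
  }
  invisible(df)
}

#' Write a CSV table at full numeric precision
#'
#' @param df data frame.
#' @param path output path (directory is created if needed).
#' @param schema optional schema checked before writing.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = NULL) {
  if (!is.null(schema)) check_schema(df, schema, where = "output table")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # full double precision (17 significant digits round-trips exactly)
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stage_registry <- function() {
  list(
    `phase-diagram` = list(
      fun = stage_phase_diagram,
      keys = c("v_plus_min", "v_plus_max", "delta_min", "delta_max",
               "n_grid", "toxicity_variant", "benefit_form", "theta",
               "vmax_b", "km_b", "g_max")
    ),
    ensemble = list(
      fun = stage_ensemble,
      keys = c("k_im", "k_ta", "theta", "delta", "n_traj", "t_end")
    ),
    `popmodel-surface` = list(
      fun = stage_popmodel_surface,
      keys = c("delta_min", "delta_max", "x_min", "x_max", "n_grid",
               "g_max", "s_max", "sigma_x")
    ),
    `synth-flow` = list(
      fun = stage_synth_flow,
      keys = c("n_events", "arrest_fraction")
    ),
    `synth-dose` = list(
      fun = stage_synth_dose,
      keys = c("a", "b", "c", "noise_sd", "replicates")
    )
  )
}

#' Run a named analysis stage from a configuration list
#'
#' Dispatches to one of the registered stages, writes its tidy CSV outputs
#' plus a JSON manifest (configuration, seed, package version) into the
#' output directory, and returns the output paths.  Unknown stages and
#' unknown configuration keys are rejected by name.  Identical
#' configurations (including the seed) produce byte-identical outputs.
#'
#' @param stage stage name: one of `"phase-diagram"`, `"ensemble"`,
#'   `"popmodel-surface"`, `"synth-flow"`, `"synth-dose"`.
#' @param config named list of stage parameters (may be empty).
#' @param out_dir output directory.
#' @param seed integer seed for stages with randomness.
#' @return named character vector of files written, invisibly.
#' @export
run_stage <- function(stage, config = list(), out_dir = tempfile("stage_"),
                      seed = 1L) {
  reg <- stage_registry()
  if (!stage %in% names(reg)) {
    stop("unknown stage '", stage, "'; known stages: ",
         paste(names(reg), collapse = ", "))
  }
  entry <- reg[[stage]]
  bad <- setdiff(names(config), entry$keys)
  if (length(bad)) {
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(bad, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- entry$fun(config, out_dir, seed)
  manifest <- list(
    stage = stage,
    config = config,
    seed = seed,
    package = "satarrest",
    version = as.character(utils::packageVersion("satarrest"))
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, manifest = mpath))
}

cfg <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

stage_phase_diagram <- function(config, out_dir, seed) {
  n <- cfg(config, "n_grid", 50L)
  p <- pathway_params(
    theta = cfg(config, "theta", 100),
    vmax_b = cfg(config, "vmax_b", 1),
    km_b = cfg(config, "km_b", 1),
    g_max = cfg(config, "g_max", 6e-4),
    toxicity_variant = cfg(config, "toxicity_variant", "substrate"),
    benefit_form = cfg(config, "benefit_form", "piecewise_linear")
  )
  pd <- phase_diagram(
    seq(cfg(config, "v_plus_min", 0.02), cfg(config, "v_plus_max", 1.4),
        length.out = n),
    seq(cfg(config, "delta_min", 0.05), cfg(config, "delta_max", 1.3),
        length.out = n),
    p
  )
  path <- file.path(out_dir, "phase_diagram.csv")
  write_table(as.data.frame(pd), path,
              schema = c(v_plus = "numeric", delta = "numeric",
                         regime = "character", norm_growth = "numeric"))
  c(phase_diagram = path)
}

stage_ensemble <- function(config, out_dir, seed) {
  sp <- build_reaction_system(
    k_im = cfg(config, "k_im", 1),
    k_tA = cfg(config, "k_ta", 0.05),
    theta = cfg(config, "theta", 1e4),
    delta = cfg(config, "delta", 400)
  )
  e <- run_ensemble(sp, n_traj = cfg(config, "n_traj", 200),
                    t_end = cfg(config, "t_end", 8000),
                    seed_base = seed, keep_samples = FALSE)
  path <- file.path(out_dir, "ensemble_trajectories.csv")
  write_table(e$trajectories, path)
  spath <- file.path(out_dir, "ensemble_summary.json")
  jsonlite::write_json(
    list(n_traj = e$n_traj, t_end = e$t_end, seed_base = e$seed_base,
         mean_growth = e$mean_growth, se_growth = e$se_growth,
         arrest_fraction = e$arrest_fraction,
         correlations = as.list(e$correlations),
         rng = e$rng),
    spath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(trajectories = path, summary = spath)
}

stage_popmodel_surface <- function(config, out_dir, seed) {
  n <- cfg(config, "n_grid", 40L)
  surf <- metastable_surface(
    seq(cfg(config, "delta_min", 0.1), cfg(config, "delta_max", 1.5),
        length.out = n),
    seq(cfg(config, "x_min", 0.05), cfg(config, "x_max", 1.6),
        length.out = n),
    g_max = cfg(config, "g_max", 1),
    s_max = cfg(config, "s_max", 1.5),
    sigma_x = cfg(config, "sigma_x", 0.1)
  )
  path <- file.path(out_dir, "metastable_surface.csv")
  write_table(surf, path,
              schema = c(delta = "numeric", x = "numeric",
                         lambda_normalized = "numeric",
                         arrested_fraction = "numeric"))
  c(surface = path)
}

stage_synth_flow <- function(config, out_dir, seed) {
  fs <- gen_flow_sample(
    n_events = cfg(config, "n_events", 10000),
    arrest_fraction = cfg(config, "arrest_fraction", 0.1),
    seed = seed
  )
  path <- file.path(out_dir, "flow_events.csv")
  write_table(fs, path,
              schema = c(fl = "numeric", fsc = "numeric", ssc = "numeric",
                         arrested = "logical"))
  c(flow_events = path)
}

stage_synth_dose <- function(config, out_dir, seed) {
  dr <- gen_dose_response(
    a = cfg(config, "a", 0.45),
    b = cfg(config, "b", 0.012),
    c = cfg(config, "c", -0.00024),
    noise_sd = cfg(config, "noise_sd", 0.02),
    replicates = cfg(config, "replicates", 3),
    seed = seed
  )
  path <- file.path(out_dir, "dose_response.csv")
  write_table(dr, path,
              schema = c(dose = "numeric", rate = "numeric",
                         replicate = "integer"))
  c(dose_response = path)
}
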