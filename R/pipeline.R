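#' Run the full isoscape pipeline
#'
#' Orchestrates simulate -> terrain -> predictors -> fit -> select ->
#' validate -> isoscape as one reproducible run: writes all intermediate
#' products as plain-text files (ESRI ASCII grids, GeoJSON, CSV, JSON) plus
#' a manifest with the configuration, per-file MD5 checksums and stage
#' timings. When a manifest from an identical configuration already exists
#' and all output checksums match, the run is skipped unless `force`.
#'
#' @param config a [sim_config]; `config$seed` drives every stage.
#' @param out_dir output directory.
#' @param truth a [truth_model].
#' @param spec a [gamm_spec] for the full model.
#' @param n_validation_runs random splits for validation.
#' @param dredge run the all-subsets selection? (64 fits; set `FALSE` for
#'   quick runs).
#' @param force rerun even when outputs are up to date.
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, truth = truth_model(),
                         spec = gamm_spec(), n_validation_runs = 100,
                         dredge = TRUE, force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config_digestable(config), auto_unbox = TRUE,
                               digits = 10)
  cfg_hash <- digest_string(as.character(cfg_json))
  man_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(man_path)) {
    old <- tryCatch(jsonlite::read_json(man_path, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (!is.null(old) && identical(old$config_hash, cfg_hash) &&
        all(file.exists(file.path(out_dir, names(old$checksums)))) &&
        identical(unname(tools::md5sum(
          file.path(out_dir, names(old$checksums)))),
          unname(unlist(old$checksums)))) {
      message("outputs up to date; skipping (use force = TRUE to rerun)")
      return(invisible(old))
    }
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  scen <- simulate_scenario(config, truth)
  write_scenario(scen, out_dir)
  write_ascii_grid(scen$terrain$twi, file.path(out_dir, "twi.asc"))
  write_ascii_grid(scen$terrain$tpi, file.path(out_dir, "tpi.asc"))
  write_ascii_grid(scen$terrain$landform, file.path(out_dir, "landform.asc"))
  jsonlite::write_json(as.list(landform_legend()),
                       file.path(out_dir, "landform_legend.json"),
                       auto_unbox = TRUE)
  write_ascii_grid(scen$stack$dist_ac, file.path(out_dir, "dist_ac.asc"))
  write_ascii_grid(scen$stack$area_ac, file.path(out_dir, "area_ac.asc"))
  write_ascii_grid(scen$stack$elev_ac, file.path(out_dir, "elev_ac.asc"))
  utils::write.csv(scen$plants, file.path(out_dir, "model_table.csv"),
                   row.names = FALSE)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  fit <- fit_gamm(scen$plants, spec)
  write_gamm_json(fit, file.path(out_dir, "fit.json"))
  timings["fit"] <- tic() - t0

  if (dredge) {
    t0 <- tic()
    sel <- dredge_gamm(scen$plants, spec)
    write_selection_csv(sel, file.path(out_dir, "selection.csv"))
    timings["select"] <- tic() - t0
  }

  t0 <- tic()
  val <- split_validate(scen$plants, spec, n_runs = n_validation_runs,
                        seed = stage_seed(config, "validate"))
  utils::write.csv(val$runs, file.path(out_dir, "validation_runs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(val[c("median_r2", "iqr_r2", "median_rmse",
                             "iqr_rmse", "n_runs", "train_frac", "seed")],
                       file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = 6)
  res <- fit$residuals
  co <- cbind(fit$train$data$x, fit$train$data$y)
  mi <- morans_i(res, co)
  sv <- semivariogram(res, co)
  utils::write.csv(mi$bins, file.path(out_dir, "moran_correlogram.csv"),
                   row.names = FALSE)
  utils::write.csv(sv$bins, file.path(out_dir, "semivariogram.csv"),
                   row.names = FALSE)
  timings["validate"] <- tic() - t0

  t0 <- tic()
  iso <- predict_isoscape(fit, scen$stack, scen$plants)
  write_ascii_grid(iso, file.path(out_dir, "isoscape.asc"))
  timings["isoscape"] <- tic() - t0

  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  manifest <- list(config = config_digestable(config),
                   config_hash = cfg_hash, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("nitroscape")),
                   timings_s = as.list(round(timings, 3)),
                   checksums = as.list(sums))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = 10)
  invisible(manifest)
}

config_digestable <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) lapply(x, unname) else unname(x))
}

## small md5-based string digest (tools::md5sum works on files only)
digest_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Command-line entry point
#'
#' Minimal CLI used by the `exec/nitroscape-pipeline` script:
#' `nitroscape-pipeline --out DIR [--seed N] [--runs N] [--no-dredge]
#' [--force] [--config cfg.json]`. A JSON config file may override any
#' [sim_config] argument; flags override the file.
#'
#' @param args character vector of command-line arguments.
#' @return The manifest, invisibly.
#' @export
nitroscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i)) default else args[i + 1L]
  }
  out <- get_opt("--out")
  if (is.null(out)) stop("usage: nitroscape-pipeline --out DIR [--seed N]")
  cfg_args <- list()
  cfg_file <- get_opt("--config")
  if (!is.null(cfg_file))
    cfg_args <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  seed <- get_opt("--seed")
  if (!is.null(seed)) cfg_args$seed <- as.integer(seed)
  config <- do.call(sim_config, cfg_args)
  runs <- as.integer(get_opt("--runs", "100"))
  run_pipeline(config, out, n_validation_runs = runs,
               dredge = !"--no-dredge" %in% args,
               force = "--force" %in% args)
}
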