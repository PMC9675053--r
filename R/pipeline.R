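# Orchestration: the full study design (noise cases x dataset sizes ->
# EMC -> registration -> R curves -> resolution-vs-snapshots table) as one
# configured, logged, resumable run.

#' Study configuration
#'
#' @param model An [atomic_model()].
#' @param geometry A [detector_geometry()].
#' @param beam A [beam_parameters()].
#' @param dataset_sizes Snapshot counts, one dataset per size.
#' @param noise_cases Subset of `"poisson_only"`, `"standard"`,
#'   `"low_noise"`, or a named list of [noise_model()]s.
#' @param emc An [emc_config()].
#' @param d_grid Resolution grid (nm) for the R-factor curves.
#' @param threshold R threshold for the resolution estimate.
#' @param target_occupancy Mean photons/pixel the datasets are tuned to.
#' @param n_emc_repeats Independent EMC seeds per (case, size); repeats > 1
#'   yield error bars (the SD of the estimated resolutions).
#' @param seeds List with `data` and `emc` base seeds.
#' @param output_dir Artifact directory.
#' @param phasing Optional [phasing_config()] to also phase each
#'   reconstruction.
#' @return Object of class `study_config`.
#' @export
study_config <- function(model, geometry, beam, dataset_sizes,
                         noise_cases = c("poisson_only", "standard", "low_noise"),
                         emc = emc_config(), d_grid = seq(3, 0.9, by = -0.1),
                         threshold = 0.2, target_occupancy = 0.1,
                         n_emc_repeats = 1L,
                         seeds = list(data = 1L, emc = 100L),
                         output_dir = tempfile("spisim_study_"),
                         phasing = NULL) {
  if (!length(dataset_sizes) || !length(noise_cases))
    stop("need at least one dataset size and one noise case")
  cfg <- list(model = model, geometry = geometry, beam = beam,
              dataset_sizes = as.integer(dataset_sizes),
              noise_cases = noise_cases, emc = emc, d_grid = d_grid,
              threshold = threshold, target_occupancy = target_occupancy,
              n_emc_repeats = as.integer(n_emc_repeats), seeds = seeds,
              output_dir = output_dir, phasing = phasing)
  class(cfg) <- "study_config"
  cfg
}

# canonical fingerprint of a study config (output_dir excluded so a moved
# study still resumes)
.config_hash <- function(config) {
  cfg <- config
  cfg$output_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(cfg, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# comparable field-level summary used in refusal diffs
.config_fields <- function(config) {
  c(dataset_sizes = paste(config$dataset_sizes, collapse = ","),
    noise_cases = paste(if (is.list(config$noise_cases))
      names(config$noise_cases) else config$noise_cases, collapse = ","),
    grid_edge = config$emc$grid_edge,
    emc_iterations = config$emc$n_iterations,
    d_grid = paste(signif(config$d_grid, 6), collapse = ","),
    threshold = config$threshold,
    target_occupancy = config$target_occupancy,
    n_emc_repeats = config$n_emc_repeats,
    seed_data = config$seeds$data, seed_emc = config$seeds$emc,
    n_atoms = config$model$n_atoms,
    total_electrons = config$model$total_electrons)
}

.run_key <- function(case, size, rep) sprintf("%s_%06d_r%02d", case, size, rep)

# one (case, size, repeat) unit: dataset -> EMC -> registration -> R curve
.run_one <- function(config, ideal, case, case_idx, size, size_idx, rep) {
  noise <- if (is.list(config$noise_cases)) config$noise_cases[[case]] else case
  seed_data <- config$seeds$data + 1000L * case_idx + size_idx
  seed_emc <- config$seeds$emc + 10000L * case_idx + 100L * size_idx + rep
  ds <- make_dataset(config$model, config$geometry, config$beam, noise,
                     n_patterns = size, seed = seed_data,
                     target_occupancy = config$target_occupancy)
  emc_cfg <- config$emc
  emc_cfg$seed <- seed_emc
  vol <- run_emc(ds, emc_cfg)
  reg <- register_rotation(vol, ideal)
  # beamstop radius in grid voxels: pixels * (q per pixel) / (q per voxel)
  g <- config$geometry
  q_per_px <- (2 * pi / g$wavelength) * (g$pixel_size / g$sdd)
  bs_vox <- ceiling(max(g$beamstop_radius, 1) * q_per_px / vol$voxel_size)
  excl <- voxel_radii(ideal) <= bs_vox
  curve <- r_factor(reg$volume, ideal, config$d_grid, exclude = excl)
  res <- resolution_at_threshold(curve, config$threshold)
  list(case = case, size = size, rep = rep,
       resolution_nm = res$resolution_nm, flag = res$flag,
       n_crossings = res$n_crossings, correlation = reg$correlation,
       curve = curve, loglik_trace = vol$metadata$trace,
       seeds = c(data = seed_data, emc = seed_emc))
}

#' Run the resolution-vs-snapshots study
#'
#' For every (noise case, dataset size, EMC repeat): generates the dataset,
#' reconstructs it with EMC, registers the volume against the noise-free
#' ideal volume, computes the R-factor curve and the resolution at the
#' threshold. Failures are recorded per run and the study continues.
#' Artifacts, a combined CSV and a resolution-vs-size summary are written
#' under `config$output_dir`; completed runs are recorded in a manifest so
#' the study can be resumed.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`: `results` (one row per run),
#'   `summary` (median/SD per case and size), `output_dir`, `config_hash`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$output_dir, "runs"), showWarnings = FALSE)
  hash <- .config_hash(config)
  saveRDS(config, file.path(config$output_dir, "config.rds"), version = 2)
  qmap <- build_qmap(config$geometry)
  vx <- config$emc$voxel_size
  if (is.null(vx)) vx <- grid_voxel_size(qmap, config$emc$grid_edge)
  ideal <- build_ideal_volume(config$model, config$emc$grid_edge, vx)
  cases <- if (is.list(config$noise_cases)) names(config$noise_cases)
           else config$noise_cases
  rows <- list()
  for (ci in seq_along(cases)) for (si in seq_along(config$dataset_sizes)) {
    for (rep in seq_len(config$n_emc_repeats)) {
      case <- cases[ci]; size <- config$dataset_sizes[si]
      key <- .run_key(case, size, rep)
      art <- file.path(config$output_dir, "runs", paste0(key, ".rds"))
      if (file.exists(art)) {
        res <- readRDS(art)
      } else {
        res <- tryCatch(
          .run_one(config, ideal, case, ci, size, si, rep),
          error = function(e) list(case = case, size = size, rep = rep,
                                   resolution_nm = NA_real_, flag = "error",
                                   n_crossings = NA_integer_,
                                   correlation = NA_real_,
                                   error = conditionMessage(e)))
        saveRDS(res, art, version = 2)
      }
      rows[[key]] <- data.frame(case = case, size = size, rep = rep,
                                resolution_nm = res$resolution_nm,
                                flag = res$flag,
                                n_crossings = res$n_crossings,
                                correlation = res$correlation)
    }
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  agg <- stats::aggregate(resolution_nm ~ case + size, data = results,
                          FUN = stats::median, na.action = stats::na.pass)
  names(agg)[3] <- "resolution_nm_median"
  sds <- stats::aggregate(resolution_nm ~ case + size, data = results,
                          FUN = stats::sd, na.action = stats::na.pass)
  agg$resolution_nm_sd <- sds$resolution_nm
  utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(agg, file.path(config$output_dir, "resolution_vs_size.csv"),
                   row.names = FALSE)
  manifest <- list(config_hash = hash,
                   config_fields = as.list(.config_fields(config)),
                   completed = names(rows))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rep <- list(results = results, summary = agg,
              output_dir = config$output_dir, config_hash = hash)
  class(rep) <- "study_report"
  rep
}

#' @exportS3Method base::print
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$results), "runs in", x$output_dir, "\n")
  print(x$summary)
  invisible(x)
}

#' Resume a partially completed study
#'
#' Re-reads the stored config, verifies it against the manifest hash
#' (refusing, with a field-level diff, if the config changed), re-executes
#' only the runs whose artifacts are missing, and recomputes the report.
#'
#' @param output_dir Directory of a previous [run_study()].
#' @param config Optional config to use; must hash-match the manifest.
#' @return A `study_report`.
#' @export
resume_study <- function(output_dir, config = NULL) {
  mf_path <- file.path(output_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest found in ", output_dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(config))
    config <- readRDS(file.path(output_dir, "config.rds"))
  config$output_dir <- output_dir
  hash <- .config_hash(config)
  if (!identical(hash, manifest$config_hash)) {
    new_f <- .config_fields(config)
    old_f <- unlist(manifest$config_fields)
    keys <- union(names(new_f), names(old_f))
    diff <- keys[vapply(keys, function(k)
      !identical(as.character(new_f[k]), as.character(old_f[k])), logical(1))]
    stop("config does not match the manifest; differing fields: ",
         paste(sprintf("%s (was %s, now %s)", diff, old_f[diff], new_f[diff]),
               collapse = "; "))
  }
  run_study(config)
}
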