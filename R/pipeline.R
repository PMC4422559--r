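#' Read a run configuration
#'
#' YAML (or JSON) configuration for the pipeline commands.  Recognized
#' top-level keys: `seed`, `output_dir`, `n_random`, `ssg_fraction`,
#' `posterior_threshold`, `frequency_threshold`, `synthetic` (passed to
#' [synthetic_config()]), `variants` (lists `interp`, `noise_cvs`,
#' `pairings`, `likelihood_modes`), `inputs` (paths: `metabolites` and
#' `transcripts` per condition, `tf_gmt`, `hub_tfs`), `conditions`.
#' Missing keys fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, output_dir = "hubmotif_out", n_random = 100,
                   ssg_fraction = 0.10, posterior_threshold = 0.5,
                   frequency_threshold = 0.5)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  for (k in c("ssg_fraction", "posterior_threshold", "frequency_threshold")) {
    v <- cfg[[k]]
    if (!(is.numeric(v) && v > 0 && v < 1)) {
      abort(paste0("config field '", k, "' must be in (0, 1)"))
    }
  }
  structure(cfg, class = "run_config")
}

config_variants <- function(cfg) {
  v <- cfg$variants
  enumerate_variants(
    interp = v$interp %||% c("linear", "smoothing_spline"),
    noise_cvs = unlist(v$noise_cvs) %||% c(0.1, 0.2, 0.3, 0.4),
    pairings = v$pairings %||% PAIRINGS,
    likelihood_modes = v$likelihood_modes %||%
      c("all_three", "bypass_plus_best_nutrient"))
}

config_conditions <- function(cfg) {
  if (is.null(cfg$conditions)) return(condition_set())
  condition_set(name = vapply(cfg$conditions, `[[`, "", "name"),
                role = vapply(cfg$conditions, `[[`, "", "role"))
}

config_hash <- function(cfg) {
  substr(rlang::hash(unclass(cfg)), 1, 12)
}

write_stamped_tsv <- function(df, path, cfg) {
  writeLines(sprintf("# hubmotif config_hash=%s seed=%d", config_hash(cfg),
                     as.integer(cfg$seed)), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Simulate a synthetic experiment to disk
#'
#' Writes per-condition metabolite and transcript TSV matrices, the TF
#' target GMT, and a JSON truth sidecar into `output_dir`.
#'
#' @param cfg A `run_config` (or path to one).
#' @return Named character vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  syn <- do.call(synthetic_config,
                 c(cfg$synthetic %||% list(), list(seed = cfg$seed)))
  sim <- generate_experiment(syn)
  es <- sim$experiment
  paths <- character()
  for (cn in es_condition_names(es)) {
    p1 <- file.path(out_dir, sprintf("metabolites_%s.tsv", cn))
    p2 <- file.path(out_dir, sprintf("transcripts_%s.tsv", cn))
    write_timecourse_tsv(es$metabolites[[cn]], p1)
    write_timecourse_tsv(es$transcripts[[cn]], p2)
    paths[paste0("metabolites_", cn)] <- p1
    paths[paste0("transcripts_", cn)] <- p2
  }
  gmt <- file.path(out_dir, "tf_targets.gmt")
  write_tf_targets_gmt(es$tf_map, gmt)
  paths["tf_gmt"] <- gmt
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(metabolites = sim$truth$metabolites,
                            genes = sim$truth$genes,
                            hub_tfs = es$tf_map$hub_tfs),
                       truth_path, digits = NA)
  paths["truth"] <- truth_path
  inform(sprintf("simulated %d metabolites x %d genes x %d conditions -> %s",
                 nrow(sim$truth$metabolites), nrow(sim$truth$genes),
                 length(es_condition_names(es)), out_dir))
  invisible(paths)
}

load_experiment_from_config <- function(cfg) {
  inputs <- cfg$inputs
  if (is.null(inputs)) abort("config has no 'inputs' section")
  conds <- config_conditions(cfg)
  mets <- lapply(setNames(conds$name, conds$name), function(cn) {
    read_timecourse_tsv(inputs$metabolites[[cn]], "metabolite", cn)
  })
  trs <- lapply(setNames(conds$name, conds$name), function(cn) {
    read_timecourse_tsv(inputs$transcripts[[cn]], "transcript", cn)
  })
  tf_map <- read_tf_targets_gmt(inputs$tf_gmt)
  hub <- unlist(inputs$hub_tfs) %||% default_hub_tfs()
  tf_map <- set_hub_tfs(tf_map, intersect(hub, tf_map$tf_ids))
  experiment_set(mets, trs, tf_map, conds)
}

#' Run the full motif inference from a configuration
#'
#' Reads the input matrices and TF prior, runs [assign_motifs()], and
#' writes feature, posterior, frequency and assignment tables (each stamped
#' with the config hash and seed).
#'
#' @param cfg A `run_config` (or path), with an `inputs` section.
#' @param es Optionally, an already-loaded [experiment_set()] (overrides
#'   `inputs`).
#' @return The `motif_assignment`, invisibly; tables under
#'   `cfg$output_dir`.
#' @export
pipeline_infer <- function(cfg, es = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(es)) es <- load_experiment_from_config(cfg)
  diags <- validate_experiment_set(es)
  if (nrow(diags) > 0) {
    abort(paste0("experiment set invalid:\n",
                 paste0("  - ", diags$invariant, ": ", diags$detail,
                        collapse = "\n")))
  }
  variants <- config_variants(cfg)
  inform(sprintf("inference: %d variants, %d metabolites, seed %d",
                 nrow(variants),
                 length(tc_features(es$metabolites[[1]])),
                 as.integer(cfg$seed)))
  ma <- assign_motifs(es, variants = variants, n_random = cfg$n_random,
                      seed = cfg$seed, ssg_fraction = cfg$ssg_fraction,
                      posterior_threshold = cfg$posterior_threshold,
                      frequency_threshold = cfg$frequency_threshold)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stamped_tsv(select(ma$cache$features, -"ssg"),
                    file.path(out_dir, "features.tsv"), cfg)
  write_stamped_tsv(ma$posteriors, file.path(out_dir, "posteriors.tsv"), cfg)
  write_stamped_tsv(ma$frequencies, file.path(out_dir, "frequencies.tsv"), cfg)
  write_stamped_tsv(ma$calls, file.path(out_dir, "assignments.tsv"), cfg)
  invisible(ma)
}

#' Run the hub-TF robustness analysis from a configuration
#'
#' @param cfg A `run_config` (or path).
#' @param ma A `motif_assignment` from [pipeline_infer()]; recomputed when
#'   `NULL`.
#' @param remove_sizes,add_sizes,n_samples Plan parameters, see
#'   [hub_tf_robustness()].
#' @return The plan tibble from [hub_tf_robustness()], invisibly; TSV
#'   reports under `cfg$output_dir`.
#' @export
pipeline_robustness <- function(cfg, ma = NULL, remove_sizes = 1:3,
                                add_sizes = 1:3, n_samples = 100) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(ma)) ma <- pipeline_infer(cfg)
  plan <- hub_tf_robustness(ma, remove_sizes = remove_sizes,
                            add_sizes = add_sizes, n_samples = n_samples,
                            seed = cfg$seed)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_met <- plan |>
    mutate(tbl = map(.data$report, function(r) r$per_metabolite)) |>
    select("kind", "size", "tbl") |>
    unnest("tbl")
  binned <- plan |>
    mutate(tbl = map(.data$report, function(r) r$binned)) |>
    select("kind", "size", "tbl") |>
    unnest("tbl") |>
    mutate(bin = as.character(.data$bin))
  write_stamped_tsv(per_met, file.path(out_dir, "robustness.tsv"), cfg)
  write_stamped_tsv(binned, file.path(out_dir, "robustness_binned.tsv"), cfg)
  invisible(plan)
}

#' Fit impulse onsets for all transcripts from a configuration
#'
#' @param cfg A `run_config` (or path).
#' @param es Optionally an [experiment_set()].
#' @param n_starts Optimization starts per gene.
#' @return Tibble of per-gene onset results, invisibly; `onsets.tsv` under
#'   `cfg$output_dir`.
#' @export
pipeline_onset <- function(cfg, es = NULL, n_starts = 10) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(es)) es <- load_experiment_from_config(cfg)
  rows <- list()
  for (cn in es_condition_names(es)) {
    a <- tc_array(es$transcripts[[cn]])
    times <- as.numeric(dimnames(a)[[2]])
    for (g in dimnames(a)[[1]]) {
      lv <- rowMeans(matrix(a[g, , ], nrow = length(times)), na.rm = TRUE)
      fit <- fit_impulse(times, lv, n_starts = n_starts,
                         seed = derive_seed(cfg$seed, nchar(g), nchar(cn)))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(gene = g, condition = cn), fit$params,
        tibble(sse = fit$sse, t_half = fit$t_half, flag = fit$flag))
    }
  }
  out <- list_rbind(rows)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stamped_tsv(out, file.path(out_dir, "onsets.tsv"), cfg)
  invisible(out)
}
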