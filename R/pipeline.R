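# End-to-end orchestration: preprocess -> repeated CV -> summaries ->
# prominence -> clinical associations, with all artifacts written to disk
# and a manifest recording seeds and the configuration hash.

#' Pipeline configuration
#'
#' @param output_dir directory for all artifacts.
#' @param covariates metadata columns appended as predictors (e.g.
#'   `c("age", "bmi")`; empty for the proteins-only experiment).
#' @param min_nonzero sparsity filter threshold (default 12 subjects).
#' @param cv a [cv_config()].
#' @param ensemble an [ensemble_config()].
#' @param top_n,threshold prominence tabulation parameters.
#' @param split_rank,bmi_cut clinical dichotomization points.
#' @param permutation_seed seed for the label-permutation control.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("hullvote_run_"),
                            covariates = character(0),
                            min_nonzero = 12L,
                            cv = cv_config(),
                            ensemble = ensemble_config(),
                            top_n = 10L, threshold = 50L,
                            split_rank = 8L, bmi_cut = 30,
                            permutation_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Preprocesses a raw cohort, runs repeated cross-validation of the hull
#' ensemble, summarizes the five performance indices, runs the
#' label-permutation control, tabulates pair prominence, and tests the
#' clinical associations. Artifacts written to `config$output_dir`:
#' `cv_runs.csv` (per-run indices plus AVG/SD/MOE rows), `cv_trace.csv`
#' (per-subject votes), `prominence_proteins.csv`, `prominence_pairs.csv`,
#' `associations.json`, and `manifest.json` (configuration, seeds and a
#' configuration hash; runs with equal hashes produce equal numbers).
#'
#' @param raw long-format raw count table (see [average_replicates()]).
#' @param meta subject metadata.
#' @param config a [pipeline_config()].
#' @param permutation run the label-permutation control too (default
#'   `TRUE`).
#' @return list with `profile`, `cv` (a `repeated_cv`), `summary`,
#'   `permutation`, `prominence`, `associations`, `paths`.
#' @export
run_pipeline <- function(raw, meta, config = pipeline_config(),
                         permutation = TRUE) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  x <- preprocess_cohort(raw, meta, min_nonzero = config$min_nonzero,
                         covariates = config$covariates)
  y <- class_labels(meta[match(rownames(x), meta$subject_id), ])
  res <- run_repeated_cv(x, y, cv = config$cv, config = config$ensemble,
                         keep_top = config$top_n)
  summ <- summarize_runs(res)
  perm <- if (permutation)
    permutation_control(x, y, cv = config$cv, config = config$ensemble,
                        perm_seed = config$permutation_seed)
  pairs <- collect_top_pairs(res, top_n = config$top_n)
  prom <- tabulate_prominence(pairs, threshold = config$threshold)
  assoc <- association_report(meta, split_rank = config$split_rank,
                              bmi_cut = config$bmi_cut)

  cfg_hash <- config_hash(config)
  paths <- c(runs = file.path(dir, "cv_runs.csv"),
             trace = file.path(dir, "cv_trace.csv"),
             proteins = file.path(dir, "prominence_proteins.csv"),
             pairs = file.path(dir, "prominence_pairs.csv"),
             assoc = file.path(dir, "associations.json"),
             manifest = file.path(dir, "manifest.json"))

  idx <- cv_index_table(res)
  runs_tab <- rbind(
    cbind(run = as.character(seq_len(nrow(idx))), round3(idx)),
    cbind(run = c("AVG", "SD", "MOE"),
          round3(data.frame(acc = stat_col(summ, "acc"),
                            sen = stat_col(summ, "sen"),
                            spc = stat_col(summ, "spc"),
                            ppv = stat_col(summ, "ppv"),
                            npv = stat_col(summ, "npv")))))
  write_artifact(runs_tab, paths["runs"], cfg_hash)
  trace <- do.call(rbind, lapply(res$runs, function(r)
    cbind(run = r$run, r$predictions)))
  write_artifact(trace, paths["trace"], cfg_hash)
  write_artifact(prom$protein_counts, paths["proteins"], cfg_hash)
  write_artifact(prom$pair_counts, paths["pairs"], cfg_hash)
  jsonlite::write_json(
    list(config_hash = cfg_hash,
         enrollment = list(table = assoc$enrollment$table,
                           p_value = assoc$enrollment$p_value),
         bmi = list(table = assoc$bmi$table,
                    p_value = assoc$bmi$p_value)),
    paths["assoc"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = cfg_hash,
         n_subjects = nrow(x), n_predictors = ncol(x),
         n_proteins = length(protein_cols(x)),
         covariates = config$covariates,
         cv = unclass(config$cv), ensemble = unclass(config$ensemble),
         permutation_seed = config$permutation_seed,
         permuted_coincident = if (permutation) perm$n_coincident else NULL),
    paths["manifest"], auto_unbox = TRUE, digits = NA)

  list(profile = x, cv = res, summary = summ, permutation = perm,
       prominence = prom, associations = assoc, paths = paths)
}

stat_col <- function(summ, index) {
  r <- summ[summ$index == index, ]
  c(r$avg, r$sd, r$moe)
}

# display rounding: 3 decimals, half-up
round3 <- function(df) {
  as.data.frame(lapply(df, function(v)
    if (is.numeric(v)) floor(v * 1000 + 0.5) / 1000 else v))
}

write_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

# djb2-style rolling hash over the canonical JSON serialization of the
# numerical configuration (output_dir excluded: it never affects numbers)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
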