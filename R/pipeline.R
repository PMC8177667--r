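#' Default run configuration
#'
#' A plain list controlling the end-to-end pipeline; round-trips losslessly
#' through JSON via \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @param seed Master seed; every random stage derives from it.
#' @param n_samples Monte-Carlo design samples.
#' @param runs,trials_per_run,practice_reps Schedule parameters.
#' @param generator,n_voxels,noise_sigma,code_scale Ground-truth parameters.
#' @param n_subjects Cohort size.
#' @param n_perm Permutations for significance tests.
#' @param alpha Significance threshold for pipeline tests.
#' @param n_replicates Capacity-curve replicates.
#' @param constraint_scope Design constraint scope ("repeating" or "all").
#' @return Named list.
#' @export
run_config <- function(seed = 1, n_samples = 1e4, runs = 2,
                       trials_per_run = 36, practice_reps = 12,
                       generator = "chunk", n_voxels = 200,
                       noise_sigma = c(novel = 8, repeating = 8),
                       code_scale = 1, n_subjects = 22, n_perm = 200,
                       alpha = 0.01, n_replicates = 200,
                       constraint_scope = "repeating") {
  as.list(environment())
}

#' @rdname run_config
#' @param config Configuration list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  if (!is.null(config$noise_sigma)) # keep condition names through JSON
    config$noise_sigma <- as.list(config$noise_sigma)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$noise_sigma)) cfg$noise_sigma <- unlist(cfg$noise_sigma)
  cfg
}

#' Generate and write the experimental design
#'
#' Runs the Monte-Carlo sequence-set search and schedule builder, writing
#' sequences.csv, schedule.csv and design_score.json into \code{out_dir}.
#' Identical configuration and seed reproduce byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param config Configuration list (\code{\link{run_config}}).
#' @return Invisibly, a list with the design and the written paths.
#' @export
run_design <- function(out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- monte_carlo_search(
    n_samples = config$n_samples, seed = config$seed,
    constraints = design_constraints(scope = config$constraint_scope))
  schedule <- build_schedule(design$sequences, design$repeating,
                             runs = config$runs,
                             trials_per_run = config$trials_per_run,
                             practice_reps = config$practice_reps,
                             seed = config$seed + 1L)
  seq_path <- file.path(out_dir, "sequences.csv")
  utils::write.csv(data.frame(
    sequence = design$sequences,
    repeating = design$sequences %in% design$repeating),
    seq_path, row.names = FALSE)
  sched_path <- file.path(out_dir, "schedule.csv")
  write_schedule(schedule, sched_path)
  score_path <- file.path(out_dir, "design_score.json")
  jsonlite::write_json(design$score, score_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(design = design, schedule = schedule,
                 files = c(seq_path, sched_path, score_path)))
}

#' Compute and write the interference tables
#'
#' Shared-code histograms (item-position and bi-gram chunk codes, exact
#' enumeration over the 256-sequence space) and the two capacity curves.
#'
#' @param out_dir Output directory.
#' @param config Configuration list.
#' @return Invisibly, list of tables and written paths.
#' @export
run_interference <- function(out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- enumerate_space()
  ref <- "ABCD"
  files <- character(0); tables <- list()
  for (m in c("item-position", "bigram-chunk")) {
    h <- shared_code_histogram(ref, m, space)
    f <- file.path(out_dir, paste0("histogram_", gsub("-", "_", m), ".csv"))
    utils::write.csv(as.data.frame(h), f, row.names = FALSE)
    cc <- capacity_curve(m, space, n_learn_max = 10,
                         n_replicates = config$n_replicates,
                         seed = config$seed)
    f2 <- file.path(out_dir, paste0("capacity_", gsub("-", "_", m), ".csv"))
    utils::write.csv(as.data.frame(cc), f2, row.names = FALSE)
    files <- c(files, f, f2)
    tables[[m]] <- list(histogram = h, capacity = cc)
  }
  invisible(list(tables = tables, files = files))
}

#' Run the full synthetic pipeline
#'
#' design -> synthetic cohort -> RSA (all four models, with noise ceiling and
#' cross-condition test) -> pattern-distance dynamics -> interference ->
#' model-recovery summary, writing CSV tables and a manifest JSON (with md5
#' checksums, the configuration and the package version) into
#' \code{out_dir}. Deterministic given the configuration.
#'
#' @param out_dir Output directory.
#' @param config Configuration list (\code{\link{run_config}}).
#' @return Invisibly, list of key results and the manifest path.
#' @export
run_pipeline <- function(out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  des <- run_design(out_dir, config)
  schedule <- des$schedule
  main_seqs <- schedule$sequence[schedule$segment == "main"]

  spec <- ground_truth_spec(config$generator, n_voxels = config$n_voxels,
                            noise_sigma = config$noise_sigma,
                            code_scale = config$code_scale)
  cohort <- simulate_cohort(schedule, spec, config$n_subjects,
                            seed = config$seed + 2L)
  rdms <- cohort_rdms(cohort)

  models <- list(
    "item-position" = model_rdm(main_seqs, "hamming"),
    "item-item" = model_rdm(main_seqs, "bigram"),
    "mixture" = model_rdm(main_seqs, "mixture"),
    "chunk" = chunk_rdm(schedule))
  rsa_rows <- NULL
  for (mn in names(models)) {
    gt <- rsa_group_test(models[[mn]], rdms, schedule,
                         n_perm = config$n_perm, alpha = config$alpha,
                         seed = config$seed + 3L)
    nc <- noise_ceiling(rdms)
    rsa_rows <- rbind(rsa_rows, data.frame(
      region = "ROI1", phase = "presentation", model = mn,
      group_r = gt$group_r, p = gt$p,
      ceiling_lower = nc[["lower"]], ceiling_upper = nc[["upper"]]))
  }
  cc <- cross_condition_rsa(models[["item-position"]], rdms, schedule,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = config$seed + 4L)
  rsa_rows$category <- cc$category
  rsa_path <- file.path(out_dir, "rsa_results.csv")
  utils::write.csv(rsa_rows, rsa_path, row.names = FALSE)

  dyn_rows <- NULL
  for (kind in c("between-repeating", "within-repeating",
                 "repeating-vs-novel", "within-novel")) {
    series <- lapply(cohort$patterns, function(p)
      build_series(p$presentation, schedule, kind))
    st <- slope_test(series, n_regions = 1)
    dyn_rows <- rbind(dyn_rows, data.frame(
      region = "ROI1", phase = "presentation", kind = kind,
      mean_slope = mean(st$slopes), t = st$t, p = st$p,
      significant = st$significant))
  }
  dyn_path <- file.path(out_dir, "dynamics_results.csv")
  utils::write.csv(dyn_rows, dyn_path, row.names = FALSE)

  intf <- run_interference(out_dir, config)

  specs <- list(
    "chunk" = ground_truth_spec("chunk", n_voxels = config$n_voxels,
                                noise_sigma = config$noise_sigma),
    "item-position" = ground_truth_spec(
      "item-position", n_voxels = config$n_voxels,
      noise_sigma = c(novel = unname(config$noise_sigma[["novel"]]),
                      repeating = unname(config$noise_sigma[["novel"]]) / 4)))
  recov <- recovery_experiment(specs, schedule,
                               n_subjects = config$n_subjects,
                               n_perm = config$n_perm, alpha = config$alpha,
                               seed = config$seed + 5L)
  recov_path <- file.path(out_dir, "recovery_summary.csv")
  utils::write.csv(recov, recov_path, row.names = FALSE)

  files <- c(des$files, rsa_path, dyn_path, intf$files, recov_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "seqchunk",
    version = as.character(utils::packageVersion("seqchunk")),
    config = config,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(rsa = rsa_rows, dynamics = dyn_rows,
                 recovery = recov, files = files,
                 manifest = manifest_path))
}
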