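#' Run the end-to-end screen analysis pipeline
#'
#' Executes (optionally) library + droplet-sort + read simulation, then
#' quality filtering, substitution calling, count thresholding, PU logistic
#' fitting per replicate, cross-replicate concordance with outlier
#' exclusion, coefficient combination, and the site-tolerance profile.
#' All tables are written as TSV under `out_dir` together with a JSON run
#' manifest; every stage logs its read/row counts. Reruns with the same
#' configuration and seed reproduce the outputs.
#'
#' @param config A YAML config path or a list from [load_config()].
#' @param out_dir Optional override of the configured output directory.
#' @param quiet Suppress per-stage messages (default FALSE).
#' @return A `run_manifest` list: config echo, seeds, per-stage counts,
#'   output paths and their MD5 digests, replicate concordance and
#'   exclusions.
#' @export
run_screen_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) load_config(config) else {
    validate_config(config)
    config
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(cfg$seed)

  if (!isTRUE(cfg$simulate) && is.null(cfg$reference_fasta))
    stop("stage[input]: reference_fasta required when simulate is false")
  if (!isTRUE(cfg$simulate))
    stop("stage[input]: analysis of pre-existing FASTQ pools is driven ",
         "through the individual functions; run_screen_pipeline currently ",
         "orchestrates simulated screens (simulate: true)")

  # --- simulate ------------------------------------------------------------
  reference <- if (!is.null(cfg$reference_fasta)) {
    read_reference_fasta(cfg$reference_fasta,
                         numbering_offset = cfg$pipeline$numbering_offset)
  } else {
    random_coding_sequence(cfg$library$n_codons, seed = seed,
                           numbering_offset = cfg$pipeline$numbering_offset)
  }
  lib <- simulate_epcr_library(reference, cfg$library$n_variants,
                               cfg$library$mean_nt_mutations, seed = seed)
  truth_keys <- sort(unique(unlist(lib$aa_subs, use.names = FALSE)))
  truth_beta <- simulate_truth_coefficients(
    truth_keys, frac_deleterious = cfg$library$frac_deleterious,
    seed = seed + 1L)
  lib <- assign_ground_truth(lib, truth_beta,
                             target_pi = cfg$screen$prior_pi,
                             seed = seed + 2L)
  say("stage[simulate]: %d variants, %.1f%% active (target %.0f%%)",
      cfg$library$n_variants, 100 * mean(lib$is_active),
      100 * cfg$screen$prior_pi)
  write_truth_table(lib, file.path(cfg$out_dir, "variant_truth.tsv"))

  scr_base <- screen_config(
    occupancy_lambda = -log(1 - cfg$screen$occupancy),
    incubation_min = cfg$screen$incubation_min,
    gate_threshold = cfg$screen$gate_threshold,
    active_rate_mean = cfg$screen$active_rate_mean,
    inactive_rate_mean = cfg$screen$inactive_rate_mean,
    expression_noise_cv = cfg$screen$expression_noise_cv,
    autofluorescence_sd = cfg$screen$autofluorescence_sd,
    prior_pi = cfg$screen$prior_pi)

  tables <- list()
  stage_counts <- list()
  paths <- character(0)
  for (r in seq_len(cfg$replicates)) {
    lib_r <- lib
    if (r %in% cfg$debug_shuffle_replicates) {
      # diagnostic hook: destroy the genotype-activity link for this replicate
      set.seed(seed + 90L + r)
      perm <- sample.int(length(lib$variant_id))
      lib_r$is_active <- lib$is_active[perm]
      lib_r$p_active <- lib$p_active[perm]
      say("stage[simulate]: replicate %d uses shuffled ground truth", r)
    }
    scr <- scr_base
    scr$seed <- seed + 10L * r
    sorted <- simulate_droplet_sort(lib_r, scr, cfg$screen$n_droplets)
    say("stage[sort rep%d]: purity %.1f%%, %.1f-fold enrichment",
        r, 100 * sorted$summary$sorted_purity,
        sorted$summary$fold_enrichment)

    reads_in <- generate_reads(sorted$input_pool, lib_r,
                               depth = cfg$sequencing$depth,
                               error_rate = cfg$sequencing$error_rate,
                               seed = seed + 10L * r + 1L,
                               pool_label = "input", replicate = r)
    reads_so <- generate_reads(sorted$sorted_pool, lib_r,
                               depth = cfg$sequencing$depth,
                               error_rate = cfg$sequencing$error_rate,
                               seed = seed + 10L * r + 2L,
                               pool_label = "sorted", replicate = r)

    # --- QC + call + count -------------------------------------------------
    reads_in <- filter_reads_by_quality(reads_in, cfg$pipeline$min_read_quality)
    reads_so <- filter_reads_by_quality(reads_so, cfg$pipeline$min_read_quality)
    say("stage[qc rep%d]: %d input + %d sorted reads pass (discarded %d + %d)",
        r, length(reads_in), length(reads_so),
        reads_in$provenance$n_discarded_quality,
        reads_so$provenance$n_discarded_quality)

    counts <- build_count_table(reads_in, reads_so, reference)
    counts_f <- apply_count_threshold(counts, cfg$pipeline$min_mutation_count)
    say("stage[count rep%d]: %d substitutions observed, %d retained",
        r, nrow(counts), nrow(counts_f))
    cpath <- file.path(cfg$out_dir, sprintf("counts_rep%d.tsv", r))
    write_count_table(counts_f, cpath)
    paths <- c(paths, cpath)

    # --- PU fit ------------------------------------------------------------
    called_in <- call_substitutions(reads_in, reference)
    called_so <- call_substitutions(reads_so, reference)
    fm <- feature_matrix(called_in$substitutions, called_so$substitutions,
                         min_mutation_count = cfg$pipeline$min_mutation_count)
    fit <- suppressWarnings(fit_pu_logistic(
      fm, prior_pi = cfg$screen$prior_pi,
      l2_penalty = cfg$fit$l2_penalty, tol = cfg$fit$tol,
      max_iter = cfg$fit$max_iter, seed = seed + 10L * r + 3L,
      compute_se = FALSE))
    say("stage[fit rep%d]: %d coefficients, beta0 = %.2f, converged: %s",
        r, nrow(fit), attr(fit, "beta0"), attr(fit, "converged"))
    fpath <- file.path(cfg$out_dir, sprintf("coefficients_rep%d.tsv", r))
    write_coefficient_table(fit, fpath)
    paths <- c(paths, fpath)
    tables[[sprintf("rep%d", r)]] <- fit
    stage_counts[[sprintf("rep%d", r)]] <- list(
      n_input_reads = length(reads_in), n_sorted_reads = length(reads_so),
      n_discarded_quality = reads_in$provenance$n_discarded_quality +
        reads_so$provenance$n_discarded_quality,
      n_substitutions_observed = nrow(counts),
      n_substitutions_retained = nrow(counts_f),
      sorted_purity = sorted$summary$sorted_purity,
      fold_enrichment = sorted$summary$fold_enrichment,
      fit_converged = attr(fit, "converged"))
  }

  # --- concordance + combine ----------------------------------------------
  excluded <- character(0)
  concordance <- NULL
  if (length(tables) >= 2L) {
    conc <- replicate_concordance(tables, cfg$fit$exclusion_threshold)
    excluded <- conc$excluded
    concordance <- conc$correlations
    say("stage[concordance]: excluded: %s",
        if (length(excluded)) paste(excluded, collapse = ", ") else "none")
  }
  combined <- combine_replicates(tables, excluded)
  combo_path <- file.path(cfg$out_dir, "coefficients_combined.tsv")
  write_coefficient_table(combined, combo_path)
  paths <- c(paths, combo_path)

  profile <- percentile_rank(site_tolerance(combined))
  tol_path <- file.path(cfg$out_dir, "tolerance.tsv")
  utils::write.table(as.data.frame(profile), tol_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, tol_path, file.path(cfg$out_dir, "variant_truth.tsv"))
  say("stage[profiles]: %d positions scored", nrow(profile))

  manifest <- list(
    tool = "dropscan",
    version = as.character(utils::packageVersion("dropscan")),
    config = unclass(cfg),
    seed = seed,
    stage_counts = stage_counts,
    concordance = if (!is.null(concordance)) as.data.frame(concordance),
    excluded_replicates = excluded,
    outputs = stats::setNames(as.list(unname(tools::md5sum(paths))),
                              basename(paths))
  )
  class(manifest) <- c("run_manifest", "list")
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
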