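#' Simulate an error-prone PCR variant library
#'
#' Each variant receives `Poisson(mean_nt_mutations)` single-nucleotide
#' substitutions placed uniformly along the gene, with the alternative base
#' drawn uniformly from the three non-reference bases (no transition bias; the
#' mutation spectrum can be swapped by post-processing the returned
#' nucleotide substitutions). Amino-acid substitutions are derived by
#' translating each mutated sequence against the reference; positions are
#' reported in canonical numbering (construct codon + `numbering_offset`).
#' Only substitutions are modelled (no indels).
#'
#' @param reference A [coding_sequence()].
#' @param n_variants Number of variants (>= 1).
#' @param mean_nt_mutations Mean nucleotide substitutions per variant
#'   (default 4.5, typical of a mutagenic PCR protocol).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @return A `variant_library`: list with `reference`, `variant_id`,
#'   `sequence` (mutated DNA), `nt_subs` (list of per-variant data frames
#'   with columns position/ref/alt), `aa_subs` (list of character vectors of
#'   substitution keys such as "D175A"), and placeholders `p_active`,
#'   `is_active` filled by [assign_ground_truth()].
#' @export
simulate_epcr_library <- function(reference, n_variants,
                                  mean_nt_mutations = 4.5, seed = 1L) {
  stopifnot(inherits(reference, "coding_sequence"))
  if (n_variants < 1L) stop("n_variants must be >= 1")
  if (mean_nt_mutations < 0) stop("mean_nt_mutations must be >= 0")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref_chars <- strsplit(reference$nucleotides, "", fixed = TRUE)[[1L]]
  L <- length(ref_chars)
  k <- pmin(stats::rpois(n_variants, mean_nt_mutations), L)

  sequence <- character(n_variants)
  nt_subs <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    if (k[i] == 0L) {
      sequence[i] <- reference$nucleotides
      nt_subs[[i]] <- data.frame(position = integer(0), ref = character(0),
                                 alt = character(0))
      next
    }
    pos <- sort(sample.int(L, k[i]))
    ref_b <- ref_chars[pos]
    # uniform choice among the 3 non-reference bases
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1L), "")
    chars <- ref_chars
    chars[pos] <- alt_b
    sequence[i] <- paste(chars, collapse = "")
    nt_subs[[i]] <- data.frame(position = pos, ref = ref_b, alt = alt_b,
                               row.names = NULL)
  }

  aa_subs <- derive_aa_substitutions(sequence, reference)
  structure(
    list(reference = reference,
         variant_id = sprintf("var%06d", seq_len(n_variants)),
         sequence = sequence, nt_subs = nt_subs, aa_subs = aa_subs,
         p_active = rep(NA_real_, n_variants),
         is_active = rep(NA, n_variants),
         seed = as.integer(seed)),
    class = "variant_library"
  )
}

#' @export
print.variant_library <- function(x, ...) {
  cat(sprintf("<variant_library> %d variants of %s (%d aa)\n",
              length(x$variant_id), x$reference$id, nchar(x$reference$aa)))
  if (!all(is.na(x$is_active)))
    cat(sprintf("  ground truth: %.1f%% active (target prior %.2f)\n",
                100 * mean(x$is_active), attr(x, "target_pi")))
  invisible(x)
}

# Amino-acid substitution keys for a vector of full-length mutant sequences,
# by codon-wise comparison of translations (canonical numbering).
derive_aa_substitutions <- function(sequence, reference) {
  n <- length(sequence)
  if (n == 0L) return(list())
  aa <- translate_nt(sequence)
  ref_aa <- strsplit(reference$aa, "", fixed = TRUE)[[1L]]
  mat <- aa_char_matrix(aa)                      # residues x variants
  diff <- which(mat != ref_aa, arr.ind = TRUE)
  out <- rep(list(character(0)), n)
  if (nrow(diff) > 0L) {
    ord <- order(diff[, 2L], diff[, 1L])
    diff <- diff[ord, , drop = FALSE]
    keys <- sub_key(ref_aa[diff[, 1L]],
                    diff[, 1L] + reference$numbering_offset,
                    mat[diff])
    sp <- split(keys, diff[, 2L])
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Assign latent activity labels to a variant library
#'
#' The activity model is logistic: `p(active) = plogis(beta0 + sum of
#' coefficients over the variant's amino-acid substitutions)`, with the
#' convention that negative coefficients are deleterious. Any stop-gain
#' substitution forces `p(active) = 0`. The intercept `beta0` is solved by
#' bisection so the library-mean activity probability equals `target_pi`,
#' then `is_active` is sampled Bernoulli per variant.
#'
#' @param library A `variant_library`.
#' @param coefficients Named numeric vector mapping substitution keys to
#'   log-odds effects; substitutions absent from the map contribute 0.
#' @param target_pi Target library-mean active fraction, in (0, 1).
#' @param seed Integer seed for the Bernoulli draws.
#' @return The library with `p_active`, `is_active`, and attributes
#'   `beta0_truth`, `target_pi`, `truth_coefficients` filled in.
#' @export
assign_ground_truth <- function(library, coefficients, target_pi = 0.25,
                                seed = 1L) {
  stopifnot(inherits(library, "variant_library"))
  if (!(target_pi > 0 && target_pi < 1)) stop("target_pi must be in (0,1)")
  set.seed(seed)
  n <- length(library$variant_id)

  flat <- unlist(library$aa_subs, use.names = FALSE)
  idx <- rep.int(seq_len(n), lengths(library$aa_subs))
  eff <- coefficients[flat]
  eff[is.na(eff)] <- 0
  eta <- numeric(n)
  if (length(flat) > 0L) {
    agg <- rowsum(eff, idx)
    eta[as.integer(rownames(agg))] <- agg[, 1L]
  }
  has_stop <- vapply(library$aa_subs,
                     function(s) any(endsWith(s, "*")), logical(1L))

  mean_p <- function(b0) {
    p <- stats::plogis(b0 + eta)
    p[has_stop] <- 0
    mean(p)
  }
  if (mean_p(50) < target_pi)
    stop("cannot calibrate intercept: achievable active fraction (",
         signif(mean_p(50), 3), ") is below target_pi; too many variants ",
         "are forced inactive")
  b0 <- stats::uniroot(function(b) mean_p(b) - target_pi,
                       lower = -50, upper = 50, tol = 1e-10)$root

  p <- stats::plogis(b0 + eta)
  p[has_stop] <- 0
  library$p_active <- p
  library$is_active <- stats::runif(n) < p
  attr(library, "beta0_truth") <- b0
  attr(library, "target_pi") <- target_pi
  attr(library, "truth_coefficients") <- coefficients
  library
}

#' Draw ground-truth fitness coefficients for simulation
#'
#' A two-component effect model typical of mutational scans: a fraction of
#' substitutions are strongly deleterious, the rest approximately neutral.
#' Stop gains need no coefficient (they are forced inactive by
#' [assign_ground_truth()]).
#'
#' @param keys Character vector of substitution keys to score.
#' @param frac_deleterious Fraction of substitutions drawn from the
#'   deleterious component (default 0.4).
#' @param del_mean,del_sd Mean/sd of the deleterious component (default -4, 1).
#' @param neut_sd Sd of the zero-mean neutral component (default 0.5).
#' @param seed Integer seed.
#' @return Named numeric vector of coefficients.
#' @export
simulate_truth_coefficients <- function(keys, frac_deleterious = 0.4,
                                        del_mean = -4, del_sd = 1,
                                        neut_sd = 0.5, seed = 1L) {
  set.seed(seed)
  n <- length(keys)
  del <- stats::runif(n) < frac_deleterious
  beta <- ifelse(del, stats::rnorm(n, del_mean, del_sd),
                 stats::rnorm(n, 0, neut_sd))
  names(beta) <- keys
  beta
}

#' Screen configuration
#'
#' Parameters of the droplet encapsulation, incubation, and fluorescence
#' gate. Defaults reproduce the operating point of a low-occupancy
#' droplet sorter: 10% of droplets occupied (`lambda = -log(0.9)`), ~3 min
#' on-chip incubation, and a gate that passes essentially all
#' active-containing droplets while co-encapsulation carryover and
#' autofluorescence provide the false-positive mechanisms.
#'
#' @param occupancy_lambda Poisson mean cells/droplet; default `-log(0.9)`
#'   so that P(>= 1 cell) = 0.10.
#' @param incubation_min On-chip incubation time, minutes.
#' @param gate_threshold Sorting gate, fluorescence units.
#' @param active_rate_mean Fluorescence accumulation rate of an active
#'   variant, units/min.
#' @param inactive_rate_mean Residual rate of an inactive variant, units/min.
#' @param expression_noise_cv Lognormal coefficient of variation of per-cell
#'   expression (multiplies the rate; mean 1).
#' @param autofluorescence_sd Gaussian droplet background, fluorescence units.
#' @param prior_pi Fraction of the input library that is active.
#' @param seed Integer seed.
#' @return A `screen_config` list.
#' @export
screen_config <- function(occupancy_lambda = -log(0.9),
                          incubation_min = 3,
                          gate_threshold = 60,
                          active_rate_mean = 100,
                          inactive_rate_mean = 2,
                          expression_noise_cv = 0.3,
                          autofluorescence_sd = 10,
                          prior_pi = 0.25,
                          seed = 1L) {
  if (occupancy_lambda <= 0) stop("occupancy_lambda must be > 0")
  if (!(prior_pi > 0 && prior_pi < 1)) stop("prior_pi must be in (0,1)")
  if (any(c(incubation_min, active_rate_mean, inactive_rate_mean,
            expression_noise_cv, autofluorescence_sd) < 0))
    stop("rates, noise, and incubation must be >= 0")
  structure(list(occupancy_lambda = occupancy_lambda,
                 incubation_min = incubation_min,
                 gate_threshold = gate_threshold,
                 active_rate_mean = active_rate_mean,
                 inactive_rate_mean = inactive_rate_mean,
                 expression_noise_cv = expression_noise_cv,
                 autofluorescence_sd = autofluorescence_sd,
                 prior_pi = prior_pi, seed = as.integer(seed)),
            class = "screen_config")
}

#' Simulate a fluorescence-gated droplet sort
#'
#' Droplets are loaded with `Poisson(lambda)` cells; each cell carries a
#' variant drawn uniformly from the library. Droplet fluorescence is the sum
#' over resident cells of rate x incubation x lognormal expression noise,
#' plus Gaussian autofluorescence. Droplets above the gate contribute ALL
#' resident variants to the sorted pool, so co-encapsulation of an inactive
#' cell with an active one is the built-in false-positive mechanism. The
#' input pool is the unsorted multiset of all encapsulated cells.
#'
#' @param library A `variant_library` with ground truth assigned.
#' @param config A [screen_config()].
#' @param n_droplets Number of droplets to simulate.
#' @return List with `input_pool` and `sorted_pool` (integer vectors of
#'   variant indices, one entry per sorted/encapsulated cell) and `summary`
#'   (occupied fraction, pool sizes, sorted purity, input active fraction,
#'   fold enrichment).
#' @export
simulate_droplet_sort <- function(library, config = screen_config(),
                                  n_droplets = 1e5) {
  stopifnot(inherits(library, "variant_library"))
  if (any(is.na(library$is_active)))
    stop("library has no ground truth; run assign_ground_truth() first")
  if (config$occupancy_lambda <= 0) stop("occupancy_lambda must be > 0")
  set.seed(config$seed)
  n_var <- length(library$variant_id)

  k <- stats::rpois(n_droplets, config$occupancy_lambda)
  occ <- which(k > 0L)
  droplet_of_cell <- rep.int(seq_along(occ), k[occ])   # index into occ
  n_cells <- length(droplet_of_cell)
  vid <- sample.int(n_var, n_cells, replace = TRUE)

  cv <- config$expression_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  expr <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  rate <- ifelse(library$is_active[vid],
                 config$active_rate_mean, config$inactive_rate_mean)
  signal <- rate * config$incubation_min * expr

  fl <- rep(0, length(occ))
  agg <- rowsum(signal, droplet_of_cell)
  fl[as.integer(rownames(agg))] <- agg[, 1L]
  fl <- fl + stats::rnorm(length(occ), 0, config$autofluorescence_sd)

  pass <- fl > config$gate_threshold
  sorted_pool <- vid[pass[droplet_of_cell]]
  input_pool <- vid

  purity <- if (length(sorted_pool)) mean(library$is_active[sorted_pool]) else NA_real_
  input_active <- if (n_cells) mean(library$is_active[input_pool]) else NA_real_
  list(
    input_pool = input_pool,
    sorted_pool = sorted_pool,
    summary = list(
      n_droplets = n_droplets,
      occupied_fraction = length(occ) / n_droplets,
      n_cells = n_cells,
      n_sorted_droplets = sum(pass),
      n_sorted_cells = length(sorted_pool),
      sorted_purity = purity,
      input_active_fraction = input_active,
      fold_enrichment = purity / input_active
    )
  )
}

#' Generate sequencing reads from a variant pool
#'
#' Full-length reads are sampled with replacement from the pool; each base is
#' substituted independently with probability `error_rate` (uniform choice of
#' the three alternative bases). Phred qualities are set consistently with
#' the error rate (`Q = -10 log10(error_rate)`, capped at 41).
#'
#' @param pool Integer vector of variant indices (a multiset, e.g. from
#'   [simulate_droplet_sort()]).
#' @param library The `variant_library` the pool indexes.
#' @param depth Number of reads to generate.
#' @param error_rate Per-base substitution error probability in [0, 0.1).
#' @param seed Integer seed; output is byte-identical across reruns.
#' @param pool_label "input" or "sorted".
#' @param replicate Integer replicate id.
#' @return A `read_set`: list with `bases`, `quals` (character vectors of
#'   equal element lengths), `pool`, `replicate`, and `provenance`.
#' @export
generate_reads <- function(pool, library, depth, error_rate = 0.001,
                           seed = 1L, pool_label = c("input", "sorted"),
                           replicate = 1L) {
  pool_label <- match.arg(pool_label)
  if (length(pool) == 0L) stop("empty pool")
  if (!(error_rate >= 0 && error_rate < 0.1))
    stop("error_rate must be in [0, 0.1)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  idx <- pool[sample.int(length(pool), depth, replace = TRUE)]
  seqs <- library$sequence[idx]
  L <- nchar(library$reference$nucleotides)

  if (error_rate > 0) {
    n_err <- stats::rbinom(depth, L, error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(L, n_err[i])
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(bases, b), 1L), "")
      seqs[i] <- paste(chars, collapse = "")
    }
  }
  q <- if (error_rate == 0) 41L else min(41L, max(2L, round(-10 * log10(error_rate))))
  quals <- rep(strrep(intToUtf8(q + 33L), L), depth)
  structure(
    list(bases = seqs, quals = quals, pool = pool_label,
         replicate = as.integer(replicate),
         source_variant = library$variant_id[idx],
         provenance = list(seed = as.integer(seed), depth = depth,
                           error_rate = error_rate,
                           reference = library$reference$id)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads (%s pool, replicate %d)\n",
              length(x$bases), x$pool, x$replicate))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$bases)

#' Write a read set to FASTQ
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  ids <- sprintf("%s_rep%d_read%06d", reads$pool, reads$replicate,
                 seq_along(reads$bases))
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$bases, ids)),
    Biostrings::PhredQuality(reads$quals)))
  # the writer warns about dropped metadata columns on the plain string set
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @param pool_label "input" or "sorted".
#' @param replicate Integer replicate id.
#' @return A `read_set`.
#' @export
read_fastq <- function(path, pool_label = c("input", "sorted"),
                       replicate = 1L) {
  pool_label <- match.arg(pool_label)
  # reader mirrors the writer's cosmetic metadata-column warning
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  structure(
    list(bases = unname(as.character(x)),
         quals = unname(as.character(methods::slot(x, "quality"))),
         pool = pool_label, replicate = as.integer(replicate),
         provenance = list(path = path)),
    class = "read_set"
  )
}

#' Screening throughput of a droplet sorter
#'
#' @param droplet_rate_hz Droplet analysis rate, Hz.
#' @param occupancy Fraction of droplets containing a cell, in [0, 1].
#' @return List with `cells_per_second` and `variants_per_hour`.
#' @examples
#' expected_throughput(1000, 0.10)  # 100 cells/s, 360,000 variants/hour
#' @export
expected_throughput <- function(droplet_rate_hz, occupancy) {
  if (droplet_rate_hz < 0) stop("droplet_rate_hz must be >= 0")
  if (!(occupancy >= 0 && occupancy <= 1)) stop("occupancy must be in [0,1]")
  cps <- droplet_rate_hz * occupancy
  list(cells_per_second = cps, variants_per_hour = 3600 * cps)
}

#' Write the variant truth table as TSV
#'
#' @param library A `variant_library` with ground truth.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(library, path) {
  df <- data.frame(
    variant_id = library$variant_id,
    aa_substitutions = vapply(library$aa_subs, paste, "", collapse = ","),
    n_nt_substitutions = vapply(library$nt_subs, nrow, 1L),
    p_active = library$p_active,
    is_active = library$is_active
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
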