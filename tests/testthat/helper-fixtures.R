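# Shared fixtures: all built in code at test time.

# Small stop-free reference gene.
toy_reference <- function(n_codons = 10L, seed = 101L, offset = 0L) {
  random_coding_sequence(n_codons, seed = seed, id = "toy",
                         numbering_offset = offset)
}

# A read_set built by hand from base/quality strings.
hand_read_set <- function(bases, quals, pool = "input", replicate = 1L) {
  structure(list(bases = bases, quals = quals, pool = pool,
                 replicate = as.integer(replicate), provenance = list()),
            class = "read_set")
}

# Quality string with a given mean Phred over length L (two-level code).
qual_with_mean <- function(mean_q, L) {
  lo <- floor(mean_q)
  n_hi <- round((mean_q - lo) * L)
  paste(intToUtf8(c(rep(lo + 1L, n_hi), rep(lo, L - n_hi)) + 33L,
                  multiple = TRUE), collapse = "")
}

# A variant library over an explicit set of substitution keys, bypassing
# sequence-level simulation: used for fitness-recovery experiments where
# the truth coefficients must act on a controlled feature set.
keyed_library <- function(keys, n_variants, max_subs = 3L, seed = 1L) {
  set.seed(seed)
  aa_subs <- lapply(seq_len(n_variants),
                    function(i) sample(keys, sample.int(max_subs, 1L)))
  structure(list(reference = NULL,
                 variant_id = sprintf("v%05d", seq_len(n_variants)),
                 sequence = NULL, nt_subs = NULL, aa_subs = aa_subs,
                 p_active = rep(NA_real_, n_variants),
                 is_active = rep(NA, n_variants)),
            class = "variant_library")
}

# Random substitution keys, parseable and position-unique.
random_keys <- function(n, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  sprintf("%s%d%s", sample(aa, n, TRUE), seq_len(n), sample(aa, n, TRUE))
}

# Observation lists (per-read substitution keys) sampled from a pool of
# variant indices.
pool_observations <- function(library, pool, depth, seed = 1L) {
  set.seed(seed)
  library$aa_subs[pool[sample.int(length(pool), depth, replace = TRUE)]]
}

# Independent codon translation oracle for enumeration tests (named lookup,
# bypassing the package's translation path).
codon_oracle <- local({
  code <- NULL
  function(codon) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    unname(code[codon])
  }
})
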