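#' Pipeline thresholds for read QC and count filtering
#'
#' @param min_read_quality Minimum mean Phred quality for a read to be kept
#'   (default 30).
#' @param min_mutation_count Minimum total observation count for a
#'   substitution to be retained (default 10).
#' @param numbering_offset Canonical-numbering offset of the construct.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_read_quality = 30, min_mutation_count = 10,
                            numbering_offset = 0L) {
  if (min_read_quality < 0 || min_mutation_count < 0)
    stop("thresholds must be >= 0")
  structure(list(min_read_quality = min_read_quality,
                 min_mutation_count = as.integer(min_mutation_count),
                 numbering_offset = as.integer(numbering_offset)),
            class = "pipeline_config")
}

#' Filter reads by mean Phred quality
#'
#' Retains exactly the reads whose mean per-base Phred quality is greater
#' than or equal to `min_read_quality`; the number discarded is recorded in
#' the returned set's `provenance$n_discarded_quality`.
#'
#' @param reads A `read_set`.
#' @param min_read_quality Mean-quality threshold in Phred units (default 30).
#' @return The filtered `read_set`.
#' @export
filter_reads_by_quality <- function(reads, min_read_quality = 30) {
  stopifnot(inherits(reads, "read_set"))
  n <- length(reads$bases)
  if (n == 0L) {
    reads$provenance$n_discarded_quality <- 0L
    return(reads)
  }
  mean_q <- vapply(reads$quals,
                   function(q) mean(utf8ToInt(q)) - 33, numeric(1L),
                   USE.NAMES = FALSE)
  keep <- mean_q >= min_read_quality
  reads$bases <- reads$bases[keep]
  reads$quals <- reads$quals[keep]
  if (!is.null(reads$source_variant))
    reads$source_variant <- reads$source_variant[keep]
  reads$provenance$n_discarded_quality <- sum(!keep)
  reads
}

#' Call amino-acid substitutions from gapless full-length reads
#'
#' Codon-aware comparison of each read's translation against the reference
#' translation. Reads must span the full construct (gapless contract); reads
#' of any other length are rejected and counted. Synonymous changes yield no
#' call; stop gains are reported with alt `*`; positions are canonical
#' (construct codon + numbering offset).
#'
#' @param reads A `read_set` or a character vector of read sequences.
#' @param reference A [coding_sequence()].
#' @return List with `substitutions` (per retained read, character vector of
#'   keys), `n_rejected_length` (reads discarded for length mismatch), and
#'   `n_reads` (retained read count).
#' @export
call_substitutions <- function(reads, reference) {
  bases <- if (inherits(reads, "read_set")) reads$bases else reads
  L <- nchar(reference$nucleotides)
  ok <- nchar(bases) == L
  calls <- derive_aa_substitutions(bases[ok], reference)
  list(substitutions = calls,
       n_rejected_length = sum(!ok),
       n_reads = sum(ok))
}

#' Tally per-substitution counts for an input/sorted read pair
#'
#' Each read increments one row per substitution it carries (a read with k
#' substitutions contributes to k rows). Totals record the number of
#' QC-passing, length-conforming reads per pool.
#'
#' @param input_reads,sorted_reads `read_set`s (after QC filtering).
#' @param reference A [coding_sequence()].
#' @return A `count_table`: data frame with columns `key`, `ref`,
#'   `position`, `alt`, `count_input`, `count_sorted`, with attributes
#'   `n_input`, `n_sorted` (reads per pool) and `replicate`.
#' @export
build_count_table <- function(input_reads, sorted_reads, reference) {
  ci <- call_substitutions(input_reads, reference)
  cs <- call_substitutions(sorted_reads, reference)
  tab_i <- table(unlist(ci$substitutions, use.names = FALSE))
  tab_s <- table(unlist(cs$substitutions, use.names = FALSE))
  keys <- union(names(tab_i), names(tab_s))
  if (length(keys) == 0L) {
    out <- data.frame(key = character(0), ref = character(0),
                      position = integer(0), alt = character(0),
                      count_input = integer(0), count_sorted = integer(0))
  } else {
    parsed <- parse_sub_key(keys)
    out <- data.frame(
      key = keys,
      ref = parsed$ref, position = parsed$position, alt = parsed$alt,
      count_input = as.integer(tab_i[keys]),
      count_sorted = as.integer(tab_s[keys])
    )
    out$count_input[is.na(out$count_input)] <- 0L
    out$count_sorted[is.na(out$count_sorted)] <- 0L
    out <- out[order(out$position, out$alt), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_input") <- ci$n_reads
  attr(out, "n_sorted") <- cs$n_reads
  attr(out, "replicate") <-
    if (inherits(input_reads, "read_set")) input_reads$replicate else NA_integer_
  class(out) <- c("count_table", "data.frame")
  out
}

#' Drop rarely observed substitutions
#'
#' Removes rows whose pooled count (input + sorted) is below
#' `min_mutation_count`; a substitution observed at least that many times is
#' retained. Pool totals are unchanged.
#'
#' @param table A `count_table`.
#' @param min_mutation_count Minimum pooled observation count (default 10).
#' @return The filtered `count_table`.
#' @export
apply_count_threshold <- function(table, min_mutation_count = 10) {
  if (min_mutation_count < 0) stop("min_mutation_count must be >= 0")
  keep <- (table$count_input + table$count_sorted) >= min_mutation_count
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("n_input", "n_sorted", "replicate"))
    attr(out, a) <- attr(table, a)
  attr(out, "n_dropped_rare") <- sum(!keep)
  class(out) <- c("count_table", "data.frame")
  out
}

#' Read pre-aligned full-length reads from a SAM file
#'
#' Accepts gapless, full-length alignments only (CIGAR `<L>M`); anything
#' else is dropped with a count. Alignment itself is outside this package's
#' scope; this is a convenience entry point for externally mapped reads.
#'
#' @param path SAM file path.
#' @param reference A [coding_sequence()]; used to check read span.
#' @param pool_label "input" or "sorted".
#' @param replicate Integer replicate id.
#' @return A `read_set`.
#' @export
read_sam_reads <- function(path, reference, pool_label = c("input", "sorted"),
                           replicate = 1L) {
  pool_label <- match.arg(pool_label)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  L <- nchar(reference$nucleotides)
  want_cigar <- paste0(L, "M")
  keep <- vapply(fields, function(f)
    length(f) >= 11L && f[6L] == want_cigar && f[4L] == "1", logical(1L))
  bases <- vapply(fields[keep], `[`, "", 10L)
  quals <- vapply(fields[keep], `[`, "", 11L)
  # '*' quality means unavailable; substitute maximal quality
  quals[quals == "*"] <- strrep(intToUtf8(41L + 33L), L)
  structure(
    list(bases = bases, quals = quals, pool = pool_label,
         replicate = as.integer(replicate),
         provenance = list(path = path, n_dropped_alignment = sum(!keep))),
    class = "read_set"
  )
}

#' Write a count table as TSV
#'
#' @param table A `count_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
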