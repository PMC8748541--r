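#' Construct a coding sequence
#'
#' A validated protein-coding DNA sequence with an optional residue-numbering
#' offset. The offset is added to construct-internal codon positions to obtain
#' canonical residue numbering, so that e.g. a pro-domain-truncated construct
#' still reports substitutions at the positions used for the full-length
#' protein.
#'
#' @param id Character identifier.
#' @param nucleotides DNA string; length must be divisible by 3 and contain
#'   only A/C/G/T. The wild-type translation must not contain an internal
#'   stop codon (a terminal stop is allowed).
#' @param numbering_offset Integer added to construct codon positions to give
#'   canonical residue numbers (default 0).
#' @return An object of class `coding_sequence` with fields `id`,
#'   `nucleotides`, `numbering_offset`, and the derived translation `aa`.
#' @examples
#' cs <- coding_sequence("toy", "ATGGATGCTTAA")
#' cs$aa  # "MDA*"
#' @export
coding_sequence <- function(id, nucleotides, numbering_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(nucleotides), length(nucleotides) == 1L)
  nucleotides <- toupper(nucleotides)
  if (nchar(nucleotides) == 0L || nchar(nucleotides) %% 3L != 0L)
    stop("coding sequence length must be a positive multiple of 3")
  if (grepl("[^ACGT]", nucleotides))
    stop("coding sequence must contain only A/C/G/T (no ambiguity codes)")
  aa <- translate_nt(nucleotides)
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", internal, fixed = TRUE))
    stop("wild-type translation contains an internal stop codon")
  structure(
    list(id = id, nucleotides = nucleotides,
         numbering_offset = as.integer(numbering_offset), aa = aa),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt / %d aa (numbering offset %+d)\n",
              x$id, nchar(x$nucleotides), nchar(x$aa), x$numbering_offset))
  invisible(x)
}

#' Translate DNA strings to amino-acid strings
#'
#' Thin vectorized wrapper around [Biostrings::translate()]; stop codons are
#' reported as `*` and may occur internally (mutant sequences).
#'
#' @param nt Character vector of DNA strings (lengths divisible by 3).
#' @return Character vector of amino-acid strings.
#' @export
translate_nt <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

#' Read a reference coding sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param numbering_offset Passed to [coding_sequence()].
#' @return A `coding_sequence`.
#' @export
read_reference_fasta <- function(path, numbering_offset = 0L) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  coding_sequence(names(ss)[1L], as.character(ss[[1L]]), numbering_offset)
}

#' Generate a random stop-free coding sequence
#'
#' Convenience generator for simulations and examples: a random gene of
#' `n_codons` codons (ATG start, TAA terminal stop, no internal stops).
#'
#' @param n_codons Number of codons including start and stop (>= 3).
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @param numbering_offset Passed to [coding_sequence()].
#' @return A `coding_sequence`.
#' @export
random_coding_sequence <- function(n_codons, seed = 1L, id = "synthetic_gene",
                                   numbering_offset = 0L) {
  stopifnot(n_codons >= 3L)
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  nt <- paste(c("ATG", body, "TAA"), collapse = "")
  coding_sequence(id, nt, numbering_offset)
}

# Split amino-acid strings into a residue matrix (rows = residues).
aa_char_matrix <- function(aa) {
  matrix(unlist(strsplit(aa, "", fixed = TRUE), use.names = FALSE),
         nrow = nchar(aa[1L]))
}

# Format a substitution key, e.g. "D175A" or "Q12*".
sub_key <- function(ref, pos, alt) paste0(ref, pos, alt)

# Parse substitution keys back into (ref, position, alt).
parse_sub_key <- function(keys) {
  m <- regmatches(keys, regexec("^([A-Z*])([0-9]+)([A-Z*])$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed substitution key: ", keys[bad][1L])
  data.frame(
    key = keys,
    ref = vapply(m, `[`, "", 2L),
    position = as.integer(vapply(m, `[`, "", 3L)),
    alt = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}
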