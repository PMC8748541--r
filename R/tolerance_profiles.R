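#' Per-site mutational tolerance
#'
#' The tolerance score of a position is the mean absolute value of all
#' retained substitution coefficients at that position: low values mark
#' sites where mutations have little effect, high values mark functionally
#' critical sites. Positions with no retained substitutions are omitted,
#' not zero-filled.
#'
#' @param coefficients A `coef_table`.
#' @return A `tolerance_profile`: data frame with `position`,
#'   `mean_abs_coefficient`, `n_mutations`, and (after
#'   [percentile_rank()]) `percentile_rank`; attribute `source = "dms"`.
#' @export
site_tolerance <- function(coefficients) {
  if (nrow(coefficients) < 1L) stop("need at least one coefficient")
  m <- rowsum(abs(coefficients$beta), coefficients$position)
  n <- rowsum(rep(1L, nrow(coefficients)), coefficients$position)
  out <- data.frame(position = as.integer(rownames(m)),
                    mean_abs_coefficient = m[, 1L] / n[, 1L],
                    n_mutations = n[, 1L])
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- "dms"
  class(out) <- c("tolerance_profile", "data.frame")
  out
}

#' Percentile-rank a tolerance profile
#'
#' Adds `percentile_rank = rank / n * 100` over the profile's tolerance
#' scores, with average ranks for ties, so profiles from scans of different
#' depth or from sequence conservation become comparable.
#'
#' @param profile A `tolerance_profile` with >= 2 positions.
#' @return The profile with a `percentile_rank` column in [0, 100].
#' @export
percentile_rank <- function(profile) {
  if (nrow(profile) < 2L) stop("need at least 2 positions to rank")
  r <- rank(profile$mean_abs_coefficient, ties.method = "average")
  profile$percentile_rank <- r / nrow(profile) * 100
  profile
}

#' Map equivalent positions between two paralogs
#'
#' Global pairwise protein alignment (BLOSUM62, affine gaps) reduced to the
#' matched-column position pairs; gapped columns are dropped, so the map is
#' strictly monotone in both coordinates.
#'
#' @param seqA,seqB Protein sequences (character strings, no gaps).
#' @param offsetA,offsetB Optional numbering offsets added to the 1-based
#'   positions of each sequence (default 0).
#' @param gap_opening,gap_extension Affine gap parameters (default 10, 0.5).
#' @return A `position_map`: data frame with columns `position_a`,
#'   `position_b`, `residue_a`, `residue_b`.
#' @export
align_positions <- function(seqA, seqB, offsetA = 0L, offsetB = 0L,
                            gap_opening = 10, gap_extension = 0.5) {
  stopifnot(nchar(seqA) > 0L, nchar(seqB) > 0L)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = data_env$BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension)
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  pos_a <- cumsum(al_a != "-")
  pos_b <- cumsum(al_b != "-")
  matched <- al_a != "-" & al_b != "-"
  out <- data.frame(position_a = pos_a[matched] + offsetA,
                    position_b = pos_b[matched] + offsetB,
                    residue_a = al_a[matched], residue_b = al_b[matched])
  rownames(out) <- NULL
  class(out) <- c("position_map", "data.frame")
  out
}

#' Cross-paralog divergence of mutational tolerance
#'
#' At each aligned position present in both profiles, `delta` is profile A's
#' tolerance minus profile B's (positive: mutations at that site have a
#' larger effect in A). A centered moving average (window truncated at the
#' edges) smooths the per-site differences into regional trends.
#'
#' @param profileA,profileB `tolerance_profile`s (positions in each
#'   paralog's own numbering).
#' @param map A [align_positions()] result linking A positions to B
#'   positions.
#' @param window Odd moving-average window (default 9).
#' @param value Column to difference: `"mean_abs_coefficient"` (default) or
#'   `"percentile_rank"`.
#' @return A `divergence_profile`: data frame with `position_a`,
#'   `position_b`, `delta`, `smoothed_delta`; attribute `window`.
#' @export
divergence_profile <- function(profileA, profileB, map, window = 9L,
                               value = "mean_abs_coefficient") {
  if (window %% 2L == 0L) stop("window must be odd")
  ia <- match(map$position_a, profileA$position)
  ib <- match(map$position_b, profileB$position)
  ok <- !is.na(ia) & !is.na(ib)
  if (sum(ok) < window)
    stop("fewer aligned positions with data (", sum(ok),
         ") than the smoothing window")
  out <- data.frame(position_a = map$position_a[ok],
                    position_b = map$position_b[ok],
                    delta = profileA[[value]][ia[ok]] - profileB[[value]][ib[ok]])
  out$smoothed_delta <- moving_average(out$delta, window)
  rownames(out) <- NULL
  attr(out, "window") <- as.integer(window)
  attr(out, "value") <- value
  class(out) <- c("divergence_profile", "data.frame")
  out
}

# Centered moving average with window truncated at the edges.
moving_average <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1L))
}

#' Sequence-conservation tolerance profile from an MSA
#'
#' For each alignment column where the reference row has a residue and at
#' most 50% of sequences are gapped, the tolerance score is the Shannon
#' entropy of the residue composition (gaps excluded) normalized by
#' `log(20)`: 0 for perfect conservation, 1 for a uniform column. Positions
#' are reported in the reference row's residue numbering.
#'
#' @param msa Named character vector of aligned protein sequences (equal
#'   lengths, `-` for gaps), or an `AAStringSet`.
#' @param reference_row Name of the reference sequence in the MSA.
#' @param numbering_offset Offset added to reference residue numbers.
#' @return A `tolerance_profile` with `source = "msa"` and a
#'   `percentile_rank` column.
#' @export
msa_tolerance <- function(msa, reference_row, numbering_offset = 0L) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  if (!reference_row %in% names(msa))
    stop("reference row '", reference_row, "' not found in MSA")
  if (length(msa) < 5L) stop("need at least 5 aligned sequences")
  if (length(unique(nchar(msa))) != 1L) stop("MSA rows have unequal lengths")
  mat <- vapply(strsplit(msa, "", fixed = TRUE), identity,
                character(nchar(msa[[1L]])))       # columns = sequences
  ref_chars <- mat[, reference_row]
  gap <- mat %in% c("-", ".")
  dim(gap) <- dim(mat)
  gap_frac <- rowMeans(gap)
  use <- ref_chars != "-" & ref_chars != "." & gap_frac <= 0.5
  ref_pos <- cumsum(ref_chars != "-" & ref_chars != ".")

  ent <- vapply(which(use), function(i) {
    res <- mat[i, !gap[i, ]]
    p <- table(res) / length(res)
    -sum(p * log(p)) / log(20)
  }, numeric(1L))

  out <- data.frame(position = ref_pos[use] + numbering_offset,
                    mean_abs_coefficient = ent,
                    n_mutations = rowSums(!gap)[use])
  rownames(out) <- NULL
  attr(out, "source") <- "msa"
  class(out) <- c("tolerance_profile", "data.frame")
  percentile_rank(out)
}

#' Coefficient-difference matrix between paralogs
#'
#' For every aligned position and alternative residue scored in BOTH
#' enzymes, the difference `beta_A - beta_B`. Substitutions scored in only
#' one enzyme yield no cell (missing is not zero), mirroring the convention
#' that unobserved mutations are blank in mutation maps.
#'
#' @param coefA,coefB `coef_table`s for the two enzymes.
#' @param map A [align_positions()] result.
#' @return Data frame with `position_a`, `position_b`, `alt`, `beta_a`,
#'   `beta_b`, `delta_beta`.
#' @export
coefficient_difference_matrix <- function(coefA, coefB, map) {
  if (nrow(coefA) == 0L || nrow(coefB) == 0L) stop("empty coefficient table")
  a <- merge(coefA, map, by.x = "position", by.y = "position_a")
  merged <- merge(a, coefB, by.x = c("position_b", "alt"),
                  by.y = c("position", "alt"),
                  suffixes = c("_a", "_b"))
  out <- data.frame(position_a = merged$position,
                    position_b = merged$position_b,
                    alt = merged$alt,
                    beta_a = merged$beta_a, beta_b = merged$beta_b,
                    delta_beta = merged$beta_a - merged$beta_b)
  out <- out[order(out$position_a, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation test for per-site tolerance divergence
#'
#' Tests, per aligned site, whether the mean absolute coefficient differs
#' between enzymes A and B by shuffling the enzyme labels of the pooled
#' substitution-level coefficients at that site; two-sided p-values are
#' Benjamini-Hochberg corrected across sites.
#'
#' @param coefA,coefB `coef_table`s.
#' @param map A [align_positions()] result.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Data frame with `position_a`, `position_b`, `delta`, `p_value`,
#'   `q_value`.
#' @export
site_divergence_test <- function(coefA, coefB, map, n_perm = 1000L,
                                 seed = 1L) {
  set.seed(seed)
  res <- lapply(seq_len(nrow(map)), function(i) {
    xa <- abs(coefA$beta[coefA$position == map$position_a[i]])
    xb <- abs(coefB$beta[coefB$position == map$position_b[i]])
    if (length(xa) == 0L || length(xb) == 0L) return(NULL)
    obs <- mean(xa) - mean(xb)
    pooled <- c(xa, xb)
    na <- length(xa)
    perm <- replicate(n_perm, {
      s <- sample.int(length(pooled))
      mean(pooled[s[seq_len(na)]]) - mean(pooled[s[-seq_len(na)]])
    })
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    data.frame(position_a = map$position_a[i], position_b = map$position_b[i],
               delta = obs, p_value = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no sites with coefficients in both enzymes")
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
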