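#' @importFrom rlang %||% abort warn .data .env
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot


check_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort(sprintf("sequence '%s' must be a single non-empty string", id))
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad) > 0L) {
    abort(sprintf(
      "sequence '%s' contains non-IUPAC character '%s' at position %d",
      id, chars[bad[1]], bad[1]
    ))
  }
  invisible(paste(chars, collapse = ""))
}

check_amplicons <- function(seqs) {
  if (!is.data.frame(seqs) || nrow(seqs) == 0L) abort("no sequences")
  if (!all(c("id", "sequence") %in% names(seqs))) {
    abort("amplicon table needs columns 'id' and 'sequence'")
  }
  if (anyDuplicated(seqs$id)) {
    abort(sprintf("duplicated sequence id '%s'", seqs$id[duplicated(seqs$id)][1]))
  }
  purrr::walk2(seqs$sequence, seqs$id, check_sequence)
  invisible(seqs)
}

check_dist_matrix <- function(d, name = "distance matrix") {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort(sprintf("%s must be square", name))
  if (max(abs(d - t(d))) > 1e-12) abort(sprintf("%s must be symmetric", name))
  if (any(abs(diag(d)) > 1e-12)) abort(sprintf("%s must have a zero diagonal", name))
  invisible(d)
}

# lower-triangle vector (the entries Mantel-type statistics correlate)
lower_tri <- function(d) d[lower.tri(d)]

# deterministic per-stage seeds derived from one root seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  offsets <- c(
    sequences = 101L, landscape = 211L, bands = 307L, community = 401L,
    profiles = 503L, stats = 601L, accumulation = 701L, ordination = 809L
  )
  off <- offsets[[stage]] %||% abort(sprintf("unknown stage '%s'", stage))
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Turn a labelled distance matrix into a tidy pair table
#'
#' @param d Symmetric numeric matrix with row/column names.
#' @param value Name of the value column in the output.
#' @return A tibble with one row per unordered pair (`id1`, `id2`, value).
#' @export
dist_pairs <- function(d, value = "distance") {
  check_dist_matrix(d)
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  idx <- which(lower.tri(d), arr.ind = TRUE)
  out <- tibble(
    id1 = ids[idx[, 2]],
    id2 = ids[idx[, 1]],
    value = d[idx]
  )
  names(out)[3] <- value
  out
}
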