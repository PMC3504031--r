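#' Restriction enzyme specification
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition sequence (top strand).
#' @param cut_offset Cut position in bases from the recognition start
#'   (top strand), `0 <= cut_offset <= nchar(recognition)`.
#' @return A one-row tibble (`name`, `recognition`, `cut_offset`).
#' @export
enzyme_spec <- function(name, recognition, cut_offset) {
  recognition <- check_sequence(recognition, name)
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    abort("cut_offset must lie within the recognition sequence")
  }
  tibble(name = name, recognition = recognition, cut_offset = as.integer(cut_offset))
}

#' Built-in enzymes for the ITS T-RFLP assay
#'
#' HaeIII cuts GG^CC (blunt, offset 2) and HinfI cuts G^ANTC (offset 1);
#' both recognition sequences are their own reverse complements, so a
#' single-strand scan finds every double-strand site.
#'
#' @param path Optional CSV (`name`, `recognition`, `cut_offset`) defining
#'   additional or alternative enzymes.
#' @return A tibble of enzyme specifications.
#' @export
default_enzymes <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(purrr::pmap_dfr(tab, enzyme_spec))
  }
  dplyr::bind_rows(
    enzyme_spec("HaeIII", "GGCC", 2L),
    enzyme_spec("HinfI", "GANTC", 1L)
  )
}

get_enzyme <- function(enzymes, name) {
  row <- enzymes[enzymes$name == name, ]
  if (nrow(row) != 1L) abort(sprintf("unknown enzyme '%s'", name))
  row
}

#' Find recognition sites on the given strand
#'
#' IUPAC codes are expanded on both sides: an ambiguity code in the
#' recognition sequence matches each base it stands for, and an ambiguous
#' base in the sequence (e.g. `N`) matches permissively (with a warning).
#' Overlapping matches are all reported.
#'
#' @param sequence Nucleotide string.
#' @param enzyme One-row enzyme tibble (see [enzyme_spec()]).
#' @return Sorted integer vector of 0-based site start positions.
#' @export
find_sites <- function(sequence, enzyme) {
  sequence <- check_sequence(sequence)
  if (grepl("[^ACGT]", sequence)) {
    warn("sequence contains ambiguity codes; matched permissively")
  }
  if (nchar(sequence) < nchar(enzyme$recognition)) return(integer(0))
  hits <- Biostrings::matchPattern(
    enzyme$recognition, Biostrings::DNAString(sequence), fixed = FALSE
  )
  sort(Biostrings::start(hits)) - 1L
}

#' Length of the labelled terminal restriction fragment
#'
#' The forward fragment runs from the 5' labelled end to the first cut
#' (`first site start + cut_offset`); the reverse fragment is the same
#' computed on the reverse complement. An uncut amplicon yields a fragment
#' equal to the full sequence length (uncut products run as peaks).
#'
#' @param sequence Nucleotide string.
#' @param enzyme One-row enzyme tibble.
#' @param end `"forward"` or `"reverse"` labelled end.
#' @return Fragment length in bases.
#' @export
terminal_fragment <- function(sequence, enzyme, end = c("forward", "reverse")) {
  end <- match.arg(end)
  sequence <- check_sequence(sequence)
  if (end == "reverse") sequence <- revcomp(sequence)
  sites <- find_sites(sequence, enzyme)
  if (length(sites) == 0L) return(nchar(sequence))
  sites[1] + enzyme$cut_offset
}

#' All fragment lengths of a complete digest
#'
#' Used for conservation checks; fragment lengths always sum to the
#' sequence length.
#'
#' @inheritParams terminal_fragment
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
digest_fragments <- function(sequence, enzyme) {
  sequence <- check_sequence(sequence)
  cuts <- find_sites(sequence, enzyme) + enzyme$cut_offset
  cuts <- cuts[cuts > 0 & cuts < nchar(sequence)]
  diff(c(0L, cuts, nchar(sequence)))
}

#' Expected TRF set for each amplicon
#'
#' Predicts the four expected terminal restriction fragments per sequence
#' (two enzymes times two labelled ends) by in-silico digestion. Fragments
#' shorter than `min_size` bases fall below the detection window of the
#' fragment analysis and are flagged undetectable.
#'
#' @param seqs Tibble of amplicons (`id`, `sequence`).
#' @param enzymes Enzyme table, by default HaeIII + HinfI.
#' @param min_size Minimum detectable fragment length in bases (default 50).
#' @return A tibble with columns `otu_id`, `enzyme`, `end`, `trf_length`,
#'   `detectable` (four rows per input sequence).
#' @export
expected_trf_set <- function(seqs, enzymes = default_enzymes(), min_size = 50) {
  check_amplicons(seqs)
  undetectable_warned <- FALSE
  out <- tidyr::expand_grid(
    otu_id = seqs$id,
    enzyme = enzymes$name,
    end = c("forward", "reverse")
  )
  seq_of <- stats::setNames(seqs$sequence, seqs$id)
  out$trf_length <- purrr::pmap_dbl(out, function(otu_id, enzyme, end) {
    terminal_fragment(seq_of[[otu_id]], get_enzyme(enzymes, enzyme), end)
  })
  out$detectable <- out$trf_length >= min_size
  n_short <- dplyr::count(out[!out$detectable, ], .data$otu_id)
  hopeless <- n_short$otu_id[n_short$n >= 2]
  if (length(hopeless) > 0L) {
    warn(sprintf(
      "OTU(s) %s have >=2 expected TRFs below %d bases and can never be called present",
      toString(hopeless), as.integer(min_size)
    ))
  }
  out
}
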