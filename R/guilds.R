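#' Read ITS amplicon sequences from a FASTA file
#'
#' Headers are split at the first space: the first token becomes the sequence
#' `id`, the remainder (if any) the free-text `description` such as a
#' closest-BLAST-match annotation.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `description`.
#' @export
read_amplicons <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  description <- ifelse(grepl("\\s", header),
                        sub("^\\S+\\s+", "", header), NA_character_)
  out <- tibble(id = id, sequence = unname(as.character(set)), description = description)
  check_amplicons(out)
}

#' Write amplicon sequences to FASTA
#'
#' @param seqs Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(seqs, path) {
  check_amplicons(seqs)
  set <- Biostrings::DNAStringSet(seqs$sequence)
  desc <- if ("description" %in% names(seqs)) seqs$description else NA_character_
  names(set) <- ifelse(is.na(desc), seqs$id, paste(seqs$id, desc))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}


# column-wise identity of two aligned strings; gap columns count as mismatch,
# IUPAC-ambiguous pairs with overlapping base sets count as match (permissive)
aligned_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  no_gap <- ca != "-" & cb != "-"
  sum(IUPAC_COMPAT[cbind(ca[no_gap], cb[no_gap])]) / length(ca)
}

#' Pairwise alignment-based distances between amplicon sequences
#'
#' Distance is `1 - identity` over all columns of a global pairwise alignment
#' (gap columns count as non-identical). Alignment scoring defaults to
#' match 1, mismatch -1, gap -2 per aligned gap position; IUPAC-ambiguous
#' pairs whose base sets overlap count as identical.
#'
#' @param seqs Tibble of amplicons (`id`, `sequence`).
#' @param match,mismatch,gap Alignment scoring parameters.
#' @return A symmetric matrix of distances in `[0, 1]` with ids as dimnames.
#' @export
pairwise_distance <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  check_amplicons(seqs)
  if (nrow(seqs) < 2L) abort("need at least two sequences")
  n <- nrow(seqs)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  pool <- Biostrings::DNAStringSet(toupper(seqs$sequence))
  pure <- !grepl("[^ACGT]", toupper(seqs$sequence))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    al <- Biostrings::pairwiseAlignment(
      pool[js], pool[[i]], type = "global",
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = -gap
    )
    # for unambiguous pairs, identity = matched columns / alignment columns;
    # every gap column consumes one residue from exactly one side, so
    # columns = len(a) + len(b) - aligned pairs. Ambiguity codes need the
    # permissive column-wise comparison instead.
    pairs_aligned <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
    columns <- Biostrings::width(pool)[js] + Biostrings::width(pool)[i] - pairs_aligned
    ident <- Biostrings::nmatch(al) / columns
    fancy <- which(!(pure[js] & pure[i]))
    if (length(fancy) > 0L) {
      pa <- as.character(Biostrings::alignedPattern(al[fancy]))
      sa <- as.character(Biostrings::alignedSubject(al[fancy]))
      ident[fancy] <- mapply(aligned_identity, pa, sa)
    }
    d[i, js] <- d[js, i] <- 1 - ident
  }
  d
}

#' Cluster sequences into OTUs by single linkage
#'
#' Nearest-neighbour (single-linkage) clustering cut at a distance threshold;
#' the conventional fungal ITS species proxy uses `threshold = 0.03`
#' (97% similarity). The lexicographically smallest member id is the OTU
#' representative, and OTUs are labelled `OTU01, OTU02, ...` in order of
#' their representative.
#'
#' @param dist Symmetric distance matrix with ids as dimnames.
#' @param threshold Distance cut-off in `[0, 1]`.
#' @return A tibble with columns `otu_id`, `member_id`, `representative_id`.
#' @export
cluster_otus <- function(dist, threshold = 0.03) {
  check_dist_matrix(dist)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]")
  }
  ids <- rownames(dist) %||% as.character(seq_len(nrow(dist)))
  if (nrow(dist) == 1L) {
    cl <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(dist), method = "single")
    cl <- stats::cutree(hc, h = threshold)
    names(cl) <- ids
  }
  members <- split(names(cl), cl)
  reps <- vapply(members, function(m) sort(m)[1], character(1))
  ord <- order(reps)
  members <- members[ord]
  reps <- reps[ord]
  otu_ids <- sprintf("OTU%02d", seq_along(members))
  purrr::map2_dfr(seq_along(members), otu_ids, function(k, oid) {
    tibble(otu_id = oid, member_id = members[[k]], representative_id = reps[[k]])
  })
}

#' Default guild keyword rules
#'
#' One row per keyword pattern, scanned in order against the OTU name and its
#' closest-match annotation; the first hit assigns the guild. `ERM` covers the
#' ericoid-mycorrhizal lineages (Sebacinales, Helotiales s.l. and named
#' ericoid ascomycetes), `ECM` ectomycorrhizal basidiomycetes, `DSE` dark
#' septate endophytes; anything unmatched is `UNKNOWN`. The rule table ships
#' as a plain CSV under `inst/extdata/` so it can be extended.
#'
#' @param path Optional path to an alternative rules CSV
#'   (columns `guild`, `pattern`).
#' @return A tibble with columns `guild`, `pattern` (regular expressions).
#' @export
guild_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "guild_rules.csv", package = "trflpr")
  rules <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("guild", "pattern") %in% names(rules))) {
    abort("guild rules need columns 'guild' and 'pattern'")
  }
  rules
}

#' Classify an OTU into a mycorrhizal guild by keyword rules
#'
#' @param otu_name OTU name(s).
#' @param description Closest-match annotation(s); may be `NA`.
#' @param rules Rule table from [guild_rules()].
#' @return Character vector of guilds: `"ERM"`, `"ECM"`, `"DSE"` or
#'   `"UNKNOWN"`.
#' @export
classify_guild <- function(otu_name, description = NA_character_,
                           rules = guild_rules()) {
  if (length(description) == 1L) description <- rep(description, length(otu_name))
  text <- paste(otu_name, dplyr::coalesce(description, ""))
  if (any(!nzchar(trimws(text)))) abort("empty annotation")
  out <- rep("UNKNOWN", length(text))
  undecided <- rep(TRUE, length(text))
  for (k in seq_len(nrow(rules))) {
    hit <- undecided & grepl(rules$pattern[k], text, ignore.case = TRUE)
    out[hit] <- rules$guild[k]
    undecided[hit] <- FALSE
  }
  out
}

#' Load the packaged reference OTU table
#'
#' A packaged fixture with the 35 root-associated fungal OTUs of the
#' reference survey of *Rhododendron decorum*: OTU name, GenBank accession,
#' closest BLAST match and identity as a matched/total base pair.
#'
#' @param path Optional alternative CSV path.
#' @return A tibble with columns `otu_name`, `accession`, `closest_match`,
#'   `identity_num`, `identity_den`, `identity` (the fraction) and `guild`
#'   from [classify_guild()].
#' @export
load_table1_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_otus.csv", package = "trflpr")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("otu_name", "accession", "closest_match", "identity_num", "identity_den")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    abort(sprintf("fixture is missing column(s): %s", toString(missing_cols)))
  }
  bad <- which(is.na(tab$identity_num) | is.na(tab$identity_den) |
                 tab$identity_num > tab$identity_den)
  if (length(bad) > 0L) {
    abort(sprintf("malformed identity pair in fixture row %d", bad[1]))
  }
  dplyr::mutate(
    tab,
    identity = .data$identity_num / .data$identity_den,
    guild = classify_guild(.data$otu_name, .data$closest_match)
  )
}
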