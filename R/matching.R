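#' Read a GeneMapper-style peak table
#'
#' Expects a CSV with columns `sample_id`, `enzyme`, `end`, `size`, `height`,
#' `area`; one row per sized peak in one sample x enzyme x labelled-end
#' channel. Peaks below `min_size` bases are retained but flagged `excluded`
#' (they fall below the fragment-analysis window and never match). Duplicate
#' `(sample_id, enzyme, end, size)` rows are merged with areas and heights
#' summed, with a warning.
#'
#' @param path CSV path.
#' @param min_size Minimum analysable fragment size in bases (default 50).
#' @return A tibble of peaks with an added logical `excluded` column.
#' @export
read_peak_table <- function(path, min_size = 50) {
  peaks <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "enzyme", "end", "size", "height", "area")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols) > 0L) {
    abort(sprintf("peak table is missing column(s): %s", toString(missing_cols)))
  }
  bad <- which(is.na(peaks$size) | peaks$size < 0)
  if (length(bad) > 0L) {
    abort(sprintf("negative or missing peak size on data row %d", bad[1]))
  }
  if (anyDuplicated(peaks[c("sample_id", "enzyme", "end", "size")])) {
    warn("duplicate (sample, enzyme, end, size) peaks merged; areas summed")
    peaks <- peaks |>
      dplyr::group_by(.data$sample_id, .data$enzyme, .data$end, .data$size) |>
      dplyr::summarise(
        height = sum(.data$height), area = sum(.data$area), .groups = "drop"
      )
  }
  dplyr::mutate(peaks, excluded = .data$size < min_size)
}

# nearest (then largest-area) observed peak within tolerance of one expected
# size; returns NA area when unmatched
match_one_key <- function(expected_size, sizes, areas, tolerance) {
  if (length(sizes) == 0L) return(NA_real_)
  dev <- abs(sizes - expected_size)
  ok <- which(dev <= tolerance)
  if (length(ok) == 0L) return(NA_real_)
  ok <- ok[order(dev[ok], -areas[ok])]
  areas[ok[1]]
}

#' Match one OTU's expected TRFs against one sample's peaks
#'
#' An expected fragment is matched when a non-excluded observed peak lies
#' within `tolerance` bases of it (inclusive); the OTU is called present when
#' at least `min_matched` of its four expected fragments match. Expected
#' fragments below the detection window (`detectable == FALSE`) can never
#' match. A missing channel simply leaves its key unmatched.
#'
#' @param expected Four-row tibble from [expected_trf_set()] for one OTU.
#' @param peaks Peak tibble for one sample (as from [read_peak_table()]).
#' @param tolerance Matching tolerance in bases (default 1, inclusive).
#' @param min_matched Matched keys required for a presence call (default 3).
#' @return A list with `present` (logical), and `keys`: a tibble with
#'   `enzyme`, `end`, `matched`, `area`.
#' @export
match_otu <- function(expected, peaks, tolerance = 1, min_matched = 3) {
  if (nrow(expected) != 4L) abort("expected TRF set must have exactly 4 rows")
  usable <- peaks[!peaks$excluded, ]
  keys <- expected |>
    dplyr::rowwise() |>
    dplyr::mutate(
      area = {
        ch <- usable[usable$enzyme == .data$enzyme & usable$end == .data$end, ]
        if (!.data$detectable) NA_real_ else
          match_one_key(.data$trf_length, ch$size, ch$area, tolerance)
      },
      matched = !is.na(.data$area)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("enzyme", "end", "matched", "area")
  list(present = sum(keys$matched) >= min_matched, keys = keys)
}

#' Build the community matrix from expected TRFs and observed peaks
#'
#' Applies the matching rule of [match_otu()] to every sample x OTU pair and
#' assembles: the OTU presence/absence matrix, the four underlying TRF-level
#' (enzyme x labelled end) matrices, and the matched peak areas. Samples with
#' no peaks at all are dropped with a warning; OTUs detected nowhere keep
#' their all-zero column.
#'
#' @param expected Expected TRF table from [expected_trf_set()].
#' @param peaks Peak tibble covering all samples.
#' @param guilds Named character vector mapping OTU id to guild
#'   (`"ERM"`, `"ECM"`, `"DSE"`, `"UNKNOWN"`); defaults to all `"UNKNOWN"`.
#' @param tolerance,min_matched Matching parameters, see [match_otu()].
#' @return A `trflp_community` object: list with `presence` (samples x OTUs
#'   0/1 matrix), `trf` (named list of four samples x OTUs matrices),
#'   `areas` (long tibble of matched areas), `guilds`, `samples`, `otus`.
#' @export
build_community <- function(expected, peaks, guilds = NULL,
                            tolerance = 1, min_matched = 3) {
  otus <- unique(expected$otu_id)
  samples <- sort(unique(peaks$sample_id))
  if (length(otus) == 0L || length(samples) == 0L) {
    abort("need at least one OTU and one sample")
  }
  if (is.null(guilds)) {
    guilds <- stats::setNames(rep("UNKNOWN", length(otus)), otus)
  }
  if (!all(otus %in% names(guilds))) abort("guilds must cover every OTU")
  guilds <- guilds[otus]

  usable <- peaks[!peaks$excluded, ]
  exp_det <- expected[expected$detectable, ]
  # one join does all samples x OTUs x keys: observed peaks within tolerance
  hits <- exp_det |>
    dplyr::inner_join(usable, by = c("enzyme", "end"),
                      relationship = "many-to-many") |>
    dplyr::filter(abs(.data$size - .data$trf_length) <= tolerance) |>
    dplyr::group_by(.data$sample_id, .data$otu_id, .data$enzyme, .data$end) |>
    dplyr::arrange(abs(.data$size - .data$trf_length), dplyr::desc(.data$area),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  key_of <- function(enzyme, end) paste(enzyme, end, sep = "_")
  keys <- unique(key_of(expected$enzyme, expected$end))
  empty <- matrix(0L, length(samples), length(otus),
                  dimnames = list(samples, otus))
  trf <- stats::setNames(lapply(keys, function(k) empty), keys)
  for (i in seq_len(nrow(hits))) {
    k <- key_of(hits$enzyme[i], hits$end[i])
    trf[[k]][hits$sample_id[i], hits$otu_id[i]] <- 1L
  }
  matched_n <- Reduce(`+`, trf)
  presence <- (matched_n >= min_matched) * 1L

  areas <- hits |>
    dplyr::select("sample_id", "otu_id", "enzyme", "end", "size", "area") |>
    dplyr::arrange(.data$sample_id, .data$otu_id, .data$enzyme, .data$end)

  structure(
    list(presence = presence, trf = trf, areas = areas, guilds = guilds,
         samples = samples, otus = otus,
         tolerance = tolerance, min_matched = min_matched),
    class = "trflp_community"
  )
}

#' @export
print.trflp_community <- function(x, ...) {
  cat(sprintf(
    "<trflp_community> %d samples x %d OTUs (%d ERM, %d non-ERM); %d presences\n",
    length(x$samples), length(x$otus), sum(x$guilds == "ERM"),
    sum(x$guilds != "ERM"), sum(x$presence)
  ))
  invisible(x)
}

#' Tidy a community matrix into long form
#'
#' @param x A `trflp_community`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `otu_id`, `guild`, `present` and the
#'   number of matched TRF keys.
#' @export
tidy.trflp_community <- function(x, ...) {
  matched_n <- Reduce(`+`, x$trf)
  tidyr::expand_grid(sample_id = x$samples, otu_id = x$otus) |>
    dplyr::mutate(
      guild = unname(x$guilds[.data$otu_id]),
      present = x$presence[cbind(.data$sample_id, .data$otu_id)] == 1L,
      n_matched = matched_n[cbind(.data$sample_id, .data$otu_id)]
    )
}

#' Split a community into ERM and NEM assemblages
#'
#' Fragments attributed to the ericoid-mycorrhizal guild form the ERM
#' assemblage; every remaining OTU (ectomycorrhizal, dark septate endophyte,
#' unknown) forms the non-ericoid (NEM) assemblage.
#'
#' @param cm A `trflp_community`.
#' @return Named list of two `trflp_community` objects, `ERM` and `NEM`.
#' @export
partition_guilds <- function(cm) {
  stopifnot(inherits(cm, "trflp_community"))
  take <- function(keep) {
    out <- cm
    out$presence <- cm$presence[, keep, drop = FALSE]
    out$trf <- lapply(cm$trf, function(m) m[, keep, drop = FALSE])
    out$areas <- cm$areas[cm$areas$otu_id %in% cm$otus[keep], ]
    out$guilds <- cm$guilds[keep]
    out$otus <- cm$otus[keep]
    out
  }
  erm <- cm$guilds == "ERM"
  list(ERM = take(erm), NEM = take(!erm))
}

#' OTU abundance from matched peak areas
#'
#' Abundance of an OTU is the mean matched peak area over its four TRFs and
#' over the samples where it was called present, log10-transformed.
#'
#' @param cm A `trflp_community`.
#' @param otu_id One or more OTU ids; default all OTUs present somewhere.
#' @return Tibble with `otu_id`, `mean_area`, `abundance` (log10 scale) and
#'   `occupancy` (number of samples where present).
#' @export
otu_abundance <- function(cm, otu_id = NULL) {
  stopifnot(inherits(cm, "trflp_community"))
  occ <- colSums(cm$presence)
  otu_id <- otu_id %||% cm$otus[occ > 0]
  never <- otu_id[occ[otu_id] == 0]
  if (length(never) > 0L) {
    abort(sprintf("OTU(s) never called present: %s", toString(never)))
  }
  present_pairs <- tidy(cm) |> dplyr::filter(.data$present)
  cm$areas |>
    dplyr::semi_join(present_pairs, by = c("sample_id", "otu_id")) |>
    dplyr::filter(.data$otu_id %in% .env$otu_id) |>
    dplyr::group_by(otu_id = .data$otu_id) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop") |>
    dplyr::mutate(abundance = log10(.data$mean_area),
                  occupancy = unname(occ[.data$otu_id])) |>
    dplyr::arrange(match(.data$otu_id, cm$otus))
}
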