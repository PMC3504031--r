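#' Sørensen dissimilarity matrix from a presence/absence matrix
#'
#' Pairwise `1 - 2|A n B| / (|A| + |B|)` between sample rows. A sample with
#' no positive entries has no defined Sørensen dissimilarity; by default this
#' is an error, but noisy fingerprinting runs do produce empty channels, so
#' `empty = "one"` treats a pair with exactly one empty sample as maximally
#' dissimilar (1) and a pair of two empty samples as identical (0).
#'
#' @param x Binary matrix, samples in rows.
#' @param empty `"error"` (default) or `"one"`.
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
sorensen_dissimilarity_matrix <- function(x, empty = c("error", "one")) {
  empty <- match.arg(empty)
  x <- (as.matrix(x) > 0) * 1
  sizes <- rowSums(x)
  if (any(sizes == 0) && empty == "error") {
    abort(sprintf(
      "sample(s) with no positive entries: %s",
      toString((rownames(x) %||% as.character(seq_len(nrow(x))))[sizes == 0])
    ))
  }
  tot <- outer(sizes, sizes, `+`)
  d <- 1 - 2 * (x %*% t(x)) / ifelse(tot == 0, 1, tot)
  both_empty <- outer(sizes == 0, sizes == 0, `&`)
  d[both_empty] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Mean community dissimilarity over the four TRF matrices
#'
#' The community dissimilarity between two root samples is the element-wise
#' arithmetic mean of the four Sørensen dissimilarity matrices (one per
#' enzyme x labelled-end channel).
#'
#' @param mats List of conformable dissimilarity matrices.
#' @return Single dissimilarity matrix.
#' @export
mean_dissimilarity <- function(mats) {
  if (length(mats) == 0L) abort("no matrices")
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) abort("matrices are not conformable")
  Reduce(`+`, mats) / length(mats)
}

#' Community dissimilarity of a guild assemblage
#'
#' Applies [sorensen_dissimilarity_matrix()] to each of the four TRF-level
#' matrices of a community and averages them.
#'
#' @param cm A `trflp_community` (typically one side of [partition_guilds()]).
#' @inheritParams sorensen_dissimilarity_matrix
#' @return Symmetric dissimilarity matrix across samples.
#' @export
community_dissimilarity <- function(cm, empty = c("error", "one")) {
  stopifnot(inherits(cm, "trflp_community"))
  if (length(cm$otus) == 0L) abort("assemblage has no OTU columns")
  mean_dissimilarity(lapply(cm$trf, sorensen_dissimilarity_matrix, empty = empty))
}

#' Great-circle distances between samples
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param samples Tibble with `sample_id`, `latitude`, `longitude` (degrees).
#' @return Symmetric distance matrix in kilometres.
#' @export
geographic_distance <- function(samples) {
  need <- c("sample_id", "latitude", "longitude")
  if (!all(need %in% names(samples))) {
    abort("need columns sample_id, latitude, longitude")
  }
  if (any(abs(samples$latitude) > 90) || any(abs(samples$longitude) > 180)) {
    abort("coordinates out of range")
  }
  pts <- cbind(samples$longitude, samples$latitude)
  n <- nrow(pts)
  d <- matrix(0, n, n, dimnames = list(samples$sample_id, samples$sample_id))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000) / 1000
  }
  (d + t(d)) / 2
}

#' Mantel test between two distance matrices
#'
#' The standardized Mantel statistic `r` is the Pearson correlation of the
#' off-diagonal entries; significance comes from jointly permuting the rows
#' and columns of the second matrix, with
#' `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)` for the one-tailed test
#' (two-tailed compares `|r|`).
#'
#' @param d1,d2 Conformable symmetric distance matrices (>= 4 samples).
#' @param n_perm Number of random permutations (default 4999).
#' @param seed Seed for the permutation draws.
#' @param tail `"greater"` (ecological convention) or `"two_sided"`.
#' @return A `trflp_mantel` object with elements `r`, `p`, `n_perm`, `tail`.
#' @export
mantel_test <- function(d1, d2, n_perm = 4999, seed = 1,
                        tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  check_dist_matrix(d1); check_dist_matrix(d2)
  n <- nrow(d1)
  if (nrow(d2) != n) abort("matrices are not conformable")
  if (n < 4L) abort("need at least 4 samples")
  v1 <- lower_tri(d1)
  if (stats::sd(v1) == 0 || stats::sd(lower_tri(d2)) == 0) {
    abort("zero variance in distance matrix")
  }
  r_obs <- stats::cor(v1, lower_tri(d2))
  r_perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(v1, lower_tri(d2[idx, idx]))
  }, numeric(1)))
  p <- if (tail == "greater") {
    (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  } else {
    (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  }
  structure(
    list(r = r_obs, p = p, n_perm = n_perm, tail = tail, r_perm = r_perm),
    class = "trflp_mantel"
  )
}

#' @export
print.trflp_mantel <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$tail, x$n_perm))
  invisible(x)
}

#' @export
tidy.trflp_mantel <- function(x, ...) {
  tibble(statistic = x$r, p.value = x$p, n_perm = x$n_perm, tail = x$tail)
}

#' Distance decay of community similarity
#'
#' Pearson correlation between geographic distance and community
#' dissimilarity over all sample pairs. Because the pairs of a distance
#' matrix are not independent, the p-value is computed by Mantel permutation;
#' the naive parametric p over pairs is reported only as a diagnostic.
#'
#' @param community_d Community dissimilarity matrix.
#' @param geographic_d Geographic distance matrix (same samples).
#' @inheritParams mantel_test
#' @return A `trflp_decay` object: `r`, `p` (permutation), `p_parametric`,
#'   `n_pairs`, plus the tidy pair table for plotting.
#' @export
distance_decay <- function(community_d, geographic_d, n_perm = 4999, seed = 1,
                           tail = c("greater", "two_sided")) {
  mt <- mantel_test(geographic_d, community_d, n_perm = n_perm, seed = seed,
                    tail = tail)
  ct <- stats::cor.test(lower_tri(geographic_d), lower_tri(community_d))
  pairs <- dist_pairs(geographic_d, "distance_km") |>
    dplyr::inner_join(dist_pairs(community_d, "dissimilarity"),
                      by = c("id1", "id2"))
  structure(
    list(r = mt$r, p = mt$p, p_parametric = ct$p.value,
         n_pairs = length(lower_tri(community_d)),
         n_perm = n_perm, pairs = pairs),
    class = "trflp_decay"
  )
}

#' @export
print.trflp_decay <- function(x, ...) {
  cat(sprintf(
    "Distance decay: r = %.3f over %d pairs, permutation p = %.4g (parametric %.4g)\n",
    x$r, x$n_pairs, x$p, x$p_parametric
  ))
  invisible(x)
}

#' @export
tidy.trflp_decay <- function(x, ...) {
  tibble(statistic = x$r, p.value = x$p, p.parametric = x$p_parametric,
         n_pairs = x$n_pairs, n_perm = x$n_perm)
}

#' Euclidean distances on max-relativized quantitative variables
#'
#' Each column is divided by its maximum over the samples before pairwise
#' Euclidean distances are taken, so every variable is bounded by 1 and the
#' result is invariant to the units of each column.
#'
#' @param samples Data frame with a `sample_id` column and numeric variables.
#' @param columns Character vector naming the columns to use.
#' @return Symmetric distance matrix.
#' @export
quantitative_matrix_distance <- function(samples, columns) {
  missing_cols <- setdiff(columns, names(samples))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing column(s): %s", toString(missing_cols)))
  }
  x <- as.matrix(samples[columns])
  maxes <- apply(x, 2, max)
  if (any(maxes <= 0)) {
    abort(sprintf("non-positive column maximum in: %s",
                  toString(columns[maxes <= 0])))
  }
  x <- sweep(x, 2, maxes, `/`)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(samples$sample_id, samples$sample_id)
  d
}

#' Occupancy-frequency distribution of TRFs
#'
#' Counts, separately for the ERM and NEM assemblages, how many OTUs
#' (detected TRF sets) occur in a given number of host individuals (5-wide
#' bins: 1-5, 6-10, ...) or in a given number of geographic regions. OTUs
#' never detected are excluded with a warning.
#'
#' @param cm A `trflp_community` with guild labels.
#' @param mode `"individuals"` or `"regions"`.
#' @param regions For `mode = "regions"`: named vector mapping sample id to
#'   region.
#' @param bin_width Width of individual-count bins (default 5).
#' @return A `trflp_occupancy` object; its [tidy()] method gives one row per
#'   bin x guild with `count` and `proportion`.
#' @export
occupancy_distribution <- function(cm, mode = c("individuals", "regions"),
                                   regions = NULL, bin_width = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "trflp_community"))
  occ <- colSums(cm$presence)
  if (any(occ == 0)) {
    warn(sprintf("OTU(s) never detected excluded: %s",
                 toString(cm$otus[occ == 0])))
  }
  keep <- occ > 0
  guild2 <- ifelse(cm$guilds == "ERM", "ERM", "NEM")[keep]
  if (mode == "individuals") {
    n_max <- length(cm$samples)
    counts <- occ[keep]
    breaks <- seq(0, ceiling(n_max / bin_width) * bin_width, by = bin_width)
    lab <- paste(utils::head(breaks, -1) + 1, breaks[-1], sep = "-")
    bins <- cut(counts, breaks = breaks, labels = lab)
  } else {
    if (is.null(regions)) abort("mode = 'regions' needs a region map")
    if (!all(cm$samples %in% names(regions))) {
      abort("region map must cover every sample")
    }
    counts <- apply(cm$presence[, keep, drop = FALSE], 2, function(col) {
      length(unique(regions[cm$samples[col == 1]]))
    })
    lev <- seq_len(length(unique(regions)))
    bins <- factor(counts, levels = lev)
  }
  tab <- tibble(guild = guild2, bin = bins) |>
    dplyr::count(.data$guild, .data$bin, .drop = FALSE, name = "count") |>
    dplyr::group_by(.data$guild) |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  structure(list(table = tab, mode = mode, occupancy = counts,
                 guild = guild2),
            class = "trflp_occupancy")
}

#' @export
print.trflp_occupancy <- function(x, ...) {
  cat(sprintf("<trflp_occupancy> by %s\n", x$mode))
  print(tidyr::pivot_wider(x$table[c("guild", "bin", "count")],
                           names_from = "guild", values_from = "count"))
  invisible(x)
}

#' @export
tidy.trflp_occupancy <- function(x, ...) x$table

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric point probabilities no
#' larger than that of the observed table (the standard exact two-sided
#' definition).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) abort("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) abort("cells must be non-negative integers")
  m <- sum(x[1, ]); n <- sum(x[2, ]); k <- sum(x[, 1])
  if (m + n == 0 || k == 0 || sum(x[, 2]) == 0 || m == 0 || n == 0) {
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Compare ERM and NEM occupancy in pooled extreme bins
#'
#' Builds the 2x2 table (guild x whether a TRF occupies at most
#' `low_max` hosts) and applies [fisher_exact_2x2()]; a significant result
#' with rarer NEM TRFs is the expected core-satellite contrast.
#'
#' @param occ A `trflp_occupancy` (mode `"individuals"`).
#' @param low_max Upper bound of the "rare" occupancy class (default 5).
#' @return Tibble with the table cells and `p.value`.
#' @export
occupancy_contrast <- function(occ, low_max = 5) {
  stopifnot(inherits(occ, "trflp_occupancy"))
  low <- occ$occupancy <= low_max
  tab <- rbind(
    ERM = c(sum(occ$guild == "ERM" & low), sum(occ$guild == "ERM" & !low)),
    NEM = c(sum(occ$guild == "NEM" & low), sum(occ$guild == "NEM" & !low))
  )
  tibble(
    erm_low = tab[1, 1], erm_high = tab[1, 2],
    nem_low = tab[2, 1], nem_high = tab[2, 2],
    p.value = fisher_exact_2x2(tab)
  )
}

#' Abundance-occupancy regression
#'
#' Ordinary least squares of log10 OTU abundance (mean matched peak area) on
#' the number of host individuals occupied; a positive slope is the
#' abundance-occupancy relationship predicted for core species.
#'
#' @param abund Tibble from [otu_abundance()] (columns `abundance`,
#'   `occupancy`).
#' @return A `trflp_regression` object wrapping the [stats::lm()] fit.
#' @export
abundance_occupancy_regression <- function(abund) {
  if (nrow(abund) < 3L) abort("need at least 3 OTUs")
  if (stats::var(abund$occupancy) == 0) abort("zero variance in occupancy")
  fit <- stats::lm(abundance ~ occupancy, data = abund)
  structure(list(fit = fit, data = abund), class = "trflp_regression")
}

#' @export
print.trflp_regression <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @export
tidy.trflp_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.trflp_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    slope = stats::coef(x$fit)[[2]], intercept = stats::coef(x$fit)[[1]],
    r.squared = s$r.squared,
    p.value = s$coefficients[2, 4], n = nrow(x$data)
  )
}

#' Species (TRF) accumulation curve
#'
#' For each number of hosts `n`, draws random `n`-subsets of samples without
#' replacement and records the percentage of the full TRF pool detected;
#' returns the mean and SD over resamples.
#'
#' @param presence Binary samples x OTUs matrix.
#' @param n_resamples Random subsets per sample count (default 1000).
#' @param seed Seed for the resampling.
#' @return A `trflp_accumulation` object; [tidy()] gives `n_hosts`,
#'   `mean_pct`, `sd_pct`.
#' @export
accumulation_curve <- function(presence, n_resamples = 1000, seed = 1) {
  presence <- (as.matrix(presence) > 0) * 1
  n <- nrow(presence)
  if (n < 2L) abort("need at least 2 samples")
  total <- sum(colSums(presence) > 0)
  if (total == 0L) abort("no TRF detected anywhere")
  stats_tab <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(k) {
      pct <- vapply(seq_len(n_resamples), function(i) {
        idx <- sample.int(n, k)
        100 * sum(colSums(presence[idx, , drop = FALSE]) > 0) / total
      }, numeric(1))
      tibble(n_hosts = k, mean_pct = mean(pct), sd_pct = stats::sd(pct))
    })
  })
  structure(list(table = stats_tab, total_trfs = total, n_resamples = n_resamples),
            class = "trflp_accumulation")
}

#' @export
print.trflp_accumulation <- function(x, ...) {
  cat(sprintf("<trflp_accumulation> %d TRFs total, %d resamples\n",
              x$total_trfs, x$n_resamples))
  print(x$table, n = 5)
  invisible(x)
}

#' @export
tidy.trflp_accumulation <- function(x, ...) x$table

#' Hosts needed to reach a coverage fraction
#'
#' Smallest number of sampled hosts whose mean accumulation reaches
#' `target_pct` percent of all TRFs.
#'
#' @param acc A `trflp_accumulation`.
#' @param target_pct Coverage target in percent (default 80).
#' @return Integer number of hosts (NA if never reached).
#' @export
hosts_for_coverage <- function(acc, target_pct = 80) {
  stopifnot(inherits(acc, "trflp_accumulation"))
  hit <- which(acc$table$mean_pct >= target_pct)
  if (length(hit) == 0L) return(NA_integer_)
  acc$table$n_hosts[hit[1]]
}

#' Bray-Curtis single-linkage clustering of OTU distribution patterns
#'
#' Clusters OTU rows of a non-negative abundance table (e.g. mean relative
#' abundance per host group and region) by Bray-Curtis distance with
#' nearest-neighbour (single) linkage, for display as an ordered heatmap.
#' Leaf order is made deterministic by seriating with row labels as
#' tie-break.
#'
#' @param x Non-negative matrix or data frame, OTUs in rows.
#' @return A `trflp_heatmap` object with the `hclust` tree, leaf `order` and
#'   the reordered `table`.
#' @export
cluster_heatmap <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("table must be non-negative")
  zero <- rowSums(x) == 0
  if (any(zero)) {
    abort(sprintf("all-zero row(s): %s",
                  toString((rownames(x) %||% seq_len(nrow(x)))[zero])))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)))
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  # deterministic leaf order: rotate merges so lexicographically smaller
  # labels come first among ties
  dend <- stats::reorder(stats::as.dendrogram(hc),
                         wts = rank(rownames(x)), agglo.FUN = min)
  ord <- stats::order.dendrogram(dend)
  structure(
    list(hclust = hc, distance = d, order = ord,
         table = x[ord, , drop = FALSE]),
    class = "trflp_heatmap"
  )
}

#' @export
print.trflp_heatmap <- function(x, ...) {
  cat(sprintf("<trflp_heatmap> %d rows, Bray-Curtis single linkage\n",
              nrow(x$table)))
  invisible(x)
}

#' @export
tidy.trflp_heatmap <- function(x, ...) {
  as_tibble(x$table, rownames = "otu_id") |>
    tidyr::pivot_longer(-"otu_id", names_to = "group", values_to = "value") |>
    dplyr::mutate(otu_id = factor(.data$otu_id, levels = rownames(x$table)))
}
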