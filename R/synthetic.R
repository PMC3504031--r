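#' Scenario configuration for synthetic studies
#'
#' Defaults mirror the reference survey's dimensions: 45 host individuals in
#' 15 sites across 4 regions, 35 OTUs of which 25 are ericoid-mycorrhizal,
#' a 119-band host ISSR matrix with 3 latent host groups, and four expected
#' TRFs per OTU. Effect sizes plant the study's assumed structure: ERM
#' occurrence follows host-genetic similarity (`beta_host`), NEM occurrence
#' follows geographic proximity to an OTU range centre (`beta_geo`), and ERM
#' OTUs include a "core" fraction of high-prevalence taxa.
#'
#' @param n_hosts,n_sites,n_regions,n_otus,n_erm Study dimensions.
#' @param n_seqs Clone-library size used for the sequence fixture.
#' @param amplicon_length Range of amplicon lengths (bases).
#' @param trf_range Range of planted forward TRF sizes (bases).
#' @param trf_min_sep Minimum per-channel separation between planted TRF
#'   sizes of different OTUs (bases).
#' @param jitter_sd SD of the size-calling jitter (bases).
#' @param dropout Per-key peak dropout probability.
#' @param spurious_rate Mean number of spurious peaks per sample x channel.
#' @param area_meanlog,area_sdlog Log-normal peak-area parameters.
#' @param area_beta Coupling of log area to OTU baseline prevalence (plants
#'   the abundance-occupancy relationship).
#' @param erm_core,nem_core Number of high-prevalence "core" OTUs per guild.
#' @param erm_core_prev,erm_sat_prev,nem_core_prev,nem_sat_prev Baseline
#'   prevalence ranges for core/satellite OTUs of each guild.
#' @param beta_host,beta_geo Logistic effect sizes (per SD of the predictor).
#' @param n_bands,n_group_bands Total ISSR bands and group-informative bands.
#' @param n_host_groups Latent host genetic groups.
#' @param group_mix Probability a host draws a random group rather than its
#'   region's group.
#' @param seed Root seed (mandatory; all stages derive their own streams).
#' @return A `trflp_scenario` list of parameters.
#' @export
scenario_config <- function(n_hosts = 45, n_sites = 15, n_regions = 4,
                            n_otus = 35, n_erm = 25, n_seqs = 75,
                            amplicon_length = c(450, 750),
                            trf_range = c(60, 440), trf_min_sep = 3,
                            jitter_sd = 0.35, dropout = 0.1,
                            spurious_rate = 2,
                            area_meanlog = 7, area_sdlog = 0.6, area_beta = 3,
                            erm_core = 12, nem_core = 2,
                            erm_core_prev = c(0.55, 0.9),
                            erm_sat_prev = c(0.1, 0.35),
                            nem_core_prev = c(0.35, 0.55),
                            nem_sat_prev = c(0.01, 0.06),
                            beta_host = 2, beta_geo = 2,
                            n_bands = 119, n_group_bands = 57,
                            n_host_groups = 3, group_mix = 1,
                            seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$dropout, cfg$group_mix)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  counts <- c(n_hosts, n_sites, n_regions, n_otus, n_erm, n_bands)
  if (any(counts <= 0)) abort("counts must be positive")
  if (is.null(seed) || is.na(seed)) abort("seed is mandatory")
  if (n_hosts %% n_sites != 0) abort("n_hosts must be a multiple of n_sites")
  structure(cfg, class = "trflp_scenario")
}

# --- sequences ---------------------------------------------------------------

PRIMER_FWD <- "CTTGGTCATTTAGAGGAAGTAA"           # ITS1F, 6-FAM labelled end
PRIMER_REV_RC <- "GCATATCAATAAGCGGAGGA"          # reverse complement of ITS4

# mutate any occurrence of the recognition motifs until none remain
scrub_sites <- function(chars, enzymes) {
  repeat {
    s <- paste(chars, collapse = "")
    pos <- unlist(lapply(seq_len(nrow(enzymes)), function(k) {
      find_sites(s, enzymes[k, ])
    }))
    if (length(pos) == 0L) return(chars)
    chars[pos[1] + 1L] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos[1] + 1L]), 1)
  }
}

#' Planted TRF truth table
#'
#' Draws, per OTU, an amplicon length and the four expected TRF sizes
#' (HaeIII/HinfI x forward/reverse; the forward and reverse fragments of one
#' enzyme sum to the amplicon length because exactly one site is planted).
#' TRF sizes of different OTUs are kept at least `trf_min_sep` bases apart
#' within each channel so the matcher can recover truth exactly at zero
#' noise.
#'
#' @param cfg A `trflp_scenario`.
#' @return Tibble: `otu_id`, `length`, `hae_fwd`, `hinf_fwd`, `hae_rev`,
#'   `hinf_rev`.
#' @export
generate_trf_truth <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, "sequences"), {
    lens <- integer(0); hf <- integer(0); gf <- integer(0)
    hr <- integer(0); gr <- integer(0)
    for (j in seq_len(cfg$n_otus)) {
      repeat {
        L <- sample(cfg$amplicon_length[1]:cfg$amplicon_length[2], 1)
        f1 <- sample(cfg$trf_range[1]:min(cfg$trf_range[2], L - 60), 1)
        f2 <- sample(cfg$trf_range[1]:min(cfg$trf_range[2], L - 60), 1)
        # one planted site per enzyme: the labelled fragments of recognition
        # length m, cut offset o satisfy forward + reverse = L + 2*o - m
        # (HaeIII: L; HinfI: L - 3)
        r1 <- L - f1; r2 <- L - f2 - 3L
        cand <- c(f1, f2, r1, r2)
        seps <- c(
          if (length(hf)) min(abs(hf - f1)) else Inf,
          if (length(gf)) min(abs(gf - f2)) else Inf,
          if (length(hr)) min(abs(hr - r1)) else Inf,
          if (length(gr)) min(abs(gr - r2)) else Inf
        )
        if (all(cand >= 50) && min(seps) >= cfg$trf_min_sep &&
            abs(f1 - f2) >= 6) break
      }
      lens <- c(lens, L); hf <- c(hf, f1); gf <- c(gf, f2)
      hr <- c(hr, r1); gr <- c(gr, r2)
    }
    tibble(
      otu_id = sprintf("OTU%02d", seq_len(cfg$n_otus)),
      length = lens, hae_fwd = hf, hinf_fwd = gf, hae_rev = hr, hinf_rev = gr
    )
  })
}

# expected_trf_set-shaped table from the planted truth
trf_truth_to_expected <- function(trfs, min_size = 50) {
  trfs |>
    tidyr::pivot_longer(c("hae_fwd", "hinf_fwd", "hae_rev", "hinf_rev"),
                        names_to = "key", values_to = "trf_length") |>
    tidyr::separate_wider_delim("key", "_", names = c("enzyme", "end")) |>
    dplyr::mutate(
      enzyme = dplyr::recode(.data$enzyme, hae = "HaeIII", hinf = "HinfI"),
      end = dplyr::recode(.data$end, fwd = "forward", rev = "reverse"),
      detectable = .data$trf_length >= min_size
    ) |>
    dplyr::select("otu_id", "enzyme", "end", "trf_length", "detectable") |>
    dplyr::arrange(.data$otu_id, .data$enzyme, dplyr::desc(.data$end == "forward"))
}

build_one_amplicon <- function(trf_row, enzymes) {
  L <- trf_row$length
  for (try in 1:200) {
    body_len <- L - nchar(PRIMER_FWD) - nchar(PRIMER_REV_RC)
    chars <- c(
      strsplit(PRIMER_FWD, "")[[1]],
      sample(c("A", "C", "G", "T"), body_len, replace = TRUE),
      strsplit(PRIMER_REV_RC, "")[[1]]
    )
    # clean interior only (primers are site-free), then plant one site each
    inner <- (nchar(PRIMER_FWD) + 1):(L - nchar(PRIMER_REV_RC))
    chars[inner] <- scrub_sites(chars, enzymes)[inner]
    hae_pos <- trf_row$hae_fwd - 2L   # 0-based site start = cut - offset
    hinf_pos <- trf_row$hinf_fwd - 1L
    chars[hae_pos + 1:4] <- c("G", "G", "C", "C")
    chars[hinf_pos + 1:5] <- c("G", "A", sample(c("A", "C", "G", "T"), 1), "T", "C")
    s <- paste(chars, collapse = "")
    ok <- length(find_sites(s, get_enzyme(enzymes, "HaeIII"))) == 1L &&
      length(find_sites(s, get_enzyme(enzymes, "HinfI"))) == 1L
    if (ok) return(s)
  }
  abort("could not plant unique restriction sites; infeasible TRF targets")
}

mutate_copy <- function(sequence, trf_row, enzymes, rate = 0.012) {
  L <- nchar(sequence)
  protected <- c(
    seq_len(nchar(PRIMER_FWD)),
    (L - nchar(PRIMER_REV_RC) + 1):L,
    trf_row$hae_fwd + (-3:4), trf_row$hinf_fwd + (-3:5)
  )
  for (try in 1:50) {
    chars <- strsplit(sequence, "")[[1]]
    k <- max(1L, stats::rbinom(1, L, rate))
    pos <- sample(setdiff(seq_len(L), protected), min(k, L - length(protected)))
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    s <- paste(chars, collapse = "")
    ok <- length(find_sites(s, get_enzyme(enzymes, "HaeIII"))) == 1L &&
      length(find_sites(s, get_enzyme(enzymes, "HinfI"))) == 1L
    if (ok) return(s)
  }
  sequence
}

#' Generate the clone-library sequence fixture
#'
#' One seed amplicon per OTU with exactly one HaeIII and one HinfI site
#' planted at the positions dictated by [generate_trf_truth()], flanked by
#' the ITS1F primer and the reverse complement of ITS4; the remaining
#' sequences are point-mutated copies (about 1% diverged, well inside the
#' 97% OTU threshold) so clustering recovers exactly `n_otus` OTUs.
#'
#' @param cfg A `trflp_scenario`.
#' @param trfs Planted truth from [generate_trf_truth()] (regenerated from
#'   `cfg` when omitted).
#' @return Tibble: `id`, `sequence`, `description`, `otu_id`.
#' @export
generate_sequences <- function(cfg, trfs = generate_trf_truth(cfg)) {
  enzymes <- default_enzymes()
  withr::with_seed(derive_seed(cfg$seed, "sequences") + 1L, {
    seeds <- vapply(seq_len(cfg$n_otus), function(j) {
      build_one_amplicon(trfs[j, ], enzymes)
    }, character(1))
    extra <- cfg$n_seqs - cfg$n_otus
    if (extra < 0) abort("n_seqs must be >= n_otus")
    extra_otu <- sort(sample(seq_len(cfg$n_otus), extra, replace = TRUE))
    rows <- tibble(
      otu = c(seq_len(cfg$n_otus), extra_otu),
      copy = c(rep(1L, cfg$n_otus),
               stats::ave(extra_otu, extra_otu, FUN = seq_along) + 1L)
    )
    rows$sequence <- purrr::map2_chr(rows$otu, rows$copy, function(j, cp) {
      if (cp == 1L) seeds[j] else mutate_copy(seeds[j], trfs[j, ], enzymes)
    })
    tibble(
      id = sprintf("clone%03d", seq_len(nrow(rows))),
      sequence = rows$sequence,
      description = sprintf("synthetic clone of %s", trfs$otu_id[rows$otu]),
      otu_id = trfs$otu_id[rows$otu]
    )
  })
}

# --- landscape and hosts -----------------------------------------------------

#' Generate the sampling landscape and per-sample environment
#'
#' Region centroids are spread over a roughly 300 km window of the study
#' area (subtropical southwest China); sites jitter around their centroid
#' and hosts sit at their site. Climatic and edaphic covariates are region
#' means plus site/host noise, with regional contrasts planted (MAT, MAP,
#' STN and pH differ between regions, as in the reference survey). Host
#' genetic groups follow a region-to-group map (group 1 spans the first and
#' last regions) with a `group_mix` chance of random assignment.
#'
#' @param cfg A `trflp_scenario`.
#' @return Tibble with one row per host: `sample_id`, `site`, `region`,
#'   `latitude`, `longitude`, `elevation`, `MAT`, `MAP`, `STC`, `STN`,
#'   `STP`, `pH`, `host_group`.
#' @export
generate_landscape <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, "landscape"), {
    nr <- cfg$n_regions
    grid <- expand.grid(
      lat = seq(25.3, 28.3, length.out = ceiling(sqrt(nr))),
      lon = seq(99.2, 102.2, length.out = ceiling(sqrt(nr)))
    )[seq_len(nr), ]
    region_lat <- grid$lat + stats::rnorm(nr, 0, 0.2)
    region_lon <- grid$lon + stats::rnorm(nr, 0, 0.2)
    mat_mean <- seq(10.9, 17.0, length.out = nr)
    map_mean <- c(900, 801, 950, 1079, seq(850, 1050, length.out = max(0, nr - 4)))[seq_len(nr)]
    stn_mean <- c(2.1, 1.8, 1.8, 3.0, rep(2.2, max(0, nr - 4)))[seq_len(nr)]
    ph_mean <- c(6.5, 6.8, 6.4, 4.8, rep(6.3, max(0, nr - 4)))[seq_len(nr)]
    elev_mean <- seq(3000, 1800, length.out = nr)
    region_of_site <- rep(seq_len(nr), length.out = cfg$n_sites)
    site_lat <- region_lat[region_of_site] + stats::rnorm(cfg$n_sites, 0, 0.15)
    site_lon <- region_lon[region_of_site] + stats::rnorm(cfg$n_sites, 0, 0.15)
    per_site <- cfg$n_hosts / cfg$n_sites
    site_idx <- rep(seq_len(cfg$n_sites), each = per_site)
    region_idx <- region_of_site[site_idx]
    g_map <- rep(seq_len(cfg$n_host_groups), length.out = nr)
    if (nr >= 2) g_map[nr] <- g_map[1]   # last region shares group 1
    host_group <- g_map[region_idx]
    mix <- stats::runif(cfg$n_hosts) < cfg$group_mix
    host_group[mix] <- sample(seq_len(cfg$n_host_groups), sum(mix), replace = TRUE)
    tibble(
      sample_id = sprintf("H%02d", seq_len(cfg$n_hosts)),
      site = sprintf("S%02d", site_idx),
      region = c("I", "II", "III", "IV", as.character(5:26))[region_idx],
      latitude = site_lat[site_idx],
      longitude = site_lon[site_idx],
      elevation = elev_mean[region_idx] + stats::rnorm(cfg$n_hosts, 0, 80),
      MAT = mat_mean[region_idx] + stats::rnorm(cfg$n_hosts, 0, 0.5),
      MAP = map_mean[region_idx] + stats::rnorm(cfg$n_hosts, 0, 25),
      STC = 35 + stats::rnorm(cfg$n_hosts, 0, 6),
      STN = stn_mean[region_idx] + stats::rnorm(cfg$n_hosts, 0, 0.25),
      STP = 0.6 + stats::rnorm(cfg$n_hosts, 0, 0.12),
      pH = ph_mean[region_idx] + stats::rnorm(cfg$n_hosts, 0, 0.2),
      host_group = host_group
    )
  })
}

#' Generate the binary host ISSR band matrix
#'
#' Three latent band-frequency profiles (one per host group): most bands are
#' shared with intermediate frequencies; `n_group_bands` informative bands
#' are frequent in their own group and rare elsewhere. Frequencies are tuned
#' so pairwise Sørensen similarities between hosts span roughly 0.36-0.84.
#'
#' @param cfg A `trflp_scenario`.
#' @param landscape Tibble from [generate_landscape()] (for host groups).
#' @return Binary matrix hosts x bands.
#' @export
generate_bands <- function(cfg, landscape = generate_landscape(cfg)) {
  withr::with_seed(derive_seed(cfg$seed, "bands"), {
    n_shared <- cfg$n_bands - cfg$n_group_bands
    shared_freq <- stats::runif(n_shared, 0.35, 0.9)
    band_group <- rep(seq_len(cfg$n_host_groups), length.out = cfg$n_group_bands)
    freq <- matrix(NA_real_, cfg$n_host_groups, cfg$n_bands)
    freq[, seq_len(n_shared)] <- matrix(shared_freq, cfg$n_host_groups,
                                        n_shared, byrow = TRUE)
    for (g in seq_len(cfg$n_host_groups)) {
      own <- n_shared + which(band_group == g)
      other <- n_shared + which(band_group != g)
      freq[g, own] <- 0.9
      freq[g, other] <- pmax(freq[g, other], 0.12, na.rm = TRUE)
    }
    bm <- matrix(0L, cfg$n_hosts, cfg$n_bands,
                 dimnames = list(landscape$sample_id,
                                 sprintf("band%03d", seq_len(cfg$n_bands))))
    for (i in seq_len(cfg$n_hosts)) {
      bm[i, ] <- stats::rbinom(cfg$n_bands, 1, freq[landscape$host_group[i], ])
    }
    bm
  })
}

# --- community truth ---------------------------------------------------------

#' Generate the true community matrix
#'
#' Per-OTU occurrence probabilities are logistic in a standardized
#' structuring covariate: for ERM OTUs, host-genetic Sørensen similarity to
#' an OTU-specific anchor host (effect `beta_host`); for NEM OTUs, negative
#' geographic distance to an OTU-specific range centre (effect `beta_geo`).
#' ERM OTUs include a core of high-baseline-prevalence taxa, planting the
#' core-satellite occupancy contrast.
#'
#' @param cfg A `trflp_scenario`.
#' @param landscape Tibble from [generate_landscape()].
#' @param bands Matrix from [generate_bands()].
#' @return List: `truth` (hosts x OTUs 0/1), `guilds`, `baseline`
#'   (per-OTU baseline prevalence).
#' @export
generate_community <- function(cfg, landscape = generate_landscape(cfg),
                               bands = generate_bands(cfg, landscape)) {
  withr::with_seed(derive_seed(cfg$seed, "community"), {
    otu_id <- sprintf("OTU%02d", seq_len(cfg$n_otus))
    guilds <- stats::setNames(
      rep(c("ERM", "UNKNOWN"), c(cfg$n_erm, cfg$n_otus - cfg$n_erm)), otu_id
    )
    n_nem <- cfg$n_otus - cfg$n_erm
    baseline <- c(
      stats::runif(cfg$erm_core, cfg$erm_core_prev[1], cfg$erm_core_prev[2]),
      stats::runif(cfg$n_erm - cfg$erm_core, cfg$erm_sat_prev[1], cfg$erm_sat_prev[2]),
      stats::runif(cfg$nem_core, cfg$nem_core_prev[1], cfg$nem_core_prev[2]),
      stats::runif(n_nem - cfg$nem_core, cfg$nem_sat_prev[1], cfg$nem_sat_prev[2])
    )
    host_sim <- 1 - host_distance_matrix(bands)
    geo <- geographic_distance(landscape)
    truth <- matrix(0L, cfg$n_hosts, cfg$n_otus,
                    dimnames = list(landscape$sample_id, otu_id))
    for (j in seq_len(cfg$n_otus)) {
      if (guilds[j] == "ERM") {
        anchor <- sample.int(cfg$n_hosts, 1)
        z <- host_sim[, anchor]
        beta <- cfg$beta_host
      } else {
        centre <- sample.int(cfg$n_hosts, 1)
        z <- -geo[, centre]
        beta <- cfg$beta_geo
      }
      z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
      p <- stats::plogis(stats::qlogis(baseline[j]) + beta * z)
      truth[, j] <- stats::rbinom(cfg$n_hosts, 1, p)
    }
    list(truth = truth, guilds = guilds, baseline = baseline)
  })
}

# --- peak profiles -----------------------------------------------------------

#' Generate noisy T-RFLP peak tables from a truth matrix
#'
#' For every present host x OTU pair and each of the four channels, a peak
#' is emitted at the planted TRF size plus Gaussian jitter, dropped with
#' probability `dropout`; areas are log-normal with a mean coupled to OTU
#' baseline prevalence. Spurious peaks (Poisson per channel, sizes uniform
#' over 30-600 bases, so some fall below the 50-base window) are added on
#' top.
#'
#' @param cfg A `trflp_scenario`.
#' @param truth Hosts x OTUs 0/1 matrix.
#' @param trfs Planted truth from [generate_trf_truth()].
#' @param baseline Per-OTU baseline prevalence (for area coupling); defaults
#'   to 0.5 for all.
#' @return Peak tibble (`sample_id`, `enzyme`, `end`, `size`, `height`,
#'   `area`, `excluded`), the schema of [read_peak_table()].
#' @export
generate_profiles <- function(cfg, truth, trfs, baseline = NULL) {
  baseline <- baseline %||% rep(0.5, nrow(trfs))
  expected <- trf_truth_to_expected(trfs, min_size = 0)
  meanlog <- cfg$area_meanlog + cfg$area_beta * (baseline - 0.5)
  names(meanlog) <- trfs$otu_id
  channels <- dplyr::distinct(expected, .data$enzyme, .data$end)
  withr::with_seed(derive_seed(cfg$seed, "profiles"), {
    pres <- which(truth == 1L, arr.ind = TRUE)
    real <- expected |>
      dplyr::inner_join(
        tibble(sample_id = rownames(truth)[pres[, 1]],
               otu_id = colnames(truth)[pres[, 2]]),
        by = "otu_id", relationship = "many-to-many"
      )
    keep <- stats::runif(nrow(real)) >= cfg$dropout
    real <- real[keep, ]
    real$size <- real$trf_length + stats::rnorm(nrow(real), 0, cfg$jitter_sd)
    real$area <- stats::rlnorm(nrow(real), meanlog[real$otu_id], cfg$area_sdlog)
    grid <- tidyr::expand_grid(sample_id = rownames(truth), channels)
    n_spur <- stats::rpois(nrow(grid), cfg$spurious_rate)
    spur <- grid[rep(seq_len(nrow(grid)), n_spur), ]
    spur$size <- stats::runif(nrow(spur), 30, 600)
    spur$area <- stats::rlnorm(nrow(spur), cfg$area_meanlog - 1, cfg$area_sdlog)
    peaks <- dplyr::bind_rows(
      dplyr::select(real, "sample_id", "enzyme", "end", "size", "area"),
      dplyr::select(spur, "sample_id", "enzyme", "end", "size", "area")
    )
    peaks |>
      dplyr::mutate(height = .data$area / 10, excluded = .data$size < 50) |>
      dplyr::arrange(.data$sample_id, .data$enzyme, .data$end, .data$size) |>
      dplyr::select("sample_id", "enzyme", "end", "size", "height", "area",
                    "excluded")
  })
}

# --- full bundle -------------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Runs every generator stage under seeds derived from the scenario's root
#' seed and returns the full bundle: planted TRF truth, clone-library
#' sequences (optional, they are only needed for clustering demonstrations),
#' landscape/environment, host band matrix, true community and noisy peak
#' tables.
#'
#' @param cfg A `trflp_scenario`.
#' @param sequences Generate the sequence fixture too (default TRUE).
#' @return A `trflp_study` list: `config`, `trfs`, `expected`, `sequences`,
#'   `landscape`, `bands`, `community` (truth/guilds/baseline), `peaks`.
#' @export
generate_study <- function(cfg = scenario_config(), sequences = TRUE) {
  trfs <- generate_trf_truth(cfg)
  landscape <- generate_landscape(cfg)
  bands <- generate_bands(cfg, landscape)
  community <- generate_community(cfg, landscape, bands)
  peaks <- generate_profiles(cfg, community$truth, trfs, community$baseline)
  seqs <- if (sequences) generate_sequences(cfg, trfs) else NULL
  structure(
    list(config = cfg, trfs = trfs,
         expected = trf_truth_to_expected(trfs),
         sequences = seqs, landscape = landscape, bands = bands,
         community = community, peaks = peaks),
    class = "trflp_study"
  )
}

#' @export
print.trflp_study <- function(x, ...) {
  cat(sprintf(
    "<trflp_study> %d hosts / %d sites / %d regions; %d OTUs (%d ERM); seed %s\n",
    x$config$n_hosts, x$config$n_sites, x$config$n_regions, x$config$n_otus,
    x$config$n_erm, format(x$config$seed)
  ))
  invisible(x)
}

#' Write a synthetic study bundle to a directory
#'
#' Emits `sequences.fasta`, `peaks.csv`, `bands.csv`, `env.csv`, `truth.csv`
#' and `config.yaml`; regenerating from the config reproduces the files
#' byte for byte.
#'
#' @param study A `trflp_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(study$sequences)) {
    write_amplicons(study$sequences, file.path(dir, "sequences.fasta"))
  }
  readr::write_csv(study$peaks[, 1:6], file.path(dir, "peaks.csv"))
  readr::write_csv(as_tibble(study$bands, rownames = "sample_id"),
                   file.path(dir, "bands.csv"))
  readr::write_csv(study$landscape, file.path(dir, "env.csv"))
  readr::write_csv(as_tibble(study$community$truth, rownames = "sample_id"),
                   file.path(dir, "truth.csv"))
  yaml::write_yaml(unclass(study$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
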