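#' Pipeline configuration
#'
#' Collects input paths and analysis settings. Defaults are the study's
#' stated settings: 1-base matching tolerance, 50-base minimum fragment,
#' 4999 Mantel permutations and 9999 envfit permutations.
#'
#' @param peaks,env,bands,fasta Input file paths (peak table CSV, per-sample
#'   environment CSV, binary ISSR band CSV, amplicon FASTA). `fasta` may be
#'   `NULL` when an expected-TRF table is supplied to [run_pipeline()]
#'   directly.
#' @param out_dir Output directory for result CSVs.
#' @param tolerance Peak matching tolerance in bases.
#' @param min_size Minimum fragment size in bases.
#' @param n_perm_mantel,n_perm_envfit Permutation counts.
#' @param seed Root seed; every stage derives its own stream from it.
#' @param empty How guild Sørensen matrices treat empty samples
#'   (see [sorensen_dissimilarity_matrix()]); the pipeline default `"one"`
#'   keeps noisy runs alive.
#' @return A `trflp_config` list.
#' @export
pipeline_config <- function(peaks, env, bands, fasta = NULL, out_dir = NULL,
                            tolerance = 1, min_size = 50,
                            n_perm_mantel = 4999, n_perm_envfit = 9999,
                            seed = 1, empty = "one") {
  structure(as.list(environment()), class = "trflp_config")
}

#' Validate pipeline inputs
#'
#' Schema checks plus sample-id cross-referencing between the peak table,
#' the environment table and the band matrix. Returns diagnostics rather
#' than failing: rows are labelled `"error"` or `"warning"`.
#'
#' @param config A `trflp_config`.
#' @return Tibble with columns `level` and `message`.
#' @export
validate_inputs <- function(config) {
  diags <- list()
  note <- function(level, message) {
    diags[[length(diags) + 1L]] <<- tibble(level = level, message = message)
  }
  peaks <- tryCatch(
    withCallingHandlers(
      read_peak_table(config$peaks, min_size = config$min_size),
      warning = function(w) {
        note("warning", conditionMessage(w)); invokeRestart("muffleWarning")
      }
    ),
    error = function(e) { note("error", conditionMessage(e)); NULL }
  )
  env <- tryCatch(readr::read_csv(config$env, show_col_types = FALSE,
                                  progress = FALSE),
                  error = function(e) { note("error", conditionMessage(e)); NULL })
  bands <- tryCatch(read_band_matrix(config$bands),
                    error = function(e) { note("error", conditionMessage(e)); NULL })
  if (!is.null(peaks) && any(peaks$excluded)) {
    note("warning", sprintf("%d peak(s) below the %d-base filter",
                            sum(peaks$excluded), as.integer(config$min_size)))
  }
  if (!is.null(peaks) && !is.null(env)) {
    miss <- setdiff(unique(peaks$sample_id), env$sample_id)
    for (id in miss) {
      note("error", sprintf("sample '%s' in peaks missing from env table", id))
    }
  }
  if (!is.null(env) && !is.null(bands)) {
    miss <- setdiff(env$sample_id, rownames(bands))
    for (id in miss) {
      note("error", sprintf("sample '%s' missing from band matrix", id))
    }
  }
  if (length(diags) == 0L) return(tibble(level = character(), message = character()))
  dplyr::bind_rows(diags)
}

#' Run the full T-RFLP workflow
#'
#' Digest -> match -> guild partition -> host genetics -> community
#' statistics -> ordination with envfit. Every result is returned in one
#' list and, when `config$out_dir` is set, written as tidy CSVs together
#' with a `run_log.txt` recording the seed, permutation counts and settings.
#'
#' @param config A `trflp_config`.
#' @param expected Optional expected-TRF table (as from [expected_trf_set()]);
#'   when omitted it is computed from `config$fasta`.
#' @param guilds Optional named guild vector per OTU; when omitted OTUs are
#'   classified from their FASTA descriptions.
#' @return A `trflp_results` list.
#' @export
run_pipeline <- function(config, expected = NULL, guilds = NULL) {
  stage <- "input validation"
  result <- tryCatch({
    diags <- validate_inputs(config)
    if (any(diags$level == "error")) {
      abort(paste("invalid inputs:",
                  paste(diags$message[diags$level == "error"], collapse = "; ")))
    }
    stage <- "in-silico digest"
    if (is.null(expected)) {
      seqs <- read_amplicons(config$fasta)
      expected <- expected_trf_set(seqs, min_size = config$min_size)
      if (is.null(guilds)) {
        guilds <- stats::setNames(
          classify_guild(seqs$id, seqs$description), seqs$id
        )
      }
    }
    stage <- "peak matching"
    peaks <- suppressWarnings(read_peak_table(config$peaks,
                                              min_size = config$min_size))
    cm <- build_community(expected, peaks, guilds = guilds,
                          tolerance = config$tolerance)
    parts <- partition_guilds(cm)
    stage <- "host genetics"
    bands <- read_band_matrix(config$bands)
    bands <- bands[cm$samples, , drop = FALSE]
    host_d <- host_distance_matrix(bands)
    pca <- host_pca(bands)
    groups <- host_groups(pca, seed = derive_seed(config$seed, "stats"))
    env <- readr::read_csv(config$env, show_col_types = FALSE, progress = FALSE)
    env <- env[match(cm$samples, env$sample_id), ]
    env$HSTPC1 <- pca$scores[cm$samples, 1]
    env$HSTPC2 <- pca$scores[cm$samples, 2]
    stage <- "community statistics"
    geo <- geographic_distance(env)
    comm_d <- lapply(parts, community_dissimilarity, empty = config$empty)
    seed_stats <- derive_seed(config$seed, "stats")
    explanatory <- list(geographic = geo, host = host_d)
    if (all(c("MAT", "MAP") %in% names(env))) {
      explanatory$climatic <- quantitative_matrix_distance(env, c("MAT", "MAP"))
    }
    if (all(c("STC", "STN", "STP") %in% names(env))) {
      explanatory$soil <- quantitative_matrix_distance(env,
                                                       c("STC", "STN", "STP"))
    }
    mantels <- purrr::imap_dfr(comm_d, function(d, g) {
      purrr::imap_dfr(explanatory, function(m, nm) {
        mt <- mantel_test(d, m, config$n_perm_mantel,
                          seed = seed_stats + match(nm, names(explanatory)))
        dplyr::mutate(tidy(mt), community = g, matrix = nm, .before = 1)
      })
    })
    decay <- purrr::map(comm_d, distance_decay, geographic_d = geo,
                        n_perm = config$n_perm_mantel, seed = seed_stats)
    occ <- occupancy_distribution(cm)
    acc <- accumulation_curve(cm$presence,
                              seed = derive_seed(config$seed, "accumulation"))
    stage <- "ordination"
    factors <- intersect(
      c("latitude", "longitude", "elevation", "MAT", "MAP", "STC", "STN",
        "STP", "pH", "HSTPC1", "HSTPC2"),
      names(env)
    )
    envfit <- envfit_table(
      list(ERM = parts$ERM$presence, NEM = parts$NEM$presence, host = bands),
      env, factors = factors, n_perm = config$n_perm_envfit,
      seed = config$seed
    )
    list(community = cm, partitions = parts, host_pca = pca,
         host_groups = groups, host_distance = host_d, geographic = geo,
         dissimilarity = comm_d, mantel = mantels, decay = decay,
         occupancy = occ, accumulation = acc, envfit = envfit, env = env)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(x, name) {
      readr::write_csv(x, file.path(config$out_dir, name))
    }
    out(tidy(result$community), "community.csv")
    out(result$mantel, "mantel.csv")
    out(tibble::as_tibble(result$envfit), "envfit.csv")
    out(tidy(result$occupancy), "occupancy.csv")
    out(tidy(result$accumulation), "accumulation.csv")
    out(result$host_groups, "host_groups.csv")
    writeLines(
      c(sprintf("seed: %s", format(config$seed)),
        sprintf("tolerance: %s", format(config$tolerance)),
        sprintf("min_size: %s", format(config$min_size)),
        sprintf("n_perm_mantel: %d", config$n_perm_mantel),
        sprintf("n_perm_envfit: %d", config$n_perm_envfit),
        sprintf("trflpr version: %s",
                as.character(utils::packageVersion("trflpr")))),
      file.path(config$out_dir, "run_log.txt")
    )
  }
  structure(result, class = "trflp_results")
}

#' @export
print.trflp_results <- function(x, ...) {
  print(x$community)
  cat("Mantel tests:\n")
  print(x$mantel)
  invisible(x)
}
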