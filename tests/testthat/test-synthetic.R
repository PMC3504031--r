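test_that("scenario configuration validates its parameters", {
  expect_s3_class(scenario_config(seed = 1), "trflp_scenario")
  expect_error(scenario_config(dropout = 1.3, seed = 1), "probabilities")
  expect_error(scenario_config(n_otus = 0, seed = 1), "positive")
  expect_error(scenario_config(seed = NA), "seed")
  expect_error(scenario_config(n_hosts = 44, seed = 1), "multiple")
})

test_that("planted TRF truth is feasible and channel-separated", {
  cfg <- scenario_config(seed = 4)
  trfs <- generate_trf_truth(cfg)
  expect_equal(nrow(trfs), 35L)
  expect_true(all(trfs[c("hae_fwd", "hinf_fwd", "hae_rev", "hinf_rev")] >= 50))
  expect_true(all(trfs$hae_fwd + trfs$hae_rev == trfs$length))
  expect_true(all(trfs$hinf_fwd + trfs$hinf_rev == trfs$length - 3))
  for (ch in c("hae_fwd", "hinf_fwd", "hae_rev", "hinf_rev")) {
    expect_gte(min(diff(sort(trfs[[ch]]))), cfg$trf_min_sep)
  }
})

test_that("planted sequences digest to the planted fragment sizes", {
  cfg <- tiny_config(seed = 2)
  trfs <- generate_trf_truth(cfg)
  seqs <- generate_sequences(cfg, trfs)
  expect_equal(nrow(seqs), cfg$n_seqs)
  reps <- seqs[!duplicated(seqs$otu_id), ]
  exp <- suppressWarnings(expected_trf_set(
    tibble::tibble(id = reps$otu_id, sequence = reps$sequence)
  ))
  wide <- tidyr::pivot_wider(exp, id_cols = "otu_id",
                             names_from = c("enzyme", "end"),
                             values_from = "trf_length")
  wide <- wide[match(trfs$otu_id, wide$otu_id), ]
  expect_equal(wide$HaeIII_forward, trfs$hae_fwd)
  expect_equal(wide$HaeIII_reverse, trfs$hae_rev)
  expect_equal(wide$HinfI_forward, trfs$hinf_fwd)
  expect_equal(wide$HinfI_reverse, trfs$hinf_rev)
  # primers flank every amplicon
  expect_true(all(startsWith(seqs$sequence, "CTTGGTCATTTAGAGGAAGTAA")))
  expect_true(all(endsWith(seqs$sequence, "GCATATCAATAAGCGGAGGA")))
})

test_that("mutated clone copies stay within the species threshold of their seed", {
  cfg <- tiny_config(seed = 8)
  seqs <- generate_sequences(cfg)
  d <- pairwise_distance(seqs)
  cl <- cluster_otus(d, 0.03)
  expect_equal(length(unique(cl$otu_id)), cfg$n_otus)
  agree <- merge(cl, seqs[, c("id", "otu_id")], by.x = "member_id", by.y = "id")
  expect_true(all(tapply(agree$otu_id.y, agree$otu_id.x,
                         function(v) length(unique(v)) == 1)))
})

test_that("landscape bookkeeping: hosts, sites, regions and planted contrasts", {
  cfg <- scenario_config(seed = 14)
  l <- generate_landscape(cfg)
  expect_equal(nrow(l), 45L)
  expect_equal(length(unique(l$site)), 15L)
  expect_equal(sort(unique(l$region)), c("I", "II", "III", "IV"))
  expect_equal(as.integer(table(l$site)), rep(3L, 15))
  # planted regional MAP contrast is large
  fit <- stats::aov(MAP ~ region, data = l)
  expect_lt(summary(fit)[[1]]$`Pr(>F)`[1], 1e-6)
})

test_that("null effect sizes leave occupancy at baseline prevalence", {
  cfg <- scenario_config(beta_host = 0, beta_geo = 0, seed = 20)
  comm <- generate_community(cfg)
  occ_rate <- colMeans(comm$truth)
  # per-OTU binomial CI check: |observed - baseline| within 3 SE
  se <- sqrt(comm$baseline * (1 - comm$baseline) / nrow(comm$truth))
  expect_gte(mean(abs(occ_rate - comm$baseline) <= 3 * pmax(se, 0.02)), 0.95)
})

test_that("every generated artifact satisfies its consumer's contract", {
  st <- generate_study(tiny_config(seed = 30))
  expect_silent(check_dist <- host_distance_matrix(st$bands))
  expect_true(all(st$peaks$size >= 0))
  expect_true(all(c("sample_id", "enzyme", "end", "size", "height", "area")
                  %in% names(st$peaks)))
  cm <- build_community(st$expected, st$peaks, guilds = st$community$guilds)
  expect_equal(cm$samples, st$landscape$sample_id)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_equal(suppressWarnings(nrow(read_peak_table(file.path(dir, "peaks.csv")))),
               nrow(dplyr::distinct(st$peaks, sample_id, enzyme, end, size)))
  expect_equal(read_band_matrix(file.path(dir, "bands.csv")), st$bands)
  expect_equal(nrow(read_amplicons(file.path(dir, "sequences.fasta"))),
               nrow(st$sequences))
})

test_that("the full bundle is bit-reproducible under its seed", {
  a <- generate_study(tiny_config(seed = 77))
  b <- generate_study(tiny_config(seed = 77))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$bands, b$bands)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$community$truth, b$community$truth)
  c <- generate_study(tiny_config(seed = 78), sequences = FALSE)
  expect_false(identical(a$peaks, c$peaks))
  # written files byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(a, d1); write_study(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
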