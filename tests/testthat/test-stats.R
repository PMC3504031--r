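test_that("Sørensen dissimilarity matrices follow the set formula", {
  x <- rbind(
    s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1), s3 = c(1, 1, 1, 0),
    s4 = c(0, 0, 0, 1)
  )
  d <- sorensen_dissimilarity_matrix(x)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s4"], 1)       # complementary presence sets
  expect_equal(d, t(d))
  x2 <- rbind(s1 = c(1, 0), s2 = c(0, 0))
  expect_error(sorensen_dissimilarity_matrix(x2), "s2")
  d2 <- sorensen_dissimilarity_matrix(x2, empty = "one")
  expect_equal(d2["s1", "s2"], 1)
  # agreement with the binary Bray-Curtis implementation in vegan
  y <- (random_distance_matrix(6, 5) > 1) * 1
  rownames(y) <- colnames(y) <- NULL
  expect_equal(
    sorensen_dissimilarity_matrix(y)[lower.tri(diag(6))],
    as.vector(vegan::vegdist(y, method = "bray", binary = TRUE))
  )
})

test_that("community dissimilarity averages the four TRF channels", {
  m <- function(v) matrix(c(0, v, v, 0), 2, 2)
  avg <- mean_dissimilarity(list(m(0.2), m(0.4), m(0.6), m(0.8)))
  expect_equal(avg[1, 2], 0.5)
  expect_equal(mean_dissimilarity(list(m(0.3), m(0.3)))[1, 2], 0.3)
  expect_error(mean_dissimilarity(list(m(1), diag(3))), "conformable")
})

test_that("great-circle distances use the 6371 km sphere", {
  s <- tibble::tibble(sample_id = c("a", "b", "c"),
                      latitude = c(0, 0, 10), longitude = c(0, 1, 3))
  d <- geographic_distance(s)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 2 * pi * 6371 / 360, tolerance = 1e-6)
  # metric property on random triples
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- tibble::tibble(sample_id = c("x", "y", "z"),
                          latitude = stats::runif(3, -80, 80),
                          longitude = stats::runif(3, -170, 170))
      dd <- geographic_distance(p)
      expect_lte(dd[1, 3], dd[1, 2] + dd[2, 3] + 1e-9)
    }
  })
  expect_error(
    geographic_distance(tibble::tibble(sample_id = "a", latitude = 95,
                                       longitude = 0)),
    "out of range"
  )
})

test_that("Mantel r equals the explicit pair-loop oracle and vegan", {
  for (s in 1:10) {
    d1 <- random_distance_matrix(7, s)
    d2 <- random_distance_matrix(7, s + 100)
    mt <- mantel_test(d1, d2, n_perm = 99, seed = 1)
    expect_equal(mt$r, oracle_mantel_r(d1, d2), tolerance = 1e-12)
    expect_equal(mt$r, unname(vegan::mantel(d1, d2, permutations = 5)$statistic),
                 tolerance = 1e-10)
  }
  d <- random_distance_matrix(5, 1)
  expect_equal(mantel_test(d, d, n_perm = 99, seed = 1)$r, 1)
  expect_error(mantel_test(d, matrix(0, 5, 5), n_perm = 9), "zero variance")
  expect_error(mantel_test(d[1:3, 1:3], d[1:3, 1:3], 9), "at least 4")
})

test_that("Mantel permutation p has the exact add-one convention and seed behaviour", {
  d1 <- random_distance_matrix(8, 2)
  d2 <- 2 * d1 + 1; diag(d2) <- 0   # perfectly correlated
  mt <- mantel_test(d1, d2, n_perm = 199, seed = 42)
  expect_equal(mt$p, 1 / 200)        # only the observed ordering reaches r = 1
  # bit-reproducible under the same seed; r unchanged under another seed
  again <- mantel_test(d1, d2, n_perm = 199, seed = 42)
  expect_identical(mt$p, again$p)
  other <- mantel_test(d1, d2, n_perm = 199, seed = 43)
  expect_identical(mt$r, other$r)
  expect_false(identical(mt$r_perm, other$r_perm))
})

test_that("distance decay reports permutation and parametric significance", {
  geo <- random_distance_matrix(10, 4)
  comm <- geo / max(geo)
  dec <- distance_decay(comm, geo, n_perm = 99, seed = 1)
  expect_equal(dec$r, 1, tolerance = 1e-12)
  expect_equal(dec$p, 1 / 100)
  expect_equal(dec$n_pairs, 45)
  expect_s3_class(autoplot(dec), "ggplot")
})

test_that("max-relativized Euclidean distances are unit-invariant", {
  s <- tibble::tibble(sample_id = c("a", "b"), MAT = c(1, 2), MAP = c(10, 30))
  d <- quantitative_matrix_distance(s, "MAT")
  expect_equal(d["a", "b"], 0.5)
  d2 <- quantitative_matrix_distance(dplyr::mutate(s, MAT = MAT * 7), "MAT")
  expect_equal(d2, d)
  expect_error(quantitative_matrix_distance(s, "pH"), "pH")
  expect_error(
    quantitative_matrix_distance(tibble::tibble(sample_id = "a", MAT = -1), "MAT"),
    "non-positive"
  )
})

test_that("occupancy distributions bin hosts and regions with conservation", {
  st <- generate_study(scenario_config(seed = 2), sequences = FALSE)
  cm <- build_community(st$expected, st$peaks, guilds = st$community$guilds)
  occ <- suppressWarnings(occupancy_distribution(cm))
  tab <- tidy(occ)
  detected <- sum(colSums(cm$presence) > 0)
  expect_equal(sum(tab$count), detected)
  expect_equal(levels(tab$bin)[1:2], c("1-5", "6-10"))
  # a TRF in 3 hosts lands in the first bin
  expect_equal(as.character(cut(3, seq(0, 45, 5), paste(
    seq(1, 41, 5), seq(5, 45, 5), sep = "-"))), "1-5")
  regions <- stats::setNames(st$landscape$region, st$landscape$sample_id)
  occ_r <- suppressWarnings(
    occupancy_distribution(cm, mode = "regions", regions = regions)
  )
  expect_equal(sum(tidy(occ_r)$count), detected)
  expect_true(all(as.integer(as.character(tidy(occ_r)$bin)) %in% 1:4))
  expect_s3_class(autoplot(occ), "ggplot")
})

test_that("Fisher's exact test matches enumeration on toy tables", {
  expect_equal(fisher_exact_2x2(rbind(c(2, 0), c(0, 2))), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_error(fisher_exact_2x2(rbind(c(-1, 1), c(1, 1))), "non-negative")
  expect_error(fisher_exact_2x2(rbind(c(0.5, 1), c(1, 1))), "integer")
})

test_that("abundance-occupancy regression reproduces hand OLS", {
  toy <- tibble::tibble(otu_id = c("a", "b", "c"),
                        abundance = c(1, 2, 4), occupancy = c(1, 2, 3))
  fit <- abundance_occupancy_regression(toy)
  gl <- glance(fit)
  expect_equal(gl$slope, 1.5)
  expect_equal(gl$intercept, -2 / 3, tolerance = 1e-12)
  perfect <- tibble::tibble(otu_id = c("a", "b", "c"),
                            abundance = c(1, 2, 3), occupancy = c(1, 2, 3))
  expect_equal(
    suppressWarnings(glance(abundance_occupancy_regression(perfect))$r.squared),
    1
  )
  same <- dplyr::mutate(toy, occupancy = 2)
  expect_error(abundance_occupancy_regression(same), "zero variance")
})

test_that("accumulation curves are complete at n = N and monotone in the mean", {
  pres <- rbind(
    H1 = c(1, 1, 0, 0), H2 = c(0, 1, 1, 0), H3 = c(0, 0, 1, 1)
  )
  acc <- accumulation_curve(pres, n_resamples = 400, seed = 9)
  tab <- tidy(acc)
  expect_equal(tab$mean_pct[3], 100)
  expect_equal(tab$sd_pct[3], 0)
  expect_true(all(diff(tab$mean_pct) >= -1e-9))
  # one sample holding every TRF: closed-form expectation at n = 1
  pres2 <- rbind(H1 = c(1, 1, 1), H2 = c(0, 0, 0), H3 = c(0, 0, 0))
  acc2 <- accumulation_curve(pres2, n_resamples = 4000, seed = 9)
  expect_equal(tidy(acc2)$mean_pct[1], 100 / 3, tolerance = 0.08)
  expect_s3_class(autoplot(acc), "ggplot")
  expect_true(is.na(hosts_for_coverage(
    accumulation_curve(pres2[1:2, ], 10, 1), 200)))
})

test_that("Bray-Curtis single linkage matches the brute-force merge order", {
  x <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0.05))
  hm <- cluster_heatmap(x)
  expect_equal(hm$distance["a", "b"], 1)     # disjoint rows
  expect_equal(hm$distance["a", "a"], 0)
  # a and c are nearest -> merged first
  expect_equal(sort(hm$hclust$merge[1, ]), c(-3, -1))
  expect_error(cluster_heatmap(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
  # brute-force single linkage oracle on random tables
  for (s in 1:5) {
    y <- withr::with_seed(s, matrix(stats::runif(32), 8))
    rownames(y) <- letters[1:8]
    hm2 <- cluster_heatmap(y)
    d <- as.matrix(vegan::vegdist(y, "bray"))
    # oracle: repeated nearest-pair merging; record merge heights
    groups <- as.list(seq_len(8))
    heights <- c()
    while (length(groups) > 1) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (i < j) {
          h <- min(d[groups[[i]], groups[[j]]])
          if (h < best[1]) best <- c(h, i, j)
        }
      }
      heights <- c(heights, best[1])
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    expect_equal(hm2$hclust$height, heights, tolerance = 1e-12)
  }
  expect_s3_class(autoplot(hm), "ggplot")
})

test_that("core-satellite contrast shows in the occupancy comparison", {
  st <- generate_study(scenario_config(seed = 6), sequences = FALSE)
  cm <- build_community(st$expected, st$peaks, guilds = st$community$guilds)
  oc <- occupancy_contrast(suppressWarnings(occupancy_distribution(cm)))
  # NEM TRFs concentrate in the rare classes relative to ERM
  expect_gt(oc$nem_low / max(1, oc$nem_low + oc$nem_high),
            oc$erm_low / (oc$erm_low + oc$erm_high))
})
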