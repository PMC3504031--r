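expected_toy <- function(sizes = c(120, 245, 88, 310)) {
  tibble::tibble(
    otu_id = "OTU1",
    enzyme = c("HaeIII", "HaeIII", "HinfI", "HinfI"),
    end = c("forward", "reverse", "forward", "reverse"),
    trf_length = sizes,
    detectable = sizes >= 50
  )
}

peaks_toy <- function(sizes, areas = rep(100, length(sizes)),
                      enzymes = c("HaeIII", "HaeIII", "HinfI"),
                      ends = c("forward", "reverse", "forward")) {
  tibble::tibble(
    sample_id = "H1", enzyme = enzymes, end = ends,
    size = sizes, height = areas / 10, area = areas, excluded = sizes < 50
  )
}

test_that("the 3-of-4 rule with a 1-base inclusive tolerance decides presence", {
  # three of four expected fragments observed (within 1 base) -> present
  m <- match_otu(expected_toy(), peaks_toy(c(121, 245, 88)))
  expect_true(m$present)
  expect_equal(sum(m$keys$matched), 3L)
  # 1.6 bases off pushes one key out -> only 2 matched -> absent
  m2 <- match_otu(expected_toy(), peaks_toy(c(121.6, 245, 88)))
  expect_false(m2$present)
  expect_equal(sum(m2$keys$matched), 2L)
  # the boundary itself matches (inclusive)
  m3 <- match_otu(expected_toy(), peaks_toy(c(121.0, 245, 88)))
  expect_true(m3$present)
})

test_that("sub-window peaks and sub-window expected fragments never match", {
  exp49 <- expected_toy(c(49, 245, 88, 310))
  pk <- peaks_toy(c(49, 245, 88))
  m <- match_otu(exp49, pk)
  expect_false(m$keys$matched[m$keys$enzyme == "HaeIII" &
                                m$keys$end == "forward"])
  expect_equal(sum(m$keys$matched), 2L)
})

test_that("nearest peak (then largest area) is booked for the matched area", {
  pk <- dplyr::bind_rows(
    peaks_toy(c(120.3, 245, 88), areas = c(50, 100, 100)),
    peaks_toy(119.9, areas = 900)  # nearer to 120 -> wins despite later row
  )
  m <- match_otu(expected_toy(), pk)
  a <- m$keys$area[m$keys$enzyme == "HaeIII" & m$keys$end == "forward"]
  expect_equal(a, 900)
})

test_that("peak tables are validated, filtered and de-duplicated on read", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    sample_id = "H1", enzyme = "HaeIII", end = "forward",
    size = c(120, 49.4, 120), height = 1, area = c(10, 5, 7)
  ), tmp)
  expect_warning(pk <- read_peak_table(tmp), "merged")
  expect_equal(nrow(pk), 2L)                         # duplicates merged
  expect_equal(pk$area[pk$size == 120], 17)          # areas summed
  expect_true(pk$excluded[pk$size == 49.4])          # below the 50-base window
  readr::write_csv(tibble::tibble(sample_id = "H1", size = 120), tmp)
  expect_error(read_peak_table(tmp), "missing column")
  readr::write_csv(tibble::tibble(
    sample_id = "H1", enzyme = "HaeIII", end = "forward",
    size = -5, height = 1, area = 1
  ), tmp)
  expect_error(read_peak_table(tmp), "negative")
})

test_that("community assembly matches a hand-computed 2x2 toy", {
  expected <- dplyr::bind_rows(
    expected_toy(),
    dplyr::mutate(expected_toy(c(200, 150, 99, 400)), otu_id = "OTU2")
  )
  # H1 carries OTU1 fully; H2 carries only 2 of OTU2's fragments
  peaks <- dplyr::bind_rows(
    peaks_toy(c(120, 245, 88, 310), enzymes = c("HaeIII", "HaeIII", "HinfI", "HinfI"),
              ends = c("forward", "reverse", "forward", "reverse")),
    dplyr::mutate(peaks_toy(c(200, 150), enzymes = c("HaeIII", "HaeIII"),
                            ends = c("forward", "reverse")), sample_id = "H2")
  )
  cm <- build_community(expected, peaks)
  expect_equal(cm$presence, matrix(c(1L, 0L, 0L, 0L), 2, 2,
                                   dimnames = list(c("H1", "H2"),
                                                   c("OTU1", "OTU2"))))
  # never-detected OTU keeps its all-zero column
  expect_true("OTU2" %in% colnames(cm$presence))
  expect_equal(sum(cm$trf[["HaeIII_forward"]]), 2L)  # both OTUs hit in H1/H2
})

test_that("guild partition is a disjoint cover of the OTU columns", {
  st <- generate_study(tiny_config(seed = 3), sequences = FALSE)
  cm <- build_community(st$expected, st$peaks, guilds = st$community$guilds)
  parts <- partition_guilds(cm)
  expect_equal(ncol(parts$ERM$presence) + ncol(parts$NEM$presence),
               ncol(cm$presence))
  expect_length(intersect(parts$ERM$otus, parts$NEM$otus), 0)
  expect_true(all(parts$ERM$guilds == "ERM"))
  expect_false(any(parts$NEM$guilds == "ERM"))
})

test_that("abundance is the log10 mean of matched areas", {
  expected <- expected_toy()
  peaks <- dplyr::bind_rows(
    peaks_toy(c(120, 245, 88, 310), areas = rep(100, 4),
              enzymes = c("HaeIII", "HaeIII", "HinfI", "HinfI"),
              ends = c("forward", "reverse", "forward", "reverse")),
    dplyr::mutate(
      peaks_toy(c(120, 245, 88, 310), areas = rep(1000, 4),
                enzymes = c("HaeIII", "HaeIII", "HinfI", "HinfI"),
                ends = c("forward", "reverse", "forward", "reverse")),
      sample_id = "H2"
    )
  )
  cm <- build_community(expected, peaks)
  ab <- otu_abundance(cm)
  expect_equal(ab$abundance, log10(550), tolerance = 1e-12)
  expect_equal(ab$occupancy, 2L)
  # scaling all areas by 10 adds exactly 1 on the log scale
  cm10 <- build_community(expected, dplyr::mutate(peaks, area = area * 10))
  expect_equal(otu_abundance(cm10)$abundance, ab$abundance + 1)
  expect_error(otu_abundance(cm, "OTUX"), "never")
})

test_that("presence is monotone non-decreasing in the matching tolerance", {
  st <- generate_study(tiny_config(seed = 5), sequences = FALSE)
  cms <- lapply(c(0.25, 0.5, 1, 2), function(tol) {
    build_community(st$expected, st$peaks, guilds = st$community$guilds,
                    tolerance = tol)$presence
  })
  for (k in seq_len(length(cms) - 1)) {
    expect_true(all(cms[[k + 1]] - cms[[k]] >= 0))
  }
})
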