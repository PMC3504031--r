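# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths they check.

ORACLE_IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_overlap <- function(x, y) {
  length(intersect(strsplit(ORACLE_IUPAC[[x]], "")[[1]],
                   strsplit(ORACLE_IUPAC[[y]], "")[[1]])) > 0L
}

# exhaustive position-by-position scan for IUPAC pattern matches (0-based)
oracle_find_sites <- function(sequence, pattern) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc)
  if (length(sc) < m) return(integer(0))
  ok <- rep(TRUE, length(sc) - m + 1L)
  for (j in seq_len(m)) {
    allowed <- names(ORACLE_IUPAC)[vapply(names(ORACLE_IUPAC), iupac_overlap,
                                          logical(1), y = pc[j])]
    ok <- ok & sc[seq_along(ok) + j - 1L] %in% allowed
  }
  which(ok) - 1L
}

# full Needleman-Wunsch: optimal score plus the identity fractions of every
# optimal-score alignment (enumerated by exhaustive traceback; tiny inputs)
oracle_nw_identities <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(-Inf, n + 1, m + 1)
  S[1, ] <- gap * (0:m); S[, 1] <- gap * (0:n)
  sub <- function(i, j) if (iupac_overlap(ca[i], cb[j])) match else mismatch
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + sub(i, j), S[i, j + 1] + gap,
                           S[i + 1, j] + gap)
  }
  idents <- new.env(); idents$set <- numeric(0)
  walk <- function(i, j, matches, cols) {
    if (i == 0 && j == 0) {
      idents$set <- union(idents$set, matches / cols)
      return(invisible())
    }
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + sub(i, j)) {
      walk(i - 1, j - 1, matches + (sub(i, j) == match), cols + 1)
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      walk(i - 1, j, matches, cols + 1)
    }
    if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] + gap) {
      walk(i, j - 1, matches, cols + 1)
    }
  }
  walk(n, m, 0, 0)
  list(score = S[n + 1, m + 1], identities = idents$set)
}

# connected components of the graph with edges d <= threshold
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (d[i, j] <= threshold && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Pearson correlation of off-diagonal entries, via explicit loops
oracle_mantel_r <- function(d1, d2) {
  n <- nrow(d1)
  x <- c(); y <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    x <- c(x, d1[i, j]); y <- c(y, d2[i, j])
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# exhaustive permutation distribution of the Mantel statistic (n = 4)
oracle_mantel_perms <- function(d1, d2) {
  perms <- rbind(
    expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  )
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  apply(perms, 1, function(p) {
    idx <- as.integer(p)
    oracle_mantel_r(d1, d2[idx, idx])
  })
}

# two-sided Fisher p by enumeration over all tables with the given margins,
# using explicit binomial-coefficient products
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- vapply(support, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# classic Holm step-down: which hypotheses are rejected at level alpha
oracle_holm_decisions <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  reject <- logical(n)
  for (k in seq_len(n)) {
    if (p[ord[k]] <= alpha / (n - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}

# small standard scenario used across tests
tiny_config <- function(seed = 1, ...) {
  scenario_config(
    n_hosts = 9, n_sites = 3, n_regions = 3, n_otus = 6, n_erm = 4,
    n_seqs = 12, erm_core = 2, nem_core = 1,
    nem_sat_prev = c(0.15, 0.3), n_bands = 30, n_group_bands = 15,
    seed = seed, ...
  )
}

random_distance_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    pts <- matrix(stats::rnorm(2 * n), n)
    as.matrix(stats::dist(pts))
  })
}
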