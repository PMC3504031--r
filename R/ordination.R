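#' Linear ordination of a community matrix
#'
#' Centred principal component analysis of the presence/absence matrix (the
#' linear, RDA-family ordination). Axis signs are fixed by the
#' largest-magnitude-loading-positive convention. An optional Hellinger
#' transformation is available for abundance-like inputs.
#'
#' @param x Samples x OTUs matrix (or a `trflp_community`).
#' @param n_axes Number of axes to retain (default 2).
#' @param hellinger Apply the Hellinger transformation first (default FALSE).
#' @return A `trflp_ordination` object: `scores` (samples x `n_axes`),
#'   `explained_variance`, `total_variance`.
#' @export
ordinate <- function(x, n_axes = 2, hellinger = FALSE) {
  if (inherits(x, "trflp_community")) x <- x$presence
  x <- as.matrix(x)
  if (nrow(x) < 3L || ncol(x) < 2L) abort("need at least 3 samples and 2 OTUs")
  if (hellinger) x <- sqrt(x / pmax(rowSums(x), 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank_x <- sum(pc$sdev > 1e-10)
  if (rank_x < n_axes) abort(sprintf("matrix rank %d < n_axes", rank_x))
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2, flip, `*`)[, seq_len(n_axes), drop = FALSE]
  structure(
    list(scores = scores, explained_variance = pc$sdev^2,
         total_variance = sum(pc$sdev^2), n_axes = n_axes),
    class = "trflp_ordination"
  )
}

#' @export
print.trflp_ordination <- function(x, ...) {
  pct <- 100 * x$explained_variance[seq_len(x$n_axes)] / x$total_variance
  cat(sprintf("<trflp_ordination> %d samples, %d axes (%s%% of variance)\n",
              nrow(x$scores), x$n_axes, paste(sprintf("%.1f", pct), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.trflp_ordination <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id")
}

# squared multiple correlation of v on the score columns, plus machinery for
# fast permutation: with Q an orthonormal basis of the centred scores,
# r2 = |Q'v|^2 / |v - mean|^2
envfit_r2_machinery <- function(scores) {
  sc <- scale(scores, center = TRUE, scale = FALSE)
  qr_sc <- qr(sc)
  qr.Q(qr_sc)[, seq_len(qr_sc$rank), drop = FALSE]
}

#' Fit one environmental vector onto ordination axes
#'
#' `r2` is the coefficient of determination of the least-squares regression
#' of the (centred) variable on the axis scores — the envfit vector-fitting
#' statistic. Its significance comes from permuting the variable across
#' samples: `p = (#{r2_perm >= r2_obs} + 1) / (n_perm + 1)`.
#'
#' @param ord A `trflp_ordination` (or a samples x axes score matrix).
#' @param variable Numeric vector, one value per sample.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Seed for the permutation draws.
#' @return Tibble with `r2` and `p_raw`.
#' @export
envfit_vector <- function(ord, variable, n_perm = 9999, seed = 1) {
  scores <- if (inherits(ord, "trflp_ordination")) ord$scores else as.matrix(ord)
  if (length(variable) != nrow(scores)) abort("variable length != sample count")
  if (stats::sd(variable) == 0) abort("constant variable")
  q_basis <- envfit_r2_machinery(scores)
  r2_of <- function(v) {
    vc <- v - mean(v)
    sum(crossprod(q_basis, vc)^2) / sum(vc^2)
  }
  r2_obs <- r2_of(variable)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) r2_of(sample(variable)), numeric(1))
  })
  tibble(r2 = r2_obs, p_raw = (sum(perm >= r2_obs - 1e-12) + 1) / (n_perm + 1))
}

#' Holm-Bonferroni step-down adjustment
#'
#' With raw p-values sorted ascending, the adjusted value at rank `j` is
#' `min(1, max_{i <= j} (N - i + 1) * p_(i))`, mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  n <- length(p)
  ord <- order(p)
  stepped <- cummax((n - seq_len(n) + 1) * p[ord])
  adj <- pmin(1, stepped)
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Envfit table across communities with Holm-Bonferroni correction
#'
#' Ordinats each community matrix and fits every factor column of the
#' environment table onto its first axes, with permutation p-values adjusted
#' by [holm_bonferroni()] within each community (N = number of factors).
#'
#' @param communities Named list of samples x OTUs matrices (or
#'   `trflp_community` objects); e.g. `list(ERM = ..., NEM = ..., host = ...)`
#'   where `host` may be the binary band matrix.
#' @param env Data frame with `sample_id` and one numeric column per factor.
#' @param factors Character vector of factor columns to fit; defaults to all
#'   numeric columns except `sample_id`.
#' @param n_perm Permutations per factor (default 9999).
#' @param seed Root seed; each community x factor combination gets its own
#'   derived stream.
#' @param n_axes Ordination axes fitted against (default 2).
#' @param alpha Significance level applied to adjusted p-values.
#' @return A `trflp_envfit` tibble: `community`, `factor`, `r2`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
envfit_table <- function(communities, env, factors = NULL, n_perm = 9999,
                         seed = 1, n_axes = 2, alpha = 0.05) {
  factors <- factors %||% setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                                  "sample_id")
  missing_cols <- setdiff(factors, names(env))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing factor column(s): %s", toString(missing_cols)))
  }
  out <- purrr::imap_dfr(communities, function(cm, cname) {
    ord <- ordinate(cm, n_axes = n_axes)
    res <- purrr::imap_dfr(stats::setNames(factors, factors), function(f, fi) {
      fit <- envfit_vector(
        ord, env[[f]], n_perm = n_perm,
        seed = derive_seed(seed, "ordination") + match(f, factors) * 131L +
          match(cname, names(communities)) * 17L
      )
      dplyr::mutate(fit, community = cname, factor = f, .before = 1)
    })
    dplyr::mutate(res, p_adj = holm_bonferroni(.data$p_raw),
                  significant = .data$p_adj < alpha)
  })
  class(out) <- c("trflp_envfit", class(out))
  out
}
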