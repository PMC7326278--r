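# Differential accessibility via an empirical-Bayes moderated t-test,
# DAP classification, PCA, K-means accessibility archetypes,
# accessibility-expression coupling, ECDF shifts, and the cell-detachment
# statistic.

#' Differential-accessibility configuration
#'
#' @param fc_threshold fold-change threshold (default 2: "FC > 2").
#' @param p_threshold raw p-value threshold (default 0.05). No
#'   multiple-testing correction is applied to DAP calls by default; set
#'   `adjust = "BH"` in [moderated_t_test()] for an optional corrected mode.
#' @param log_pseudocount pseudocount added before the log2 transform.
#' @return list of class `dap_config`.
#' @export
dap_config <- function(fc_threshold = 2, p_threshold = 0.05,
                       log_pseudocount = 1) {
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold < 1)
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 log_pseudocount = log_pseudocount), class = "dap_config")
}

# Newton solve of trigamma(y) = x (x > 0), as used for the prior df fit.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Empirical-Bayes prior (d0, s0_sq) for the variance ensemble, by matching
# moments of log(s2) to a scaled-F / log-chi-square model:
#   s2_g ~ s0_sq * F(df1, d0)
#   E log s2_g  = log s0_sq + [psi(df1/2) - log(df1/2)] - [psi(d0/2) - log(d0/2)]
#   Var log s2_g = psi'(df1/2) + psi'(d0/2)
# so with e_g = log s2_g - psi(df1/2) + log(df1/2):
#   trigamma(d0/2) = var(e) - trigamma(df1/2)
#   log s0_sq      = mean(e) + psi(d0/2) - log(d0/2)
# A non-positive excess variance (or a degenerate ensemble) gives d0 = Inf
# and s0_sq = the ensemble's (geometric-mean-based) variance.
fit_variance_prior <- function(s2, df1, d0_cap = 1e6) {
  pos <- s2[s2 > 0]
  if (length(pos) < 2L)
    return(list(d0 = Inf, s0_sq = if (length(pos)) exp(mean(log(pos)))
                else mean(s2)))
  e <- log(pos) - digamma(df1 / 2) + log(df1 / 2)
  evar <- stats::var(e) - trigamma(df1 / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  if (d0 > d0_cap) return(list(d0 = Inf, s0_sq = exp(mean(e))))
  list(d0 = d0, s0_sq = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated t-test for differential accessibility
#'
#' Per peak, on `x = log2(signal + pseudocount)`: group means and the pooled
#' residual variance `s2_g` with `d_g = n1 + n2 - 2` df; an empirical-Bayes
#' prior `(d0, s0_sq)` fitted to the ensemble of `s2_g` by closed-form
#' moment matching on `log s2` (see source); posterior variance
#' `(d0 s0_sq + d_g s2_g) / (d0 + d_g)`;
#' `t = (mean2 - mean1) / sqrt(post_var (1/n1 + 1/n2))`; two-sided p from a
#' t distribution with `d0 + d_g` df (Normal when `d0 = Inf`). With
#' `d0 = 0` forced, this is exactly the ordinary pooled two-sample t-test.
#'
#' @param mat peaks x samples signal matrix (normalized).
#' @param group1,group2 column names of the two sample groups (>= 2 each).
#' @param config a [dap_config()].
#' @param d0 optional override of the prior degrees of freedom (`0` disables
#'   moderation; `Inf` fully shrinks to the prior variance).
#' @param adjust `"none"` (default, raw p thresholds as in the DAP
#'   definition) or `"BH"`.
#' @return data.frame with `peak_id`, `log2fc` (group2 - group1), `s2`,
#'   `post_var`, `t_mod`, `p`, `status`, plus attributes `d0`, `s0_sq`.
#' @export
moderated_t_test <- function(mat, group1, group2, config = dap_config(),
                             d0 = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples for a residual variance")
  x <- log2(mat[, c(group1, group2), drop = FALSE] + config$log_pseudocount)
  x1 <- x[, group1, drop = FALSE]; x2 <- x[, group2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  dfree <- n1 + n2 - 2L
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dfree
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dfree)
  } else {
    prior <- list(d0 = d0,
                  s0_sq = if (d0 > 0) fit_variance_prior(s2, dfree)$s0_sq
                  else NA_real_)
  }
  post_var <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2))
  else if (prior$d0 == 0) s2
  else (prior$d0 * prior$s0_sq + dfree * s2) / (prior$d0 + dfree)
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  t_mod <- (m2 - m1) / se
  df_tot <- prior$d0 + dfree
  p <- if (is.finite(df_tot)) 2 * stats::pt(-abs(t_mod), df = df_tot)
  else 2 * stats::pnorm(-abs(t_mod))
  p[!is.finite(t_mod)] <- NA_real_
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  res <- data.frame(peak_id = rownames(mat), log2fc = m2 - m1, s2 = s2,
                    post_var = post_var, t_mod = t_mod, p = p,
                    stringsAsFactors = FALSE)
  res$status <- dap_status(res$log2fc, res$p, config)
  attr(res, "d0") <- prior$d0
  attr(res, "s0_sq") <- prior$s0_sq
  res
}

dap_status <- function(log2fc, p, config) {
  lfc <- log2(config$fc_threshold)
  ifelse(!is.na(p) & p < config$p_threshold & log2fc > lfc, "gained",
         ifelse(!is.na(p) & p < config$p_threshold & log2fc < -lfc, "lost",
                "unchanged"))
}

#' Classify differentially accessible peaks
#'
#' Applies the DAP thresholds (fold change > `fc_threshold` and
#' p < `p_threshold`) to a [moderated_t_test()] result.
#'
#' @param results a [moderated_t_test()] result.
#' @param config a [dap_config()].
#' @return list with `n_gained`, `n_lost`, and the per-peak `status` vector
#'   named by peak_id.
#' @export
classify_daps <- function(results, config = dap_config()) {
  status <- dap_status(results$log2fc, results$p, config)
  names(status) <- results$peak_id
  list(n_gained = sum(status == "gained"),
       n_lost = sum(status == "lost"),
       status = status)
}

#' PCA of a signal matrix
#'
#' Samples are the observations and peaks the features; every peak is
#' centered across samples and the decomposition is by SVD
#' (`stats::prcomp`, unscaled). PC signs follow the convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param mat peaks x samples signal matrix.
#' @return list with `scores` (samples x PCs), `variance_explained`
#'   (fractions summing to 1), and `loadings` (peaks x PCs).
#' @export
pca_signal <- function(mat) {
  if (ncol(mat) < 2L) stop("PCA needs >= 2 samples")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  list(scores = scores,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = loadings)
}

#' K-means accessibility archetypes
#'
#' Rows are z-scored across samples (zero-variance rows become zero
#' vectors) so clusters reflect the shape of the accessibility profile, not
#' its amplitude, and then clustered with `stats::kmeans` (10 random
#' restarts, up to 300 iterations), seeded for full determinism.
#'
#' @param mat peaks x samples signal matrix.
#' @param k number of clusters (default 4).
#' @param seed RNG seed.
#' @return list of class `cluster_result` with `labels` (named by peak_id),
#'   `centroids` (k x samples, on the z-score scale), `inertia`, `k`, `seed`.
#' @export
kmeans_cluster <- function(mat, k = 4L, seed = 1L) {
  if (k < 1L || k > nrow(mat)) stop("k must be in [1, nrow(mat)]")
  z <- zscore_rows(mat)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = 10L, iter.max = 300L)
  structure(list(labels = stats::setNames(km$cluster, rownames(mat)),
                 centroids = km$centers, inertia = km$tot.withinss,
                 k = k, seed = seed),
            class = "cluster_result")
}

zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  z <- (mat - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Correlate accessibility change with expression change
#'
#' Pairs per-peak accessibility log2 fold changes with the log2 fold change
#' of the peak's assigned (nearest) gene and reports the Pearson correlation
#' with its two-sided t-based p-value.
#'
#' @param peak_delta named numeric (peak_id -> accessibility log2fc).
#' @param gene_delta named numeric (gene_id -> expression log2fc).
#' @param peak_gene data.frame with `peak_id`, `gene_id` columns (e.g. from
#'   [annotate_peaks()]).
#' @return list with `r`, `p`, `n`.
#' @export
correlate_accessibility_expression <- function(peak_delta, gene_delta,
                                               peak_gene) {
  pg <- peak_gene[peak_gene$peak_id %in% names(peak_delta) &
                    peak_gene$gene_id %in% names(gene_delta), , drop = FALSE]
  x <- peak_delta[pg$peak_id]
  y <- gene_delta[pg$gene_id]
  if (length(x) < 3L) stop("fewer than 3 peak-gene pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a vector is constant")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' ECDF curves and KS shifts between sets of accessibility changes
#'
#' @param deltas_by_set named list of numeric vectors (e.g. log2 fold
#'   changes per condition); every set must be non-empty.
#' @return list with `ecdf` (named list of right-continuous ECDF functions)
#'   and `pairs`: a data.frame (set_a, set_b, D, p) with the two-sample
#'   Kolmogorov-Smirnov statistic and asymptotic p-value per pair.
#' @export
ecdf_shift <- function(deltas_by_set) {
  if (any(lengths(deltas_by_set) == 0L)) stop("empty set in ECDF comparison")
  fns <- lapply(deltas_by_set, stats::ecdf)
  nm <- names(deltas_by_set)
  pairs <- if (length(nm) >= 2L) utils::combn(nm, 2L) else
    matrix(character(), 2L, 0L)
  res <- data.frame(set_a = pairs[1L, ], set_b = pairs[2L, ],
                    D = numeric(ncol(pairs)), p = numeric(ncol(pairs)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    kt <- suppressWarnings(stats::ks.test(deltas_by_set[[pairs[1L, j]]],
                                          deltas_by_set[[pairs[2L, j]]],
                                          exact = FALSE))
    res$D[j] <- unname(kt$statistic)
    res$p[j] <- kt$p.value
  }
  list(ecdf = fns, pairs = res)
}

#' Detached-cell percentage
#'
#' `detached (%) = floating / (floating + adherent) * 100`.
#'
#' @param floating,adherent cell counts; their sum must be positive.
#' @return percentage in `[0, 100]`.
#' @export
detachment_percentage <- function(floating, adherent) {
  stopifnot(floating >= 0, adherent >= 0, floating + adherent > 0)
  floating / (floating + adherent) * 100
}
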