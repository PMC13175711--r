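#' Permutation null distribution of the synchrony index
#'
#' Each replicate independently permutes every taxon's abundance values
#' across years (without replacement) and recomputes the synchrony index.
#' The permutation leaves each taxon's multiset of values -- hence its
#' temporal variance, and the index denominator -- exactly unchanged, so the
#' null isolates the contribution of between-taxon covariation: it is the
#' distribution of the index for communities of randomly co-fluctuating
#' populations with the observed population-level variation.
#'
#' @param m numeric years x taxa matrix (>= 3 years).
#' @param n_reps number of null replicates (default 10000).
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of `n_reps` null synchrony values.
#' @export
si_null_distribution <- function(m, n_reps = 10000L, seed = NULL) {
  m <- as_site_year_matrix(m)
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_reps), function(r) {
    synchrony_index(permute_years_within_taxa(m))
  }, numeric(1))
}

# One null replicate: reorder each taxon's values across years, without
# replacement, independently per taxon. Each column keeps its exact
# multiset of values, hence its temporal variance.
permute_years_within_taxa <- function(m) {
  ny <- nrow(m)
  apply(m, 2, function(col) col[sample.int(ny)])
}

#' Classify an observed synchrony value against its null
#'
#' The central 95% quantile range (QR) of the null distribution is computed
#' with linearly interpolated order statistics (quantile type 7). Observed
#' values strictly below the lower bound are significant evidence of
#' negative covariation among populations; values strictly above the upper
#' bound, of positive covariation. Ties with a bound are not significant.
#'
#' @param observed observed synchrony index.
#' @param null_values numeric vector of null synchrony values.
#' @param level central quantile-range mass (default 0.95).
#' @return list with `classification` (one of `negative_covariation`,
#'   `positive_covariation`, `not_significant`), `null_quantile_low`,
#'   `null_quantile_high`, `n_reps`.
#' @export
classify_si <- function(observed, null_values, level = 0.95) {
  stopifnot(length(null_values) >= 1, level > 0, level < 1)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(null_values, c(alpha, 1 - alpha),
                        type = 7, names = FALSE)
  cls <- if (observed < qs[1]) {
    "negative_covariation"
  } else if (observed > qs[2]) {
    "positive_covariation"
  } else {
    "not_significant"
  }
  list(classification = cls,
       null_quantile_low = qs[1], null_quantile_high = qs[2],
       n_reps = length(null_values))
}

#' Observed synchrony plus permutation-null classification for one matrix
#'
#' Convenience composition of [synchrony_index()], [si_null_distribution()]
#' and [classify_si()].
#'
#' @inheritParams si_null_distribution
#' @inheritParams classify_si
#' @return list with `observed_si`, `null_quantile_low`,
#'   `null_quantile_high`, `classification`, `n_reps`.
#' @export
synchrony_test <- function(m, n_reps = 10000L, seed = NULL, level = 0.95) {
  obs <- synchrony_index(m)
  null_vals <- si_null_distribution(m, n_reps = n_reps, seed = seed)
  res <- classify_si(obs, null_vals, level = level)
  c(list(observed_si = obs), res)
}

# One-way within-subjects F decomposition on a balanced sites x years
# matrix: SS_total = SS_sites + SS_year + SS_error.
rm_f_stat <- function(x) {
  n_s <- nrow(x); n_y <- ncol(x)
  grand <- mean(x)
  ss_sites <- n_y * sum((rowMeans(x) - grand)^2)
  ss_year <- n_s * sum((colMeans(x) - grand)^2)
  ss_error <- sum((x - grand)^2) - ss_sites - ss_year
  ms_year <- ss_year / (n_y - 1)
  ms_error <- ss_error / ((n_y - 1) * (n_s - 1))
  if (ms_error <= 0) {
    if (ms_year <= 0) return(NaN)  # all-constant data: F undefined
    return(Inf)
  }
  ms_year / ms_error
}

#' Bootstrapped repeated-measures ANOVA
#'
#' Tests for differences in mean abundance between years with a one-way
#' within-subjects (repeated-measures) F-ratio, using a permutation null in
#' place of the parametric F distribution: abundance values are resampled
#' without replacement to randomly reassign year membership, and the
#' F-ratio recomputed, `n_reps` times. By default year labels are shuffled
#' within each site, preserving the repeated-measures blocking; the pooled
#' alternative shuffles all site-year values globally.
#'
#' @param totals numeric sites x years matrix of total cover (balanced,
#'   complete).
#' @param n_reps number of null replicates (default 10000).
#' @param seed optional RNG seed.
#' @param shuffle `"within_site"` (default) or `"global"`.
#' @return list with `f_observed`, `df_between`, `df_error`, `p_boot`,
#'   `n_reps`, `shuffle`.
#' @export
bootstrap_rm_anova <- function(totals, n_reps = 10000L, seed = NULL,
                               shuffle = c("within_site", "global")) {
  shuffle <- match.arg(shuffle)
  x <- as.matrix(totals)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 sites and >= 2 years")
  if (anyNA(x)) stop("balanced design required: no missing cells")
  if (!is.null(seed)) set.seed(seed)
  n_y <- ncol(x)
  f_obs <- rm_f_stat(x)
  if (is.nan(f_obs)) {
    return(list(f_observed = NA_real_, df_between = n_y - 1L,
                df_error = (n_y - 1L) * (nrow(x) - 1L),
                p_boot = 1, n_reps = as.integer(n_reps), shuffle = shuffle))
  }
  f_null <- vapply(seq_len(n_reps), function(r) {
    xp <- if (shuffle == "within_site") {
      t(apply(x, 1, function(row) row[sample.int(n_y)]))
    } else {
      matrix(sample(as.vector(x)), nrow = nrow(x))
    }
    rm_f_stat(xp)
  }, numeric(1))
  p <- (1 + sum(f_null >= f_obs, na.rm = TRUE)) / (n_reps + 1)
  list(f_observed = f_obs, df_between = n_y - 1L,
       df_error = (n_y - 1L) * (nrow(x) - 1L),
       p_boot = p, n_reps = as.integer(n_reps), shuffle = shuffle)
}

#' Bootstrap post hoc year differences
#'
#' For every pair of years, the observed difference of across-site mean
#' abundance is compared with a null distribution built by resampling group
#' assignments with replacement from the pooled values of the two years.
#' Two-sided p-values are raw (no multiple-testing correction), matching
#' reporting at a fixed alpha; apply `stats::p.adjust` downstream if
#' desired.
#'
#' @inheritParams bootstrap_rm_anova
#' @return data.frame with columns `year_a`, `year_b`, `difference`
#'   (mean_a - mean_b), `p_boot`.
#' @export
posthoc_year_differences <- function(totals, n_reps = 10000L, seed = NULL) {
  x <- as.matrix(totals)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 sites and >= 2 years")
  if (anyNA(x)) stop("balanced design required: no missing cells")
  if (!is.null(seed)) set.seed(seed)
  yrs <- colnames(x)
  if (is.null(yrs)) yrs <- as.character(seq_len(ncol(x)))
  pairs <- utils::combn(ncol(x), 2)
  n <- nrow(x)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- x[, pairs[1, p]]; b <- x[, pairs[2, p]]
    d_obs <- mean(a) - mean(b)
    pooled <- c(a, b)
    d_null <- vapply(seq_len(n_reps), function(r) {
      mean(sample(pooled, n, replace = TRUE)) -
        mean(sample(pooled, n, replace = TRUE))
    }, numeric(1))
    pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_reps + 1)
    data.frame(year_a = yrs[pairs[1, p]], year_b = yrs[pairs[2, p]],
               difference = d_obs, p_boot = pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact two-tailed binomial probability at p = 0.5
#'
#' Probability, under a fair binomial, of an outcome as or more extreme
#' than `k` successes in `n` trials, where "more extreme" is defined by
#' probability ordering (all outcomes no more probable than the observed
#' one are summed). At p = 0.5 this equals the doubled tail beyond
#' `max(k, n - k)`, capped at 1.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @return p-value in (0, 1].
#' @export
two_tailed_binomial_p <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  probs <- stats::dbinom(0:n, n, 0.5)
  p <- sum(probs[probs <= probs[k + 1] * (1 + 1e-9)])
  min(1, p)
}

#' Cross-site consistency of covariance signs
#'
#' Tests, for each taxon pair, whether the sign of temporal covariance is
#' consistent across sites more often than chance. A pair "occurs" at a
#' site when both taxa have positive temporal variance there (sign not
#' `"undefined"`); sites with exactly zero covariance count toward
#' occurrence but toward neither sign. Under the null, positive and
#' negative covariance are equally likely and independent across sites, so
#' the larger sign count is referred to an exact two-tailed binomial test
#' ([two_tailed_binomial_p()]) on the number of occupied sites.
#'
#' @param pair_table data.frame with columns `site`, `taxon_i`, `taxon_j`,
#'   `sign` -- typically [pairwise_covariances()] results stacked over
#'   sites.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default, raw p-values) or `"holm"`.
#' @return data.frame with one row per pair: `taxon_i`, `taxon_j`,
#'   `n_sites_present`, `n_positive`, `n_negative`, `p_binomial`,
#'   `significant`. Pairs occupying zero sites are omitted with a warning.
#' @export
covariance_sign_consistency <- function(pair_table, alpha = 0.05,
                                        adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("site", "taxon_i", "taxon_j", "sign") %in%
                  names(pair_table)))
  key <- paste(pair_table$taxon_i, pair_table$taxon_j, sep = " / ")
  out <- lapply(split(pair_table, key), function(g) {
    present <- g$sign != "undefined"
    n <- sum(present)
    if (n == 0) return(NULL)
    n_pos <- sum(g$sign == "+")
    n_neg <- sum(g$sign == "-")
    data.frame(taxon_i = g$taxon_i[1], taxon_j = g$taxon_j[1],
               n_sites_present = n, n_positive = n_pos, n_negative = n_neg,
               p_binomial = two_tailed_binomial_p(max(n_pos, n_neg), n),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d pair(s) occupied no sites and were omitted", dropped))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(res)
  rownames(res) <- NULL
  p <- if (adjust == "holm") stats::p.adjust(res$p_binomial, "holm") else
    res$p_binomial
  res$significant <- p < alpha
  res
}
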