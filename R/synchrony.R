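#' Community synchrony index
#'
#' Computes the synchrony index
#' \deqn{\varphi = \frac{\sum_{ij} v_{ij}}{\left(\sum_i \sqrt{v_{ii}}\right)^2}}
#' where \eqn{v} is the temporal covariance matrix of the taxa. The
#' numerator equals the temporal variance of total community abundance, so
#' \eqn{\varphi = 1} when populations fluctuate perfectly synchronously and
#' \eqn{\varphi = 0} when total abundance is constant (perfect asynchrony).
#'
#' Sample (n-1) normalization is used throughout; the index is invariant to
#' this choice as long as numerator and denominator agree. Zero-variance
#' taxa contribute zero to both sums and are retained, so taxon sets stay
#' comparable across sites.
#'
#' @param m numeric years x taxa matrix (>= 3 years).
#' @return synchrony index in \[0, 1\].
#' @export
synchrony_index <- function(m) {
  m <- as_site_year_matrix(m)
  v <- stats::cov(m)
  denom <- sum(sqrt(diag(v)))^2
  if (denom == 0) {
    stop("degenerate community: all taxa are temporally constant")
  }
  num <- sum(v)
  if (num <= 0) return(0)  # tiny negative values are rounding of zero
  min(num / denom, 1)
}

as_site_year_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need >= 3 years")
  if (ncol(m) < 1) stop("need >= 1 taxon")
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("values must be finite and non-negative")
  }
  m
}

#' Coefficient of variation and its inverse
#'
#' The CV (sd/mean, sample sd) measures temporal variability of an
#' abundance series; its inverse is the conventional stability measure
#' (larger = more stable). A constant series has CV 0 and an infinite
#' inverse, flagged explicitly.
#'
#' @param x numeric abundance series (>= 2 values, mean > 0).
#' @return list with `cv`, `inverse_cv`, and `zero_variance` flag.
#' @export
coefficient_of_variation <- function(x) {
  stopifnot(length(x) >= 2)
  mu <- mean(x)
  if (mu <= 0) stop("mean abundance must be positive")
  cv <- stats::sd(x) / mu
  list(cv = cv,
       inverse_cv = if (cv == 0) Inf else 1 / cv,
       zero_variance = cv == 0)
}

#' Pairwise temporal covariances and correlations
#'
#' One record per unordered taxon pair: the temporal covariance (same n-1
#' normalization as [synchrony_index()]), the Pearson correlation, and the
#' covariance sign. Pairs involving a zero-variance taxon get sign
#' `"undefined"` and `NA` correlation.
#'
#' @param m numeric years x taxa matrix (>= 3 years, >= 2 taxa).
#' @return data.frame with columns `taxon_i`, `taxon_j`, `covariance`,
#'   `pearson_r`, `sign`.
#' @export
pairwise_covariances <- function(m) {
  m <- as_site_year_matrix(m)
  if (ncol(m) < 2) stop("need >= 2 taxa for pairwise covariances")
  taxa <- colnames(m)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(m)))
  v <- stats::cov(m)
  sds <- sqrt(diag(v))
  idx <- utils::combn(ncol(m), 2)
  i <- idx[1, ]; j <- idx[2, ]
  covij <- v[cbind(i, j)]
  defined <- sds[i] > 0 & sds[j] > 0
  r <- ifelse(defined, covij / (sds[i] * sds[j]), NA_real_)
  sgn <- ifelse(!defined, "undefined",
                ifelse(covij > 0, "+", ifelse(covij < 0, "-", "0")))
  data.frame(taxon_i = taxa[i], taxon_j = taxa[j],
             covariance = covij, pearson_r = r, sign = sgn,
             stringsAsFactors = FALSE)
}

#' Per-taxon CV table for a series
#'
#' Convenience wrapper applying [coefficient_of_variation()] to every
#' (site, taxon) series with positive mean cover.
#'
#' @param series an `abundance_series`.
#' @return data.frame with columns `site`, `taxon`, `mean_cover`, `cv`,
#'   `inverse_cv`. Taxa with zero mean at a site are omitted (their CV is
#'   undefined).
#' @export
cv_table <- function(series) {
  validate_abundance(series)
  rows <- list()
  for (s in series_sites(series)) {
    m <- site_matrix(series, s)
    for (tx in colnames(m)) {
      x <- m[, tx]
      if (mean(x) <= 0) next
      cvr <- coefficient_of_variation(x)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, taxon = tx, mean_cover = mean(x),
        cv = cvr$cv, inverse_cv = cvr$inverse_cv,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
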