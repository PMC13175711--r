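#' Define a synthetic community scenario
#'
#' Parameterizes the generative model used to emulate a multi-site benthic
#' percent-cover monitoring design: lognormal cover fluctuations around
#' per-taxon baselines with configurable shared, independent, or
#' compensatory structure, an optional multi-year systematic decline (a
#' predator-outbreak stand-in), and multinomial point-intercept observation
#' noise.
#'
#' The default scenario mirrors a 15-site, 9-year (2013-2021), 12-taxon
#' fore-reef design: baselines sum to 30% coral cover, a decline with
#' per-year survival 0.72 starts in 2018 (cumulative ~0.52 after two
#' years), and plots are sampled with 2500 points (25 points/m2 over
#' 10 m x 10 m).
#'
#' @param n_sites number of sites (plots).
#' @param years integer survey years.
#' @param taxa named numeric vector of baseline mean percent cover per
#'   taxon; the remainder to 100 is implicit non-coral substrate.
#' @param dynamics_mode `"independent"`, `"common_forcing"`, or
#'   `"compensatory"`.
#' @param sigma_log standard deviation of log-cover fluctuations.
#' @param rho_shared loading of the shared site-year effect in \[0, 1\]
#'   (`common_forcing`), or target negative pairwise correlation in
#'   \[-1, 0) (`compensatory`; feasibility bound `>= -1/(k-1)` for k taxa).
#' @param decline `NULL`, or a list with `start_year` and `survival` (a
#'   scalar or per-taxon per-year survival multiplier, applied
#'   cumulatively from `start_year`).
#' @param n_points point-intercept samples per plot per year.
#' @param seed RNG seed.
#' @return a `community_scenario` list.
#' @export
community_scenario <- function(n_sites = 15L,
                               years = 2013:2021,
                               taxa = default_taxa(),
                               dynamics_mode = c("independent",
                                                 "common_forcing",
                                                 "compensatory"),
                               sigma_log = 0.3,
                               rho_shared = NULL,
                               decline = list(start_year = 2018L,
                                              survival = 0.72),
                               n_points = 2500L,
                               seed = NULL) {
  dynamics_mode <- match.arg(dynamics_mode)
  stopifnot(n_sites >= 1, length(years) >= 2, length(taxa) >= 1,
            !is.null(names(taxa)), all(taxa > 0), sigma_log >= 0,
            n_points >= 1)
  if (sum(taxa) > 100) stop("baseline covers must sum to <= 100")
  k <- length(taxa)
  if (dynamics_mode == "common_forcing") {
    if (is.null(rho_shared)) rho_shared <- 1
    stopifnot(rho_shared >= 0, rho_shared <= 1)
  }
  if (dynamics_mode == "compensatory") {
    if (is.null(rho_shared)) rho_shared <- -1 / (k - 1)
    if (rho_shared >= 0 || rho_shared < -1) {
      stop("compensatory rho_shared must lie in [-1, 0)")
    }
    if (rho_shared < -1 / (k - 1) - 1e-12) {
      stop(sprintf(
        "rho_shared = %.3f infeasible for %d taxa (bound -1/(k-1) = %.3f)",
        rho_shared, k, -1 / (k - 1)
      ))
    }
  }
  if (!is.null(decline)) {
    stopifnot(is.list(decline), !is.null(decline$start_year),
              !is.null(decline$survival), all(decline$survival > 0),
              all(decline$survival <= 1))
  }
  structure(
    list(n_sites = as.integer(n_sites), years = as.integer(years),
         taxa = taxa, dynamics_mode = dynamics_mode, sigma_log = sigma_log,
         rho_shared = rho_shared, decline = decline,
         n_points = as.integer(n_points), seed = seed),
    class = "community_scenario"
  )
}

#' Default focal-taxon baselines
#'
#' Twelve groups with baseline island-mean covers summing to 30 percent,
#' spanning the dominance gradient typical of fore-reef coral assemblages
#' (one dominant massive group, a long tail of sub-percent groups).
#'
#' @return named numeric vector of baseline percent covers.
#' @export
default_taxa <- function() {
  stats::setNames(
    c(8, 5, 4, 3, 2.5, 2, 1.5, 1.2, 1.0, 0.8, 0.6, 0.4),
    sprintf("group_%02d", 1:12)
  )
}

#' Simulate true (noise-free) percent cover
#'
#' Generative model on the log scale:
#' `log cover[s,t,i] = log baseline[i] + lambda[i] * u[s,t] + eps[s,t,i]`
#' with `u` a shared standard-normal site-year effect and `eps` mean-zero
#' Gaussian noise with standard deviation `sigma_log`. `independent` sets all `lambda = 0`
#' with independent `eps`; `common_forcing` sets `lambda = rho_shared` for
#' every taxon; `compensatory` draws `eps` jointly across taxa with
#' constant negative pairwise correlation `rho_shared`. An optional decline
#' multiplies cover by the survival multiplier cumulatively from its start
#' year. Covers are proportionally rescaled (with a message) only when a
#' site-year total exceeds 100.
#'
#' @param scenario a [community_scenario()].
#' @param seed RNG seed; defaults to the scenario's seed. Pass `NA` to use
#'   the current RNG state (used when composing with [vpi_sample()]).
#' @return an `abundance_series` of true cover.
#' @export
simulate_true_cover <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "community_scenario"))
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  S <- scenario$n_sites; yrs <- scenario$years; Tn <- length(yrs)
  taxa <- scenario$taxa; K <- length(taxa)
  sig <- scenario$sigma_log
  eps <- switch(scenario$dynamics_mode,
    compensatory = {
      R <- matrix(scenario$rho_shared, K, K); diag(R) <- 1
      e <- MASS::mvrnorm(S * Tn, mu = rep(0, K), Sigma = sig^2 * R,
                         tol = 1e-6)
      array(e, dim = c(S, Tn, K))
    },
    array(stats::rnorm(S * Tn * K, 0, sig), dim = c(S, Tn, K))
  )
  lam <- switch(scenario$dynamics_mode,
                common_forcing = scenario$rho_shared, 0)
  u <- matrix(stats::rnorm(S * Tn), S, Tn)  # unit-variance shared factor
  logc <- array(rep(log(taxa), each = S * Tn), dim = c(S, Tn, K)) +
    array(lam * u, dim = c(S, Tn, K)) + eps
  cov3 <- exp(logc)
  if (!is.null(scenario$decline)) {
    surv <- rep_len(scenario$decline$survival, K)
    after <- which(yrs >= scenario$decline$start_year)
    for (j in seq_along(after)) {
      cov3[, after[j], ] <- sweep(cov3[, after[j], , drop = FALSE],
                                  3, surv^j, "*")
    }
  }
  tot <- apply(cov3, c(1, 2), sum)
  over <- tot > 100
  if (any(over)) {
    message(sprintf("%d site-year total(s) exceeded 100; rescaled", sum(over)))
    scl <- ifelse(over, 100 / tot, 1)
    cov3 <- cov3 * array(scl, dim = dim(cov3))
  }
  dimnames(cov3) <- list(site = sprintf("site_%02d", seq_len(S)),
                         year = yrs, taxon = names(taxa))
  abundance_series(cov3)
}

#' Point-intercept observation sampling
#'
#' Emulates virtual point-intercept estimation of cover: for each site and
#' year, `n_points` point classifications are drawn from a multinomial with
#' probabilities `cover/100` per taxon plus the implicit remainder class,
#' and observed cover is `100 * counts / n_points`. Point placement is
#' treated as exchangeable (no spatial autocorrelation).
#'
#' @param true_series an `abundance_series` of true cover.
#' @param n_points points per plot per year (default 2500, i.e. 25
#'   points/m2 on a 10 m x 10 m plot).
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return an `abundance_series` of observed cover.
#' @export
vpi_sample <- function(true_series, n_points = 2500L, seed = NULL) {
  validate_abundance(true_series)
  if (!is.null(seed)) set.seed(seed)
  cov3 <- true_series$cover
  d <- dim(cov3)
  out <- cov3
  for (s in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      p <- cov3[s, y, ] / 100
      counts <- stats::rmultinom(1, n_points, c(p, 1 - sum(p)))
      out[s, y, ] <- 100 * counts[seq_len(d[3])] / n_points
    }
  }
  abundance_series(out, taxon_meta = true_series$taxon_meta)
}

#' Generate an observation-noise fixture from a scenario
#'
#' Composes [simulate_true_cover()] and [vpi_sample()] under a single seed,
#' yielding a series ready for the analysis pipeline; bit-identical across
#' runs for a fixed scenario seed.
#'
#' @param scenario a [community_scenario()].
#' @return an `abundance_series` of observed (point-sampled) cover.
#' @export
make_fixture <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  true <- simulate_true_cover(scenario, seed = NA)
  vpi_sample(true, n_points = scenario$n_points, seed = NULL)
}
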