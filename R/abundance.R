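#' Construct an abundance time series
#'
#' The central exchange object of the package: a dense site x year x taxon
#' array of percent cover (fraction of plot area, times 100), with optional
#' per-taxon metadata (life-history label, species-level flag) carried along
#' as pass-through annotation.
#'
#' @param cover numeric 3-d array with `dimnames` `site`, `year`, `taxon`.
#'   Years must be coercible to strictly increasing integers.
#' @param taxon_meta optional `data.frame` with a `taxon` column and any
#'   further metadata columns (e.g. `life_history`, `species_level`).
#' @return an object of class `abundance_series`.
#' @export
abundance_series <- function(cover, taxon_meta = NULL) {
  stopifnot(is.array(cover), length(dim(cover)) == 3L)
  dn <- dimnames(cover)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    stop("cover must have complete dimnames (site, year, taxon)")
  }
  names(dimnames(cover)) <- c("site", "year", "taxon")
  obj <- structure(
    list(cover = cover, taxon_meta = taxon_meta),
    class = "abundance_series"
  )
  validate_abundance(obj)
}

#' Validate an abundance series
#'
#' Checks the structural invariants: finite cover in \[0, 100\], strictly
#' increasing integer years, and per (site, year) total cover not exceeding
#' 100 (taxa are mutually exclusive substrate classes).
#'
#' @param series an `abundance_series`.
#' @return the series, invisibly usable, unchanged.
#' @export
validate_abundance <- function(series) {
  stopifnot(inherits(series, "abundance_series"))
  cov3 <- series$cover
  yrs <- series_years(series)
  if (anyNA(yrs) || any(diff(yrs) <= 0)) {
    stop("years must be strictly increasing integers")
  }
  if (any(!is.finite(cov3))) stop("cover contains non-finite values")
  if (any(cov3 < 0) || any(cov3 > 100)) {
    stop("cover values must lie in [0, 100]")
  }
  tot <- apply(cov3, c(1, 2), sum)
  if (any(tot > 100 + 1e-8)) {
    bad <- which(tot > 100 + 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "total cover exceeds 100 at site '%s', year %s",
      rownames(tot)[bad[1]], colnames(tot)[bad[2]]
    ))
  }
  series
}

series_sites <- function(series) dimnames(series$cover)$site
series_years <- function(series) as.integer(dimnames(series$cover)$year)
series_taxa <- function(series) dimnames(series$cover)$taxon

#' @export
print.abundance_series <- function(x, ...) {
  d <- dim(x$cover)
  cat(sprintf(
    "<abundance_series> %d sites x %d years (%s-%s) x %d taxa\n",
    d[1], d[2], min(series_years(x)), max(series_years(x)), d[3]
  ))
  invisible(x)
}

#' @export
as.data.frame.abundance_series <- function(x, ...) {
  long <- expand.grid(
    site = series_sites(x), year = series_years(x), taxon = series_taxa(x),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  long$cover <- as.vector(x$cover)
  long[order(long$site, long$year, long$taxon), , drop = FALSE]
}

#' Read a long-format abundance table
#'
#' Reads a delimited text file with columns `site`, `year`, `taxon`,
#' `cover` into a validated [abundance_series()]. Combinations absent from
#' the file are filled with zero cover (absence from a point sample is a
#' true zero under point-intercept sampling); one warning is emitted per
#' fill.
#'
#' @param path path to a CSV file (UTF-8).
#' @param percent_scale if `TRUE` (default) cover is on the canonical
#'   percent scale \[0, 100\]; if `FALSE`, proportions \[0, 1\] are accepted
#'   and rescaled to percent on ingest.
#' @param taxon_meta_path optional sidecar CSV with a `taxon` column.
#' @return an `abundance_series`.
#' @export
read_abundance_table <- function(path, percent_scale = TRUE,
                                 taxon_meta_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("site", "year", "taxon", "cover")
  if (!all(need %in% names(df))) {
    stop("input must have columns site, year, taxon, cover")
  }
  meta <- NULL
  if (!is.null(taxon_meta_path)) {
    meta <- utils::read.csv(taxon_meta_path, stringsAsFactors = FALSE)
    if (!"taxon" %in% names(meta)) stop("taxon metadata needs a 'taxon' column")
  }
  abundance_from_long(df, percent_scale = percent_scale, taxon_meta = meta)
}

#' Build an abundance series from a long data frame
#'
#' @param df data.frame with columns `site`, `year`, `taxon`, `cover`.
#' @inheritParams read_abundance_table
#' @param taxon_meta optional taxon metadata data.frame.
#' @export
abundance_from_long <- function(df, percent_scale = TRUE, taxon_meta = NULL) {
  key <- paste(df$site, df$year, df$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate record for site '%s', year %s, taxon '%s'",
                 dup$site, dup$year, dup$taxon))
  }
  hi <- if (percent_scale) 100 else 1
  if (any(!is.finite(df$cover)) || any(df$cover < 0) || any(df$cover > hi)) {
    stop(sprintf("cover values must lie in [0, %g]", hi))
  }
  if (!percent_scale) df$cover <- df$cover * 100
  sites <- sort(unique(as.character(df$site)))
  years <- sort(unique(as.integer(df$year)))
  taxa <- sort(unique(as.character(df$taxon)))
  n_missing <- length(sites) * length(years) * length(taxa) - nrow(df)
  if (n_missing > 0) {
    warning(sprintf(
      "%d missing (site, year, taxon) combination%s filled with 0 cover",
      n_missing, if (n_missing == 1) "" else "s"
    ))
  }
  cov3 <- array(0, dim = c(length(sites), length(years), length(taxa)),
                dimnames = list(site = sites, year = years, taxon = taxa))
  cov3[cbind(match(as.character(df$site), sites),
             match(as.integer(df$year), years),
             match(as.character(df$taxon), taxa))] <- df$cover
  abundance_series(cov3, taxon_meta = taxon_meta)
}

#' Write an abundance series as a long-format CSV
#'
#' Inverse of [read_abundance_table()]: `read(write(x))` is the identity on
#' validated series.
#'
#' @param series an `abundance_series`.
#' @param path output CSV path.
#' @export
write_abundance_table <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Define analysis phases
#'
#' A phase is an a priori, inclusive window of survey years; every analysis
#' is sliced by phase. Defaults follow a two-phase design: a pre-disturbance
#' window (2013-2017) and a post-predator-outbreak window (2018-2021).
#'
#' @param phases named list of `c(first_year, last_year)` integer pairs.
#' @return a `phase_config` data.frame with columns `name`, `first_year`,
#'   `last_year`.
#' @export
phase_config <- function(phases = list(phase1 = c(2013L, 2017L),
                                       phase2 = c(2018L, 2021L))) {
  stopifnot(length(phases) >= 1, !is.null(names(phases)))
  pc <- data.frame(
    name = names(phases),
    first_year = vapply(phases, function(p) as.integer(p[1]), integer(1)),
    last_year = vapply(phases, function(p) as.integer(p[2]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(pc$last_year - pc$first_year + 1L < 3L)) {
    stop("each phase must span at least 3 years")
  }
  pc <- pc[order(pc$first_year), , drop = FALSE]
  if (nrow(pc) > 1 && any(pc$first_year[-1] <= pc$last_year[-nrow(pc)])) {
    stop("phase windows must not overlap")
  }
  class(pc) <- c("phase_config", "data.frame")
  pc
}

#' Select focal groups
#'
#' A taxon is focal when its across-site (island) mean cover exceeds
#' `mean_cover_threshold` percent in at least one year, and it is present
#' (cover > 0 in at least one year) at `min_sites` or more sites. The
#' returned taxa are ordered by descending overall mean cover.
#'
#' @param series an `abundance_series`.
#' @param mean_cover_threshold island-mean percent-cover threshold
#'   (strictly exceeded in >= 1 year); default 0.5.
#' @param min_sites minimum number of sites of presence; default 4.
#' @return character vector of focal taxa (possibly empty, with a warning).
#' @export
select_focal_groups <- function(series, mean_cover_threshold = 0.5,
                                min_sites = 4L) {
  validate_abundance(series)
  island <- apply(series$cover, c(2, 3), mean)        # year x taxon
  hits_threshold <- apply(island, 2, function(v) any(v > mean_cover_threshold))
  present_at <- apply(series$cover, c(1, 3), function(v) any(v > 0))
  n_sites_present <- colSums(present_at)
  keep <- hits_threshold & n_sites_present >= min_sites
  taxa <- series_taxa(series)[keep]
  if (length(taxa) == 0) {
    warning("no taxa satisfy the focal-group criteria")
    return(character(0))
  }
  overall <- apply(series$cover[, , taxa, drop = FALSE], 3, mean)
  taxa[order(-overall)]
}

#' Subset an abundance series by taxa
#'
#' @param series an `abundance_series`.
#' @param taxa character vector of taxa to keep (order preserved).
#' @export
subset_taxa <- function(series, taxa) {
  stopifnot(all(taxa %in% series_taxa(series)))
  meta <- series$taxon_meta
  if (!is.null(meta)) meta <- meta[meta$taxon %in% taxa, , drop = FALSE]
  abundance_series(series$cover[, , taxa, drop = FALSE], taxon_meta = meta)
}

#' Slice an abundance series into phases
#'
#' @param series an `abundance_series`.
#' @param phases a [phase_config()].
#' @return named list of `abundance_series`, one per phase, each holding
#'   exactly the years inside its window; sites and taxa unchanged.
#' @export
split_phases <- function(series, phases = phase_config()) {
  validate_abundance(series)
  yrs <- series_years(series)
  out <- lapply(seq_len(nrow(phases)), function(i) {
    inside <- yrs >= phases$first_year[i] & yrs <= phases$last_year[i]
    if (sum(inside) < 3L) {
      stop(sprintf("phase '%s' (%d-%d) contains %d survey years; >= 3 required",
                   phases$name[i], phases$first_year[i], phases$last_year[i],
                   sum(inside)))
    }
    abundance_series(series$cover[, inside, , drop = FALSE],
                     taxon_meta = series$taxon_meta)
  })
  names(out) <- phases$name
  out
}

#' Collapse sites to the island mean
#'
#' Returns a one-site series whose cover is the unweighted arithmetic mean
#' over sites for each (year, taxon). Sites are weighted equally: plots are
#' equal-area sampling units.
#'
#' @param series an `abundance_series`.
#' @param site_name name for the synthetic aggregate site.
#' @export
island_mean_series <- function(series, site_name = "island_mean") {
  validate_abundance(series)
  m <- apply(series$cover, c(2, 3), mean)
  cov3 <- array(m, dim = c(1, dim(m)),
                dimnames = c(list(site = site_name), dimnames(m)))
  abundance_series(cov3, taxon_meta = series$taxon_meta)
}

#' Extract one site's years x taxa matrix
#'
#' The per-site matrix consumed by [synchrony_index()] and the resampling
#' procedures.
#'
#' @param series an `abundance_series`.
#' @param site site identifier.
#' @return numeric matrix, years in rows, taxa in columns.
#' @export
site_matrix <- function(series, site) {
  stopifnot(site %in% series_sites(series))
  m <- series$cover[site, , , drop = TRUE]
  if (is.null(dim(m))) {  # single taxon collapses to a vector
    m <- matrix(m, ncol = 1,
                dimnames = list(dimnames(series$cover)$year,
                                series_taxa(series)))
  }
  m
}

#' Site x year matrix of total community cover
#'
#' @param series an `abundance_series`.
#' @return numeric matrix, sites in rows, years in columns.
#' @export
total_cover_matrix <- function(series) {
  apply(series$cover, c(1, 2), sum)
}
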