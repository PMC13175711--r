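# Small in-code fixtures shared across test files.

# Dense series builder from a long specification.
toy_series <- function(sites, years, taxa, cover) {
  cov3 <- array(cover, dim = c(length(sites), length(years), length(taxa)),
                dimnames = list(site = sites, year = years, taxon = taxa))
  abundance_series(cov3)
}

# Random valid years x taxa matrix (positive, non-degenerate a.s.).
random_matrix <- function(n_years, n_taxa) {
  matrix(stats::rlnorm(n_years * n_taxa, meanlog = 1, sdlog = 0.5),
         nrow = n_years,
         dimnames = list(NULL, sprintf("t%02d", seq_len(n_taxa))))
}

# Long data.frame for a tiny 1-site, 2-year, 2-taxon table.
toy_long <- function() {
  data.frame(
    site = "A", year = rep(c(2013L, 2014L), each = 2),
    taxon = rep(c("x", "y"), 2),
    cover = c(10, 5, 12, 4),
    stringsAsFactors = FALSE
  )
}
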