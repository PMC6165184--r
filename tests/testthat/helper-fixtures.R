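# fixtures built in code for the unit tests

fixture_path <- function(f) exampleDataPath(f)

# a random but reproducible instrument set in the magnitude regime of
# the bundled tables
random_instruments <- function(n, seed, sdScale = 0.33) {
  set.seed(seed)
  data.frame(rsid = sprintf("rs%04d", seq_len(n)),
             beta_exp = runif(n, 0.02, 0.10),
             se_exp = runif(n, 0.002, 0.02),
             beta_out = rnorm(n, 0, 0.03),
             se_out = runif(n, 0.016, 0.022),
             stringsAsFactors = FALSE) |>
    InstrumentSet(exposureName = "random", sdScale = sdScale)
}

# minimal exposure/outcome association tables with full allele pairs
make_assoc <- function(rsid, ea, oa, eaf, beta, se, p = 1e-10,
                       role = "exposure", unit = NULL) {
  SnpAssociations(data.frame(rsid = rsid, effect_allele = ea,
                             other_allele = oa, eaf = eaf, beta = beta,
                             se = se, pvalue = p,
                             stringsAsFactors = FALSE),
                  role = role, unit = unit)
}

# independent weighted-median oracle: evaluate the interpolated
# weighted quantile function on a dense grid and pick the value whose
# standardized midpoint cumulative weight is closest to 1/2
grid_weighted_median <- function(r, w, grid_n = 1e6) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  grid <- seq(min(r), max(r), length.out = grid_n)
  sg <- approx(r, s, xout = grid, rule = 2, ties = "ordered")$y
  grid[which.min(abs(sg - 0.5))]
}
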