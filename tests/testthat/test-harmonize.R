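test_that("significance filtering uses a strict threshold and preserves order", {
  a <- make_assoc(c("rs1", "rs2", "rs3"), "A", "G", 0.3,
                  c(0.05, 0.04, 0.03), 0.005,
                  p = c(1e-10, 5e-8, 4.9e-8))
  f <- filterInstruments(a)
  # p exactly at the threshold is excluded
  expect_identical(rsids(f), c("rs1", "rs3"))
  # subset of the input, idempotent
  expect_identical(as.data.frame(filterInstruments(f)), as.data.frame(f))
  expect_true(all(rsids(f) %in% rsids(a)))
})

test_that("LD pruning keeps the smaller-p member of a correlated pair", {
  a <- make_assoc(c("rsA", "rsB"), "A", "G", 0.3, 0.05, 0.005,
                  p = c(1e-9, 1e-10))
  ld <- LdInfo(data.frame(rsid1 = "rsA", rsid2 = "rsB", r2 = 1.0))
  expect_identical(rsids(filterInstruments(a, ld = ld)), "rsB")

  # tie on p broken by smaller se, then rsid
  b <- make_assoc(c("rsA", "rsB"), "A", "G", 0.3, 0.05,
                  se = c(0.004, 0.005), p = 1e-10)
  expect_identical(rsids(filterInstruments(b, ld = ld)), "rsA")

  # the two CYP2R1 variants at r2 = 0.03 both survive the 0.05 cutoff
  vitd <- readSummaryTable(fixture_path("vitd_exposure.tsv"), "exposure")
  keep <- filterInstruments(vitd, ld = readLdPairs(fixture_path("ld_pairs.tsv")))
  expect_length(keep, 7L)
})

test_that("proxy substitution carries the proxy's record under the target rsid", {
  ad <- readSummaryTable(fixture_path("ad_outcome.tsv"), "outcome")
  pm <- readProxyMap(fixture_path("proxy_map.tsv"))
  sub <- substituteProxy(ad, pm, minR2 = 0.8)
  d <- as.data.frame(sub)
  i <- match("rs10745742", d$rsid)
  expect_equal(d$beta[i], -0.006)
  expect_equal(d$se[i], 0.016)
  expect_identical(d$proxied_by[i], "rs1968487")
  expect_false("rs1968487" %in% d$rsid)

  # identity on an empty map
  expect_identical(as.data.frame(substituteProxy(ad, pm[0, ])),
                   as.data.frame(ad))
  # refusal below minR2 and on a missing proxy
  expect_error(substituteProxy(ad, transform(pm, r2 = 0.5), minR2 = 0.8),
               "refused")
  expect_error(substituteProxy(ad, transform(pm, proxy_rsid = "rs0")),
               "absent from outcome")
})

test_that("SD-unit conversion scales beta and se, preserving the z-score", {
  vitd <- readSummaryTable(fixture_path("vitd_exposure.tsv"), "exposure")
  conv <- convertUnits(vitd, 0.33)
  d0 <- as.data.frame(vitd)
  d1 <- as.data.frame(conv)
  i <- match("rs117913124", d1$rsid)
  expect_equal(d1$beta[i], 0.430 * 0.33)  # 0.1419
  expect_equal(d1$se[i], 0.020 * 0.33)    # 0.0066
  expect_identical(d1$unit[i], "ln_trait")
  expect_equal(d1$beta[i] / d1$se[i], d0$beta[i] / d0$se[i])
  # other rows untouched
  j <- d1$rsid != "rs117913124"
  expect_identical(d1$beta[j], d0$beta[j])
  # second call has nothing to convert: warns and returns input
  expect_warning(again <- convertUnits(conv, 0.33), "no sd_of_ln_trait")
  expect_identical(as.data.frame(again), d1)
  # identity scale flips only the unit flag
  one <- suppressWarnings(convertUnits(vitd, 1))
  expect_identical(as.data.frame(convertUnits(vitd, 1))$beta[i], d0$beta[i])
})

test_that("orientation flip is an involution and never touches se", {
  a <- make_assoc(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                  c(0.2, 0.8), c(0.05, -0.03), c(0.004, 0.005))
  f <- flipOrientation(a)
  # involution up to floating point on eaf (1 - (1 - x))
  expect_equal(as.data.frame(flipOrientation(f)), as.data.frame(a))
  expect_identical(as.data.frame(f)$se, as.data.frame(a)$se)
  expect_equal(as.data.frame(f)$beta, -as.data.frame(a)$beta)
  expect_equal(as.data.frame(f)$eaf, 1 - as.data.frame(a)$eaf)
})

test_that("allele alignment follows the four-case truth table", {
  # exposure oriented A(effect)/G(other); all four outcome codings
  expo <- make_assoc("rs1", "A", "G", 0.3, 0.05, 0.004)
  cases <- list(
    list(ea = "A", oa = "G", sign = +1),  # same alleles
    list(ea = "G", oa = "A", sign = -1),  # swapped
    list(ea = "T", oa = "C", sign = +1),  # complement strand
    list(ea = "C", oa = "T", sign = -1))  # complement strand, swapped
  for (cs in cases) {
    out <- make_assoc("rs1", cs$ea, cs$oa, 0.4, 0.02, 0.01,
                      role = "outcome")
    h <- harmonize(expo, out)
    expect_equal(as.data.frame(h)$beta_out, cs$sign * 0.02,
                 info = paste(cs$ea, cs$oa))
  }
  # irreconcilable pair errors per SNP
  bad <- make_assoc("rs1", "A", "C", 0.4, 0.02, 0.01, role = "outcome")
  expect_error(harmonize(expo, bad), "irreconcilable")
})

test_that("exposure-decreasing alleles are re-oriented before alignment", {
  expo <- make_assoc("rs1", "A", "G", 0.3, -0.05, 0.004)
  out <- make_assoc("rs1", "A", "G", 0.3, 0.02, 0.01, role = "outcome")
  h <- harmonize(expo, out)
  d <- as.data.frame(h)
  expect_equal(d$beta_exp, 0.05)   # oriented to the increasing allele
  expect_equal(d$beta_out, -0.02)  # outcome follows the flip
  expect_equal(d$se_exp, 0.004)    # SEs untouched by orientation
  expect_true(all(as.data.frame(h)$beta_exp >= 0))
})

test_that("palindromic SNPs follow the chosen policy", {
  expo <- make_assoc("rs1", "A", "T", 0.2, 0.05, 0.004)
  out_same <- make_assoc("rs1", "A", "T", 0.25, 0.02, 0.01, role = "outcome")
  out_flip <- make_assoc("rs1", "A", "T", 0.75, 0.02, 0.01, role = "outcome")

  # drop excludes; a lone palindromic SNP leaves nothing
  expect_error(harmonize(expo, out_same, palindromePolicy = "drop"),
               "no instruments remain")
  # trust takes alleles at face value
  expect_equal(as.data.frame(harmonize(expo, out_same,
                                       palindromePolicy = "trust"))$beta_out,
               0.02)
  # eaf_infer: same side of 0.5 keeps the sign, opposite side flips it
  expect_equal(as.data.frame(harmonize(expo, out_same))$beta_out, 0.02)
  expect_equal(as.data.frame(harmonize(expo, out_flip))$beta_out, -0.02)
  # ambiguous frequency fails loudly
  out_mid <- make_assoc("rs1", "A", "T", 0.52, 0.02, 0.01, role = "outcome")
  expect_error(harmonize(expo, out_mid), "eaf too close to 0.5")
})

test_that("pre-oriented tables (no other allele) harmonize by trust", {
  pth <- readSummaryTable(fixture_path("pth_exposure.tsv"), "exposure")
  ad <- readSummaryTable(fixture_path("ad_outcome.tsv"), "outcome")
  h <- harmonize(pth, ad, exposureName = "S-PTH", sdScale = 0.33)
  d <- as.data.frame(h)
  expect_equal(d$beta_exp, c(0.07, 0.03, 0.04, 0.02, 0.03))
  expect_equal(d$beta_out, c(0.028, 0.012, 0.023, 0.005, -0.032))
  expect_true(all(d$beta_exp >= 0))
  # missing exposure rsids are a hard error naming them
  expect_error(harmonize(pth, ad[1:3]), "rs4443100")
})

test_that("harmonization refuses exposures still in SD units", {
  vitd <- readSummaryTable(fixture_path("vitd_exposure.tsv"), "exposure")
  ad <- readSummaryTable(fixture_path("ad_outcome.tsv"), "outcome")
  ad <- substituteProxy(ad, readProxyMap(fixture_path("proxy_map.tsv")))
  expect_error(harmonize(vitd, ad), "convertUnits")
  h <- harmonize(convertUnits(vitd, 0.33), ad, sdScale = 0.33)
  expect_length(h, 7L)
  expect_identical(as.data.frame(h)$proxied_by[rsids(h) == "rs10745742"],
                   "rs1968487")
})
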