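test_that("Wald ratios match direct arithmetic on the bundled PTH set", {
  pth <- exampleInstruments("pth")
  w <- waldRatio(pth, perSD = FALSE)
  est <- vapply(w, estimate, numeric(1))
  names(est) <- vapply(w, function(x) x@label, character(1))
  expect_equal(unname(est["rs6127099"]), 0.028 / 0.07)    # 0.40
  expect_equal(unname(est["rs73186030"]), -0.032 / 0.03)  # about -1.067
  # only one negative ratio in the set
  expect_identical(sum(est < 0), 1L)
  # beta_out = 0 gives estimate 0 with p = 1
  z <- InstrumentSet(data.frame(rsid = "rs1", beta_exp = 0.05,
                                se_exp = 0.004, beta_out = 0,
                                se_out = 0.02))
  expect_equal(estimate(waldRatio(z)[[1]]), 0)
  expect_equal(pvalue(waldRatio(z)[[1]]), 1)
  # zero exposure effect is an undefined ratio
  z@data$beta_exp <- 0
  expect_error(waldRatio(z), "rs1")
})

test_that("IVW agrees with a WLS-through-origin oracle to 1e-12 relative", {
  for (seed in c(11, 12, 13)) {
    x <- random_instruments(6, seed)
    d <- as.data.frame(x)
    fit <- lm(beta_out ~ 0 + beta_exp, data = d, weights = 1 / d$se_out^2)
    res <- mrIVW(x)
    expect_equal(estimate(res), coef(fit)[["beta_exp"]] * sdScale(x),
                 tolerance = 1e-12)
    # fixed-effect SE is the weight-sum form, not the residual-scaled one
    expect_equal(stdError(res),
                 sdScale(x) / sqrt(sum((d$beta_exp / d$se_out)^2)),
                 tolerance = 1e-12)
  }
})

test_that("single-instrument IVW degenerates to the rescaled Wald ratio", {
  x <- random_instruments(1, 21)
  expect_equal(estimate(mrIVW(x)), estimate(waldRatio(x, perSD = TRUE)[[1]]))
  expect_equal(stdError(mrIVW(x)), stdError(waldRatio(x, perSD = TRUE)[[1]]))
  expect_error(mrIVW(x, mode = "random_multiplicative"), "at least 2")
})

test_that("random-effects IVW inflates the SE by max(1, sqrt(Q/df))", {
  x <- random_instruments(8, 31)
  fixed <- mrIVW(x)
  rnd <- mrIVW(x, mode = "random_multiplicative")
  qr <- qStatistic(cochranQ(x))
  expect_equal(estimate(rnd), estimate(fixed))
  expect_equal(stdError(rnd),
               stdError(fixed) * max(1, sqrt(qr$q / qr$df)))
})

test_that("IVW is invariant to per-SNP sign flips; the Egger intercept is not", {
  x <- random_instruments(7, 41)
  flip <- as.data.frame(x)
  flip$beta_exp[3] <- -flip$beta_exp[3]
  flip$beta_out[3] <- -flip$beta_out[3]
  xf <- InstrumentSet(flip, sdScale = sdScale(x))
  expect_equal(estimate(mrIVW(xf)), estimate(mrIVW(x)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(estimate(mrEgger(xf)$intercept),
                                estimate(mrEgger(x)$intercept))))
})

test_that("adding an instrument at the pooled estimate shrinks the SE only", {
  x <- random_instruments(5, 51)
  theta <- estimate(mrIVW(x)) / sdScale(x)  # per ln-unit
  d <- rbind(as.data.frame(x),
             data.frame(rsid = "rs_new", beta_exp = 0.05, se_exp = 0.003,
                        beta_out = theta * 0.05, se_out = 0.02,
                        proxied_by = NA_character_))
  x2 <- InstrumentSet(d, sdScale = sdScale(x))
  expect_equal(estimate(mrIVW(x2)), estimate(mrIVW(x)), tolerance = 1e-12)
  expect_lt(stdError(mrIVW(x2)), stdError(mrIVW(x)))
})

test_that("weighted median matches the dense-grid quantile oracle", {
  for (seed in c(61, 62)) {
    x <- random_instruments(5, seed)
    d <- as.data.frame(x)
    r <- d$beta_out / d$beta_exp
    w <- (d$beta_exp / d$se_out)^2
    wm <- mrWeightedMedian(x, nBoot = 10)
    expect_equal(estimate(wm) / sdScale(x), grid_weighted_median(r, w),
                 tolerance = 1e-4)
  }
})

test_that("weighted median reduces to the interpolated unweighted median", {
  d <- data.frame(rsid = c("a", "b", "c"), beta_exp = 0.05, se_exp = 0.003,
                  beta_out = 0.05 * c(1, 2, 9), se_out = 0.02)
  x <- InstrumentSet(d, sdScale = 0.33)
  # equal weights: midpoint interpolation lands on the middle ratio
  expect_equal(estimate(mrWeightedMedian(x, nBoot = 5)), 2 * 0.33)
  # always within the ratio range
  y <- random_instruments(9, 71)
  ry <- as.data.frame(y)$beta_out / as.data.frame(y)$beta_exp
  est <- estimate(mrWeightedMedian(y, nBoot = 5)) / sdScale(y)
  expect_gte(est, min(ry))
  expect_lte(est, max(ry))
})

test_that("weighted-median bootstrap is deterministic given the seed", {
  x <- random_instruments(6, 81)
  a <- mrWeightedMedian(x, nBoot = 500, seed = 7L)
  b <- mrWeightedMedian(x, nBoot = 500, seed = 7L)
  expect_identical(stdError(a), stdError(b))
  c <- mrWeightedMedian(x, nBoot = 500, seed = 8L)
  expect_false(identical(stdError(a), stdError(c)))
  expect_error(mrWeightedMedian(x, nBoot = 0), "nBoot")
})

test_that("Egger matches a weighted normal-equations oracle to 1e-12 relative", {
  for (seed in c(91, 92)) {
    x <- random_instruments(7, seed)
    d <- as.data.frame(x)
    fit <- lm(beta_out ~ beta_exp, data = d, weights = 1 / d$se_out^2)
    eg <- mrEgger(x)
    expect_equal(estimate(eg$slope), coef(fit)[["beta_exp"]] * sdScale(x),
                 tolerance = 1e-12)
    expect_equal(estimate(eg$intercept), coef(fit)[["(Intercept)"]],
                 tolerance = 1e-12)
    # SEs: lm scales by the residual SD; ours floors that inflation at 1
    sm <- summary(fit)
    un_slope <- sm$coefficients["beta_exp", "Std. Error"] / sm$sigma
    un_int <- sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma
    expect_equal(stdError(eg$slope),
                 un_slope * max(1, sm$sigma) * sdScale(x),
                 tolerance = 1e-10)
    expect_equal(stdError(eg$intercept), un_int * max(1, sm$sigma),
                 tolerance = 1e-10)
  }
})

test_that("Egger on a perfect line through the origin finds a zero intercept", {
  d <- data.frame(rsid = sprintf("rs%d", 1:4),
                  beta_exp = c(0.02, 0.04, 0.06, 0.08), se_exp = 0.003,
                  beta_out = 0.5 * c(0.02, 0.04, 0.06, 0.08), se_out = 0.02)
  x <- InstrumentSet(d, sdScale = 0.33)
  eg <- mrEgger(x)
  expect_equal(estimate(eg$intercept), 0, tolerance = 1e-14)
  expect_equal(estimate(eg$slope), 0.5 * 0.33, tolerance = 1e-14)
  expect_error(mrEgger(x[1:2]), "at least 3")
  flat <- transform(d, beta_exp = 0.05)
  expect_error(mrEgger(InstrumentSet(flat)), "zero variance")
  # t-distribution option widens the interval at small n
  egt <- mrEgger(x, distribution = "t")
  expect_gt(estimate(egt$slope) - egt$slope@ciLow,
            estimate(eg$slope) - eg$slope@ciLow)
})

test_that("Cochran's Q matches term-by-term summation and detects homogeneity", {
  x <- random_instruments(8, 101)
  d <- as.data.frame(x)
  r <- d$beta_out / d$beta_exp
  w <- (d$beta_exp / d$se_out)^2
  q_oracle <- 0
  ivw <- sum(w * r) / sum(w)
  for (j in seq_along(r)) q_oracle <- q_oracle + w[j] * (r[j] - ivw)^2
  qr <- qStatistic(cochranQ(x))
  expect_equal(qr$q, q_oracle, tolerance = 1e-12)
  expect_identical(qr$df, 7L)
  # identical ratios: Q = 0, p = 1
  same <- data.frame(rsid = c("a", "b", "c"), beta_exp = c(0.02, 0.04, 0.08),
                     se_exp = 0.003, beta_out = 2 * c(0.02, 0.04, 0.08),
                     se_out = 0.02)
  qs <- qStatistic(cochranQ(InstrumentSet(same)))
  expect_equal(qs$q, 0)
  expect_equal(qs$pvalue, 1)
  # Q is dimensionless: unchanged by the SD scale
  y <- InstrumentSet(d, sdScale = 1)
  expect_equal(qStatistic(cochranQ(y))$q, qr$q)
})

test_that("rescaling per SD shifts estimate and CI but not z or p", {
  d <- as.data.frame(random_instruments(6, 111))
  a <- mrIVW(InstrumentSet(d, sdScale = 1))
  b <- mrIVW(InstrumentSet(d, sdScale = 0.33))
  expect_equal(estimate(b), estimate(a) * 0.33)
  expect_equal(stdError(b), stdError(a) * 0.33)
  expect_equal(unname(ci(b)), unname(ci(a)) * 0.33)
  expect_equal(pvalue(b), pvalue(a))
})

test_that("leave-one-out equals IVW on the explicit subsets", {
  vitd <- exampleInstruments("vitd")
  loo <- leaveOneOut(vitd)
  expect_length(loo, 7L)
  omit <- match("rs3755967", rsids(vitd))
  direct <- mrIVW(vitd[-omit])
  kept <- loo[[omit]]
  expect_identical(kept@label, "rs3755967")
  expect_equal(estimate(kept), estimate(direct))
  expect_equal(stdError(kept), stdError(direct))
  # three instruments give three two-SNP pools
  x3 <- random_instruments(3, 121)
  expect_length(leaveOneOut(x3), 3L)
  expect_identical(leaveOneOut(x3)[[1]]@nSnps, 2L)
  expect_error(leaveOneOut(random_instruments(2, 122)), "at least 3")
})

test_that("forest tables stack per-SNP rows then pooled rows", {
  pth <- exampleInstruments("pth")
  ft <- forestTable(pth, pooled = list(mrIVW(pth)))
  expect_identical(nrow(ft), 6L)
  expect_identical(ft$type, c(rep("snp", 5), "pooled"))

  vitd <- exampleInstruments("vitd")
  eg <- mrEgger(vitd)
  ft2 <- forestTable(vitd, pooled = list(mrIVW(vitd),
                                         mrWeightedMedian(vitd, nBoot = 10),
                                         eg$slope))
  expect_identical(nrow(ft2), 10L)
  # rs17216707 has the most negative per-SNP log-OR ratio in the set
  expect_lt(ft2$estimate[ft2$label == "rs17216707"], 0)
  expect_error(forestTable(pth, pooled = list()), "non-empty")
})
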