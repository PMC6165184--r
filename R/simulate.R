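#' Construct a SimulationSpec
#'
#' Defaults emulate the magnitudes of the bundled PTH/25OHD instrument
#' tables: around a dozen independent instruments with per-allele
#' exposure effects of 0.02-0.10 ln-units, exposure SEs of 0.002-0.02
#' and outcome (log-odds) SEs of 0.016-0.022, reported per 0.33
#' ln-units (one SD of the ln exposure).
#'
#' @param nSnps number of instruments, default 12.
#' @param theta true causal effect (log-OR per ln-unit), default 0.
#' @param gammaRange uniform range of true exposure effects.
#' @param pleiotropy "none" (default), "balanced" or "directional".
#' @param tau SD of per-SNP pleiotropic effects, default 0.
#' @param muAlpha mean pleiotropic effect (directional), default 0.
#' @param seExpRange,seOutRange uniform ranges for the SE draws.
#' @param sdScale ln-units per SD, default 0.33.
#' @param seed integer seed, default 1.
#' @return A \linkS4class{SimulationSpec}.
#' @export
SimulationSpec <- function(nSnps = 12L, theta = 0,
                           gammaRange = c(0.02, 0.10),
                           pleiotropy = c("none", "balanced", "directional"),
                           tau = 0, muAlpha = 0,
                           seExpRange = c(0.002, 0.02),
                           seOutRange = c(0.016, 0.022),
                           sdScale = 0.33, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  new("SimulationSpec", nSnps = as.integer(nSnps), theta = as.numeric(theta),
      gammaRange = as.numeric(gammaRange), pleiotropy = pleiotropy,
      tau = as.numeric(tau), muAlpha = as.numeric(muAlpha),
      seExpRange = as.numeric(seExpRange),
      seOutRange = as.numeric(seOutRange), sdScale = as.numeric(sdScale),
      seed = as.integer(seed))
}

#' Simulate two-sample summary statistics with known truth
#'
#' Draws, per SNP j: true exposure effect gamma_j ~
#' Uniform(gammaRange); pleiotropic outcome effect alpha_j = 0
#' ("none"), Normal(0, tau^2) ("balanced") or Normal(muAlpha, tau^2)
#' ("directional" — independent of gamma_j, satisfying InSIDE);
#' standard errors uniformly from their ranges; then observed
#' beta_exp_j ~ Normal(gamma_j, se_exp_j^2) and beta_out_j ~
#' Normal(theta gamma_j + alpha_j, se_out_j^2). Deterministic given
#' the spec's seed. Because beta_exp is observed with noise it can be
#' negative for weak instruments; alleles are exposure-increasing in
#' truth (gamma_j > 0), so no re-orientation is applied.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param ... unused.
#' @return list with \code{instruments} (an
#'   \linkS4class{InstrumentSet}) and \code{truth} (list with theta,
#'   gamma, alpha).
#' @rdname simulateInstruments
#' @export
setMethod("simulateInstruments", "SimulationSpec", function(spec, ...) {
  .with_seed(spec@seed, {
    n <- spec@nSnps
    gamma <- stats::runif(n, spec@gammaRange[1], spec@gammaRange[2])
    alpha <- switch(spec@pleiotropy,
                    none = rep(0, n),
                    balanced = stats::rnorm(n, 0, spec@tau),
                    directional = stats::rnorm(n, spec@muAlpha, spec@tau))
    se_exp <- stats::runif(n, spec@seExpRange[1], spec@seExpRange[2])
    se_out <- stats::runif(n, spec@seOutRange[1], spec@seOutRange[2])
    beta_exp <- stats::rnorm(n, gamma, se_exp)
    beta_out <- stats::rnorm(n, spec@theta * gamma + alpha, se_out)
    d <- data.frame(rsid = sprintf("sim%03d", seq_len(n)),
                    beta_exp = beta_exp, se_exp = se_exp,
                    beta_out = beta_out, se_out = se_out,
                    proxied_by = NA_character_, stringsAsFactors = FALSE)
    list(instruments = InstrumentSet(d, exposureName = "simulated",
                                     sdScale = spec@sdScale),
         truth = list(theta = spec@theta, gamma = gamma, alpha = alpha))
  })
})

#' Serialize a simulated InstrumentSet as summary-statistic tables
#'
#' Writes the exposure and outcome sides in the same delimited format
#' the readers accept, so simulated data round-trip through the full
#' input pipeline. Simulated SNPs carry synthetic alleles (effect A,
#' other G) and eaf 0.5 placeholders.
#'
#' @param x an \linkS4class{InstrumentSet}.
#' @param exposurePath,outcomePath output file paths.
#' @return invisibly, c(exposurePath, outcomePath).
#' @export
writeInstrumentTables <- function(x, exposurePath, outcomePath) {
  stopifnot(is(x, "InstrumentSet"))
  d <- x@data
  mk <- function(beta, se, role) {
    SnpAssociations(data.frame(rsid = d$rsid, effect_allele = "A",
                               other_allele = "G", eaf = 0.5, beta = beta,
                               se = se,
                               pvalue = 2 * stats::pnorm(-abs(beta / se)),
                               stringsAsFactors = FALSE),
                    role = role)
  }
  writeSummaryTable(mk(d$beta_exp, d$se_exp, "exposure"), exposurePath)
  writeSummaryTable(mk(d$beta_out, d$se_out, "outcome"), outcomePath)
  invisible(c(exposurePath, outcomePath))
}

#' Monte-Carlo performance of the estimators
#'
#' Runs \code{nReps} independent replicates of a
#' \linkS4class{SimulationSpec} (replicate seeds drawn once from the
#' spec's seed, making the whole table deterministic) and summarizes
#' each requested method against the true SD-scale effect
#' theta * sdScale: mean bias, empirical SD of the estimates, mean
#' estimated SE, empirical coverage of the 95\% CI, and rejection rate
#' at alpha = 0.05.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param nReps number of replicates, >= 1.
#' @param methods subset of c("ivw", "weighted_median", "egger",
#'   "egger_intercept").
#' @param nBoot bootstrap replicates for the weighted median per
#'   replicate, default 200 (SE quality, not point estimates, is all
#'   it affects here).
#' @param ... unused.
#' @return data.frame with one row per method: method, n_reps, bias,
#'   emp_sd, mean_se, coverage, rejection. For "egger_intercept" the
#'   reference value is muAlpha (the mean pleiotropic effect), on the
#'   per-allele log-OR scale.
#' @rdname runReplicates
#' @export
setMethod("runReplicates", "SimulationSpec",
          function(spec, nReps, methods = "ivw", nBoot = 200L, ...) {
  nReps <- as.integer(nReps)
  if (nReps < 1L) stop("nReps must be >= 1")
  known <- c("ivw", "weighted_median", "egger", "egger_intercept")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  seeds <- .with_seed(spec@seed,
                      sample.int(.Machine$integer.max - 1L, nReps))
  target <- spec@theta * spec@sdScale
  est <- se <- matrix(NA_real_, nReps, length(known),
                      dimnames = list(NULL, known))
  for (i in seq_len(nReps)) {
    rep_spec <- spec
    rep_spec@seed <- seeds[i]
    sim <- simulateInstruments(rep_spec)
    ins <- sim$instruments
    if ("ivw" %in% methods) {
      r <- mrIVW(ins)
      est[i, "ivw"] <- r@estimate; se[i, "ivw"] <- r@se
    }
    if ("weighted_median" %in% methods) {
      r <- mrWeightedMedian(ins, nBoot = nBoot, seed = seeds[i])
      est[i, "weighted_median"] <- r@estimate
      se[i, "weighted_median"] <- r@se
    }
    if (any(c("egger", "egger_intercept") %in% methods)) {
      r <- mrEgger(ins)
      est[i, "egger"] <- r$slope@estimate; se[i, "egger"] <- r$slope@se
      est[i, "egger_intercept"] <- r$intercept@estimate
      se[i, "egger_intercept"] <- r$intercept@se
    }
  }
  zq <- stats::qnorm(0.975)
  do.call(rbind, lapply(methods, function(m) {
    ref <- if (m == "egger_intercept") spec@muAlpha else target
    e <- est[, m]; s <- se[, m]
    data.frame(method = m, n_reps = nReps, bias = mean(e - ref),
               emp_sd = stats::sd(e), mean_se = mean(s),
               coverage = mean(e - zq * s <= ref & ref <= e + zq * s),
               rejection = mean(abs(e / s) > zq),
               stringsAsFactors = FALSE)
  }))
})
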