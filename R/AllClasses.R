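#' @import methods
NULL

.ASSOC_COLS <- c("rsid", "chrom", "nearby_gene", "effect_allele",
                 "other_allele", "eaf", "beta", "se", "pvalue", "unit",
                 "proxied_by")

.UNITS <- c("ln_trait", "sd_of_ln_trait", "log_odds")

#' SnpAssociations: per-SNP summary statistics for one trait
#'
#' A validated container for one GWAS's per-SNP summary statistics:
#' one row per variant with effect allele, optional other allele and
#' effect-allele frequency, signed effect size \code{beta}, its standard
#' error and p-value, and a unit flag. The unit is \code{"ln_trait"}
#' (per-allele effect on the natural-log-transformed trait),
#' \code{"sd_of_ln_trait"} (effect in standard deviations of the
#' standardized log trait; exposure only, convert before harmonizing),
#' or \code{"log_odds"} (case-control log odds ratio; outcome only).
#'
#' Missing \code{other_allele} or \code{eaf} are representable (many
#' published instrument tables omit them) and only block operations
#' that need them, such as strand-aware harmonization. A p-value of 0
#' is admitted as the parse of a value below double precision (e.g.
#' 4.74e-343).
#'
#' @slot data data.frame with columns rsid, chrom, nearby_gene,
#'   effect_allele, other_allele, eaf, beta, se, pvalue, unit,
#'   proxied_by.
#' @slot role "exposure" or "outcome".
#' @export
setClass("SnpAssociations",
         representation(data = "data.frame", role = "character"))

setValidity("SnpAssociations", function(object) {
  d <- object@data
  msgs <- character()
  if (!identical(names(d), .ASSOC_COLS))
    return(paste("data columns must be exactly:",
                 paste(.ASSOC_COLS, collapse = ", ")))
  if (length(object@role) != 1L || !object@role %in% c("exposure", "outcome"))
    msgs <- c(msgs, "role must be 'exposure' or 'outcome'")
  if (anyDuplicated(d$rsid))
    msgs <- c(msgs, sprintf("duplicate rsid: %s",
                            paste(unique(d$rsid[duplicated(d$rsid)]),
                                  collapse = ", ")))
  if (nrow(d)) {
    if (any(is.na(d$beta)) || any(is.na(d$se)))
      msgs <- c(msgs, "beta and se must be present for every row")
    if (any(!is.na(d$se) & d$se <= 0))
      msgs <- c(msgs, "se must be > 0")
    bad_eaf <- !is.na(d$eaf) & (d$eaf <= 0 | d$eaf >= 1)
    if (any(bad_eaf))
      msgs <- c(msgs, sprintf("eaf outside (0,1) for %s",
                              paste(d$rsid[bad_eaf], collapse = ", ")))
    bad_p <- !is.na(d$pvalue) & (d$pvalue < 0 | d$pvalue > 1)
    if (any(bad_p))
      msgs <- c(msgs, "pvalue must lie in [0,1]")
    if (any(!d$unit %in% .UNITS))
      msgs <- c(msgs, sprintf("unit must be one of %s",
                              paste(.UNITS, collapse = ", ")))
    if (identical(object@role, "exposure") && any(d$unit == "log_odds"))
      msgs <- c(msgs, "unit 'log_odds' is only valid for outcome associations")
    if (identical(object@role, "outcome") && any(d$unit == "sd_of_ln_trait"))
      msgs <- c(msgs, "unit 'sd_of_ln_trait' is only valid for exposure associations")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' InstrumentSet: harmonized instruments for one exposure
#'
#' Exposure and outcome effects aligned per SNP to a common (exposure-
#' increasing) allele, with the exposure's SD scale attached so pooled
#' estimates can be reported per standard deviation of the
#' ln-transformed exposure.
#'
#' @slot exposureName character label for the exposure trait.
#' @slot sdScale SD of the ln-transformed exposure, in ln-units per SD.
#' @slot data data.frame with columns rsid, beta_exp, se_exp, beta_out,
#'   se_out, proxied_by.
#' @export
setClass("InstrumentSet",
         representation(exposureName = "character", sdScale = "numeric",
                        data = "data.frame"))

setValidity("InstrumentSet", function(object) {
  d <- object@data
  msgs <- character()
  need <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out", "proxied_by")
  if (!identical(names(d), need))
    return(paste("data columns must be exactly:", paste(need, collapse = ", ")))
  if (length(object@sdScale) != 1L || is.na(object@sdScale) ||
      object@sdScale <= 0)
    msgs <- c(msgs, "sdScale must be a single positive number")
  if (nrow(d) < 1L)
    msgs <- c(msgs, "at least one instrument is required")
  if (anyDuplicated(d$rsid))
    msgs <- c(msgs, "instrument rsids must be unique")
  if (nrow(d) && (any(d$se_exp <= 0) || any(d$se_out <= 0)))
    msgs <- c(msgs, "se_exp and se_out must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MrResult: one method's causal estimate
#'
#' The estimate is a log odds ratio per SD of the ln-transformed
#' exposure (per ln-unit for the Egger intercept, which is a log-OR
#' offset and is never rescaled). Confidence bounds and the two-sided
#' p-value are on the same scale; \code{\link{or}} and \code{\link{orCI}}
#' exponentiate.
#'
#' @slot method one of "wald", "ivw_fixed", "ivw_random",
#'   "weighted_median", "egger_slope", "egger_intercept".
#' @slot estimate,se,ciLow,ciHigh,pvalue numeric scalars.
#' @slot level confidence level (default 0.95).
#' @slot nSnps number of instruments used.
#' @slot label free-text label (rsid for per-SNP or leave-one-out rows).
#' @slot metadata list of method details (seed, nBoot, mode, ...).
#' @export
setClass("MrResult",
         representation(method = "character", estimate = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pvalue = "numeric", level = "numeric",
                        nSnps = "integer", label = "character",
                        metadata = "list"))

setValidity("MrResult", function(object) {
  msgs <- character()
  ok_m <- c("wald", "ivw_fixed", "ivw_random", "weighted_median",
            "egger_slope", "egger_intercept")
  if (!object@method %in% ok_m)
    msgs <- c(msgs, sprintf("method must be one of %s",
                            paste(ok_m, collapse = ", ")))
  if (!is.na(object@se) && object@se < 0)
    msgs <- c(msgs, "se must be >= 0")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@estimate && object@estimate <= object@ciHigh))
    msgs <- c(msgs, "ciLow <= estimate <= ciHigh must hold")
  if (object@level <= 0 || object@level >= 1)
    msgs <- c(msgs, "level must lie in (0,1)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' HeterogeneityResult: Cochran's Q for an instrument set
#'
#' @slot q Q statistic (weighted sum of squared ratio deviations).
#' @slot df degrees of freedom, n_snps - 1.
#' @slot pvalue upper-tail chi-square probability.
#' @export
setClass("HeterogeneityResult",
         representation(q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  msgs <- character()
  if (object@q < 0) msgs <- c(msgs, "q must be >= 0")
  if (object@df < 1L) msgs <- c(msgs, "df must be >= 1")
  if (object@pvalue <= 0 || object@pvalue > 1)
    msgs <- c(msgs, "pvalue must lie in (0,1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' LdInfo: pairwise linkage disequilibrium
#'
#' Symmetric store of r-squared values for unordered rsid pairs; pairs
#' not listed are treated as independent (r2 = 0).
#'
#' @slot pairs data.frame with columns rsid1, rsid2, r2.
#' @export
setClass("LdInfo", representation(pairs = "data.frame"))

setValidity("LdInfo", function(object) {
  p <- object@pairs
  if (!identical(names(p), c("rsid1", "rsid2", "r2")))
    return("pairs must have columns rsid1, rsid2, r2")
  if (nrow(p) && (any(p$r2 < 0) || any(p$r2 > 1)))
    return("r2 must lie in [0,1]")
  TRUE
})

#' SimulationSpec: generative model for synthetic summary statistics
#'
#' Describes a two-sample summary-statistic experiment with J
#' independent instruments: true per-allele exposure effects gamma_j
#' drawn uniformly from \code{gammaRange}, optional per-SNP pleiotropic
#' outcome effects alpha_j (none; balanced, Normal(0, tau^2);
#' directional, Normal(muAlpha, tau^2) — independent of gamma_j, so the
#' InSIDE condition holds), and observed effects
#' beta_exp ~ N(gamma_j, se_exp^2), beta_out ~ N(theta gamma_j +
#' alpha_j, se_out^2) with standard errors drawn uniformly from
#' \code{seExpRange} / \code{seOutRange}. Defaults mimic the magnitudes
#' of the bundled PTH / 25OHD instrument tables.
#'
#' @slot nSnps number of instruments.
#' @slot theta true causal effect, log-OR per ln-unit of exposure.
#' @slot gammaRange range of true exposure effects (uniform draw).
#' @slot pleiotropy "none", "balanced" or "directional".
#' @slot tau pleiotropy scale (SD of alpha_j), >= 0.
#' @slot muAlpha mean pleiotropic effect (directional only).
#' @slot seExpRange,seOutRange ranges for the uniform SE draws.
#' @slot sdScale ln-units per SD of the exposure.
#' @slot seed integer seed making the draw deterministic.
#' @export
setClass("SimulationSpec",
         representation(nSnps = "integer", theta = "numeric",
                        gammaRange = "numeric", pleiotropy = "character",
                        tau = "numeric", muAlpha = "numeric",
                        seExpRange = "numeric", seOutRange = "numeric",
                        sdScale = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msgs <- character()
  if (object@nSnps < 1L) msgs <- c(msgs, "nSnps must be >= 1")
  if (!object@pleiotropy %in% c("none", "balanced", "directional"))
    msgs <- c(msgs, "pleiotropy must be none, balanced or directional")
  if (object@tau < 0) msgs <- c(msgs, "tau must be >= 0")
  rng_ok <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  if (!rng_ok(object@gammaRange)) msgs <- c(msgs, "gammaRange must be c(lo, hi)")
  if (!rng_ok(object@seExpRange) || object@seExpRange[1] <= 0)
    msgs <- c(msgs, "seExpRange must be positive c(lo, hi)")
  if (!rng_ok(object@seOutRange) || object@seOutRange[1] <= 0)
    msgs <- c(msgs, "seOutRange must be positive c(lo, hi)")
  if (object@sdScale <= 0) msgs <- c(msgs, "sdScale must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
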