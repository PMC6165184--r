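## Per-SNP ratio estimates and inverse-variance weights shared by the
## pooled estimators: r_j = beta_out/beta_exp, w_j = (beta_exp/se_out)^2.
## The first-order delta-method ratio SE (se_out/|beta_exp|, ignoring
## se_exp) makes w_j exactly the inverse ratio variance.
.ratios <- function(x) {
  d <- x@data
  if (any(d$beta_exp == 0))
    stop("beta_exp is zero for ", paste(d$rsid[d$beta_exp == 0],
                                        collapse = ", "),
         "; Wald ratio undefined")
  list(r = d$beta_out / d$beta_exp, w = (d$beta_exp / d$se_out)^2,
       se = d$se_out / abs(d$beta_exp), rsid = d$rsid)
}

## rescale a log-OR-per-ln-unit estimate per SD of the ln exposure
.per_sd <- function(est, se, sdScale) list(est = est * sdScale,
                                           se = se * sdScale)

#' Per-SNP Wald ratio estimates
#'
#' The ratio beta_out / beta_exp estimates the causal log odds ratio
#' per ln-unit of exposure from a single instrument; its first-order
#' delta-method standard error is se_out / |beta_exp|. With
#' \code{perSD = TRUE} (default) estimate and SE are multiplied by the
#' set's SD scale to report per SD of the ln-transformed exposure.
#'
#' @param x an \linkS4class{InstrumentSet}.
#' @param perSD rescale per SD of the ln exposure? Default TRUE.
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return list of \linkS4class{MrResult}, one per SNP, labeled by rsid.
#' @rdname waldRatio
#' @export
setMethod("waldRatio", "InstrumentSet",
          function(x, perSD = TRUE, level = 0.95, ...) {
  rt <- .ratios(x)
  scale <- if (perSD) x@sdScale else 1
  lapply(seq_along(rt$r), function(j) {
    .mrResult("wald", rt$r[j] * scale, rt$se[j] * scale, level = level,
              nSnps = 1L, label = rt$rsid[j])
  })
})

#' Inverse-variance weighted causal estimate
#'
#' Pools the per-SNP Wald ratios r_j with weights w_j =
#' (beta_exp_j/se_out_j)^2: estimate = sum(w r)/sum(w), which equals
#' the weighted least-squares slope of beta_out on beta_exp through
#' the origin. Fixed-effect SE is 1/sqrt(sum(w));
#' \code{"random_multiplicative"} inflates it by max(1, sqrt(Q/df)).
#' The log-scale estimate and SE are then multiplied by the set's SD
#' scale so the result is a log OR per SD of the ln-transformed
#' exposure; inference is z-based.
#'
#' @param x an \linkS4class{InstrumentSet}.
#' @param mode "fixed" (default) or "random_multiplicative".
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return An \linkS4class{MrResult}.
#' @examples
#' pth <- exampleInstruments("pth")
#' or(mrIVW(pth))   # 1.11
#' @rdname mrIVW
#' @export
setMethod("mrIVW", "InstrumentSet",
          function(x, mode = c("fixed", "random_multiplicative"),
                   level = 0.95, ...) {
  mode <- match.arg(mode)
  rt <- .ratios(x)
  n <- length(rt$r)
  if (mode == "random_multiplicative" && n < 2L)
    stop("random_multiplicative mode needs at least 2 instruments")
  est <- sum(rt$w * rt$r) / sum(rt$w)
  se <- 1 / sqrt(sum(rt$w))
  method <- "ivw_fixed"
  if (mode == "random_multiplicative") {
    q <- sum(rt$w * (rt$r - est)^2)
    se <- se * max(1, sqrt(q / (n - 1L)))
    method <- "ivw_random"
  }
  sc <- .per_sd(est, se, x@sdScale)
  .mrResult(method, sc$est, sc$se, level = level, nSnps = n,
            metadata = list(mode = mode, sd_scale = x@sdScale))
})

## Interpolated weighted median of ratios r with weights w: sort r,
## form standardized midpoint cumulative weights s_j =
## (cum_j - w_j/2)/sum(w), linearly interpolate r at s = 0.5.
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(s)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The midpoint-interpolated weighted median of the per-SNP Wald
#' ratios, consistent when valid instruments carry at least half the
#' total weight. The SE comes from a parametric bootstrap: beta_exp
#' and beta_out are resampled independently from Normal(beta,
#' se^2) per SNP, the weighted median recomputed per replicate, and
#' the SE taken as the SD over replicates (deterministic given
#' \code{seed}). Normal-theory CI and p from the point estimate and
#' bootstrap SE; the result is rescaled per SD of the ln exposure.
#'
#' @param x an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param nBoot bootstrap replicates, default 10000.
#' @param seed integer seed, default 20180906.
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return An \linkS4class{MrResult} with seed and nBoot in metadata.
#' @rdname mrWeightedMedian
#' @export
setMethod("mrWeightedMedian", "InstrumentSet",
          function(x, nBoot = 10000L, seed = 20180906L, level = 0.95, ...) {
  if (nrow(x@data) < 3L) stop("weighted median needs at least 3 instruments")
  if (nBoot < 1L) stop("nBoot must be >= 1")
  rt <- .ratios(x)
  if (all(rt$w == 0)) stop("all weights are zero")
  est <- .weighted_median(rt$r, rt$w)
  d <- x@data
  n <- nrow(d)
  boots <- .with_seed(as.integer(seed), {
    vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(n, d$beta_exp, d$se_exp)
      by <- stats::rnorm(n, d$beta_out, d$se_out)
      .weighted_median(by / bx, (bx / d$se_out)^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  sc <- .per_sd(est, se, x@sdScale)
  .mrResult("weighted_median", sc$est, sc$se, level = level, nSnps = n,
            metadata = list(seed = as.integer(seed),
                            n_boot = as.integer(nBoot),
                            sd_scale = x@sdScale))
})

#' MR-Egger regression
#'
#' Weighted linear regression of beta_out on beta_exp with weights
#' 1/se_out^2 and a free intercept, fitted by explicit weighted
#' normal equations. The slope estimates the causal effect under the
#' InSIDE condition and is rescaled per SD of the ln exposure; the
#' intercept estimates the average directional pleiotropic effect, a
#' log-OR offset per allele, and is never rescaled. Coefficient SEs
#' are the weighted least-squares SEs inflated by max(1, s) where s^2
#' is the weighted residual mean square on n - 2 df. Inference is
#' normal-theory by default; \code{distribution = "t"} uses t with
#' n - 2 df.
#'
#' Instruments must be oriented to the exposure-increasing allele
#' (beta_exp > 0) upstream: unlike IVW, the intercept is not invariant
#' to per-SNP sign flips.
#'
#' @param x an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param distribution "normal" (default) or "t".
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return list with elements \code{slope} and \code{intercept}, both
#'   \linkS4class{MrResult}.
#' @rdname mrEgger
#' @export
setMethod("mrEgger", "InstrumentSet",
          function(x, distribution = c("normal", "t"), level = 0.95, ...) {
  distribution <- match.arg(distribution)
  d <- x@data
  n <- nrow(d)
  if (n < 3L) stop("MR-Egger needs at least 3 instruments")
  bx <- d$beta_exp; by <- d$beta_out; w <- 1 / d$se_out^2
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  det <- sw * swx2 - swx^2
  if (det <= .Machine$double.eps * sw * swx2)
    stop("beta_exp has (weighted) zero variance; Egger slope not identifiable")
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swx2 * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  s2 <- sum(w * resid^2) / (n - 2L)
  infl <- max(1, sqrt(s2))
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(swx2 / det) * infl
  pfun <- function(est, se) {
    if (distribution == "t") {
      q <- stats::qt(1 - (1 - level) / 2, df = n - 2L)
      p <- 2 * stats::pt(-abs(est / se), df = n - 2L)
    } else {
      q <- stats::qnorm(1 - (1 - level) / 2)
      p <- 2 * stats::pnorm(-abs(est / se))
    }
    list(lo = est - q * se, hi = est + q * se, p = p)
  }
  sc <- .per_sd(slope, se_slope, x@sdScale)
  ps <- pfun(sc$est, sc$se)
  pi <- pfun(intercept, se_int)
  meta <- list(distribution = distribution, inflation = infl,
               sd_scale = x@sdScale)
  list(slope = .mrResult("egger_slope", sc$est, sc$se, level = level,
                         nSnps = n, metadata = meta, ciLow = ps$lo,
                         ciHigh = ps$hi, pvalue = ps$p),
       intercept = .mrResult("egger_intercept", intercept, se_int,
                             level = level, nSnps = n, metadata = meta,
                             ciLow = pi$lo, ciHigh = pi$hi, pvalue = pi$p))
})

#' Cochran's Q heterogeneity test
#'
#' Q = sum over SNPs of w_j (r_j - theta_ivw)^2 with the fixed-effect
#' IVW weights and ratios; under instrument homogeneity Q is
#' chi-square with n - 1 df. Q is dimensionless: it is unchanged by SD
#' rescaling, and zero exactly when all ratios agree.
#'
#' @param x an \linkS4class{InstrumentSet} with at least 2 instruments.
#' @param ... unused.
#' @return A \linkS4class{HeterogeneityResult}.
#' @rdname cochranQ
#' @export
setMethod("cochranQ", "InstrumentSet", function(x, ...) {
  rt <- .ratios(x)
  n <- length(rt$r)
  if (n < 2L) stop("Cochran's Q needs at least 2 instruments")
  theta <- sum(rt$w * rt$r) / sum(rt$w)
  q <- sum(rt$w * (rt$r - theta)^2)
  new("HeterogeneityResult", q = q, df = n - 1L,
      pvalue = stats::pchisq(q, df = n - 1L, lower.tail = FALSE))
})

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the pooled estimate omitting each instrument in turn;
#' each result is labeled by the omitted rsid.
#'
#' @param x an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param method currently "ivw_fixed".
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return list of \linkS4class{MrResult}, one per omitted SNP.
#' @rdname leaveOneOut
#' @export
setMethod("leaveOneOut", "InstrumentSet",
          function(x, method = "ivw_fixed", level = 0.95, ...) {
  method <- match.arg(method, "ivw_fixed")
  n <- nrow(x@data)
  if (n < 3L) stop("leave-one-out needs at least 3 instruments")
  lapply(seq_len(n), function(j) {
    res <- mrIVW(x[-j], mode = "fixed", level = level)
    res@label <- x@data$rsid[j]
    res@metadata <- c(res@metadata, list(omitted = x@data$rsid[j]))
    res
  })
})

#' Forest table of per-SNP and pooled estimates
#'
#' One row per instrument (its SD-rescaled Wald ratio) followed by one
#' row per pooled result, in a layout ready for forest plotting or
#' TSV export.
#'
#' @param x an \linkS4class{InstrumentSet}.
#' @param pooled non-empty list of pooled \linkS4class{MrResult}s.
#' @param level confidence level for the per-SNP rows, default 0.95.
#' @param ... unused.
#' @return data.frame with columns label, type, method, estimate, se,
#'   ci_low, ci_high, or, or_low, or_high, pvalue, n_snps.
#' @rdname forestTable
#' @export
setMethod("forestTable", "InstrumentSet",
          function(x, pooled, level = 0.95, ...) {
  if (missing(pooled) || !length(pooled))
    stop("pooled must be a non-empty list of MrResult")
  rows <- c(waldRatio(x, perSD = TRUE, level = level), pooled)
  types <- c(rep("snp", nrow(x@data)), rep("pooled", length(pooled)))
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(label = if (!is.na(r@label)) r@label else r@method,
               type = types[i], method = r@method, estimate = r@estimate,
               se = r@se, ci_low = r@ciLow, ci_high = r@ciHigh,
               or = exp(r@estimate), or_low = exp(r@ciLow),
               or_high = exp(r@ciHigh), pvalue = r@pvalue,
               n_snps = r@nSnps, stringsAsFactors = FALSE)
  }))
})

#' Tabulate a list of MrResults
#'
#' @param results list of \linkS4class{MrResult}.
#' @return data.frame with one row per result.
#' @export
mrResultsTable <- function(results) {
  if (is(results, "MrResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r@method,
               label = r@label,
               n_snps = r@nSnps,
               estimate = r@estimate,
               se = r@se,
               or = exp(r@estimate),
               or_low = exp(r@ciLow),
               or_high = exp(r@ciHigh),
               ci_low = r@ciLow,
               ci_high = r@ciHigh,
               pvalue = r@pvalue,
               level = r@level,
               seed = if (!is.null(r@metadata$seed)) r@metadata$seed else NA,
               n_boot = if (!is.null(r@metadata$n_boot)) r@metadata$n_boot
                        else NA,
               stringsAsFactors = FALSE)
  }))
}
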