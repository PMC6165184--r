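.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complement <- function(a) {
  out <- .COMPLEMENT[toupper(a)]
  ifelse(is.na(out), NA_character_, unname(out))
}

.is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & .complement(ea) == toupper(oa)
}

#' Flip the allele orientation of every record
#'
#' Re-expresses each association on the opposite allele: beta is
#' negated, effect and other alleles are swapped, eaf becomes 1 - eaf.
#' Standard errors and p-values are untouched. Applying the flip twice
#' returns the original object.
#'
#' @param assocs a \linkS4class{SnpAssociations}.
#' @return the flipped \linkS4class{SnpAssociations}.
#' @export
flipOrientation <- function(assocs) {
  stopifnot(is(assocs, "SnpAssociations"))
  d <- assocs@data
  ea <- d$effect_allele
  d$effect_allele <- d$other_allele
  d$other_allele <- ea
  d$beta <- -d$beta
  d$eaf <- 1 - d$eaf
  initialize(assocs, data = d)
}

#' Select instruments by significance and LD independence
#'
#' Keeps associations with p-value strictly below \code{pThreshold},
#' then prunes linkage disequilibrium: among any pair with r2 >=
#' \code{r2Threshold} only the SNP with the smaller p-value is retained
#' (ties broken by smaller se, then lexicographically smaller rsid).
#' Input order is preserved in the output; filtering is idempotent.
#'
#' @param assocs a \linkS4class{SnpAssociations}.
#' @param pThreshold significance threshold, default genome-wide 5e-8.
#' @param ld an \linkS4class{LdInfo}; missing pairs count as independent.
#' @param r2Threshold LD pruning threshold, default 0.05.
#' @return the filtered \linkS4class{SnpAssociations}.
#' @export
filterInstruments <- function(assocs, pThreshold = 5e-8, ld = LdInfo(),
                              r2Threshold = 0.05) {
  stopifnot(is(assocs, "SnpAssociations"), is(ld, "LdInfo"))
  if (pThreshold <= 0 || pThreshold >= 1) stop("pThreshold must be in (0,1)")
  if (r2Threshold <= 0 || r2Threshold > 1) stop("r2Threshold must be in (0,1]")
  d <- assocs@data
  keep <- !is.na(d$pvalue) & d$pvalue < pThreshold
  d <- d[keep, , drop = FALSE]
  if (nrow(d) > 1L) {
    ## greedy accept in (p, se, rsid) priority order
    pri <- order(d$pvalue, d$se, d$rsid)
    accepted <- integer()
    for (i in pri) {
      correlated <- any(vapply(accepted, function(j) {
        ldR2(ld, d$rsid[i], d$rsid[j]) >= r2Threshold
      }, logical(1)))
      if (!correlated) accepted <- c(accepted, i)
    }
    d <- d[sort(accepted), , drop = FALSE]
  }
  rownames(d) <- NULL
  initialize(assocs, data = d)
}

#' Substitute proxy SNPs for missing outcome records
#'
#' For each mapped target rsid, the outcome association of the proxy
#' rsid replaces (or supplies) the target's record: the result carries
#' the target's rsid with the proxy's beta, se, p-value and alleles,
#' and \code{proxied_by} records the proxy. Substitution is refused
#' when the mapped r2 falls below \code{minR2}.
#'
#' @param assocs outcome-role \linkS4class{SnpAssociations}.
#' @param proxyMap data.frame with columns target_rsid, proxy_rsid, r2
#'   (see \code{\link{readProxyMap}}).
#' @param minR2 minimum proxy r2, default 0.8.
#' @return \linkS4class{SnpAssociations} with substituted records.
#' @export
substituteProxy <- function(assocs, proxyMap, minR2 = 0.8) {
  stopifnot(is(assocs, "SnpAssociations"))
  if (is.null(proxyMap) || nrow(proxyMap) == 0L) return(assocs)
  d <- assocs@data
  for (k in seq_len(nrow(proxyMap))) {
    target <- proxyMap$target_rsid[k]
    proxy <- proxyMap$proxy_rsid[k]
    r2 <- proxyMap$r2[k]
    if (is.na(r2) || r2 < minR2)
      stop(sprintf("proxy %s for %s refused: r2 = %s < minR2 = %s",
                   proxy, target, format(r2), format(minR2)))
    pi <- match(proxy, d$rsid)
    if (is.na(pi))
      stop(sprintf("proxy rsid %s (for %s) absent from outcome data",
                   proxy, target))
    rec <- d[pi, , drop = FALSE]
    rec$rsid <- target
    rec$proxied_by <- proxy
    ti <- match(target, d$rsid)
    if (is.na(ti)) {
      d <- d[-pi, , drop = FALSE]
      d <- rbind(d, rec)
    } else {
      d[ti, ] <- rec
      d <- d[-pi, , drop = FALSE]
    }
  }
  rownames(d) <- NULL
  initialize(assocs, data = d)
}

#' Convert SD-unit exposure effects to ln-trait units
#'
#' Rows flagged \code{sd_of_ln_trait} (effects reported per SD of the
#' standardized log trait) are multiplied — beta and se alike — by
#' \code{sdScale} ln-units per SD and re-flagged \code{ln_trait}. The
#' z-score beta/se is unchanged. Calling on a set with nothing left to
#' convert warns and returns the input (idempotence by unit flag).
#'
#' @param assocs exposure-role \linkS4class{SnpAssociations}.
#' @param sdScale ln-units per SD, > 0.
#' @return \linkS4class{SnpAssociations} fully in ln_trait units.
#' @export
convertUnits <- function(assocs, sdScale) {
  stopifnot(is(assocs, "SnpAssociations"))
  if (!is.numeric(sdScale) || length(sdScale) != 1L || sdScale <= 0)
    stop("sdScale must be a single positive number")
  d <- assocs@data
  idx <- d$unit == "sd_of_ln_trait"
  if (!any(idx)) {
    warning("no sd_of_ln_trait records to convert; returning input unchanged")
    return(assocs)
  }
  d$beta[idx] <- d$beta[idx] * sdScale
  d$se[idx] <- d$se[idx] * sdScale
  d$unit[idx] <- "ln_trait"
  initialize(assocs, data = d)
}

## Align one outcome record to the oriented exposure alleles.
## Returns list(action = "same" | "flip" | "drop", note) or stops.
.align_outcome <- function(exp_ea, exp_oa, out_ea, out_oa, exp_eaf, out_eaf,
                           rsid, palindromePolicy, eafTolerance) {
  pre_oriented <- is.na(exp_oa) || is.na(out_oa)
  if (pre_oriented) {
    ## no full allele pairs: trust the printed orientation when the
    ## effect alleles agree (or the outcome allele is unrecorded)
    if (is.na(out_ea) || is.na(exp_ea) || toupper(out_ea) == toupper(exp_ea))
      return(list(action = "same", note = "pre-oriented"))
    if (!is.na(exp_oa) && toupper(out_ea) == toupper(exp_oa))
      return(list(action = "flip", note = "pre-oriented, opposite allele"))
    stop(sprintf("%s: cannot reconcile alleles (exposure %s, outcome %s) without both allele pairs",
                 rsid, exp_ea, out_ea))
  }
  exp_ea <- toupper(exp_ea); exp_oa <- toupper(exp_oa)
  out_ea <- toupper(out_ea); out_oa <- toupper(out_oa)
  palindromic <- .is_palindromic(exp_ea, exp_oa)
  if (palindromic) {
    if (palindromePolicy == "drop")
      return(list(action = "drop", note = "palindromic SNP dropped"))
    if (palindromePolicy == "trust") {
      if (out_ea == exp_ea && out_oa == exp_oa)
        return(list(action = "same", note = "palindromic, trusted strand"))
      if (out_ea == exp_oa && out_oa == exp_ea)
        return(list(action = "flip", note = "palindromic, trusted strand"))
      stop(sprintf("%s: palindromic alleles do not match under trust policy", rsid))
    }
    ## eaf_infer: use allele frequency side to fix the strand
    if (is.na(exp_eaf) || is.na(out_eaf))
      stop(sprintf("%s: palindromic SNP needs eaf on both sides for eaf_infer", rsid))
    if (abs(exp_eaf - 0.5) < eafTolerance || abs(out_eaf - 0.5) < eafTolerance)
      stop(sprintf("%s: palindromic SNP with eaf too close to 0.5 (tolerance %g)",
                   rsid, eafTolerance))
    same_side <- (exp_eaf > 0.5) == (out_eaf > 0.5)
    if (out_ea == exp_ea && out_oa == exp_oa)
      return(list(action = if (same_side) "same" else "flip",
                  note = "palindromic, eaf-inferred"))
    if (out_ea == exp_oa && out_oa == exp_ea)
      return(list(action = if (same_side) "flip" else "same",
                  note = "palindromic, eaf-inferred"))
    stop(sprintf("%s: irreconcilable palindromic allele pair", rsid))
  }
  if (out_ea == exp_ea && out_oa == exp_oa)
    return(list(action = "same", note = "alleles match"))
  if (out_ea == exp_oa && out_oa == exp_ea)
    return(list(action = "flip", note = "alleles swapped"))
  ## strand complement attempt
  c_ea <- .complement(out_ea); c_oa <- .complement(out_oa)
  if (!is.na(c_ea) && !is.na(c_oa)) {
    if (c_ea == exp_ea && c_oa == exp_oa)
      return(list(action = "same", note = "complement strand"))
    if (c_ea == exp_oa && c_oa == exp_ea)
      return(list(action = "flip", note = "complement strand, swapped"))
  }
  stop(sprintf("%s: irreconcilable allele pair (exposure %s/%s, outcome %s/%s)",
               rsid, exp_ea, exp_oa, out_ea, out_oa))
}

#' Harmonize exposure and outcome associations into an InstrumentSet
#'
#' Per SNP: the exposure record is oriented to its trait-increasing
#' allele (records with beta < 0 are flipped); the outcome effect is
#' then aligned to that allele, attempting a strand-complement match
#' before declaring alleles irreconcilable. Palindromic (A/T, C/G)
#' SNPs are handled per \code{palindromePolicy}: \code{"drop"} excludes
#' them, \code{"eaf_infer"} aligns by which side of 0.5 the allele
#' frequencies fall (failing within \code{eafTolerance} of 0.5), and
#' \code{"trust"} assumes both studies report the same strand. Tables
#' published with effect alleles only (no other_allele column) are
#' treated as pre-oriented: the printed outcome beta refers to the
#' printed exposure allele, and is negated only if the exposure record
#' itself is flipped.
#'
#' @param exposure exposure-role \linkS4class{SnpAssociations}, all in
#'   ln_trait units (run \code{\link{convertUnits}} first).
#' @param outcome outcome-role \linkS4class{SnpAssociations} covering
#'   every exposure rsid (after \code{\link{substituteProxy}}).
#' @param palindromePolicy "eaf_infer" (default), "drop" or "trust".
#' @param eafTolerance half-width of the ambiguous eaf band around 0.5
#'   for eaf_infer, default 0.08.
#' @param exposureName,sdScale metadata attached to the result.
#' @return An \linkS4class{InstrumentSet}; all beta_exp >= 0.
#' @export
harmonize <- function(exposure, outcome,
                      palindromePolicy = c("eaf_infer", "drop", "trust"),
                      eafTolerance = 0.08, exposureName = "exposure",
                      sdScale = 1) {
  stopifnot(is(exposure, "SnpAssociations"), is(outcome, "SnpAssociations"))
  palindromePolicy <- match.arg(palindromePolicy)
  ed <- exposure@data
  od <- outcome@data
  if (any(ed$unit != "ln_trait"))
    stop("exposure records must be in ln_trait units; run convertUnits() first")
  missing <- setdiff(ed$rsid, od$rsid)
  if (length(missing))
    stop("exposure rsid(s) missing from outcome data: ",
         paste(missing, collapse = ", "))
  rows <- vector("list", nrow(ed))
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    o <- od[match(e$rsid, od$rsid), ]
    flipped_exp <- FALSE
    if (e$beta < 0) {
      flipped_exp <- TRUE
      tmp <- e$effect_allele
      e$effect_allele <- e$other_allele
      e$other_allele <- tmp
      e$beta <- -e$beta
      e$eaf <- 1 - e$eaf
    }
    al <- .align_outcome(e$effect_allele, e$other_allele,
                         o$effect_allele, o$other_allele,
                         e$eaf, o$eaf, e$rsid,
                         palindromePolicy, eafTolerance)
    if (al$action == "drop") next
    beta_out <- o$beta
    if (al$action == "flip") beta_out <- -beta_out
    ## pre-oriented tables report the outcome on the printed exposure
    ## allele, so an exposure flip carries the outcome with it
    if (flipped_exp && al$note == "pre-oriented") beta_out <- -beta_out
    rows[[i]] <- data.frame(rsid = e$rsid, beta_exp = e$beta, se_exp = e$se,
                            beta_out = beta_out, se_out = o$se,
                            proxied_by = o$proxied_by,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no instruments remain after harmonization")
  InstrumentSet(do.call(rbind, rows), exposureName = exposureName,
                sdScale = sdScale)
}
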