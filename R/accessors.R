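#' Construct a SnpAssociations object
#'
#' @param data data.frame holding at least rsid, beta, se; optional
#'   columns chrom, nearby_gene, effect_allele, other_allele, eaf,
#'   pvalue, unit, proxied_by are filled with NA (unit with the role
#'   default) when absent.
#' @param role "exposure" or "outcome".
#' @param unit default unit assigned to rows without one; defaults to
#'   "ln_trait" for exposures and "log_odds" for outcomes.
#' @return A \linkS4class{SnpAssociations} object.
#' @export
SnpAssociations <- function(data, role = c("exposure", "outcome"),
                            unit = NULL) {
  role <- match.arg(role)
  if (is.null(unit)) unit <- if (role == "exposure") "ln_trait" else "log_odds"
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in .ASSOC_COLS) {
    if (!col %in% names(data)) {
      fill <- if (col == "unit") unit
              else if (col %in% c("eaf", "beta", "se", "pvalue")) NA_real_
              else NA_character_
      data[[col]] <- rep(fill, nrow(data))
    }
  }
  data$unit[is.na(data$unit)] <- unit
  data <- data[.ASSOC_COLS]
  for (col in c("eaf", "beta", "se", "pvalue")) data[[col]] <- as.numeric(data[[col]])
  rownames(data) <- NULL
  new("SnpAssociations", data = data, role = role)
}

#' Construct an InstrumentSet
#'
#' @param data data.frame with columns rsid, beta_exp, se_exp,
#'   beta_out, se_out and optionally proxied_by.
#' @param exposureName label for the exposure trait.
#' @param sdScale SD of the ln-transformed exposure (ln-units per SD).
#' @return An \linkS4class{InstrumentSet}.
#' @export
InstrumentSet <- function(data, exposureName = "exposure", sdScale = 1) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"proxied_by" %in% names(data)) data$proxied_by <- NA_character_
  data <- data[c("rsid", "beta_exp", "se_exp", "beta_out", "se_out",
                 "proxied_by")]
  rownames(data) <- NULL
  new("InstrumentSet", exposureName = exposureName,
      sdScale = as.numeric(sdScale), data = data)
}

#' Construct an LdInfo store
#'
#' @param pairs data.frame with columns rsid1, rsid2, r2 (unordered
#'   pairs); NULL or zero rows mean all pairs independent.
#' @return An \linkS4class{LdInfo}.
#' @export
LdInfo <- function(pairs = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(rsid1 = character(), rsid2 = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs <- pairs[c("rsid1", "rsid2", "r2")]
  pairs$r2 <- as.numeric(pairs$r2)
  rownames(pairs) <- NULL
  new("LdInfo", pairs = pairs)
}

#' Pairwise r-squared lookup
#'
#' @param ld an \linkS4class{LdInfo}.
#' @param a,b rsids (scalar).
#' @return r2 for the unordered pair, 0 if unlisted.
#' @export
ldR2 <- function(ld, a, b) {
  p <- ld@pairs
  hit <- (p$rsid1 == a & p$rsid2 == b) | (p$rsid1 == b & p$rsid2 == a)
  if (any(hit)) max(p$r2[hit]) else 0
}

## internal MrResult builder: CI and p from normal theory when not given
.mrResult <- function(method, estimate, se, level = 0.95, nSnps = 1L,
                      label = NA_character_, metadata = list(),
                      ciLow = NULL, ciHigh = NULL, pvalue = NULL) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(ciLow)) ciLow <- estimate - zq * se
  if (is.null(ciHigh)) ciHigh <- estimate + zq * se
  if (is.null(pvalue))
    pvalue <- if (is.na(se)) NA_real_
              else if (se > 0) 2 * stats::pnorm(-abs(estimate / se))
              else as.numeric(estimate == 0)
  new("MrResult", method = method, estimate = as.numeric(estimate),
      se = as.numeric(se), ciLow = as.numeric(ciLow),
      ciHigh = as.numeric(ciHigh), pvalue = as.numeric(pvalue),
      level = level, nSnps = as.integer(nSnps),
      label = as.character(label), metadata = metadata)
}

#' Accessors for summaryMR objects
#'
#' \code{estimate}, \code{stdError}, \code{pvalue}, \code{ci} return the
#' log-odds-scale fields of an \linkS4class{MrResult}; \code{or} and
#' \code{orCI} exponentiate them. \code{nSnps} and \code{mrMethod}
#' return metadata. \code{exposureName}, \code{sdScale} and
#' \code{rsids} describe an \linkS4class{InstrumentSet};
#' \code{rsids} and \code{traitRole} also apply to
#' \linkS4class{SnpAssociations}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("estimate", "MrResult", function(x) x@estimate)

#' @rdname accessors
setMethod("stdError", "MrResult", function(x) x@se)

#' @rdname accessors
setMethod("pvalue", "MrResult", function(x) x@pvalue)

#' @rdname accessors
setMethod("pvalue", "HeterogeneityResult", function(x) x@pvalue)

#' @rdname accessors
setMethod("ci", "MrResult", function(x) c(lower = x@ciLow, upper = x@ciHigh))

#' @rdname accessors
setMethod("or", "MrResult", function(x) exp(x@estimate))

#' @rdname accessors
setMethod("orCI", "MrResult",
          function(x) c(lower = exp(x@ciLow), upper = exp(x@ciHigh)))

#' @rdname accessors
setMethod("nSnps", "MrResult", function(x) x@nSnps)

#' @rdname accessors
setMethod("mrMethod", "MrResult", function(x) x@method)

#' @rdname accessors
setMethod("exposureName", "InstrumentSet", function(x) x@exposureName)

#' @rdname accessors
setMethod("sdScale", "InstrumentSet", function(x) x@sdScale)

#' @rdname accessors
setMethod("rsids", "InstrumentSet", function(x) x@data$rsid)

#' @rdname accessors
setMethod("rsids", "SnpAssociations", function(x) x@data$rsid)

#' @rdname accessors
setMethod("traitRole", "SnpAssociations", function(x) x@role)

#' @rdname accessors
setMethod("nSnps", "InstrumentSet", function(x) nrow(x@data))

#' Q statistic of a HeterogeneityResult
#' @param x a \linkS4class{HeterogeneityResult}.
#' @return list with q, df, pvalue.
#' @export
qStatistic <- function(x) {
  stopifnot(is(x, "HeterogeneityResult"))
  list(q = x@q, df = x@df, pvalue = x@pvalue)
}

#' @export
setMethod("length", "SnpAssociations", function(x) nrow(x@data))

#' @export
setMethod("length", "InstrumentSet", function(x) nrow(x@data))

#' @export
setMethod("as.data.frame", "SnpAssociations",
          function(x, ...) x@data)

#' @export
setMethod("as.data.frame", "InstrumentSet",
          function(x, ...) x@data)

#' @export
setMethod("[", "SnpAssociations", function(x, i, j, ..., drop = FALSE) {
  initialize(x, data = x@data[i, , drop = FALSE], role = x@role)
})

#' @export
setMethod("[", "InstrumentSet", function(x, i, j, ..., drop = FALSE) {
  d <- x@data[i, , drop = FALSE]
  rownames(d) <- NULL
  initialize(x, data = d)
})

setMethod("show", "SnpAssociations", function(object) {
  cat(sprintf("SnpAssociations (%s): %d SNPs\n", object@role,
              nrow(object@data)))
  if (nrow(object@data))
    print(utils::head(object@data[c("rsid", "effect_allele", "eaf",
                                    "beta", "se", "pvalue", "unit")], 8L))
  invisible(object)
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet '%s': %d instruments (sdScale = %g)\n",
              object@exposureName, nrow(object@data), object@sdScale))
  print(utils::head(object@data, 8L))
  invisible(object)
})

setMethod("show", "MrResult", function(object) {
  lv <- round(100 * object@level)
  if (object@method == "egger_intercept") {
    cat(sprintf("MR %s: %.4f (%d%% CI %.4f to %.4f), p = %.3g [n = %d]\n",
                object@method, object@estimate, lv, object@ciLow,
                object@ciHigh, object@pvalue, object@nSnps))
  } else {
    cat(sprintf("MR %s: OR %.3f (%d%% CI %.3f-%.3f), p = %.3g [n = %d]\n",
                object@method, exp(object@estimate), lv, exp(object@ciLow),
                exp(object@ciHigh), object@pvalue, object@nSnps))
  }
  invisible(object)
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
              object@q, object@df, object@pvalue))
  invisible(object)
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: %d SNPs, theta = %g, pleiotropy = %s",
                     " (tau = %g, mu = %g), seed = %d\n"),
              object@nSnps, object@theta, object@pleiotropy, object@tau,
              object@muAlpha, object@seed))
  invisible(object)
})
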