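#' Default column-name mapping for summary-statistic tables
#'
#' Canonical field -> column name in the file. Override entries to
#' match a particular export, e.g.
#' \code{summaryDialect(rsid = "SNP", pvalue = "P")}.
#'
#' @param ... named overrides of the defaults.
#' @return named character vector.
#' @export
summaryDialect <- function(...) {
  d <- c(rsid = "rsid", chrom = "chr", nearby_gene = "gene",
         effect_allele = "effect_allele", other_allele = "other_allele",
         eaf = "eaf", beta = "beta", se = "se", pvalue = "pval",
         unit = "unit")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a per-SNP summary-statistic table
#'
#' Reads a delimited (tab or comma; sniffed from the header) table of
#' per-SNP associations into a validated \linkS4class{SnpAssociations}.
#' Rows with missing beta or se are rejected with an error naming the
#' line, never silently dropped. The unit is taken from a unit column
#' when the file has one, else from the role default ("ln_trait" for
#' exposures, "log_odds" for outcomes).
#'
#' @param path file path.
#' @param role "exposure" or "outcome".
#' @param dialect column mapping from \code{\link{summaryDialect}}.
#' @return A \linkS4class{SnpAssociations}.
#' @examples
#' p <- system.file("extdata", "pth_exposure.tsv", package = "summaryMR")
#' readSummaryTable(p, role = "exposure")
#' @export
readSummaryTable <- function(path, role = c("exposure", "outcome"),
                             dialect = summaryDialect()) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  mandatory <- c("rsid", "beta", "se")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(raw))
      stop(sprintf("mandatory column '%s' (field %s) missing from %s",
                   dialect[[f]], f, path))
  }
  n <- nrow(raw)
  get_col <- function(field) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, n)
  }
  num_col <- function(field, required = FALSE) {
    v <- get_col(field)
    v[v %in% c("", "NA", ".")] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(out)
    if (any(bad))
      stop(sprintf("non-numeric %s at line %s of %s", field,
                   paste(which(bad) + 1L, collapse = ", "), path))
    if (required && anyNA(out))
      stop(sprintf("missing %s at line %s of %s", field,
                   paste(which(is.na(out)) + 1L, collapse = ", "), path))
    out
  }
  beta <- num_col("beta", required = n > 0)
  se <- num_col("se", required = n > 0)
  if (any(se <= 0))
    stop(sprintf("se must be > 0; offending line %s of %s",
                 paste(which(se <= 0) + 1L, collapse = ", "), path))
  d <- data.frame(rsid = get_col("rsid"), chrom = get_col("chrom"),
                  nearby_gene = get_col("nearby_gene"),
                  effect_allele = get_col("effect_allele"),
                  other_allele = get_col("other_allele"),
                  eaf = num_col("eaf"), beta = beta, se = se,
                  pvalue = num_col("pvalue"), unit = get_col("unit"),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$rsid))
    stop("duplicate rsid in ", path, ": ",
         paste(unique(d$rsid[duplicated(d$rsid)]), collapse = ", "))
  SnpAssociations(d, role = role)
}

#' Write a SnpAssociations table
#'
#' Serializes at full double precision (round-trips through
#' \code{\link{readSummaryTable}} bit-exactly); display rounding is a
#' reporting concern only.
#'
#' @param assocs a \linkS4class{SnpAssociations}.
#' @param path output file path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
writeSummaryTable <- function(assocs, path) {
  stopifnot(is(assocs, "SnpAssociations"))
  d <- assocs@data
  out <- data.frame(rsid = d$rsid, chr = d$chrom, gene = d$nearby_gene,
                    effect_allele = d$effect_allele,
                    other_allele = d$other_allele,
                    eaf = sprintf("%.17g", d$eaf),
                    beta = sprintf("%.17g", d$beta),
                    se = sprintf("%.17g", d$se),
                    pval = sprintf("%.17g", d$pvalue),
                    unit = d$unit, stringsAsFactors = FALSE)
  out$eaf[is.na(d$eaf)] <- NA
  out$pval[is.na(d$pvalue)] <- NA
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a proxy map
#'
#' @param path delimited file with columns target_rsid, proxy_rsid, r2.
#' @return data.frame with those columns.
#' @export
readProxyMap <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         stringsAsFactors = FALSE)
  need <- c("target_rsid", "proxy_rsid", "r2")
  if (!all(need %in% names(m)))
    stop("proxy map must have columns ", paste(need, collapse = ", "))
  m[need]
}

#' Read pairwise LD information
#'
#' @param path delimited file with columns rsid1, rsid2, r2.
#' @return An \linkS4class{LdInfo}.
#' @export
readLdPairs <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         stringsAsFactors = FALSE)
  LdInfo(p)
}
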