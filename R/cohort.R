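#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value for association in a 2x2 contingency table,
#' defined as the sum of hypergeometric point probabilities (over all
#' tables with the observed margins) no greater than the observed table's
#' probability — the convention of mainstream implementations. The value
#' is returned at full precision; reporting layers may round.
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   counts; conventionally rows = amplification status, columns = feature
#'   presence.
#' @return the two-sided p-value (numeric scalar in (0, 1]).
#' @examples
#' fisher_exact_two_sided(matrix(c(8, 2, 5, 26), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("table must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Build the amplification-by-feature contingency table
#'
#' Cross-tabulates per-sample high-level amplification (copy number at or
#' above `cn_threshold`) against presence of a rearrangement feature:
#' `a` = amplified with feature, `b` = amplified without, `c` = not
#' amplified with feature, `d` = neither.
#'
#' @param samples list (or data.frame) of per-sample summaries with fields
#'   `cn` and the feature flags `has_sv` / `has_phased_sv`.
#' @param feature `"has_sv"` or `"has_phased_sv"`.
#' @param cn_threshold copy-number threshold for the high row (default 8).
#' @return 2x2 integer matrix with dimnames.
#' @export
build_contingency <- function(samples, feature = c("has_sv", "has_phased_sv"),
                              cn_threshold = 8) {
  feature <- match.arg(feature)
  samples <- as_sample_table(samples)
  if (!nrow(samples)) stop("need at least one sample")
  high <- flag_high_cn(samples$cn, cn_threshold)
  feat <- as.logical(samples[[feature]])
  tab <- matrix(c(sum(high & feat), sum(high & !feat),
                  sum(!high & feat), sum(!high & !feat)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(cn = c("high", "not_high"),
                                feature = c("present", "absent")))
  storage.mode(tab) <- "integer"
  tab
}

#' Cohort alteration frequencies
#'
#' Counts and percentages of samples carrying each alteration class:
#' high-level amplification, kept (oncogenic) SNVs, and SV calls.
#' Percentages are rounded half-away-from-zero to integers.
#'
#' @param samples list/data.frame of per-sample summaries with fields
#'   `high_cn` (or `cn`), `n_snvs_kept`, `has_sv`.
#' @param cn_threshold used to derive `high_cn` from `cn` when the flag is
#'   absent.
#' @return data.frame with one row per alteration class: `alteration,
#'   count, n, fraction, percent`.
#' @export
cohort_summary <- function(samples, cn_threshold = 8) {
  samples <- as_sample_table(samples)
  if (!nrow(samples)) stop("empty cohort")
  n <- nrow(samples)
  high <- if ("high_cn" %in% names(samples)) as.logical(samples$high_cn)
  else flag_high_cn(samples$cn, cn_threshold)
  snv <- if ("n_snvs_kept" %in% names(samples)) samples$n_snvs_kept > 0
  else rep(FALSE, n)
  sv <- as.logical(samples$has_sv)
  counts <- c(amplification = sum(high), snv = sum(snv), sv = sum(sv))
  data.frame(alteration = names(counts), count = unname(counts), n = n,
             fraction = unname(counts) / n,
             percent = round_half_up(100 * unname(counts) / n),
             stringsAsFactors = FALSE)
}

## normalise a list of per-sample summary lists into one data.frame
as_sample_table <- function(samples) {
  if (is.data.frame(samples)) return(samples)
  if (!is.list(samples)) stop("samples must be a list or data.frame")
  fields <- unique(unlist(lapply(samples, names)))
  rows <- lapply(samples, function(s) {
    vals <- lapply(fields, function(f) s[[f]] %||% NA)
    setNames(as.data.frame(vals, stringsAsFactors = FALSE), fields)
  })
  do.call(rbind, rows)
}
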