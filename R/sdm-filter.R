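#' Single-dose marker filter for a maternal haplotype map
#'
#' Keeps genotyping-by-sequencing markers suitable for a haplotype-resolved
#' maternal linkage map of an autotetraploid cross, applying three rules in
#' order: (a) the marker is simplex x nulliplex — maternal dosage 1
#' (0/0/0/1) and paternal dosage 0 (0/0/0/0); (b) strictly less than
#' `max_missing` missing progeny calls; (c) presence/absence counts among
#' non-missing progeny are consistent with 1:1 segregation by a chi-square
#' goodness-of-fit test at level `alpha` (kept when `p >= alpha`; no
#' continuity correction, no multiplicity adjustment). The audit table
#' records the first rule each rejected marker failed.
#'
#' @param markers Data frame: columns `marker_id`, `chrom`, `pos`,
#'   `maternal`, `paternal` (integer dosages 0-4), then one column per
#'   progeny individual coded 1 (present), 0 (absent) or `NA` (missing).
#' @param max_missing Strict upper bound on the missing-call fraction.
#' @param alpha Significance level of the segregation test.
#' @return List with `markers` (retained rows) and `audit` (one row per
#'   input marker: counts, missing fraction, chi-square statistic and
#'   p-value, `rule_failed` in `{dosage, missing, segregation, none}`,
#'   `kept`).
#' @export
filter_single_dose <- function(markers, max_missing = 0.05, alpha = 0.05) {
  meta <- c("marker_id", "chrom", "pos", "maternal", "paternal")
  if (!all(meta %in% names(markers)))
    stop("markers must have columns ", paste(meta, collapse = ", "))
  calls <- as.matrix(markers[, setdiff(names(markers), meta), drop = FALSE])
  if (!ncol(calls)) stop("no progeny columns")
  storage.mode(calls) <- "double"
  if (any(markers$maternal < 0 | markers$maternal > 4 |
          markers$paternal < 0 | markers$paternal > 4))
    stop("dosages must be within 0-4")

  n_ind <- ncol(calls)
  n_missing <- rowSums(is.na(calls))
  n_present <- rowSums(calls == 1, na.rm = TRUE)
  n_absent <- rowSums(calls == 0, na.rm = TRUE)
  missing_frac <- n_missing / n_ind

  ok_dosage <- markers$maternal == 1 & markers$paternal == 0
  ok_missing <- missing_frac < max_missing
  chisq_stat <- rep(NA_real_, nrow(markers))
  p_value <- rep(NA_real_, nrow(markers))
  nm <- n_present + n_absent
  has_obs <- nm > 0
  chisq_stat[has_obs] <- (n_present[has_obs] - n_absent[has_obs])^2 / nm[has_obs]
  p_value[has_obs] <- stats::pchisq(chisq_stat[has_obs], df = 1L,
                                    lower.tail = FALSE)
  ok_seg <- !is.na(p_value) & p_value >= alpha

  rule_failed <- rep("none", nrow(markers))
  rule_failed[!ok_seg] <- "segregation"
  rule_failed[!ok_missing] <- "missing"
  rule_failed[!ok_dosage] <- "dosage"
  kept <- ok_dosage & ok_missing & ok_seg

  audit <- data.frame(marker_id = markers$marker_id,
                      maternal = markers$maternal,
                      paternal = markers$paternal,
                      n_present = n_present, n_absent = n_absent,
                      n_missing = n_missing, missing_frac = missing_frac,
                      chisq_stat = chisq_stat, p_value = p_value,
                      rule_failed = rule_failed, kept = kept,
                      stringsAsFactors = FALSE)
  list(markers = markers[kept, , drop = FALSE], audit = audit)
}

#' Read a dosage-genotype matrix from TSV
#'
#' @param path TSV with columns `marker_id`, `chrom`, `pos`, `maternal`,
#'   `paternal`, then progeny individuals coded 0/1/NA.
#' @return Data frame suitable for [filter_single_dose()].
#' @export
read_dosage_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a dosage-genotype matrix to TSV
#' @param markers Data frame as in [filter_single_dose()].
#' @param path Output file.
#' @export
write_dosage_tsv <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
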