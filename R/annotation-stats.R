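#' Half-up decimal rounding
#'
#' Printed annotation summaries conventionally round halves away from zero
#' (so 0.825 -> 0.83), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  # snap away float error before applying the half-up rule
  sign(x) * floor(round(abs(x) * f, 9) + 0.5) / f
}

#' Percentage of a count over a denominator
#'
#' @param n Numerator.
#' @param d Denominator, > 0.
#' @param decimals Decimal places (half-up).
#' @return `100 * n / d`, rounded.
#' @examples
#' proportion(22713, 40397, 2)   # 56.22
#' proportion(293379, 555442, 1) # 52.8
#' @export
proportion <- function(n, d, decimals = 1L) {
  if (any(d <= 0)) stop("denominator must be > 0")
  round_half_up(100 * n / d, decimals)
}

#' Ratio of two quantities
#'
#' @param a Numerator.
#' @param b Denominator, > 0.
#' @param decimals Decimal places (half-up).
#' @examples
#' ratio(409, 217, 1)        # 1.9 (Copia:Gypsy style ratio)
#' ratio(2411.81, 2935, 2)   # 0.82 (cM per marker)
#' @export
ratio <- function(a, b, decimals = 1L) {
  if (any(b <= 0)) stop("denominator must be > 0")
  round_half_up(a / b, decimals)
}

#' Annotation summary statistics
#'
#' Groups transcript models by gene and computes the headline annotation
#' numbers: gene/transcript totals, the isoforms-per-gene histogram, mean
#' gene length (span of all isoforms), mean introns per gene (distinct
#' intron keys across isoforms), and median intron/exon lengths over all
#' transcripts (even counts use the midpoint of the two central values).
#' When a support classification is supplied, mean protein length
#' (CDS nt / 3 - 1, stop excluded) and intronless counts are reported for
#' supported vs unsupported transcripts.
#'
#' @param transcripts List of [transcript_model] objects.
#' @param support Optional classification data frame from
#'   [classify_support_all()].
#' @return A list of class `annotation_summary`. Empty input yields the
#'   zero-count sentinel.
#' @export
summarize_annotation <- function(transcripts, support = NULL) {
  if (!length(transcripts)) {
    return(structure(list(n_genes = 0L, n_transcripts = 0L,
                          isoform_histogram = table(integer(0)),
                          mean_gene_length_bp = NA_real_,
                          mean_introns_per_gene = NA_real_,
                          median_intron_bp = NA_real_,
                          median_exon_bp = NA_real_,
                          by_category = NULL),
                     class = "annotation_summary"))
  }
  gids <- vapply(transcripts, `[[`, character(1L), "gene_id")
  by_gene <- split(transcripts, gids)
  n_genes <- length(by_gene)
  n_tx <- length(transcripts)
  iso_counts <- vapply(by_gene, length, integer(1L))
  gene_len <- vapply(by_gene, function(ts) {
    sp <- vapply(ts, tx_span, numeric(2L))
    max(sp[2L, ]) - min(sp[1L, ])
  }, numeric(1L))
  introns_per_gene <- vapply(by_gene, function(ts) {
    length(unique(unlist(lapply(ts, intron_keys))))
  }, numeric(1L))
  all_exon_len <- unlist(lapply(transcripts, function(t)
    t$exons[, 2L] - t$exons[, 1L]))
  all_intron_len <- unlist(lapply(transcripts, function(t) {
    ii <- tx_introns(t)
    if (nrow(ii)) ii[, 2L] - ii[, 1L] else numeric(0)
  }))

  by_category <- NULL
  if (!is.null(support)) {
    ids <- vapply(transcripts, `[[`, character(1L), "id")
    m <- match(ids, support$transcript_id)
    grp <- ifelse(support$any_support[m], "supported", "unsupported")
    aa <- vapply(transcripts, function(t) tx_cds_len(t) / 3 - 1, numeric(1L))
    intronless <- vapply(transcripts, function(t) tx_n_exons(t) == 1L, logical(1L))
    by_category <- do.call(rbind, lapply(split(seq_along(transcripts), grp),
      function(idx) data.frame(category = grp[idx[1L]],
                               n_transcripts = length(idx),
                               mean_protein_aa = mean(aa[idx]),
                               intronless = sum(intronless[idx]),
                               stringsAsFactors = FALSE)))
    rownames(by_category) <- NULL
  }

  structure(list(
    n_genes = n_genes,
    n_transcripts = n_tx,
    isoform_histogram = table(iso_counts),
    mean_gene_length_bp = mean(gene_len),
    mean_introns_per_gene = mean(introns_per_gene),
    median_intron_bp = if (length(all_intron_len)) stats::median(all_intron_len) else NA_real_,
    median_exon_bp = stats::median(all_exon_len),
    by_category = by_category), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf(paste0("annotation_summary: %d genes, %d transcripts\n",
                     "  mean gene length %.1f bp; %.2f introns/gene;\n",
                     "  median intron %.0f bp; median exon %.0f bp\n"),
              x$n_genes, x$n_transcripts, x$mean_gene_length_bp,
              x$mean_introns_per_gene, x$median_intron_bp, x$median_exon_bp))
  if (!is.null(x$by_category)) print(x$by_category)
  invisible(x)
}
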