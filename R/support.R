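#' Classify a predicted transcript by external evidence support
#'
#' Applies the evidence-support rules per class:
#' \itemize{
#' \item Multiexon, Iso-Seq: \emph{full} when a single Iso-Seq transcript
#'   contains every intron of the prediction and any additional introns of
#'   that isoform lie entirely outside the prediction's CDS genomic span
#'   (i.e. only in its UTRs).
#' \item Multiexon, RNA-Seq or protein: \emph{full} when every intron of the
#'   prediction has a matching intron hint in the respective set.
#' \item Single-exon, Iso-Seq: \emph{full} when some isoform's projected
#'   lORF start and end both equal the prediction's CDS bounds.
#' \item Single-exon, protein: \emph{full} when both the start and the stop
#'   codon are matched by protein hints.
#' \item \emph{partial}: not full, but at least one element matched — an
#'   intron key, a start/stop hint, or (Iso-Seq) at least `min_overlap` bp of
#'   same-strand overlap between the prediction's CDS span and an Iso-Seq
#'   ORF.
#' }
#'
#' @param t A [transcript_model] with CDS (hard error otherwise).
#' @param isoforms List of `aligned_isoform` objects (with lORFs) — the
#'   mapped Iso-Seq set.
#' @param rnaseq_hints,protein_hints `hint_set` objects.
#' @param min_overlap Minimum Iso-Seq CDS overlap (bp) counting as partial.
#' @return A one-row data frame: `transcript_id`, levels `isoseq`, `rnaseq`,
#'   `protein` (each `"full"`, `"partial"` or `"none"`), `any_support`,
#'   `fully_supported_any`.
#' @export
classify_support <- function(t, isoforms, rnaseq_hints, protein_hints,
                             min_overlap = 1L) {
  if (tx_cds_len(t) <= 0)
    stop("transcript ", t$id, " has no CDS; support is defined on coding models")
  tk <- intron_keys(t)
  multiexon <- tx_n_exons(t) >= 2L
  cds_span <- tx_cds_span(t)

  rk <- hint_keys(rnaseq_hints[rnaseq_hints$kind == "intron", , drop = FALSE])
  pk <- hint_keys(protein_hints[protein_hints$kind == "intron", , drop = FALSE])
  codons <- cds_codon_keys(t)
  pstart <- hint_keys(protein_hints[protein_hints$kind == "start", , drop = FALSE])
  pstop <- hint_keys(protein_hints[protein_hints$kind == "stop", , drop = FALSE])
  start_hit <- codons["start"] %in% pstart
  stop_hit <- codons["stop"] %in% pstop

  if (multiexon) {
    rnaseq <- level_from(all(tk %in% rk), any(tk %in% rk))
    protein <- level_from(all(tk %in% pk),
                          any(tk %in% pk) || start_hit || stop_hit)
  } else {
    rnaseq <- "none"
    protein <- level_from(start_hit && stop_hit, start_hit || stop_hit)
  }

  iso_full <- FALSE
  iso_overlap <- 0
  for (iso in isoforms) {
    it <- iso$transcript
    if (it$seq_id != t$seq_id || it$strand != t$strand) next
    if (!is.null(iso$genome_cds))
      iso_overlap <- max(iso_overlap,
                         overlap_bp(iso$genome_cds, cds_span))
    if (multiexon) {
      ik <- intron_keys(it)
      if (length(tk) && all(tk %in% ik)) {
        extra <- tx_introns(it)[!(ik %in% tk), , drop = FALSE]
        outside <- !nrow(extra) ||
          all(extra[, 2L] <= cds_span[1L] | extra[, 1L] >= cds_span[2L])
        if (outside) iso_full <- TRUE
      }
    } else if (!is.null(iso$genome_cds)) {
      proj <- c(iso$genome_cds[1L, 1L], iso$genome_cds[nrow(iso$genome_cds), 2L])
      if (proj[1L] == cds_span[1L] && proj[2L] == cds_span[2L]) iso_full <- TRUE
    }
  }
  isoseq <- level_from(iso_full, iso_overlap >= min_overlap)

  lv <- c(isoseq, rnaseq, protein)
  data.frame(transcript_id = t$id, isoseq = isoseq, rnaseq = rnaseq,
             protein = protein, any_support = any(lv != "none"),
             fully_supported_any = any(lv == "full"),
             stringsAsFactors = FALSE)
}

level_from <- function(full, partial) {
  if (full) "full" else if (partial) "partial" else "none"
}

## bp of overlap between an interval matrix and a single span
overlap_bp <- function(m, span) {
  if (is.null(m) || !nrow(m)) return(0)
  sum(pmax(0, pmin(m[, 2L], span[2L]) - pmax(m[, 1L], span[1L])))
}

## start/stop codon location keys of a transcript's CDS (strand-aware)
cds_codon_keys <- function(t) {
  sp <- tx_cds_span(t)
  lo <- sprintf("%s:%s:%d-%d(%s)", t$seq_id, c("lo"), as.integer(sp[1L]),
                as.integer(sp[1L] + 3L), t$strand)
  hi <- sprintf("%s:%s:%d-%d(%s)", t$seq_id, c("hi"), as.integer(sp[2L] - 3L),
                as.integer(sp[2L]), t$strand)
  if (t$strand == "-") {
    c(start = sub(":hi:", ":start:", hi), stop = sub(":lo:", ":stop:", lo))
  } else {
    c(start = sub(":lo:", ":start:", lo), stop = sub(":hi:", ":stop:", hi))
  }
}

#' Classify many transcripts
#'
#' @param transcripts List of [transcript_model] objects with CDS.
#' @inheritParams classify_support
#' @return Data frame with one row per transcript (see [classify_support()]).
#' @export
classify_support_all <- function(transcripts, isoforms, rnaseq_hints,
                                 protein_hints, min_overlap = 1L) {
  do.call(rbind, lapply(transcripts, classify_support, isoforms = isoforms,
                        rnaseq_hints = rnaseq_hints,
                        protein_hints = protein_hints,
                        min_overlap = min_overlap))
}

#' Select the training-gene set
#'
#' Predictions fully supported by mapped Iso-Seq transcripts or by protein
#' hints are the training candidates; RNA-Seq support alone never qualifies.
#'
#' @param records Classification data frame from [classify_support_all()].
#' @return Character vector of transcript ids.
#' @export
select_training <- function(records) {
  if (is.null(records) || !nrow(records)) return(character(0))
  records$transcript_id[records$isoseq == "full" | records$protein == "full"]
}

#' Support-category counts
#'
#' Tabulates full support per evidence class plus the three-way partition
#' fully supported / partial only / unsupported, which always sums to the
#' transcript total.
#'
#' @param records Classification data frame from [classify_support_all()].
#' @return Data frame with columns `category` and `count`.
#' @export
category_counts <- function(records) {
  n <- if (is.null(records)) 0L else nrow(records)
  cnt <- function(x) if (n) sum(x) else 0L
  data.frame(
    category = c("full_isoseq", "full_rnaseq", "full_protein",
                 "fully_supported_any", "partial_any", "unsupported", "total"),
    count = c(cnt(records$isoseq == "full"),
              cnt(records$rnaseq == "full"),
              cnt(records$protein == "full"),
              cnt(records$fully_supported_any),
              cnt(records$any_support & !records$fully_supported_any),
              cnt(!records$any_support),
              n),
    stringsAsFactors = FALSE)
}
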