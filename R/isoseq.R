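#' Build aligned-isoform records from Iso-Seq transcript models
#'
#' Attaches alignment identity/coverage (parsed from transcript attributes;
#' values above 1 are auto-detected as percentages) and the longest ORF of
#' the spliced sequence, projected to genome coordinates.
#'
#' @param transcripts List of [transcript_model] objects (`source = "isoseq"`).
#' @param genome A [masked_genome] the models are aligned to.
#' @return List of `aligned_isoform` objects with elements `transcript`,
#'   `identity`, `coverage`, `lorf` (possibly `NULL`) and `genome_cds`.
#' @export
align_isoforms <- function(transcripts, genome) {
  lapply(transcripts, function(t) {
    idn <- parse_fraction(t$attributes["identity"])
    cov <- parse_fraction(t$attributes["coverage"])
    lorf <- longest_orf(spliced_seq(genome, t), transcript_id = t$id)
    aligned_isoform(t, identity = idn, coverage = cov, lorf = lorf)
  })
}

parse_fraction <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v)) return(NA_real_)
  if (v > 1) v <- v / 100   # percentage on input
  v
}

#' Aligned Iso-Seq isoform
#'
#' @param transcript A [transcript_model].
#' @param identity,coverage Alignment fractions in \[0, 1\] (may be `NA` when
#'   unknown; [filter_alignments()] then errors).
#' @param lorf An `orf` from [longest_orf()], or `NULL`.
#' @return An object of class `aligned_isoform`; `genome_cds` holds the
#'   genomic projection of the lORF (or `NULL`).
#' @export
aligned_isoform <- function(transcript, identity = NA_real_,
                            coverage = NA_real_, lorf = NULL) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (!is.na(identity) && (identity < 0 || identity > 1))
    stop("identity outside [0, 1] for ", transcript$id)
  if (!is.na(coverage) && (coverage < 0 || coverage > 1))
    stop("coverage outside [0, 1] for ", transcript$id)
  structure(list(transcript = transcript, identity = identity,
                 coverage = coverage, lorf = lorf,
                 genome_cds = if (is.null(lorf)) NULL else
                   project_orf(transcript, lorf)),
            class = "aligned_isoform")
}

#' Filter Iso-Seq alignments on identity and coverage
#'
#' Keeps alignments with `identity >= min_identity` and
#' `coverage >= min_coverage`, both inclusive (defaults: at least 95%
#' identity and 90% coverage).
#'
#' @param isoforms List of `aligned_isoform` objects.
#' @param min_identity,min_coverage Inclusive thresholds as fractions.
#' @return Filtered list.
#' @export
filter_alignments <- function(isoforms, min_identity = 0.95,
                              min_coverage = 0.90) {
  keep <- vapply(isoforms, function(x) {
    if (is.na(x$identity) || is.na(x$coverage))
      stop("isoform ", x$transcript$id, " lacks identity/coverage attributes")
    x$identity >= min_identity && x$coverage >= min_coverage
  }, logical(1L))
  isoforms[keep]
}

#' Select nonoverlapping representative isoforms
#'
#' Reduces a set of aligned isoforms to one representative per locus:
#' (1) isoforms without a complete lORF are dropped; (2) loci are the
#' connected components of same-strand genomic-span overlap (>= 1 bp);
#' (3) the representative of each locus is the isoform with the longest
#' lORF (ties: smaller span start, then lexicographic id); (4) only then
#' are representatives with a lORF shorter than `min_lorf_nt` or any intron
#' longer than `max_intron_nt` removed — so a locus can end up with no
#' representative at all. Output spans are pairwise disjoint per strand.
#'
#' @param isoforms List of `aligned_isoform` objects.
#' @param min_lorf_nt Minimum lORF length kept (strictly shorter is removed).
#' @param max_intron_nt Maximum intron length kept (strictly longer removes
#'   the isoform).
#' @return List of representative `aligned_isoform` objects.
#' @export
select_representatives <- function(isoforms, min_lorf_nt = 300,
                                   max_intron_nt = 10000) {
  isoforms <- Filter(function(x) !is.null(x$lorf), isoforms)
  if (!length(isoforms)) return(isoforms)
  spans <- t(vapply(isoforms, function(x) tx_span(x$transcript), numeric(2L)))
  seqs <- vapply(isoforms, function(x) x$transcript$seq_id, character(1L))
  strands <- vapply(isoforms, function(x) x$transcript$strand, character(1L))
  comp <- integer(length(isoforms))
  next_comp <- 0L
  for (grp in split(seq_along(isoforms), paste(seqs, strands))) {
    ir <- IRanges::IRanges(spans[grp, 1L] + 1L, spans[grp, 2L])
    # components of the >=1 bp overlap graph = membership in merged runs
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, merged, minoverlap = 1L)
    comp[grp] <- next_comp + S4Vectors::subjectHits(hit)
    next_comp <- next_comp + length(merged)
  }
  lens <- vapply(isoforms, function(x) x$lorf$length_nt, numeric(1L))
  ids <- vapply(isoforms, function(x) x$transcript$id, character(1L))
  reps <- vapply(split(seq_along(isoforms), comp), function(idx) {
    o <- order(-lens[idx], spans[idx, 1L], ids[idx])
    idx[o[1L]]
  }, integer(1L))
  out <- isoforms[sort(reps)]
  # paper's order: size/intron filters run AFTER representative choice
  Filter(function(x) {
    introns <- tx_introns(x$transcript)
    x$lorf$length_nt >= min_lorf_nt &&
      (nrow(introns) == 0L || max(introns[, 2L] - introns[, 1L]) <= max_intron_nt)
  }, out)
}

#' Convert an aligned isoform to a transcript model with its lORF as CDS
#'
#' @param iso An `aligned_isoform` with a non-`NULL` lORF.
#' @return A [transcript_model] whose CDS is the lORF genome projection.
#' @export
isoform_to_model <- function(iso) {
  if (is.null(iso$lorf)) stop("isoform ", iso$transcript$id, " has no lORF")
  t <- iso$transcript
  transcript_model(t$id, t$gene_id, t$seq_id, t$strand, t$exons,
                   cds = iso$genome_cds, source = "isoseq",
                   attributes = t$attributes)
}
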