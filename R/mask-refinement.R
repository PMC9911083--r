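#' Refine repeat soft-masking over supported Iso-Seq ORFs
#'
#' Unmasks every base that is currently soft-masked and lies inside an
#' evidence-supported Iso-Seq ORF interval. Only the intersection of masked
#' runs with ORF intervals is unmasked, never whole repeat runs; residues
#' are untouched. The caller restricts `orfs` to ORFs with protein or
#' RNA-Seq support (see [supported_orf_table()]).
#'
#' @param genome A [masked_genome].
#' @param orfs Data frame with columns `locus_id`, `seq_id`, `start`, `end`
#'   (0-based half-open genomic CDS intervals, one row per interval).
#' @return List with `genome` (refined [masked_genome]) and `report` (list
#'   with `unmasked_bp`; `n_loci` — loci whose intervals overlap at least
#'   one base masked on entry, judged against the incoming mask so the count
#'   is order-independent; and a `per_sequence` data frame of changed bases).
#' @examples
#' g <- masked_genome(c(chr = paste(rep(tolower("ACGT"), 250), collapse = "")))
#' orfs <- data.frame(locus_id = "L1", seq_id = "chr", start = 100, end = 400)
#' refine_mask(g, orfs)$report$unmasked_bp  # 300
#' @export
refine_mask <- function(genome, orfs) {
  stopifnot(inherits(genome, "masked_genome"))
  need <- c("locus_id", "seq_id", "start", "end")
  if (!all(need %in% names(orfs)))
    stop("orfs must have columns ", paste(need, collapse = ", "))
  mask0 <- genome$mask   # loci are judged against the mask state at entry,
                         # so overlapping ORFs each count their own locus
  changed_by_locus <- numeric(0)
  per_seq <- stats::setNames(numeric(length(genome$seq)), names(genome$seq))
  for (i in seq_len(nrow(orfs))) {
    sid <- orfs$seq_id[i]
    m <- genome$mask[[sid]]
    if (is.null(m)) stop("sequence ", sid, " not in genome")
    a <- orfs$start[i]; b <- orfs$end[i]
    if (a < 0 || b > length(m) || a >= b)
      stop("ORF interval [", a, ", ", b, ") out of bounds on ", sid)
    idx <- (a + 1L):b
    hit <- m[idx]
    nch <- sum(hit)
    if (nch > 0) {
      m[idx][hit] <- FALSE
      genome$mask[[sid]] <- m
      per_seq[sid] <- per_seq[sid] + nch
    }
    lid <- as.character(orfs$locus_id[i])
    changed_by_locus[lid] <- sum(changed_by_locus[lid],
                                 sum(mask0[[sid]][idx]), na.rm = TRUE)
  }
  report <- list(
    unmasked_bp = sum(per_seq),
    n_loci = sum(changed_by_locus > 0),
    per_sequence = data.frame(seq_id = names(per_seq),
                              unmasked_bp = unname(per_seq),
                              stringsAsFactors = FALSE))
  list(genome = genome, report = report)
}

#' ORF intervals of isoforms with RNA-Seq or protein support
#'
#' Eligibility for mask refinement: an isoform counts as supported when its
#' support level from RNA-Seq or protein evidence is at least partial under
#' the same rules as [classify_support()] (>= 1 intron in the respective
#' hint set, or for single-exon isoforms a protein start/stop hint match on
#' the lORF codons).
#'
#' @param isoforms List of `aligned_isoform` objects with lORFs.
#' @param rnaseq_hints,protein_hints Hint sets (see [hint_set()]).
#' @return Data frame of supported ORF intervals suitable for
#'   [refine_mask()]; one locus per isoform.
#' @export
supported_orf_table <- function(isoforms, rnaseq_hints, protein_hints) {
  rows <- list()
  for (iso in isoforms) {
    if (is.null(iso$lorf)) next
    m <- isoform_to_model(iso)
    rec <- classify_support(m, list(), rnaseq_hints, protein_hints)
    if (rec$rnaseq == "none" && rec$protein == "none") next
    cds <- iso$genome_cds
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = m$id, seq_id = m$seq_id,
      start = cds[, 1L], end = cds[, 2L], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(locus_id = character(0), seq_id = character(0),
                      start = numeric(0), end = numeric(0)))
  do.call(rbind, rows)
}
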