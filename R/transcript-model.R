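#' Transcript model
#'
#' A stranded chain of exon intervals on one sequence, with an optional CDS
#' sub-chain. Used both for predicted gene models and for aligned Iso-Seq
#' transcripts. Exons (and CDS pieces) are stored in ascending genomic order
#' regardless of strand; biological (5'->3') order is derived where needed.
#'
#' @param id Transcript identifier (unique within a set).
#' @param gene_id Gene identifier the transcript belongs to.
#' @param seq_id Sequence name.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param exons Two-column numeric matrix of 0-based half-open exon intervals,
#'   sorted, pairwise disjoint.
#' @param cds Optional two-column matrix of CDS intervals; every CDS piece
#'   must lie inside an exon.
#' @param source `"prediction"` or `"isoseq"`.
#' @param attributes Named character vector of free-form attributes
#'   (e.g. `identity`, `coverage`).
#' @return An object of class `transcript_model`.
#' @examples
#' t <- transcript_model("t1", "g1", "chr1", "+",
#'                       exons = rbind(c(0, 100), c(200, 300)))
#' tx_introns(t)
#' @export
transcript_model <- function(id, gene_id, seq_id, strand, exons, cds = NULL,
                             source = c("prediction", "isoseq"),
                             attributes = character()) {
  source <- match.arg(source)
  if (!nzchar(id) || !nzchar(gene_id) || !nzchar(seq_id))
    stop("id, gene_id and seq_id must be nonempty")
  if (!strand %in% c("+", "-", "*")) stop("bad strand for ", id)
  exons <- check_interval_matrix(exons, "exon")
  if (nrow(exons) == 0L) stop("transcript ", id, " has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons of ", id, " overlap")
  if (!is.null(cds)) {
    cds <- check_interval_matrix(cds, "CDS")
    if (nrow(cds) == 0L) {
      cds <- NULL
    } else {
      cds <- cds[order(cds[, 1L]), , drop = FALSE]
      inside <- vapply(seq_len(nrow(cds)), function(i) {
        any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
      }, logical(1L))
      if (!all(inside))
        stop("CDS of ", id, " extends outside its exons")
    }
  }
  structure(list(id = id, gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, cds = cds, source = source,
                 attributes = attributes),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s:%s-%s(%s) %d exon(s)%s [%s]\n",
              x$id, x$gene_id, x$seq_id,
              format(tx_span(x)[1L], big.mark = ","),
              format(tx_span(x)[2L], big.mark = ","),
              x$strand, nrow(x$exons),
              if (is.null(x$cds)) "" else sprintf(", CDS %d nt", tx_cds_len(x)),
              x$source))
  invisible(x)
}

#' Genomic span of a transcript
#' @param t A [transcript_model].
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
tx_span <- function(t) c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L])

#' Number of exons
#' @param t A [transcript_model].
#' @export
tx_n_exons <- function(t) nrow(t$exons)

#' Total exonic (spliced) length in nucleotides
#' @param t A [transcript_model].
#' @export
tx_exonic_len <- function(t) sum(t$exons[, 2L] - t$exons[, 1L])

#' Total CDS length in nucleotides
#' @param t A [transcript_model].
#' @return Integer; 0 if the transcript has no CDS.
#' @export
tx_cds_len <- function(t) if (is.null(t$cds)) 0 else sum(t$cds[, 2L] - t$cds[, 1L])

#' Genomic span of the CDS
#' @param t A [transcript_model].
#' @return `c(start, end)` or `NULL` if no CDS.
#' @export
tx_cds_span <- function(t) {
  if (is.null(t$cds)) return(NULL)
  c(t$cds[1L, 1L], t$cds[nrow(t$cds), 2L])
}

#' Introns of a transcript
#'
#' One interval per gap between consecutive exons, in ascending genomic
#' order; a single-exon transcript has none.
#'
#' @param t A [transcript_model].
#' @return Two-column matrix of 0-based half-open intron intervals
#'   (zero rows for single-exon transcripts).
#' @examples
#' t <- transcript_model("t1", "g1", "c", "+",
#'                       rbind(c(0, 100), c(200, 300), c(400, 500)))
#' tx_introns(t)  # (100,200), (300,400)
#' @export
tx_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(matrix(numeric(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
}

## intron location keys in the same format as hint_keys(), so transcript
## introns and intron hints compare directly
intron_keys <- function(t) {
  ii <- tx_introns(t)
  if (nrow(ii) == 0L) return(character(0))
  sprintf("%s:intron:%d-%d(%s)", t$seq_id, as.integer(ii[, 1L]),
          as.integer(ii[, 2L]), t$strand)
}

#' Spliced transcript sequence
#'
#' Extracts and concatenates exon sequences from a genome, reverse-
#' complementing for minus-strand transcripts so the result reads 5'->3'
#' in transcript orientation. Masking case is ignored.
#'
#' @param genome A [masked_genome].
#' @param t A [transcript_model].
#' @return A character string over the DNA alphabet (uppercase).
#' @export
spliced_seq <- function(genome, t) {
  s <- genome$seq[[t$seq_id]]
  if (is.null(s)) stop("sequence ", t$seq_id, " not in genome")
  pieces <- substring(s, t$exons[, 1L] + 1L, t$exons[, 2L])
  out <- paste(pieces, collapse = "")
  if (t$strand == "-") out <- revcomp(out)
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Map a transcript-relative interval to genome coordinates
#'
#' Projects `[s, e)` (0-based half-open, transcript orientation) through the
#' exon chain. On the minus strand, transcript position 0 corresponds to the
#' highest genomic exon base.
#'
#' @param t A [transcript_model].
#' @param s,e Transcript-relative bounds, `0 <= s < e <= spliced length`.
#' @return Two-column matrix of genomic intervals in ascending order.
#' @export
map_tx_to_genome <- function(t, s, e) {
  L <- tx_exonic_len(t)
  if (s < 0 || e > L || s >= e)
    stop("transcript interval [", s, ", ", e, ") outside transcript of length ", L)
  if (t$strand == "-") { tmp <- s; s <- L - e; e <- L - tmp }
  widths <- t$exons[, 2L] - t$exons[, 1L]
  offs <- cumsum(c(0, widths))  # transcript offset (plus orientation) at exon starts
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(t$exons))) {
    a <- max(s, offs[i]); b <- min(e, offs[i + 1L])
    if (a < b) {
      g0 <- t$exons[i, 1L] + (a - offs[i])
      out <- rbind(out, c(g0, g0 + (b - a)))
    }
  }
  colnames(out) <- c("start", "end")
  out
}
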