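#' Longest open reading frame in a spliced transcript
#'
#' Scans the three forward frames of a sense-oriented cDNA sequence for
#' complete ORFs (ATG through an in-frame stop, stop included) and returns
#' the longest; ties are broken by the smallest start position. Full-length
#' Iso-Seq reads are orientation-resolved upstream (primer/polyA
#' classification), so reverse frames are never scanned. Codons containing
#' ambiguity codes qualify neither as start nor as stop.
#'
#' @param cdna Nucleotide sequence (character scalar, case-insensitive).
#' @param transcript_id Optional id recorded on the result.
#' @return An object of class `orf` with elements `transcript_id`,
#'   `tx_start`, `tx_end` (0-based half-open, transcript-relative) and
#'   `length_nt`, or `NULL` if the sequence contains no complete ORF.
#' @examples
#' longest_orf("ATGAAATAG")  # 9 nt at position 0
#' longest_orf("CCCCCC")     # NULL
#' @export
longest_orf <- function(cdna, transcript_id = NA_character_) {
  if (is.null(cdna) || !nzchar(cdna)) return(NULL)
  s <- toupper(cdna)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < 2L) next
    pos <- f + 3L * (seq_len(n_cod) - 1L)           # 0-based codon starts
    codons <- substring(s, pos + 1L, pos + 3L)
    atg_i <- which(codons == "ATG")
    stop_i <- which(codons %in% stops)
    if (!length(atg_i) || !length(stop_i)) next
    # next in-frame stop at or after each ATG (strictly after: an ATG is not
    # a stop, so "at or after" and "after" coincide)
    nxt <- findInterval(atg_i, stop_i) + 1L
    ok <- nxt <= length(stop_i)
    if (!any(ok)) next
    atg_i <- atg_i[ok]
    stop_at <- stop_i[nxt[ok]]
    lens <- (stop_at - atg_i + 1L) * 3L
    starts0 <- pos[atg_i]
    for (k in seq_along(lens)) {
      if (is.null(best) || lens[k] > best$length_nt ||
          (lens[k] == best$length_nt && starts0[k] < best$tx_start)) {
        best <- list(tx_start = starts0[k],
                     tx_end = starts0[k] + lens[k],
                     length_nt = lens[k])
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(c(list(transcript_id = transcript_id), best), class = "orf")
}

#' @export
print.orf <- function(x, ...) {
  cat(sprintf("orf%s: [%d, %d) %d nt\n",
              if (is.na(x$transcript_id)) "" else paste0(" ", x$transcript_id),
              x$tx_start, x$tx_end, x$length_nt))
  invisible(x)
}

#' Project an ORF onto genome coordinates
#'
#' Maps the transcript-relative ORF interval through the transcript's exon
#' chain, honouring strand (on `-`, transcript position 0 maps to the
#' highest genomic exon base).
#'
#' @param t A [transcript_model].
#' @param orf An `orf` from [longest_orf()].
#' @return Two-column matrix of genomic CDS intervals (ascending); total
#'   width equals `orf$length_nt`.
#' @export
project_orf <- function(t, orf) {
  if (is.null(orf)) stop("orf is NULL")
  if (orf$tx_end > tx_exonic_len(t))
    stop("ORF of ", t$id, " extends past the transcript length")
  map_tx_to_genome(t, orf$tx_start, orf$tx_end)
}
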