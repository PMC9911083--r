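#' Extrinsic hint sets
#'
#' A hint is a located evidence atom: an intron (full intron span) or a
#' start/stop codon (3-bp interval), from RNA-Seq or protein alignments,
#' with a multiplicity (read/protein support count). A hint set holds one
#' record per (seq_id, kind, start, end, strand, source) key; constructing
#' one collapses duplicate keys by summing multiplicities.
#'
#' @param seq_id,start,end,strand Hint locations (0-based half-open).
#' @param kind `"intron"`, `"start"` or `"stop"`.
#' @param source `"rnaseq"` or `"protein"`.
#' @param mult Multiplicities (integer, >= 1).
#' @return A data frame of class `hint_set`.
#' @export
hint_set <- function(seq_id = character(0), kind = character(0),
                     start = numeric(0), end = numeric(0),
                     strand = character(0), source = character(0),
                     mult = integer(0)) {
  df <- data.frame(seq_id = as.character(seq_id), kind = as.character(kind),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   source = as.character(source), mult = as.numeric(mult),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$kind %in% c("intron", "start", "stop")),
              all(df$source %in% c("rnaseq", "protein")),
              all(df$mult >= 1), all(df$start < df$end))
    key <- paste(hint_keys(df), df$source)
    if (anyDuplicated(key)) {
      df <- do.call(rbind, lapply(split(df, key), function(d) {
        d$mult[1L] <- sum(d$mult); d[1L, , drop = FALSE]
      }))
    }
    df <- df[order(df$seq_id, df$kind, df$start, df$end, df$strand, df$source), ]
    rownames(df) <- NULL
  }
  class(df) <- c("hint_set", "data.frame")
  df
}

#' Location keys of a hint set
#' @param h A `hint_set` (or compatible data frame).
#' @return Character keys `seq:kind:start-end(strand)`, one per row.
#' @export
hint_keys <- function(h) {
  if (!nrow(h)) return(character(0))
  sprintf("%s:%s:%d-%d(%s)", h$seq_id, h$kind, as.integer(h$start),
          as.integer(h$end), h$strand)
}

#' Tally intron hints from spliced alignments
#'
#' Each distinct intron key found in the models becomes one hint whose
#' multiplicity is the number of models containing it.
#'
#' @param models List of [transcript_model] objects (e.g. spliced RNA-Seq
#'   read models or assembled transcripts).
#' @param source Source tag for the resulting hints.
#' @return A `hint_set` of intron hints.
#' @export
introns_from_alignments <- function(models, source = "rnaseq") {
  rows <- lapply(models, function(t) {
    ii <- tx_introns(t)
    if (!nrow(ii)) return(NULL)
    data.frame(seq_id = t$seq_id, kind = "intron", start = ii[, 1L],
               end = ii[, 2L], strand = t$strand, source = source,
               mult = 1, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(hint_set())
  hint_set(rows$seq_id, rows$kind, rows$start, rows$end, rows$strand,
           rows$source, rows$mult)
}

#' Filter hints on multiplicity
#'
#' @param h A `hint_set`.
#' @param min_multiplicity Inclusive threshold (e.g. 3 for the standard
#'   intron-coverage filter, 100 for the training tier); must be >= 1.
#' @return The subset with `mult >= min_multiplicity`.
#' @export
filter_hints <- function(h, min_multiplicity) {
  if (min_multiplicity < 1) stop("min_multiplicity must be >= 1")
  out <- h[h$mult >= min_multiplicity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect RNA-Seq and protein hint sets
#'
#' Returns intron hints whose location key occurs in both sets (the
#' high-confidence tier); start/stop hints never intersect across kinds.
#' The combined multiplicity is the pairwise minimum.
#'
#' @param rnaseq,protein `hint_set` objects.
#' @return A `hint_set` with `source = "rnaseq"` dropped in favour of a
#'   single record per shared key, tagged by the first argument's source.
#' @export
intersect_hints <- function(rnaseq, protein) {
  a <- rnaseq[rnaseq$kind == "intron", , drop = FALSE]
  b <- protein[protein$kind == "intron", , drop = FALSE]
  ka <- hint_keys(a); kb <- hint_keys(b)
  shared <- intersect(ka, kb)
  out <- a[match(shared, ka), , drop = FALSE]
  if (nrow(out)) out$mult <- pmin(out$mult, b$mult[match(shared, kb)])
  rownames(out) <- NULL
  class(out) <- c("hint_set", "data.frame")
  out
}

#' Merge two hint sets
#'
#' Key union; the same location key arriving from two different sources is
#' kept as two source-tagged records, while records sharing both key and
#' source are collapsed by summing multiplicities.
#'
#' @param a,b `hint_set` objects.
#' @return The merged `hint_set`.
#' @export
merge_hints <- function(a, b) {
  both <- rbind(as.data.frame(a), as.data.frame(b))
  if (!nrow(both)) return(hint_set())
  hint_set(both$seq_id, both$kind, both$start, both$end, both$strand,
           both$source, both$mult)
}

#' Read hints from an AUGUSTUS-style GFF file
#'
#' Expects features `intron`, `start` or `stop` with attributes `src=`
#' (`E` for RNA-Seq, `P` for protein) and `mult=` (defaults to 1).
#'
#' @param path GFF file.
#' @return A `hint_set`.
#' @export
read_hints_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  if (!all(type %in% c("intron", "start", "stop")))
    stop("unexpected hint feature type(s): ",
         paste(setdiff(unique(type), c("intron", "start", "stop")), collapse = ", "))
  src <- if ("src" %in% names(mc)) as.character(mc$src) else rep("E", length(gr))
  mult <- if ("mult" %in% names(mc))
    suppressWarnings(as.numeric(as.character(mc$mult))) else rep(1, length(gr))
  mult[is.na(mult)] <- 1
  hint_set(as.character(GenomicRanges::seqnames(gr)), type,
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           as.character(GenomicRanges::strand(gr)),
           ifelse(src == "P", "protein", "rnaseq"), mult)
}

#' Write hints to an AUGUSTUS-style GFF file
#' @param h A `hint_set`.
#' @param path Output file.
#' @export
write_hints_gff <- function(h, path) {
  if (!nrow(h)) { writeLines("##gff-version 3", path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(h$seq_id,
                               IRanges::IRanges(h$start + 1L, h$end),
                               strand = h$strand)
  S4Vectors::mcols(gr)$type <- h$kind
  S4Vectors::mcols(gr)$src <- ifelse(h$source == "protein", "P", "E")
  S4Vectors::mcols(gr)$mult <- as.integer(h$mult)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
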