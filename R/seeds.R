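#' Combine predicted genes and Iso-Seq ORFs into seed regions
#'
#' Non-overlapping members of the two inputs pass through. Where an Iso-Seq
#' ORF and a prediction overlap on the same strand (CDS genomic spans,
#' >= 1 bp), the Iso-Seq seed is kept only when its ORF is strictly more
#' than `margin` nt longer than the prediction's CDS; otherwise the
#' prediction is kept. When one Iso-Seq seed overlaps several predictions
#' the rule is applied against the longest-CDS prediction, and all
#' overlapped members of the losing side are removed. Both inputs must be
#' internally non-overlapping (contract of the upstream stages).
#'
#' @param predictions List of [transcript_model] objects with CDS
#'   (`source = "prediction"`).
#' @param isoseq_orfs List of `aligned_isoform` objects (the nonoverlapping
#'   representative set) or [transcript_model] objects with CDS.
#' @param margin Length advantage (nt) the Iso-Seq ORF must strictly exceed.
#' @return List of seed records, each `list(origin, model, cds_len_nt)` with
#'   `origin` in `{"prediction", "isoseq"}`; no two seeds overlap on the
#'   same strand.
#' @export
combine_seeds <- function(predictions, isoseq_orfs, margin = 50) {
  iso_models <- lapply(isoseq_orfs, function(x) {
    if (inherits(x, "aligned_isoform")) isoform_to_model(x) else x
  })
  for (t in c(predictions, iso_models))
    if (tx_cds_len(t) <= 0) stop("seed candidate ", t$id, " has no CDS")
  check_nonoverlap(predictions, "predictions")
  check_nonoverlap(iso_models, "isoseq_orfs")

  pred_keep <- rep(TRUE, length(predictions))
  iso_keep <- rep(TRUE, length(iso_models))
  pred_len <- vapply(predictions, tx_cds_len, numeric(1L))
  iso_len <- vapply(iso_models, tx_cds_len, numeric(1L))

  ov <- cds_span_overlaps(iso_models, predictions)
  if (nrow(ov)) {
    for (i in unique(ov$query)) {
      opp <- ov$subject[ov$query == i]
      chief <- opp[which.max(pred_len[opp])]
      if (iso_len[i] - pred_len[chief] > margin) {
        pred_keep[opp] <- FALSE    # Iso-Seq wins: overlapped predictions go
      } else {
        iso_keep[i] <- FALSE       # prediction side wins: the Iso-Seq seed goes
      }
    }
  }
  c(lapply(predictions[pred_keep], function(t)
      list(origin = "prediction", model = t, cds_len_nt = tx_cds_len(t))),
    lapply(iso_models[iso_keep], function(t)
      list(origin = "isoseq", model = t, cds_len_nt = tx_cds_len(t))))
}

## same-strand CDS-span overlap pairs between two model lists
cds_span_overlaps <- function(a, b) {
  if (!length(a) || !length(b))
    return(data.frame(query = integer(0), subject = integer(0)))
  spa <- t(vapply(a, tx_cds_span, numeric(2L)))
  spb <- t(vapply(b, tx_cds_span, numeric(2L)))
  keya <- paste(vapply(a, `[[`, character(1L), "seq_id"),
                vapply(a, `[[`, character(1L), "strand"))
  keyb <- paste(vapply(b, `[[`, character(1L), "seq_id"),
                vapply(b, `[[`, character(1L), "strand"))
  out <- data.frame(query = integer(0), subject = integer(0))
  for (k in intersect(unique(keya), unique(keyb))) {
    ia <- which(keya == k); ib <- which(keyb == k)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(spa[ia, 1L] + 1L, spa[ia, 2L]),
      IRanges::IRanges(spb[ib, 1L] + 1L, spb[ib, 2L]), minoverlap = 1L)
    out <- rbind(out, data.frame(query = ia[S4Vectors::queryHits(hits)],
                                 subject = ib[S4Vectors::subjectHits(hits)]))
  }
  out
}

check_nonoverlap <- function(models, what) {
  ov <- cds_span_overlaps(models, models)
  ov <- ov[ov$query < ov$subject, , drop = FALSE]
  if (nrow(ov))
    stop(what, " contain same-strand overlapping CDS spans (e.g. ",
         models[[ov$query[1L]]]$id, " / ", models[[ov$subject[1L]]]$id,
         "); inputs to combine_seeds must be internally nonoverlapping")
}

#' Write seed regions to GFF3
#' @param seeds Result of [combine_seeds()].
#' @param path Output file.
#' @export
write_seeds_gff3 <- function(seeds, path) {
  models <- lapply(seeds, function(s) {
    t <- s$model
    t$attributes["seed_origin"] <- s$origin
    t
  })
  write_gff3(models, path)
}
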