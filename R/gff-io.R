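## GFF3 / BED12 readers and writers for transcript models.
## All parsing is delegated to rtracklayer; this layer resolves the
## gene/mRNA/exon/CDS hierarchy and converts between the 1-based inclusive
## file convention and the internal 0-based half-open one.

std_gff_cols <- c("source", "type", "score", "phase", "ID", "Name", "Parent")

first_parent <- function(parent_list) {
  vapply(parent_list, function(p) if (length(p)) p[[1L]] else NA_character_,
         character(1L))
}

#' Read gene models from GFF3
#'
#' Expects a gene/mRNA/exon/CDS hierarchy with 1-based inclusive coordinates;
#' coordinates are converted to the internal 0-based half-open convention and
#' parent/child links are resolved. Extra attributes on mRNA features (for
#' example `identity` and `coverage` on Iso-Seq alignments) are kept on the
#' transcript. Duplicate feature IDs and unresolvable Parent references are
#' hard errors: evidence matching downstream is ID-sensitive.
#'
#' @param path GFF3 file.
#' @param source Label recorded on every transcript: `"prediction"` or
#'   `"isoseq"`.
#' @return List of [transcript_model] objects, ordered by
#'   (seq_id, span start, id).
#' @export
read_gff3 <- function(path, source = c("prediction", "isoseq")) {
  source <- match.arg(source)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) as.list(mc$Parent) else
    rep(list(character(0)), length(gr))

  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  named_ids <- ids[(is_gene | is_mrna) & !is.na(ids)]
  if (anyDuplicated(named_ids))
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(unique(named_ids[duplicated(named_ids)]), collapse = ", "))

  gene_ids <- ids[is_gene]
  mrna_idx <- which(is_mrna)
  if (!length(mrna_idx)) return(list())

  mrna_parent <- first_parent(parents[mrna_idx])
  bad <- !is.na(mrna_parent) & !(mrna_parent %in% gene_ids)
  if (any(bad))
    stop("mRNA feature(s) with unresolvable Parent: ",
         paste(sprintf("%s -> %s", ids[mrna_idx][bad], mrna_parent[bad]),
               collapse = ", "))

  extra_cols <- setdiff(names(mc), std_gff_cols)
  seqn <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  strands[strands == "*"] <- "*"
  starts0 <- GenomicRanges::start(gr) - 1L
  ends0 <- GenomicRanges::end(gr)

  child_parent <- first_parent(parents)
  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  orphan <- (is_exon | is_cds) &
    (is.na(child_parent) | !(child_parent %in% ids[mrna_idx]))
  if (any(orphan))
    stop("exon/CDS feature(s) with unresolvable Parent in ", path, ": ",
         paste(unique(child_parent[orphan]), collapse = ", "))

  models <- lapply(mrna_idx, function(i) {
    tid <- ids[i]
    if (is.na(tid)) stop("mRNA feature without ID in ", path)
    gid <- mrna_parent[match(i, mrna_idx)]
    if (is.na(gid)) gid <- tid
    ex <- which(is_exon & child_parent == tid)
    cd <- which(is_cds & child_parent == tid)
    if (!length(ex)) stop("transcript ", tid, " has no exon features")
    attrs <- character(0)
    for (cn in extra_cols) {
      v <- mc[[cn]][i]
      if (is.list(v) || methods::is(v, "List")) v <- unlist(v)[1L]
      if (length(v) == 1L && !is.na(v)) attrs[cn] <- as.character(v)
    }
    transcript_model(
      id = tid, gene_id = gid, seq_id = seqn[i],
      strand = if (strands[i] %in% c("+", "-")) strands[i] else "*",
      exons = cbind(starts0[ex], ends0[ex]),
      cds = if (length(cd)) cbind(starts0[cd], ends0[cd]) else NULL,
      source = source, attributes = attrs)
  })
  sort_models(models)
}

sort_models <- function(models) {
  if (!length(models)) return(models)
  key <- order(vapply(models, `[[`, character(1L), "seq_id"),
               vapply(models, function(t) tx_span(t)[1L], numeric(1L)),
               vapply(models, `[[`, character(1L), "id"))
  models[key]
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: emits gene/mRNA/exon/CDS features with 1-based
#' inclusive coordinates, CDS phases, and transcript attributes, such that a
#' read/write/read round trip reproduces the models exactly.
#'
#' @param models List of [transcript_model] objects.
#' @param path Output file.
#' @export
write_gff3 <- function(models, path) {
  models <- sort_models(models)
  rows <- list()
  attr_names <- unique(unlist(lapply(models, function(t) names(t$attributes))))
  # gene features span all transcripts sharing a gene_id; a gene id that
  # collides with a transcript id (e.g. BED12-derived models) is suffixed
  # to keep feature IDs unique in the file
  gids <- vapply(models, `[[`, character(1L), "gene_id")
  tids <- vapply(models, `[[`, character(1L), "id")
  for (g0 in unique(gids)) {
    members <- models[gids == g0]
    g <- if (g0 %in% tids) paste0(g0, ".gene") else g0
    spans <- vapply(members, tx_span, numeric(2L))
    rows[[length(rows) + 1L]] <- data.frame(
      seq = members[[1L]]$seq_id, start = min(spans[1L, ]) + 1L,
      end = max(spans[2L, ]), strand = members[[1L]]$strand,
      type = "gene", ID = g, Parent = NA_character_, phase = NA_integer_,
      stringsAsFactors = FALSE)
    for (t in members) {
      sp <- tx_span(t)
      base <- data.frame(seq = t$seq_id, start = NA_real_, end = NA_real_,
                         strand = t$strand, type = NA_character_,
                         ID = NA_character_, Parent = NA_character_,
                         phase = NA_integer_, stringsAsFactors = FALSE)
      mr <- base; mr$start <- sp[1L] + 1L; mr$end <- sp[2L]
      mr$type <- "mRNA"; mr$ID <- t$id; mr$Parent <- g
      for (an in attr_names) mr[[an]] <- unname(t$attributes[an])
      rows[[length(rows) + 1L]] <- mr
      for (i in seq_len(nrow(t$exons))) {
        r <- base; r$start <- t$exons[i, 1L] + 1L; r$end <- t$exons[i, 2L]
        r$type <- "exon"; r$Parent <- t$id
        rows[[length(rows) + 1L]] <- r
      }
      if (!is.null(t$cds)) {
        n <- nrow(t$cds)
        ord <- if (t$strand == "-") rev(seq_len(n)) else seq_len(n)
        cum <- 0L
        phase <- integer(n)
        for (j in ord) {
          phase[j] <- (3L - (cum %% 3L)) %% 3L
          cum <- cum + (t$cds[j, 2L] - t$cds[j, 1L])
        }
        for (i in seq_len(n)) {
          r <- base; r$start <- t$cds[i, 1L] + 1L; r$end <- t$cds[i, 2L]
          r$type <- "CDS"; r$Parent <- t$id; r$phase <- phase[i]
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    for (an in attr_names) if (is.null(r[[an]])) r[[an]] <- NA_character_
    r[, c("seq", "start", "end", "strand", "type", "ID", "Parent", "phase",
          attr_names), drop = FALSE]
  }))
  gr <- GenomicRanges::GRanges(df$seq, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- df$phase
  for (an in attr_names) S4Vectors::mcols(gr)[[an]] <- df[[an]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read Iso-Seq alignments from BED12
#'
#' Converts blockStarts/blockSizes to exon chains. The BED name column is
#' used as both transcript and gene identifier; models are tagged
#' `source = "isoseq"`.
#'
#' @param path BED12 file.
#' @return List of [transcript_model] objects.
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mc <- S4Vectors::mcols(gr)
  if (!"blocks" %in% names(mc))
    stop(path, " is not BED12 (no block structure)")
  seqn <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  models <- lapply(seq_along(gr), function(i) {
    bl <- mc$blocks[[i]]
    # blocks are 1-based offsets within the record's span
    off <- GenomicRanges::start(gr)[i] - 1L   # 0-based record start
    exons <- cbind(off + IRanges::start(bl) - 1L, off + IRanges::end(bl))
    transcript_model(id = mc$name[i], gene_id = mc$name[i], seq_id = seqn[i],
                     strand = if (strands[i] %in% c("+", "-")) strands[i] else "*",
                     exons = exons, source = "isoseq")
  })
  sort_models(models)
}
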