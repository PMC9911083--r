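# Independent reference implementations ("oracles") and small builders used
# across the suite. Oracles are deliberately naive: brute-force enumeration
# and per-base bookkeeping, sharing no code with the package internals.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute force: try every ATG, walk codon by codon to the first stop
orf_oracle <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (a in seq_len(max(0L, n - 2L))) {
    if (substring(s, a, a + 2L) != "ATG") next
    p <- a + 3L
    while (p + 2L <= n) {
      cod <- substring(s, p, p + 2L)
      if (cod %in% stops) {
        len <- p + 3L - a
        if (is.null(best) || len > best$length_nt ||
            (len == best$length_nt && (a - 1L) < best$tx_start))
          best <- list(tx_start = a - 1L, tx_end = a - 1L + len, length_nt = len)
        break
      }
      p <- p + 3L
    }
  }
  best
}

# per-base projection: list every transcript base's genomic coordinate,
# then take the slice
projection_oracle <- function(t, s, e) {
  g <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    seq(t$exons[i, 1L], t$exons[i, 2L] - 1L)))
  if (t$strand == "-") g <- rev(g)
  picked <- sort(g[(s + 1L):e])
  runs <- split(picked, cumsum(c(1L, diff(picked) != 1L)))
  do.call(rbind, lapply(runs, function(r) c(min(r), max(r) + 1L)))
}

# connected components of the same-strand span-overlap graph by repeated BFS
component_oracle <- function(spans, seqs, strands) {
  n <- nrow(spans)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  overlaps <- function(i, j) {
    seqs[i] == seqs[j] && strands[i] == strands[j] &&
      spans[i, 1L] < spans[j, 2L] && spans[j, 1L] < spans[i, 2L]
  }
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      for (w in seq_len(n))
        if (is.na(comp[w]) && overlaps(v, w)) queue <- c(queue, w)
    }
  }
  comp
}

# literal restatement of the representative-selection rules
representatives_oracle <- function(isoforms, min_lorf = 300, max_intron = 10000) {
  isoforms <- Filter(function(x) !is.null(x$lorf), isoforms)
  if (!length(isoforms)) return(isoforms)
  spans <- t(sapply(isoforms, function(x) tx_span(x$transcript)))
  seqs <- sapply(isoforms, function(x) x$transcript$seq_id)
  strands <- sapply(isoforms, function(x) x$transcript$strand)
  comp <- component_oracle(spans, seqs, strands)
  keep <- c()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    lens <- sapply(isoforms[idx], function(x) x$lorf$length_nt)
    ids <- sapply(isoforms[idx], function(x) x$transcript$id)
    o <- order(-lens, spans[idx, 1L], ids)
    keep <- c(keep, idx[o[1L]])
  }
  out <- isoforms[sort(keep)]
  Filter(function(x) {
    ii <- tx_introns(x$transcript)
    x$lorf$length_nt >= min_lorf &&
      (nrow(ii) == 0L || max(ii[, 2L] - ii[, 1L]) <= max_intron)
  }, out)
}

# literal restatement of the support rules, structured around plain loops
support_oracle <- function(t, isoforms, rnaseq_hints, protein_hints,
                           min_overlap = 1L) {
  key_of <- function(seq, kind, a, b, strand)
    paste(seq, kind, a, b, strand, sep = "|")
  hk <- function(h) {
    if (!nrow(h)) return(character(0))
    mapply(key_of, h$seq_id, h$kind, h$start, h$end, h$strand, USE.NAMES = FALSE)
  }
  tkeys <- function(tt) {
    ii <- tx_introns(tt)
    if (!nrow(ii)) return(character(0))
    mapply(key_of, tt$seq_id, "intron", ii[, 1L], ii[, 2L], tt$strand,
           USE.NAMES = FALSE)
  }
  tk <- tkeys(t)
  sp <- tx_cds_span(t)
  multi <- nrow(t$exons) >= 2L
  rk <- hk(rnaseq_hints[rnaseq_hints$kind == "intron", , drop = FALSE])
  pik <- hk(protein_hints[protein_hints$kind == "intron", , drop = FALSE])
  if (t$strand == "-") {
    skey <- key_of(t$seq_id, "start", sp[2L] - 3, sp[2L], t$strand)
    ekey <- key_of(t$seq_id, "stop", sp[1L], sp[1L] + 3, t$strand)
  } else {
    skey <- key_of(t$seq_id, "start", sp[1L], sp[1L] + 3, t$strand)
    ekey <- key_of(t$seq_id, "stop", sp[2L] - 3, sp[2L], t$strand)
  }
  s_hit <- skey %in% hk(protein_hints[protein_hints$kind == "start", , drop = FALSE])
  e_hit <- ekey %in% hk(protein_hints[protein_hints$kind == "stop", , drop = FALSE])

  lev <- function(full, part) if (full) "full" else if (part) "partial" else "none"
  if (multi) {
    rnaseq <- lev(length(tk) > 0 && all(tk %in% rk), any(tk %in% rk))
    protein <- lev(length(tk) > 0 && all(tk %in% pik),
                   any(tk %in% pik) || s_hit || e_hit)
  } else {
    rnaseq <- "none"
    protein <- lev(s_hit && e_hit, s_hit || e_hit)
  }
  iso_full <- FALSE
  ov <- 0  # per-isoform maximum: "overlap with AN Iso-Seq ORF"
  for (iso in isoforms) {
    it <- iso$transcript
    if (it$seq_id != t$seq_id || it$strand != t$strand) next
    if (!is.null(iso$genome_cds)) {
      tot <- 0
      for (r in seq_len(nrow(iso$genome_cds))) {
        a <- max(iso$genome_cds[r, 1L], sp[1L])
        b <- min(iso$genome_cds[r, 2L], sp[2L])
        tot <- tot + max(0, b - a)
      }
      ov <- max(ov, tot)
    }
    if (multi) {
      ik <- tkeys(it)
      if (length(tk) && all(tk %in% ik)) {
        ii <- tx_introns(it)
        extras <- ii[!(ik %in% tk), , drop = FALSE]
        ok <- TRUE
        if (nrow(extras))
          for (r in seq_len(nrow(extras)))
            if (extras[r, 1L] < sp[2L] && extras[r, 2L] > sp[1L]) ok <- FALSE
        if (ok) iso_full <- TRUE
      }
    } else if (!is.null(iso$genome_cds)) {
      if (iso$genome_cds[1L, 1L] == sp[1L] &&
          iso$genome_cds[nrow(iso$genome_cds), 2L] == sp[2L]) iso_full <- TRUE
    }
  }
  isoseq <- lev(iso_full, ov >= min_overlap)
  list(isoseq = isoseq, rnaseq = rnaseq, protein = protein)
}

# quick builders -------------------------------------------------------------

mk_tx <- function(id, exons, strand = "+", seq_id = "chr1", cds = NULL,
                  gene_id = paste0(id, "_g"), source = "prediction",
                  attributes = character()) {
  transcript_model(id, gene_id, seq_id, strand, exons, cds = cds,
                   source = source, attributes = attributes)
}

mk_iso <- function(id, exons, lorf_len, strand = "+", seq_id = "chr1",
                   identity = 0.99, coverage = 0.99, lorf_start = 0L) {
  t <- mk_tx(id, exons, strand, seq_id, source = "isoseq")
  orf <- structure(list(transcript_id = id, tx_start = lorf_start,
                        tx_end = lorf_start + lorf_len, length_nt = lorf_len),
                   class = "orf")
  aligned_isoform(t, identity = identity, coverage = coverage, lorf = orf)
}

# random multi-exon transcript on a given strand
rand_tx <- function(id, seq_id = "chr1", strand = sample(c("+", "-"), 1L),
                    n_exons = sample(1:5, 1L), with_cds = FALSE) {
  starts <- cumsum(sample(50:500, n_exons * 2))
  exons <- cbind(starts[seq(1, 2 * n_exons, 2)], starts[seq(2, 2 * n_exons, 2)])
  mk_tx(id, exons, strand, seq_id, cds = if (with_cds) exons else NULL)
}
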