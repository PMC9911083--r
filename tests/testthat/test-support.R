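# a 3-exon prediction with CDS over all exons, plus hint/isoform builders
pred3 <- function() mk_tx("p", rbind(c(100, 200), c(300, 400), c(500, 600)),
                          cds = rbind(c(100, 200), c(300, 400), c(500, 600)))

intron_hints_for <- function(t, source) {
  ii <- tx_introns(t)
  hint_set(rep(t$seq_id, nrow(ii)), rep("intron", nrow(ii)),
           ii[, 1L], ii[, 2L], rep(t$strand, nrow(ii)),
           rep(source, nrow(ii)), rep(1, nrow(ii)))
}

test_that("an extra isoform intron inside the CDS span blocks full Iso-Seq support", {
  t <- mk_tx("p", rbind(c(100, 200), c(300, 400), c(500, 700), c(800, 900)),
             cds = rbind(c(100, 200), c(300, 400), c(500, 700), c(800, 900)))
  # isoform carries all 3 introns of t plus one extra inside t's CDS span
  iso_in <- mk_iso("iA", rbind(c(100, 200), c(300, 400), c(500, 550),
                               c(600, 700), c(800, 900)), 300,
                   lorf_start = 0L)
  rec <- classify_support(t, list(iso_in), hint_set(), hint_set())
  expect_equal(rec$isoseq, "partial")
  # same extra intron but outside the CDS span (in the isoform's UTR): full
  iso_out <- mk_iso("iB", rbind(c(50, 60), c(80, 200), c(300, 400),
                                c(500, 700), c(800, 950)), 300,
                    lorf_start = 60L)
  rec2 <- classify_support(t, list(iso_out), hint_set(), hint_set())
  expect_equal(rec2$isoseq, "full")
})

test_that("full RNA-Seq support needs every intron in the hint set", {
  t <- pred3()
  all_h <- intron_hints_for(t, "rnaseq")
  expect_equal(classify_support(t, list(), all_h, hint_set())$rnaseq, "full")
  one <- all_h[1L, , drop = FALSE]
  class(one) <- c("hint_set", "data.frame")
  expect_equal(classify_support(t, list(), one, hint_set())$rnaseq, "partial")
  expect_equal(classify_support(t, list(), hint_set(), hint_set())$rnaseq,
               "none")
})

test_that("single-exon protein support needs both start and stop hints", {
  t <- mk_tx("s", rbind(c(1000, 1600)), cds = rbind(c(1000, 1600)))
  start_h <- hint_set("chr1", "start", 1000, 1003, "+", "protein", 1)
  stop_h <- hint_set("chr1", "stop", 1597, 1600, "+", "protein", 1)
  both <- merge_hints(start_h, stop_h)
  expect_equal(classify_support(t, list(), hint_set(), start_h)$protein,
               "partial")
  expect_equal(classify_support(t, list(), hint_set(), both)$protein, "full")
  # minus strand: codons swap ends
  tm <- mk_tx("sm", rbind(c(1000, 1600)), strand = "-",
              cds = rbind(c(1000, 1600)))
  start_m <- hint_set("chr1", "start", 1597, 1600, "-", "protein", 1)
  stop_m <- hint_set("chr1", "stop", 1000, 1003, "-", "protein", 1)
  expect_equal(classify_support(tm, list(), hint_set(),
                                merge_hints(start_m, stop_m))$protein, "full")
})

test_that("single-exon Iso-Seq support requires exact projected lORF bounds", {
  t <- mk_tx("s", rbind(c(1000, 1600)), cds = rbind(c(1000, 1600)))
  exact <- mk_iso("ie", rbind(c(900, 1700)), 600, lorf_start = 100L)
  off <- mk_iso("io", rbind(c(900, 1700)), 600, lorf_start = 97L)
  expect_equal(classify_support(t, list(exact), hint_set(), hint_set())$isoseq,
               "full")
  expect_equal(classify_support(t, list(off), hint_set(), hint_set())$isoseq,
               "partial")   # 1-bp-shifted ORF still overlaps the CDS
})

test_that("a transcript matching nothing is unsupported", {
  rec <- classify_support(pred3(), list(), hint_set(), hint_set())
  expect_equal(unlist(rec[, c("isoseq", "rnaseq", "protein")],
                      use.names = FALSE), rep("none", 3L))
  expect_false(rec$any_support)
  expect_false(rec$fully_supported_any)
})

test_that("a transcript without CDS is a hard error", {
  t <- mk_tx("nocds", rbind(c(0, 300)))
  expect_error(classify_support(t, list(), hint_set(), hint_set()), "CDS")
})

test_that("classification equals the literal-rule oracle on random fixtures", {
  set.seed(55)
  for (round in 1:3) {
    fx <- generate_annotation_fixture(
      fixture_config(seed = 100 + round, n_genes = 40,
                     genome_length_bp = 320000))
    isoforms <- align_isoforms(fx$isoseq, fx$genome)
    got <- classify_support_all(fx$predictions, isoforms,
                                fx$rnaseq_hints, fx$protein_hints)
    for (i in seq_along(fx$predictions)) {
      want <- support_oracle(fx$predictions[[i]], isoforms,
                             fx$rnaseq_hints, fx$protein_hints)
      expect_equal(got$isoseq[i], want$isoseq, label = got$transcript_id[i])
      expect_equal(got$rnaseq[i], want$rnaseq, label = got$transcript_id[i])
      expect_equal(got$protein[i], want$protein, label = got$transcript_id[i])
    }
  }
})

test_that("adding hints never demotes a support level", {
  lvl <- c(none = 0L, partial = 1L, full = 2L)
  set.seed(66)
  fx <- generate_annotation_fixture(
    fixture_config(seed = 77, n_genes = 30, genome_length_bp = 250000,
                   rnaseq_intron_prob = 0.4, protein_intron_prob = 0.4))
  isoforms <- align_isoforms(fx$isoseq, fx$genome)
  base <- classify_support_all(fx$predictions, isoforms,
                               fx$rnaseq_hints, fx$protein_hints)
  # add every true intron as both hint kinds plus all start/stop hints
  full_r <- introns_from_alignments(fx$predictions, source = "rnaseq")
  full_p <- introns_from_alignments(fx$predictions, source = "protein")
  more <- classify_support_all(fx$predictions, isoforms,
                               merge_hints(fx$rnaseq_hints, full_r),
                               merge_hints(fx$protein_hints, full_p))
  expect_true(all(lvl[more$rnaseq] >= lvl[base$rnaseq]))
  expect_true(all(lvl[more$protein] >= lvl[base$protein]))
  expect_true(all(lvl[more$isoseq] == lvl[base$isoseq]))
})

test_that("training-gene selection is Iso-Seq-full OR protein-full", {
  rec <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    isoseq = c("full", "none", "none", "partial"),
    rnaseq = c("none", "full", "none", "full"),
    protein = c("none", "none", "full", "partial"),
    any_support = c(TRUE, TRUE, TRUE, TRUE),
    fully_supported_any = c(TRUE, TRUE, TRUE, FALSE))
  expect_setequal(select_training(rec), c("a", "c"))  # rnaseq-only excluded
  expect_length(select_training(rec[0, ]), 0L)
  # training set is a subset of the fully supported
  expect_true(all(select_training(rec) %in%
                    rec$transcript_id[rec$fully_supported_any]))
})

test_that("category counts partition the transcript total", {
  set.seed(88)
  fx <- generate_annotation_fixture(
    fixture_config(seed = 88, n_genes = 50, genome_length_bp = 400000))
  isoforms <- align_isoforms(fx$isoseq, fx$genome)
  rec <- classify_support_all(fx$predictions, isoforms,
                              fx$rnaseq_hints, fx$protein_hints)
  cc <- category_counts(rec)
  g <- function(k) cc$count[cc$category == k]
  expect_equal(g("fully_supported_any") + g("partial_any") + g("unsupported"),
               g("total"))
  expect_equal(g("total"), nrow(rec))
  # degenerate single record, full everywhere
  one <- data.frame(transcript_id = "x", isoseq = "full", rnaseq = "full",
                    protein = "full", any_support = TRUE,
                    fully_supported_any = TRUE)
  cc1 <- category_counts(one)
  expect_equal(cc1$count[cc1$category %in%
                           c("full_isoseq", "full_rnaseq", "full_protein")],
               c(1L, 1L, 1L))
  expect_equal(cc1$count[cc1$category == "unsupported"], 0L)
})
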