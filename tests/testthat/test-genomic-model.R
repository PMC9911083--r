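test_that("GFF3 coordinates convert to 0-based half-open and back", {
  gff <- c("##gff-version 3",
           "chr1\tx\tgene\t101\t350\t.\t+\t.\tID=g1",
           "chr1\tx\tmRNA\t101\t350\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tx\texon\t101\t200\t.\t+\t.\tParent=t1",
           "chr1\tx\texon\t251\t350\t.\t+\t.\tParent=t1",
           "chr1\tx\tCDS\t101\t200\t.\t+\t0\tParent=t1",
           "chr1\tx\tCDS\t251\t350\t.\t+\t2\tParent=t1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  models <- read_gff3(f)
  expect_length(models, 1L)
  t <- models[[1L]]
  # exon 101..200 (1-based inclusive) is (100, 200) internally, length 100
  expect_equal(t$exons[1L, ], c(100, 200), ignore_attr = TRUE)
  expect_equal(t$exons[1L, 2L] - t$exons[1L, 1L], 100)
  expect_equal(tx_cds_len(t), 200)
})

test_that("a gap between exons is one intron at the internal coordinates", {
  gff <- c("##gff-version 3",
           "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=g1",
           "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tx\texon\t1\t100\t.\t+\t.\tParent=t1",
           "chr1\tx\texon\t201\t300\t.\t+\t.\tParent=t1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  t <- read_gff3(f)[[1L]]
  expect_equal(tx_introns(t), cbind(start = 100, end = 200))
})

test_that("GFF3 round trip is lossless on a 20-gene synthetic fixture", {
  fx <- generate_annotation_fixture(
    fixture_config(seed = 11, n_genes = 20, genome_length_bp = 150000))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fx$truth, f)
  back <- read_gff3(f)
  expect_length(back, length(fx$truth))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$id, fx$truth[[i]]$id)
    expect_equal(back[[i]]$gene_id, fx$truth[[i]]$gene_id)
    expect_equal(back[[i]]$strand, fx$truth[[i]]$strand)
    expect_equal(back[[i]]$exons, fx$truth[[i]]$exons, ignore_attr = TRUE)
    expect_equal(back[[i]]$cds, fx$truth[[i]]$cds, ignore_attr = TRUE)
  }
  # attributes round-trip too (identity/coverage on isoforms)
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fx$isoseq, f2)
  back2 <- read_gff3(f2, source = "isoseq")
  expect_equal(
    vapply(back2, function(t) unname(t$attributes["identity"]), character(1L)),
    vapply(fx$isoseq, function(t) unname(t$attributes["identity"]), character(1L)))
})

test_that("malformed parent references and duplicate IDs are hard errors", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=gMISSING",
               "chr1\tx\texon\t1\t300\t.\t+\t.\tParent=t1"), f)
  expect_error(read_gff3(f), "Parent")

  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t1\t300\t.\t+\t.\tParent=t1",
               "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1"), f)
  expect_error(read_gff3(f), "duplicate")
})

test_that("CDS outside exons is rejected", {
  expect_error(mk_tx("t1", rbind(c(0, 100)), cds = rbind(c(50, 150))),
               "outside")
})

test_that("interval_length matches both conventions and the paper interval", {
  # printed candidate-locus bounds on Ra02
  expect_equal(interval_length(c(25901374, 37085204), "one_based_inclusive"),
               11183831)
  expect_equal(round_half_up(11183831 / 1e6, 1), 11.2)
  # single-base printed interval (5..5) has length 1
  expect_equal(interval_length(c(5, 5), "one_based_inclusive"), 1)
  expect_equal(interval_length(genomic_interval("c", 5, 6),
                               "one_based_inclusive"), 2)
  set.seed(42)
  for (i in 1:1000) {
    a <- sample.int(1e6, 1L); b <- a + sample.int(1e4, 1L)
    # brute force: count contained integer positions
    expect_equal(interval_length(c(a, b), "one_based_inclusive"),
                 length(a:b))
    expect_equal(interval_length(c(a, b)), length(a:b) - 1L)
  }
})

test_that("introns_of equals the pairwise-gap oracle on random transcripts", {
  set.seed(7)
  for (i in 1:50) {
    t <- rand_tx(paste0("t", i))
    ii <- tx_introns(t)
    expect_equal(nrow(ii), tx_n_exons(t) - 1L)
    if (nrow(ii)) {
      for (k in seq_len(nrow(ii))) {
        expect_equal(unname(ii[k, 1L]), t$exons[k, 2L])
        expect_equal(unname(ii[k, 2L]), t$exons[k + 1L, 1L])
      }
      # introns disjoint from exons
      for (k in seq_len(nrow(ii)))
        expect_true(all(ii[k, 2L] <= t$exons[, 1L] | ii[k, 1L] >= t$exons[, 2L]))
    }
  }
  expect_equal(nrow(tx_introns(mk_tx("s", rbind(c(0, 500))))), 0L)
})

test_that("BED12 blocks become exon chains", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 999, 2000, "isoA", 0, "+", 999, 2000, "0",
                     "2", "301,500", "0,501"), collapse = "\t"), f)
  m <- read_bed12(f)
  expect_length(m, 1L)
  expect_equal(m[[1L]]$exons, rbind(c(999, 1300), c(1500, 2000)),
               ignore_attr = TRUE)
  expect_equal(m[[1L]]$source, "isoseq")
})

test_that("masked FASTA round trip preserves case-encoded masking", {
  g <- masked_genome(c(s1 = "ACGTacgtNNacGT"))
  expect_equal(total_masked_bp(g), 6)
  f <- withr::local_tempfile(fileext = ".fa")
  write_masked_fasta(g, f)
  g2 <- read_masked_fasta(f)
  expect_equal(g2$seq, g$seq)
  expect_equal(g2$mask, g$mask)
})
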