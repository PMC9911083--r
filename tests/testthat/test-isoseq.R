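test_that("alignment filter boundaries are inclusive", {
  at <- function(idn, cov) mk_iso("x", rbind(c(0, 1000)), 300,
                                  identity = idn, coverage = cov)
  expect_length(filter_alignments(list(at(0.95, 0.90))), 1L)   # kept
  expect_length(filter_alignments(list(at(0.949, 0.95))), 0L)  # identity below
  expect_length(filter_alignments(list(at(0.96, 0.899))), 0L)  # coverage below
})

test_that("missing identity/coverage is a hard error naming the record", {
  t <- mk_tx("noattr", rbind(c(0, 1000)), source = "isoseq")
  iso <- aligned_isoform(t)
  expect_error(filter_alignments(list(iso)), "noattr")
})

test_that("alignment filter equals the predicate oracle on a mixed set", {
  set.seed(12)
  isos <- lapply(1:100, function(i)
    mk_iso(sprintf("i%03d", i), rbind(c(i * 2000, i * 2000 + 900)), 300,
           identity = runif(1, 0.90, 1), coverage = runif(1, 0.85, 1)))
  kept <- filter_alignments(isos)
  want <- Filter(function(x) x$identity >= 0.95 && x$coverage >= 0.90, isos)
  expect_equal(vapply(kept, function(x) x$transcript$id, character(1L)),
               vapply(want, function(x) x$transcript$id, character(1L)))
})

test_that("overlapping isoforms collapse to the longest-lORF representative", {
  a <- mk_iso("a", rbind(c(0, 1000)), 600)
  b <- mk_iso("b", rbind(c(500, 1500)), 450)
  reps <- select_representatives(list(a, b))
  expect_length(reps, 1L)
  expect_equal(reps[[1L]]$transcript$id, "a")
})

test_that("lORF-length and intron-length filters use strict boundaries", {
  ok <- mk_iso("ok", rbind(c(0, 1000)), 300)
  short <- mk_iso("short", rbind(c(5000, 6000)), 299)
  reps <- select_representatives(list(ok, short))
  expect_equal(vapply(reps, function(x) x$transcript$id, character(1L)), "ok")

  # intron of exactly 10,000 nt is retained; 10,001 is removed
  long_ok <- mk_iso("lok", rbind(c(0, 500), c(10500, 11000)), 400)
  long_bad <- mk_iso("lbad", rbind(c(20000, 20500), c(30501, 31000)), 400)
  reps2 <- select_representatives(list(long_ok, long_bad))
  expect_equal(vapply(reps2, function(x) x$transcript$id, character(1L)), "lok")
})

test_that("size filters run after representative choice (a locus can empty)", {
  # the long-lORF isoform wins its locus, then fails the intron filter;
  # the shorter isoform must NOT inherit the locus
  winner <- mk_iso("win", rbind(c(0, 500), c(11000, 12000)), 800)
  runner <- mk_iso("run", rbind(c(100, 600)), 500)
  reps <- select_representatives(list(winner, runner))
  expect_length(reps, 0L)
})

test_that("isoforms without an lORF are dropped before grouping", {
  t <- mk_tx("nol", rbind(c(0, 1000)), source = "isoseq")
  no_orf <- aligned_isoform(t, identity = 0.99, coverage = 0.99, lorf = NULL)
  with_orf <- mk_iso("yes", rbind(c(200, 900)), 350)
  reps <- select_representatives(list(no_orf, with_orf))
  expect_equal(vapply(reps, function(x) x$transcript$id, character(1L)), "yes")
})

test_that("representative selection equals the brute-force oracle", {
  set.seed(77)
  for (rep_i in 1:5) {
    isos <- lapply(1:200, function(i) {
      start <- sample.int(50000, 1L)
      n_ex <- sample(1:3, 1L)
      width <- sample(200:3000, n_ex)
      gaps <- if (n_ex > 1L) sample(c(50:200, 9950:10050), n_ex - 1L) else integer(0)
      starts <- start + c(0, cumsum(width[-n_ex] + gaps))
      exons <- cbind(starts, starts + width)
      mk_iso(sprintf("i%03d", i), exons,
             sample(150:min(600, sum(width)), 1L),
             strand = sample(c("+", "-"), 1L),
             seq_id = sample(c("c1", "c2"), 1L))
    })
    got <- select_representatives(isos)
    want <- representatives_oracle(isos)
    expect_equal(vapply(got, function(x) x$transcript$id, character(1L)),
                 vapply(want, function(x) x$transcript$id, character(1L)))
    # invariants: output within input, lORF >= 300, introns <= 10000,
    # same-strand spans pairwise disjoint
    for (x in got) {
      expect_gte(x$lorf$length_nt, 300)
      ii <- tx_introns(x$transcript)
      if (nrow(ii)) expect_lte(max(ii[, 2L] - ii[, 1L]), 10000)
    }
    key <- vapply(got, function(x)
      paste(x$transcript$seq_id, x$transcript$strand), character(1L))
    for (k in unique(key)) {
      sp <- t(vapply(got[key == k], function(x) tx_span(x$transcript),
                     numeric(2L)))
      if (nrow(sp) > 1L) {
        sp <- sp[order(sp[, 1L]), , drop = FALSE]
        expect_true(all(sp[-1L, 1L] >= sp[-nrow(sp), 2L]))
      }
    }
  }
})

test_that("identity/coverage percentages are auto-detected on GFF3 input", {
  fx <- generate_annotation_fixture(
    fixture_config(seed = 3, n_genes = 5, genome_length_bp = 60000,
                   isoseq_prob = 1))
  iso <- fx$isoseq[[1L]]
  iso$attributes["identity"] <- "97.5"  # percentage form
  iso$attributes["coverage"] <- "95"
  a <- align_isoforms(list(iso), fx$genome)[[1L]]
  expect_equal(a$identity, 0.975)
  expect_equal(a$coverage, 0.95)
})
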