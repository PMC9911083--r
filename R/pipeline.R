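#' Pipeline configuration
#'
#' Input paths plus every stage threshold, at the defaults the package is
#' built around: alignment identity/coverage 0.95/0.90, minimum lORF 300 nt,
#' maximum intron 10,000 nt, intron-hint coverage 3 (training tier 100),
#' seed margin 50 nt, marker missingness 0.05 and segregation alpha 0.05.
#'
#' @param genome_fasta Soft-masked genome FASTA.
#' @param predictions_gff GFF3 of predicted gene models (with CDS).
#' @param isoseq_gff GFF3 of aligned Iso-Seq transcripts carrying
#'   `identity=` and `coverage=` attributes (use `isoseq_bed12` instead for
#'   BED12 alignments).
#' @param rnaseq_hints_gff,protein_hints_gff Hint GFF files.
#' @param out_dir Run directory for stage outputs and the manifest.
#' @param isoseq_bed12 Optional BED12 alternative to `isoseq_gff`.
#' @param markers_tsv Optional dosage matrix; adds the marker-filter stage.
#' @param min_identity,min_coverage,min_lorf,max_intron,min_cov,training_cov,seed_margin,min_overlap,max_missing,alpha
#'   Stage thresholds (see module functions).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, predictions_gff, isoseq_gff = NULL,
                            rnaseq_hints_gff = NULL, protein_hints_gff = NULL,
                            out_dir = tempfile("annoweave_run"),
                            isoseq_bed12 = NULL, markers_tsv = NULL,
                            min_identity = 0.95, min_coverage = 0.90,
                            min_lorf = 300, max_intron = 10000,
                            min_cov = 3, training_cov = 100,
                            seed_margin = 50, min_overlap = 1L,
                            max_missing = 0.05, alpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the evidence-integration pipeline
#'
#' Executes the stages in order — Iso-Seq ORF detection, alignment
#' filtering, representative-isoform selection, mask refinement, hint
#' filtering/merging/intersection, seed combination, support
#' classification, and summary statistics (plus single-dose marker
#' filtering when a dosage matrix is supplied) — writing each stage's
#' output in a standard format under `out_dir` together with a
#' machine-readable JSON manifest of per-stage record counts.
#'
#' @param cfg A [pipeline_config].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("read_genome", read_masked_fasta(cfg$genome_fasta))
  predictions <- stage("read_predictions",
                       read_gff3(cfg$predictions_gff, source = "prediction"))
  iso_models <- stage("read_isoseq", {
    if (!is.null(cfg$isoseq_bed12)) read_bed12(cfg$isoseq_bed12)
    else if (!is.null(cfg$isoseq_gff)) read_gff3(cfg$isoseq_gff, source = "isoseq")
    else list()
  })
  counts$predictions <- length(predictions)
  counts$isoseq_alignments <- length(iso_models)

  isoforms <- stage("orfs", align_isoforms(iso_models, genome))
  counts$isoforms_with_lorf <-
    sum(vapply(isoforms, function(x) !is.null(x$lorf), logical(1L)))
  filtered <- stage("filter_alignments",
                    if (length(isoforms))
                      filter_alignments(isoforms, cfg$min_identity,
                                        cfg$min_coverage) else isoforms)
  counts$isoforms_passing_alignment_filter <- length(filtered)
  reps <- stage("select_representatives",
                select_representatives(filtered, cfg$min_lorf, cfg$max_intron))
  counts$representative_isoforms <- length(reps)
  if (length(reps))
    write_gff3(lapply(reps, isoform_to_model),
               file.path(cfg$out_dir, "representatives.gff3"))

  rnaseq_raw <- stage("read_rnaseq_hints",
                      if (is.null(cfg$rnaseq_hints_gff)) hint_set()
                      else read_hints_gff(cfg$rnaseq_hints_gff))
  protein <- stage("read_protein_hints",
                   if (is.null(cfg$protein_hints_gff)) hint_set()
                   else read_hints_gff(cfg$protein_hints_gff))
  rnaseq <- stage("filter_hints", filter_hints(rnaseq_raw, cfg$min_cov))
  counts$rnaseq_hints <- nrow(rnaseq)
  counts$rnaseq_hints_training_tier <-
    nrow(filter_hints(rnaseq_raw, cfg$training_cov))
  counts$protein_hints <- nrow(protein)
  merged <- stage("merge_hints", merge_hints(protein, rnaseq))
  high_conf <- stage("intersect_hints", intersect_hints(rnaseq, protein))
  counts$merged_hints <- nrow(merged)
  counts$high_confidence_introns <- nrow(high_conf)
  write_hints_gff(merged, file.path(cfg$out_dir, "hints_merged.gff"))
  write_hints_gff(high_conf, file.path(cfg$out_dir, "hints_high_confidence.gff"))

  refine <- stage("refine_mask", {
    orfs <- supported_orf_table(reps, rnaseq, protein)
    refine_mask(genome, orfs)
  })
  counts$unmasked_bp <- refine$report$unmasked_bp
  counts$unmasked_loci <- refine$report$n_loci
  write_masked_fasta(refine$genome, file.path(cfg$out_dir, "genome_refined.fasta"))
  utils::write.table(refine$report$per_sequence,
                     file.path(cfg$out_dir, "mask_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seeds <- stage("combine_seeds",
                 combine_seeds(predictions, reps, margin = cfg$seed_margin))
  counts$seeds <- length(seeds)
  counts$seeds_isoseq <-
    sum(vapply(seeds, function(s) s$origin == "isoseq", logical(1L)))
  write_seeds_gff3(seeds, file.path(cfg$out_dir, "seeds.gff3"))

  support <- stage("classify", classify_support_all(
    predictions, filtered, rnaseq, protein, min_overlap = cfg$min_overlap))
  cat_tab <- category_counts(support)
  training <- select_training(support)
  counts$training_genes <- length(training)
  for (i in seq_len(nrow(cat_tab)))
    counts[[cat_tab$category[i]]] <- cat_tab$count[i]
  utils::write.table(support, file.path(cfg$out_dir, "support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cat_tab, file.path(cfg$out_dir, "category_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(training, file.path(cfg$out_dir, "training_ids.txt"))

  summary <- stage("stats", summarize_annotation(predictions, support))
  counts$n_genes <- summary$n_genes
  counts$n_transcripts <- summary$n_transcripts

  if (!is.null(cfg$markers_tsv)) {
    sdm <- stage("filter_markers",
                 filter_single_dose(read_dosage_tsv(cfg$markers_tsv),
                                    cfg$max_missing, cfg$alpha))
    counts$markers_in <- nrow(sdm$audit)
    counts$markers_retained <- nrow(sdm$markers)
    utils::write.table(sdm$audit, file.path(cfg$out_dir, "marker_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_dosage_tsv(sdm$markers, file.path(cfg$out_dir, "markers_retained.tsv"))
  }

  manifest <- list(
    package = "annoweave",
    version = as.character(utils::packageVersion("annoweave")),
    config = { c0 <- unclass(cfg); c0[!vapply(c0, is.null, logical(1L))] },
    counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
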