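#' Soft-masked genome
#'
#' Named nucleotide sequences with a per-base masking flag. On FASTA I/O the
#' flag is encoded as lowercase; internally residues are held uppercase and
#' the mask as a logical vector, so residue identity is case-invariant under
#' any mask operation.
#'
#' @param seqs Named character vector of sequences; lowercase letters are
#'   read as masked.
#' @return An object of class `masked_genome` with elements `seq` (uppercase
#'   character vector) and `mask` (list of logical vectors).
#' @examples
#' g <- masked_genome(c(chr1 = "ACGTacgtNN"))
#' total_masked_bp(g)
#' @export
masked_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  mask <- lapply(unname(seqs), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch %in% letters
  })
  names(mask) <- names(seqs)
  structure(list(seq = toupper(seqs), mask = mask), class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf("masked_genome: %d sequence(s), %s bp total, %s bp masked\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ","),
              format(total_masked_bp(x), big.mark = ",")))
  invisible(x)
}

#' Total soft-masked bases in a genome
#' @param genome A [masked_genome].
#' @export
total_masked_bp <- function(genome) sum(vapply(genome$mask, sum, numeric(1L)))

## re-apply lowercase masking to get FASTA-ready strings
masked_strings <- function(genome) {
  out <- vapply(names(genome$seq), function(nm) {
    ch <- strsplit(genome$seq[[nm]], "", fixed = TRUE)[[1L]]
    m <- genome$mask[[nm]]
    ch[m] <- tolower(ch[m])
    paste(ch, collapse = "")
  }, character(1L))
  out
}

#' Read a soft-masked FASTA file
#' @param path FASTA file; lowercase encodes masking.
#' @return A [masked_genome].
#' @export
read_masked_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  # FASTA headers may carry descriptions; the sequence name is the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  masked_genome(seqs)
}

#' Write a soft-masked FASTA file
#' @param genome A [masked_genome].
#' @param path Output path.
#' @export
write_masked_fasta <- function(genome, path) {
  x <- Biostrings::BStringSet(masked_strings(genome))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
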