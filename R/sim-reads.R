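## Read synthesis from true genotypes.

# haplotype chromosome sequences for one sample: splice each allele array
# into the reference genome. hap is 1 or 2. Returns named character vector
# (possibly missing chromosomes absent from that haplotype).
haplotype_seqs <- function(truth, ref, sample, hap, sex) {
  g <- truth$genotypes[truth$genotypes$sample == sample, ]
  loci <- ref$loci
  out <- character(0)
  for (ch in names(ref$genome)) {
    ct <- chrom_type(ch)
    present <- switch(ct,
      A = TRUE,
      X = (sex == "F") || (hap == 1L),
      Y = (sex == "M") && (hap == 2L))
    if (!present) next
    refseq <- as.character(ref$genome[[ch]])
    sel <- loci[loci$chrom == ch, ]
    sel <- sel[order(sel$start), ]
    segs <- character(0)
    pos <- 0L
    for (i in seq_len(nrow(sel))) {
      li <- sel[i, ]
      row <- g[g$locus == li$locus, ]
      cgl <- 0L
      if (nrow(row)) {
        cgl <- if (ct == "Y" || (ct == "X" && sex == "M")) row$a1[1]
               else if (hap == 1L) row$a1[1] else row$a2[1]
      }
      if (is.na(cgl)) cgl <- 0L
      allele <- build_array(li$pattern, li$ref_copies + cgl)
      segs <- c(segs, substring(refseq, pos + 1L, li$start), allele)
      pos <- li$end
    }
    segs <- c(segs, substring(refseq, pos + 1L, nchar(refseq)))
    out[ch] <- paste(segs, collapse = "")
  }
  out
}

apply_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  for (i in seq_along(reads)) {
    n <- nchar(reads[i])
    k <- rbinom(1L, n, error_rate)
    if (k == 0L) next
    pos <- sample.int(n, k)
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Synthesize short reads for one sample
#'
#' Samples fixed-length reads uniformly from both haplotype genomes of a
#' sample (alleles spliced in from the true genotypes), on both strands,
#' at the stated fold coverage, with independent per-base substitution
#' errors. The read count approximates `coverage * genome_length /
#' read_length` (Lander-Waterman); hemizygous chromosomes are covered at
#' half depth.
#'
#' @param truth A `vntr_truth`.
#' @param ref The matching `vntr_reference`.
#' @param sample Sample id.
#' @param read_length Read length (bp).
#' @param coverage Fold coverage (0 gives an empty set).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
synthesize_reads <- function(truth, ref, sample, read_length = 150L,
                             coverage = 30, error_rate = 0, seed = NULL) {
  stopifnot(sample %in% truth$samples$sample, read_length >= 1)
  sex <- truth$samples$sex[truth$samples$sample == sample]
  min_array <- suppressWarnings(min(ref$loci$pattern_length *
                                      ref$loci$ref_copies))
  if (is.finite(min_array) && read_length < min_array + 20)
    warning("read_length is too short to span any locus array plus flanks")
  with_seed(seed, {
    reads <- character(0)
    for (hap in 1:2) {
      hs <- haplotype_seqs(truth, ref, sample, hap, sex)
      for (ch in names(hs)) {
        len <- nchar(hs[ch])
        if (len < read_length) next
        n <- as.integer(round(coverage / 2 * len / read_length))
        if (n <= 0L) next
        starts <- sample.int(len - read_length + 1L, n, replace = TRUE)
        rs <- substring(hs[ch], starts, starts + read_length - 1L)
        flip <- runif(n) < 0.5
        rs[flip] <- vapply(rs[flip], revcomp_chr, character(1),
                           USE.NAMES = FALSE)
        reads <- c(reads, rs)
      }
    }
    reads <- apply_substitution_errors(reads, error_rate)
    if (length(reads))
      names(reads) <- sprintf("%s_r%05d", sample, seq_along(reads))
    Biostrings::DNAStringSet(reads)
  })
}

#' Write reads as FASTQ
#'
#' Plain uncompressed FASTQ with a constant quality character (the
#' generator models substitution errors, not quality scores).
#'
#' @param reads A [Biostrings::DNAStringSet] (named).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- as.character(reads)
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("read%05d", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", nm), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}

#' Synthesize per-locus long reads for one sample
#'
#' Emits, for each locus and each haplotype present, `n_per_locus` long
#' reads spanning the full allele array plus both flanks — the situation
#' after long reads have been aligned and extracted per reference locus.
#'
#' @param truth A `vntr_truth`.
#' @param ref The matching `vntr_reference`.
#' @param sample Sample id.
#' @param n_per_locus Reads per haplotype per locus.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Named list: locus id -> character vector of read sequences.
#' @export
synthesize_long_reads <- function(truth, ref, sample, n_per_locus = 2L,
                                  error_rate = 0, seed = NULL) {
  stopifnot(sample %in% truth$samples$sample)
  g <- truth$genotypes[truth$genotypes$sample == sample, ]
  loci <- ref$loci
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(loci))) {
      li <- loci[i, ]
      row <- g[g$locus == li$locus, ]
      if (!nrow(row)) next
      alleles <- c(row$a1[1], row$a2[1])
      alleles <- alleles[!is.na(alleles)]
      reads <- character(0)
      for (a in alleles) {
        seq <- paste0(li$flank_left, build_array(li$pattern,
                                                 li$ref_copies + a),
                      li$flank_right)
        reads <- c(reads, rep(seq, n_per_locus))
      }
      reads <- apply_substitution_errors(reads, error_rate)
      out[[as.character(li$locus)]] <- reads
    }
    out
  })
}
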