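## Synthetic reference TR set and genome.

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tandem array: pattern repeated to `copies` (fractional tail truncated)
build_array <- function(pattern, copies) {
  len <- as.integer(rnd_half_up(nchar(pattern) * copies))
  if (len <= 0L) return("")
  substring(strrep(pattern, ceiling(copies) + 1L), 1L, len)
}

#' Generate a synthetic reference TR set and genome
#'
#' Builds `n_loci` non-overlapping tandem repeat loci embedded in a random
#' genome. Each locus has a random repeat unit (length within the config's
#' pattern range), a reference copy number, and 50 bp flanks. Loci are
#' spread over an autosome plus optional chrX/chrY portions. A
#' configurable fraction of loci is flagged *indistinguishable*: such loci
#' come in families sharing the repeat pattern and near-identical flanks
#' (one flank base mutated), emulating dispersed repeat families whose
#' reads cannot be attributed to a unique locus. All remaining loci are
#' *singletons*, unique by pattern plus flank context.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return A `vntr_reference`: list with `loci` (data.frame: `locus`,
#'   `chrom`, `start`, `end` 0-based half-open array coordinates,
#'   `pattern`, `pattern_length`, `ref_copies`, `flank_left`,
#'   `flank_right`, `indistinguishable`, `family`, `canonical`) and
#'   `genome` (named [Biostrings::DNAStringSet]).
#' @export
generate_reference <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    n <- config$n_loci
    if (n == 0L) {
      loci <- empty_loci_df()
      return(structure(list(loci = loci,
                            genome = Biostrings::DNAStringSet()),
                       class = "vntr_reference"))
    }
    n_y <- as.integer(round(config$y_frac * n))
    n_x <- as.integer(round(config$x_frac * n))
    n_a <- n - n_x - n_y
    chrom <- c(rep("chr1", n_a), rep("chrX", n_x), rep("chrY", n_y))

    plen <- sample(seq(config$pattern_length_range[1],
                       config$pattern_length_range[2]), n, replace = TRUE)
    copies <- round(runif(n, config$ref_copies_range[1],
                          config$ref_copies_range[2]), 1)
    pattern <- vapply(plen, random_dna, character(1))
    fl <- vapply(rep(config$flank, n), random_dna, character(1))
    fr <- vapply(rep(config$flank, n), random_dna, character(1))
    for (i in seq_len(n)) {
      bb <- break_repeat_boundary(fl[i], fr[i], pattern[i],
                                  as.integer(rnd_half_up(plen[i] *
                                                           copies[i])))
      fl[i] <- bb$fl; fr[i] <- bb$fr
    }

    indist <- rep(FALSE, n)
    family <- rep(NA_integer_, n)
    k <- as.integer(round(config$indistinguishable_frac * n))
    if (k >= 2L) {
      idx <- sample.int(n, k)
      fam <- 0L
      for (i in seq(1L, k - 1L, by = 2L)) {
        fam <- fam + 1L
        a <- idx[i]; b <- idx[i + 1L]
        # family member b shares a's pattern/copies and near-identical flanks
        pattern[b] <- pattern[a]; plen[b] <- plen[a]; copies[b] <- copies[a]
        fl[b] <- mutate_one_base(fl[a]); fr[b] <- fr[a]
        indist[c(a, b)] <- TRUE
        family[c(a, b)] <- fam
      }
      if (k %% 2L == 1L) {  # odd one out joins the first family
        b <- idx[k]; a <- idx[1L]
        pattern[b] <- pattern[a]; plen[b] <- plen[a]; copies[b] <- copies[a]
        fl[b] <- mutate_one_base(fl[a]); fr[b] <- fr[a]
        indist[b] <- TRUE; family[b] <- family[a]
      }
    }

    arrays <- mapply(build_array, pattern, copies, USE.NAMES = FALSE)

    # lay out each chromosome: spacer | flankL array flankR | spacer | ...
    loci <- data.frame(locus = seq_len(n), chrom = chrom, start = 0L,
                       end = 0L, pattern = pattern, pattern_length = plen,
                       ref_copies = copies, flank_left = fl, flank_right = fr,
                       indistinguishable = indist, family = family,
                       canonical = vapply(pattern, canonical_pattern,
                                          character(1), USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
    genome <- character(0)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      segs <- character(0)
      pos <- 0L
      for (i in sel) {
        sp <- random_dna(config$spacer)
        segs <- c(segs, sp, fl[i], arrays[i], fr[i])
        pos <- pos + nchar(sp) + nchar(fl[i])
        loci$start[i] <- pos
        pos <- pos + nchar(arrays[i])
        loci$end[i] <- pos
        pos <- pos + nchar(fr[i])
      }
      segs <- c(segs, random_dna(config$spacer))
      genome[ch] <- paste(segs, collapse = "")
    }
    if (!is.null(config$genome_length)) {
      used <- sum(nchar(genome))
      if (used > config$genome_length)
        stop("loci cannot be placed without overlap in the requested ",
             "genome length (need ", used, " bp, have ",
             config$genome_length, ")")
      pad <- config$genome_length - used
      genome[length(genome)] <- paste0(genome[length(genome)],
                                       random_dna(pad))
    }
    structure(list(loci = loci,
                   genome = Biostrings::DNAStringSet(genome)),
              class = "vntr_reference")
  })
}

empty_loci_df <- function() {
  data.frame(locus = integer(0), chrom = character(0), start = integer(0),
             end = integer(0), pattern = character(0),
             pattern_length = integer(0), ref_copies = numeric(0),
             flank_left = character(0), flank_right = character(0),
             indistinguishable = logical(0), family = integer(0),
             canonical = character(0), stringsAsFactors = FALSE)
}

mutate_one_base <- function(s) {
  i <- sample.int(nchar(s), 1L)
  old <- substring(s, i, i)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substring(s, 1L, i - 1L), new, substring(s, i + 1L))
}

# Curated TR arrays are maximal: the flanking sequence must not continue
# the repeat. Force the two flank bases adjacent to each array boundary
# to differ from the cyclic continuation of the pattern, so copy-number
# measurements cannot drift into the flanks. Allele length changes are
# whole copies, so the boundary phases are allele-independent.
break_repeat_boundary <- function(fl, fr, pattern, arr_len) {
  plen <- nchar(pattern)
  pchar <- strsplit(pattern, "", fixed = TRUE)[[1]]
  cyc <- function(i) pchar[((i - 1L) %% plen) + 1L]
  end_phase <- arr_len %% plen
  nl <- nchar(fl)
  for (k in 1:2) {
    # right flank position k continues the array at end_phase + k
    want <- cyc(end_phase + k)
    if (substring(fr, k, k) == want) {
      substr(fr, k, k) <- sample(setdiff(c("A", "C", "G", "T"), want), 1L)
    }
    # left flank position nl - k + 1 precedes phase 1 by k
    want_l <- cyc(plen + 1L - k)
    pos <- nl - k + 1L
    if (substring(fl, pos, pos) == want_l) {
      substr(fl, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             want_l), 1L)
    }
  }
  list(fl = fl, fr = fr)
}

#' @export
print.vntr_reference <- function(x, ...) {
  cat(sprintf("vntr_reference: %d loci on %d sequence(s), %d bp total\n",
              nrow(x$loci), length(x$genome), sum(Biostrings::width(x$genome))))
  invisible(x)
}

#' Write a reference TR set to disk
#'
#' Emits the genome as FASTA, the locus intervals as BED (0-based
#' half-open, locus ids as names), and the locus table as TSV.
#'
#' @param ref A `vntr_reference`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "loci.bed")
  tsv <- file.path(dir, "loci.tsv")
  Biostrings::writeXStringSet(ref$genome, fa)
  bed_df <- ref$loci[, c("chrom", "start", "end", "locus")]
  write.table(bed_df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(ref$loci[, c("locus", "chrom", "start", "end", "pattern",
                           "pattern_length", "ref_copies",
                           "indistinguishable", "family")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, bed, tsv))
}

chrom_type <- function(chrom) {
  out <- ifelse(chrom == "chrX", "X", ifelse(chrom == "chrY", "Y", NA))
  auto <- grepl("^chr[0-9]+$", chrom)
  out[auto] <- "A"
  if (anyNA(out))
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[is.na(out)]), collapse = ", "))
  out
}
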