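## Cyclic (wraparound) alignment core and detectability calculus.

BASES <- c("A", "C", "G", "T", "N")

# nearest integer, halves away from zero -- used consistently for copy
# rounding so that fractional reference copies (e.g. 3.5) encode and
# measure identically (R's round() alone rounds halves to even)
rnd_half_up <- function(x) trunc(x + sign(x) * 0.5)

# encode a nucleotide string as integers A=0 C=1 G=2 T=3 N=4
encode_seq <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,N}")
  v - 1L
}

# reverse complement of a plain character string (N maps to N)
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Alignment scoring scheme
#'
#' Match/mismatch/gap scores for the wraparound aligner. Defaults are the
#' scheme used throughout the package for repeat copy-number estimation:
#' match +2, mismatch -5, gap -7 per gapped base (linear gap penalty).
#'
#' @param match Positive score for a matching base pair.
#' @param mismatch Negative score for a mismatching pair (N always
#'   mismatches).
#' @param gap Negative score per gapped base.
#' @return A `scoring_scheme` object (named list).
#' @export
#' @examples
#' scoring_scheme()
scoring_scheme <- function(match = 2L, mismatch = -5L, gap = -7L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  if (!(match > 0 && mismatch < 0 && gap < 0))
    stop("scoring scheme requires match > 0 > mismatch, gap")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' Local wraparound alignment of a sequence against a cyclic pattern
#'
#' Computes the maximum-scoring local alignment of `seq` against the
#' infinite cyclic extension of `pattern` (the pattern repeated without
#' bound, beginning at any phase). This is the operation used to count
#' repeat copies in a read: the alignment may enter and leave the repeat
#' array anywhere and wrap around the pattern as many times as the data
#' support.
#'
#' Internally the pattern is unrolled far enough that the optimum over the
#' finite text equals the optimum over the cyclic extension (a local
#' alignment with positive score under a linear gap penalty cannot consume
#' more than `9/7 * nchar(seq)` text bases, since each skipped text base
#' costs more than a match can recover).
#'
#' @param seq Query nucleotide string (alphabet A,C,G,T,N; N scores as a
#'   mismatch).
#' @param pattern Repeat unit, same alphabet.
#' @param scoring A [scoring_scheme()].
#' @return A `wraparound_alignment`: list with `score`, `copies` (pattern
#'   copies spanned, to 0.01 resolution), `seq_start`/`seq_end` (0-based
#'   half-open query positions), `path` (string over M/X/I/D), and
#'   `pattern_length`.
#' @export
#' @examples
#' wraparound_align("ACGACGACG", "ACG")$score  # 18: nine matches
wraparound_align <- function(seq, pattern, scoring = scoring_scheme()) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("seq must be a non-empty nucleotide string")
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L)
    stop("pattern must be a non-empty nucleotide string")
  q <- encode_seq(seq)
  p <- encode_seq(pattern)
  n <- length(q); m <- length(p)
  k <- max(ceiling(n / m) + 2L, ceiling(1.5 * n / m) + 2L)
  text <- rep.int(p, k)
  res <- sw_align_cpp(q, text, scoring$match, scoring$mismatch, scoring$gap)
  consumed <- path_pattern_consumed(res$path)
  structure(list(
    score = res$score,
    copies = round(consumed / m, 2),
    seq_start = res$q_start,
    seq_end = res$q_end,
    path = res$path,
    pattern_length = m,
    pattern_phase = res$t_start %% m
  ), class = "wraparound_alignment")
}

# number of pattern (text) positions consumed along an alignment path
path_pattern_consumed <- function(path) {
  if (!nzchar(path)) return(0L)
  ops <- strsplit(path, "", fixed = TRUE)[[1]]
  sum(ops %in% c("M", "X", "D"))
}

#' @export
print.wraparound_alignment <- function(x, ...) {
  cat(sprintf("wraparound alignment: score %d, %.2f copies, query [%d,%d)\n",
              x$score, x$copies, x$seq_start, x$seq_end))
  invisible(x)
}

#' Pattern copies spanned by an alignment
#'
#' Copy counting convention: the number of pattern positions consumed along
#' the alignment path (match, mismatch, or deletion columns) divided by the
#' pattern length, reported to 0.01 resolution. A perfect k-fold repeat
#' yields exactly k.
#'
#' @param aln A `wraparound_alignment`.
#' @param pattern_length Repeat unit length in bp.
#' @return Fractional copy number.
#' @export
copy_number <- function(aln, pattern_length = aln$pattern_length) {
  stopifnot(inherits(aln, "wraparound_alignment"), pattern_length >= 1)
  round(path_pattern_consumed(aln$path) / pattern_length, 2)
}

#' Can a repeat array be genotyped at a given read length?
#'
#' A locus is genotypable from reads of a given length when the tandem
#' array plus a minimum flank on each side fits within a single read.
#'
#' @param array_length Tandem array length(s) in bp.
#' @param read_length Read length in bp.
#' @param min_flank Minimum flank on each side (default 10 bp).
#' @return Logical vector.
#' @export
#' @examples
#' is_genotypable(130, 150)  # TRUE: 130 + 20 <= 150
#' is_genotypable(131, 150)  # FALSE
is_genotypable <- function(array_length, read_length, min_flank = 10) {
  stopifnot(all(array_length >= 0), all(read_length >= 0), min_flank >= 0)
  array_length + 2 * min_flank <= read_length
}

#' Detectable copies-gained/lost interval for a locus
#'
#' Returns the integer CGL interval `[cgl_min, cgl_max]` of alleles that
#' could in principle be observed at a locus given the read length: the
#' allele must retain at least `min_copies` pattern copies (the detection
#' floor of the repeat finder) and its array plus flanks must fit within a
#' read.
#'
#' @param pattern_length Repeat unit length (bp).
#' @param ref_copies Reference copy number (may be fractional).
#' @param read_length Read length (bp).
#' @param min_copies Minimum pattern copies an allele must retain
#'   (default 1.9, the conservative end of the 1.8-1.9 range).
#' @param min_flank Minimum flank per side (default 10 bp).
#' @return Integer vector `c(cgl_min, cgl_max)`; `c(NA, NA)` when no
#'   allele is detectable.
#' @export
#' @examples
#' detectable_cgl_range(30, 4, 150)  # gain of one copy does not fit
detectable_cgl_range <- function(pattern_length, ref_copies, read_length,
                                 min_copies = 1.9, min_flank = 10) {
  stopifnot(pattern_length >= 1, ref_copies > 0, read_length >= 0)
  lo <- as.integer(ceiling(min_copies - ref_copies - 1e-9))
  hi <- as.integer(floor((read_length - 2 * min_flank) / pattern_length -
                           ref_copies + 1e-9))
  if (lo > hi) return(c(NA_integer_, NA_integer_))
  c(lo, hi)
}

# vectorized membership test: is cgl within the detectable range of its locus
cgl_detectable <- function(cgl, pattern_length, ref_copies, read_length,
                           min_copies = 1.9, min_flank = 10) {
  copies <- ref_copies + cgl
  copies >= min_copies - 1e-9 &
    is_genotypable(pattern_length * copies, read_length, min_flank)
}

#' Canonical form of a repeat pattern
#'
#' The lexicographically smallest string among all rotations of the
#' pattern and all rotations of its reverse complement. Two patterns that
#' describe the same cyclic repeat on either strand share a canonical
#' form.
#'
#' @param pattern Nucleotide string.
#' @return Canonical pattern string.
#' @export
canonical_pattern <- function(pattern) {
  p <- toupper(pattern)
  rots <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
      paste0(substring(s, i, n), substring(s, 1, i - 1L)), character(1))
  }
  min(c(rots(p), rots(revcomp_chr(p))))
}

# fraction of equal characters between two equal-length strings
string_identity <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(va) == length(vb))
  mean(va == vb)
}

#' Match a repeat detected in a read to a reference locus
#'
#' Given a tandem repeat found in a read (its pattern and the flanking
#' sequence on each side), finds the unique singleton reference locus with
#' the same canonical pattern (up to rotation and reverse complement) and
#' matching flanks. Flanks are compared over 10-50 bp; a candidate must
#' reach the identity threshold on both sides. Ties between two or more
#' loci, or matches into an indistinguishable repeat family, return
#' no-match, since such reads could mis-genotype a dispersed family.
#'
#' @param read_tr List with `pattern`, `flank_left`, `flank_right`
#'   (flanks as read sequence adjacent to the array, at least `min_flank`
#'   bp each).
#' @param ref A `vntr_reference` (see [generate_reference()]).
#' @param min_flank,max_flank Flank comparison window (default 10-50 bp).
#' @param min_identity Minimum per-flank identity (default 0.9).
#' @return Locus id (integer) or `NA` for no-match.
#' @export
match_read_to_locus <- function(read_tr, ref, min_flank = 10, max_flank = 50,
                                min_identity = 0.9) {
  stopifnot(is.list(read_tr),
            all(c("pattern", "flank_left", "flank_right") %in% names(read_tr)))
  loci <- ref$loci
  if (nchar(read_tr$flank_left) < min_flank ||
      nchar(read_tr$flank_right) < min_flank)
    stop("read repeat must carry at least min_flank bases of flank per side")
  canon <- canonical_pattern(read_tr$pattern)
  cand <- which(loci$canonical == canon)
  if (!length(cand)) return(NA_integer_)
  ok <- logical(length(cand))
  for (i in seq_along(cand)) {
    lr <- loci[cand[i], ]
    nl <- min(nchar(read_tr$flank_left), nchar(lr$flank_left), max_flank)
    nr <- min(nchar(read_tr$flank_right), nchar(lr$flank_right), max_flank)
    if (nl < min_flank || nr < min_flank) next
    idl <- string_identity(substring(read_tr$flank_left,
                                     nchar(read_tr$flank_left) - nl + 1L),
                           substring(lr$flank_left,
                                     nchar(lr$flank_left) - nl + 1L))
    idr <- string_identity(substring(read_tr$flank_right, 1L, nr),
                           substring(lr$flank_right, 1L, nr))
    ok[i] <- idl >= min_identity && idr >= min_identity
  }
  hits <- cand[ok]
  if (length(hits) != 1L) return(NA_integer_)
  if (loci$indistinguishable[hits]) return(NA_integer_)
  loci$locus[hits]
}
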