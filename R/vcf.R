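## VCF output and input for CGL/SP genotype calls.
##
## Layout: one record per locus, positions 1-based per the VCF standard
## (internal intervals are 0-based half-open). Two specialized FORMAT
## fields carry the genotype: SP, the number of reads supporting each
## allele (integer list), and CGL, the alleles as signed copies
## gained/lost (string list, e.g. "0,+2" for a heterozygous reference /
## gain-of-two locus). INFO carries the repeat unit (RU), its length
## (PL) and the reference copy number (RC).

fmt_cgl <- function(cgl) ifelse(cgl > 0, paste0("+", cgl), as.character(cgl))

parse_cgl <- function(x) as.integer(sub("^\\+", "", x))

#' Write cohort genotypes as VCF
#'
#' Writes one VCF with every genotyped TR locus and, optionally, a second
#' restricted to VNTR-flagged loci (those with any non-reference allele
#' in any sample).
#'
#' @param cohort A [vntr_cohort()].
#' @param file Path for the all-loci VCF.
#' @param vntr_file Optional path for the VNTR-only VCF.
#' @return Invisibly, the path(s) written.
#' @export
write_vntr_vcf <- function(cohort, file, vntr_file = NULL) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  loci <- cohort$loci
  loci <- loci[loci$locus %in% cohort$calls$locus, , drop = FALSE]
  loci <- loci[order(loci$chrom, if (!is.null(loci$start)) loci$start
                     else loci$locus), ]
  samples <- cohort$samples$sample
  vntr_flag <- classify_vntr_loci(cohort)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vntrscope",
    "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
    "##INFO=<ID=PL,Number=1,Type=Integer,Description=\"Repeat unit length\">",
    "##INFO=<ID=RC,Number=1,Type=Float,Description=\"Reference copy number\">",
    "##INFO=<ID=VNTR,Number=0,Type=Flag,Description=\"Non-reference allele observed in some sample\">",
    paste0("##FORMAT=<ID=SP,Number=.,Type=Integer,Description=",
           "\"Reads supporting each allele\">"),
    paste0("##FORMAT=<ID=CGL,Number=.,Type=String,Description=",
           "\"Copies gained or lost per allele\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  calls <- cohort$calls
  key <- split(seq_len(nrow(calls)), paste(calls$sample, calls$locus))
  body <- character(nrow(loci))
  is_vntr <- setNames(vntr_flag$is_vntr, vntr_flag$locus)
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    info <- sprintf("RU=%s;PL=%d;RC=%g",
                    if (!is.null(li$pattern)) li$pattern else "N",
                    li$pattern_length, li$ref_copies)
    if (isTRUE(is_vntr[[as.character(li$locus)]]))
      info <- paste0(info, ";VNTR")
    gts <- vapply(samples, function(s) {
      idx <- key[[paste(s, li$locus)]]
      if (is.null(idx)) return(".")
      idx <- idx[order(calls$cgl[idx])]
      paste(paste(calls$sp[idx], collapse = ","),
            paste(fmt_cgl(calls$cgl[idx]), collapse = ","), sep = ":")
    }, character(1))
    pos1 <- if (!is.null(li$start)) li$start + 1L else li$locus
    body[i] <- paste(c(li$chrom, pos1, li$locus, "N", ".", ".", ".",
                       info, "SP:CGL", gts), collapse = "\t")
  }
  writeLines(c(header, body), file)
  out <- file
  if (!is.null(vntr_file)) {
    keep <- vapply(loci$locus, function(l)
      isTRUE(is_vntr[[as.character(l)]]), logical(1))
    writeLines(c(header, body[keep]), vntr_file)
    out <- c(file, vntr_file)
  }
  invisible(out)
}

#' Read a CGL/SP VCF back into a cohort
#'
#' Parses VCFs written by [write_vntr_vcf()]. Malformed lines raise an
#' error naming the offending line number. Sample sex is not encoded in
#' VCF; supply it via `samples` to restore full metadata.
#'
#' @param file VCF path.
#' @param samples Optional sample metadata data.frame (`sample`, `sex`,
#'   ...) to attach; defaults to unknown sex.
#' @return A [vntr_cohort()].
#' @export
read_vntr_vcf <- function(file, samples = NULL) {
  lines <- readLines(file)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L)
    stop("VCF parse error: missing #CHROM header line in ", file)
  cols <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop("VCF parse error at line ", hdr_idx, ": no sample columns")
  sample_ids <- cols[-(1:9)]
  body_idx <- which(seq_along(lines) > hdr_idx & nzchar(lines))
  calls <- list()
  loci <- list()
  for (ln in body_idx) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop("VCF parse error at line ", ln, ": expected ", length(cols),
           " fields, found ", length(f))
    pos <- suppressWarnings(as.integer(f[2]))
    locus <- suppressWarnings(as.integer(f[3]))
    if (is.na(pos) || is.na(locus))
      stop("VCF parse error at line ", ln, ": bad POS or ID")
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    val <- function(k) {
      i <- match(k, keys)
      if (is.na(i) || length(kv[[i]]) < 2L) NA_character_ else kv[[i]][2]
    }
    pat <- val("RU")
    plen <- suppressWarnings(as.integer(val("PL")))
    rc <- suppressWarnings(as.numeric(val("RC")))
    if (is.na(plen) || is.na(rc))
      stop("VCF parse error at line ", ln, ": missing PL/RC INFO")
    if (f[9] != "SP:CGL")
      stop("VCF parse error at line ", ln, ": FORMAT must be SP:CGL")
    loci[[length(loci) + 1L]] <- data.frame(
      locus = locus, chrom = f[1], start = pos - 1L, pattern = pat,
      pattern_length = plen, ref_copies = rc, stringsAsFactors = FALSE)
    for (j in seq_along(sample_ids)) {
      g <- f[9L + j]
      if (g == "." || g == "") next
      parts <- strsplit(g, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("VCF parse error at line ", ln, ": bad genotype field '",
             g, "'")
      sp <- suppressWarnings(as.integer(strsplit(parts[1], ",")[[1]]))
      cgl <- suppressWarnings(parse_cgl(strsplit(parts[2], ",")[[1]]))
      if (anyNA(sp) || anyNA(cgl) || length(sp) != length(cgl))
        stop("VCF parse error at line ", ln,
             ": SP/CGL lists malformed or of unequal length")
      calls[[length(calls) + 1L]] <- data.frame(
        sample = sample_ids[j], locus = locus, cgl = cgl, sp = sp,
        stringsAsFactors = FALSE)
    }
  }
  loci_df <- if (length(loci)) unique(do.call(rbind, loci)) else
    data.frame(locus = integer(0), chrom = character(0),
               start = integer(0), pattern = character(0),
               pattern_length = integer(0), ref_copies = numeric(0))
  loci_df$end <- loci_df$start +
    as.integer(round(loci_df$pattern_length * loci_df$ref_copies))
  calls_df <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample = character(0), locus = integer(0),
               cgl = integer(0), sp = integer(0))
  if (is.null(samples))
    samples <- data.frame(sample = sample_ids, sex = NA_character_,
                          stringsAsFactors = FALSE)
  rownames(calls_df) <- rownames(loci_df) <- NULL
  vntr_cohort(calls_df, samples, loci_df)
}
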