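## Gene annotations and expression with planted eQTL effects.

#' Simulate gene intervals around reference TR loci
#'
#' Places one gene per selected locus at a controlled gap from the locus
#' interval (on the same chromosome), plus optional distant genes far
#' beyond the pairing window. Genes are annotation intervals only; no
#' sequence is attached.
#'
#' @param ref A `vntr_reference`.
#' @param loci Locus ids to receive a nearby gene (default: all).
#' @param gap Gap in bp between locus end and gene start (recycled).
#' @param width Gene width in bp.
#' @param n_far Number of additional genes placed far (> 1 Mb) from all
#'   loci.
#' @return data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
simulate_genes <- function(ref, loci = ref$loci$locus, gap = 500L,
                           width = 1000L, n_far = 0L) {
  sel <- ref$loci[match(loci, ref$loci$locus), ]
  gap <- rep_len(as.integer(gap), nrow(sel))
  genes <- data.frame(
    gene = sprintf("GENE_%d", sel$locus),
    chrom = sel$chrom,
    start = sel$end + gap,
    end = sel$end + gap + as.integer(width),
    stringsAsFactors = FALSE)
  if (n_far > 0L) {
    base <- max(genes$end, ref$loci$end) + 1e6
    far <- data.frame(
      gene = sprintf("FARGENE_%d", seq_len(n_far)),
      chrom = genes$chrom[1],
      start = as.integer(base + (seq_len(n_far) - 1L) * (width + 1000L)),
      end = as.integer(base + (seq_len(n_far) - 1L) * (width + 1000L) +
                         width),
      stringsAsFactors = FALSE)
    genes <- rbind(genes, far)
  }
  rownames(genes) <- NULL
  genes
}

#' Simulate a TPM expression matrix with planted VNTR effects
#'
#' Expression on the `log2(TPM + 1)` scale is a sum of a per-gene
#' baseline, a sex effect, a population effect, hidden-factor loadings,
#' a planted per-genotype shift at eQTL genes, and Gaussian noise:
#' carriers of any non-reference allele at the paired locus are shifted by
#' the planted effect (log2 units). Hidden factor scores are returned for
#' recovery experiments.
#'
#' @param truth A `vntr_truth` (supplies samples, sex, population and
#'   genotypes).
#' @param genes Gene table from [simulate_genes()] (or any data.frame
#'   with a `gene` column).
#' @param eqtl_effect_spec `NULL` or data.frame `gene`, `locus`,
#'   `effect` (log2 shift for non-reference carriers).
#' @param n_hidden_factors Number of standard-normal hidden factors.
#' @param noise_sd Residual noise SD (log2 units).
#' @param effect_sd SD of the per-gene sex and population effects.
#' @param seed Integer seed.
#' @return List with `tpm` (genes x samples matrix), `covariates`
#'   (data.frame `sample`, `sex`, `population`) and `hidden` (samples x
#'   factors score matrix).
#' @export
simulate_expression <- function(truth, genes, eqtl_effect_spec = NULL,
                                n_hidden_factors = 0L, noise_sd = 0.5,
                                effect_sd = 0.3, seed = NULL) {
  sm <- truth$samples
  gn <- genes$gene
  if (!is.null(eqtl_effect_spec)) {
    if (!all(eqtl_effect_spec$gene %in% gn))
      stop("eqtl_effect_spec references unknown gene(s)")
    if (!all(eqtl_effect_spec$locus %in% truth$genotypes$locus))
      stop("eqtl_effect_spec references unknown locus id(s)")
  }
  with_seed(seed, {
    n_g <- length(gn); n_s <- nrow(sm)
    baseline <- runif(n_g, 3, 8)
    sex_eff <- rnorm(n_g, 0, effect_sd)
    pops <- unique(sm$population)
    pop_eff <- matrix(rnorm(n_g * length(pops), 0, effect_sd),
                      n_g, dimnames = list(gn, pops))
    log2m <- matrix(baseline, n_g, n_s, dimnames = list(gn, sm$sample))
    log2m <- log2m + outer(sex_eff, as.numeric(sm$sex == "M"))
    log2m <- log2m + pop_eff[, sm$population, drop = FALSE]
    hidden <- matrix(0, n_s, 0)
    if (n_hidden_factors > 0L) {
      hidden <- matrix(rnorm(n_s * n_hidden_factors), n_s,
                       dimnames = list(sm$sample, NULL))
      load <- matrix(rnorm(n_g * n_hidden_factors, 0, 0.5), n_g)
      log2m <- log2m + load %*% t(hidden)
    }
    if (!is.null(eqtl_effect_spec)) {
      g <- truth$genotypes
      for (i in seq_len(nrow(eqtl_effect_spec))) {
        sp <- eqtl_effect_spec[i, ]
        rows <- g[g$locus == sp$locus, ]
        carrier <- rows$sample[(!is.na(rows$a1) & rows$a1 != 0L) |
                                 (!is.na(rows$a2) & rows$a2 != 0L)]
        idx <- sm$sample %in% carrier
        log2m[sp$gene, idx] <- log2m[sp$gene, idx] + sp$effect
      }
    }
    log2m <- log2m + matrix(rnorm(n_g * n_s, 0, noise_sd), n_g)
    log2m[log2m < 0] <- 0
    tpm <- 2^log2m - 1
    list(tpm = tpm,
         covariates = sm[, c("sample", "sex", "population")],
         hidden = hidden)
  })
}
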