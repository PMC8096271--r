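## VNTR-expression association: pairing, genotype classes,
## residualization with surrogate hidden factors, one-way ANOVA scan.

#' Pair genes with VNTR loci within a distance window
#'
#' A gene and a locus are paired when the minimum distance between their
#' intervals is at most `window` bp (0 when they overlap). Distance is
#' measured between interval hulls; both inputs are 0-based half-open on
#' a shared coordinate system.
#'
#' @param genes data.frame `gene`, `chrom`, `start`, `end`.
#' @param loci data.frame `locus`, `chrom`, `start`, `end`.
#' @param window Maximum pairing distance in bp (default 10000).
#' @return data.frame `gene`, `locus`, `distance`.
#' @export
pair_genes_vntrs <- function(genes, loci, window = 10000L) {
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L,
                                                genes$end))
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L,
                                                loci$end))
  hits <- GenomicRanges::findOverlaps(gg, lg, maxgap = window)
  d <- GenomicRanges::distance(gg[S4Vectors::queryHits(hits)],
                               lg[S4Vectors::subjectHits(hits)])
  out <- data.frame(gene = genes$gene[S4Vectors::queryHits(hits)],
                    locus = loci$locus[S4Vectors::subjectHits(hits)],
                    distance = as.integer(d), stringsAsFactors = FALSE)
  out <- out[out$distance <= window, ]
  rownames(out) <- NULL
  out
}

#' Genotype classes at a locus for an expression cohort
#'
#' Each sample's class label is its sorted CGL multiset (e.g. `"0/+1"`);
#' samples without a genotype call at the locus form the pooled `"other"`
#' class (their alleles are presumed outside the detection range). The
#' locus is usable only when there are at least two classes (three if
#' `"other"` is among them) and every class has at least `min_class`
#' members.
#'
#' @param calls Call data.frame (`sample`, `locus`, `cgl`).
#' @param locus Locus id.
#' @param samples Character vector: the expression cohort sample ids.
#' @param min_class Minimum members per class (default 20).
#' @return List `classes` (factor over `samples`), `counts` — or `NULL`
#'   when the locus fails the filters.
#' @export
build_genotype_classes <- function(calls, locus, samples,
                                   min_class = 20L) {
  cs <- calls[calls$locus == locus & calls$sample %in% samples, ]
  by_sample <- if (nrow(cs))
    vapply(split(cs$cgl, cs$sample), function(g)
      paste(fmt_cgl(sort(g)), collapse = "/"), character(1))
  else character(0)
  lab <- unname(by_sample[samples])
  lab[is.na(lab)] <- "other"
  counts <- table(lab)
  if (any(counts < min_class)) return(NULL)
  n_needed <- if ("other" %in% names(counts)) 3L else 2L
  if (length(counts) < n_needed) return(NULL)
  list(classes = factor(lab, levels = names(counts)), counts = counts)
}

# design matrix from a covariate data.frame/matrix (no intercept column;
# factors expanded to dummies)
covariate_matrix <- function(covariates) {
  if (is.matrix(covariates)) return(covariates)
  df <- as.data.frame(covariates)
  df <- df[, setdiff(names(df), "sample"), drop = FALSE]
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  # constant covariates (single-level factors) carry no information
  keep <- vapply(df, function(x)
    if (is.factor(x)) nlevels(droplevels(x)) >= 2L else TRUE, logical(1))
  df <- df[, keep, drop = FALSE]
  if (!ncol(df)) return(matrix(0, nrow(df), 0))
  # keep NA rows so missing covariates can be reported per sample
  old_na <- options(na.action = "na.pass")
  on.exit(options(old_na))
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Residualize expression on known covariates
#'
#' Per-gene ordinary least squares of `log2(TPM + 1)` on the covariate
#' design (plus intercept); returns the residual matrix. Residuals are
#' orthogonal to every design column. Errors name collinear covariate
#' columns (rank deficiency) or samples with missing covariate values.
#'
#' @param log2_expr Genes x samples matrix (already log2 scale).
#' @param covariates data.frame or matrix of per-sample covariates
#'   (rows aligned with the matrix columns; a `sample` column is
#'   ignored).
#' @return Residual matrix, same shape as `log2_expr`.
#' @export
residualize <- function(log2_expr, covariates) {
  X <- covariate_matrix(covariates)
  if (nrow(X) != ncol(log2_expr))
    stop("covariates rows must align with expression columns")
  if (anyNA(X)) {
    bad <- colnames(log2_expr)[apply(X, 1, anyNA)]
    stop("missing covariate values for sample(s): ",
         paste(bad, collapse = ", "))
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    drop_cols <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- lm.fit(Xi, t(log2_expr))
  t(fit$residuals)
}

#' Estimate surrogate hidden expression factors
#'
#' Iterative residual-PC surrogate factor estimation: repeatedly
#' residualize the expression matrix on the known covariates plus the
#' factors accepted so far, take the leading principal component of the
#' residual (per-sample scores), and accept it unless its absolute
#' correlation with any existing covariate or accepted factor exceeds
#' `corr_cutoff`. Stops at the first rejection or at `max_k` factors.
#'
#' @param log2_expr Genes x samples matrix (log2 scale).
#' @param covariates Known covariates (as in [residualize()]).
#' @param max_k Maximum factors to accept (default 15).
#' @param corr_cutoff Correlation stopping threshold (default 0.85).
#' @return Samples x k matrix of factor scores (k may be 0).
#' @export
estimate_hidden_factors <- function(log2_expr, covariates, max_k = 15L,
                                    corr_cutoff = 0.85) {
  X <- covariate_matrix(covariates)
  factors <- matrix(0, ncol(log2_expr), 0)
  repeat {
    if (ncol(factors) >= max_k) break
    design <- cbind(X, factors)
    res <- residualize(log2_expr, design)
    sv <- svd(res - rowMeans(res), nu = 0, nv = 1)
    cand <- sv$v[, 1]
    cors <- abs(cor(cand, design))
    if (max(cors) > corr_cutoff) break
    factors <- cbind(factors, cand)
    colnames(factors) <- paste0("HF", seq_len(ncol(factors)))
  }
  rownames(factors) <- colnames(log2_expr)
  factors
}

#' One-way ANOVA scan over gene-VNTR pairs
#'
#' For each pair, a fixed-effects one-way ANOVA of the gene's expression
#' residuals across the locus's genotype classes; p-values are
#' Benjamini-Hochberg adjusted across all tested pairs. Significant
#' records carry the maximum pairwise difference of class residual
#' means.
#'
#' @param residuals Genes x samples residual matrix.
#' @param pairs data.frame `gene`, `locus` (from
#'   [pair_genes_vntrs()]).
#' @param classings Named list: locus id -> result of
#'   [build_genotype_classes()] (entries may be `NULL` = excluded).
#' @param fdr Significance threshold on q (default 0.05).
#' @return List: `tested` (data.frame `gene`, `locus`, `f`, `p`, `q`,
#'   `max_mean_diff`, `n_classes`, `significant`), `significant` (the
#'   q < fdr subset).
#' @export
anova_scan <- function(residuals, pairs, classings, fdr = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]; l <- as.character(pairs$locus[i])
    cl <- classings[[l]]
    if (is.null(cl) || !(g %in% rownames(residuals))) next
    y <- residuals[g, ]
    grp <- cl$classes
    ft <- oneway.test(y ~ grp, var.equal = TRUE)
    means <- tapply(y, grp, mean)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, locus = pairs$locus[i],
      f = unname(ft$statistic), p = unname(ft$p.value),
      max_mean_diff = max(means) - min(means),
      n_classes = nlevels(grp), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    tested <- data.frame(gene = character(0), locus = integer(0),
                         f = numeric(0), p = numeric(0),
                         max_mean_diff = numeric(0),
                         n_classes = integer(0), q = numeric(0),
                         significant = logical(0))
    return(list(tested = tested, significant = tested))
  }
  tested <- do.call(rbind, rows)
  tested$q <- p.adjust(tested$p, method = "BH")
  tested$significant <- tested$q < fdr
  tested <- tested[order(tested$q, tested$p), ]
  rownames(tested) <- NULL
  list(tested = tested, significant = tested[tested$significant, ])
}

#' Full eQTL scan from cohort calls and expression
#'
#' Convenience pipeline: pair genes with loci, build genotype classes
#' with the `"other"` rule and class-size filters, drop genes whose
#' median TPM is zero, residualize `log2(TPM + 1)` on known covariates
#' plus estimated hidden factors, and run the ANOVA scan.
#'
#' @param cohort A [vntr_cohort()].
#' @param genes Gene interval table.
#' @param tpm Genes x samples TPM matrix.
#' @param covariates Known covariates (see [residualize()]).
#' @param window Pairing window (default 10 kb).
#' @param min_class Minimum class size (default 20).
#' @param max_hidden Maximum surrogate factors (default 15).
#' @param corr_cutoff Surrogate-factor stopping threshold (default
#'   0.85).
#' @param fdr FDR threshold (default 0.05).
#' @return As [anova_scan()], plus `pairs` and `n_hidden`.
#' @export
eqtl_scan <- function(cohort, genes, tpm, covariates, window = 10000L,
                      min_class = 20L, max_hidden = 15L,
                      corr_cutoff = 0.85, fdr = 0.05) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  expr_samples <- colnames(tpm)
  pairs <- pair_genes_vntrs(genes, cohort$loci, window)
  keep_gene <- apply(tpm, 1, function(x) median(x) > 0)
  pairs <- pairs[pairs$gene %in% rownames(tpm)[keep_gene], ]
  calls_by_locus <- split(cohort$calls, cohort$calls$locus)
  classings <- list()
  for (l in unique(pairs$locus)) {
    k <- as.character(l)
    cl <- calls_by_locus[[k]]
    if (is.null(cl)) cl <- cohort$calls[0, ]
    classings[[k]] <- build_genotype_classes(cl, l, expr_samples,
                                             min_class)
  }
  log2m <- log2(tpm + 1)
  hf <- estimate_hidden_factors(log2m, covariates, max_hidden,
                                corr_cutoff)
  design <- cbind(covariate_matrix(covariates), hf)
  res <- residualize(log2m, design)
  out <- anova_scan(res, pairs, classings, fdr)
  out$pairs <- pairs
  out$n_hidden <- ncol(hf)
  out
}
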