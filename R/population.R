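## Population structure: allele matrix, PCA, ancestry tree, Fisher markers.

#' Binary sample-by-allele presence matrix
#'
#' One column per observed (locus, CGL) allele; entry 1 when the sample
#' carries the allele at least once (carrier coding, not dosage). Alleles
#' present in fewer than `min_presence` of the samples are uninformative
#' and dropped. Typically restricted to common VNTR loci before calling.
#'
#' @param cohort A [vntr_cohort()].
#' @param loci Optional locus ids to restrict to (e.g. common VNTRs).
#' @param min_presence Minimum carrier fraction per column (default
#'   0.05).
#' @return Numeric 0/1 matrix, rownames samples, colnames
#'   `"locus:cgl"`; attribute `"populations"` carries sample labels when
#'   present in the metadata.
#' @export
build_allele_matrix <- function(cohort, loci = NULL, min_presence = 0.05) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  calls <- cohort$calls
  if (!is.null(loci)) calls <- calls[calls$locus %in% loci, ]
  samples <- cohort$samples$sample
  if (!nrow(calls)) {
    m <- matrix(0, nrow = length(samples), ncol = 0,
                dimnames = list(samples, NULL))
  } else {
    key <- paste0(calls$locus, ":", fmt_cgl(calls$cgl))
    cols <- sort(unique(key))
    m <- matrix(0, nrow = length(samples), ncol = length(cols),
                dimnames = list(samples, cols))
    m[cbind(match(calls$sample, samples), match(key, cols))] <- 1
    keep <- colMeans(m) >= min_presence
    m <- m[, keep, drop = FALSE]
  }
  if (!is.null(cohort$samples$population))
    attr(m, "populations") <- setNames(cohort$samples$population, samples)
  m
}

#' Principal components of an allele matrix
#'
#' Mean-centered (unscaled) PCA of the binary presence matrix. Scores are
#' deterministic up to sign; explained-variance shares are non-increasing
#' and sum to at most one.
#'
#' @param m Samples x alleles matrix from [build_allele_matrix()].
#' @param n_pcs Number of components to return (default: all).
#' @return List: `scores` (samples x PCs), `explained` (variance
#'   shares).
#' @export
pca_embed <- function(m, n_pcs = NULL) {
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("PCA needs at least 2 samples and 2 alleles")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / max(sum(p$sdev^2), .Machine$double.eps)
  k <- if (is.null(n_pcs)) ncol(p$x) else min(n_pcs, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)])
}

# stratified train/test split: indices of the training rows
stratified_split <- function(labels, train_frac) {
  train <- integer(0)
  for (p in unique(labels)) {
    idx <- which(labels == p)
    n_tr <- round(train_frac * length(idx))
    if (n_tr < 1L || n_tr >= length(idx))
      stop("population '", p, "' too small for a stratified split")
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Ancestry classification from principal components
#'
#' Stratified 70/30 train/test split, then a decision tree on the top
#' `n_pcs` components. Tree depth is chosen by 10-fold cross-validation
#' on the training split over depths {3, 5, 8, unbounded}; per-population
#' recall is reported on the held-out split.
#'
#' @param scores Sample x PC score matrix (rownames = samples).
#' @param labels Population label per sample.
#' @param n_pcs PCs used as predictors (default 10).
#' @param train_frac Training fraction (default 0.7).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed driving the split, fold assignment and tree.
#' @return List: `recall` (named per-population recall on the test
#'   split), `min_recall`, `confusion` (test-split table), `depth`
#'   (selected), `model` (rpart fit), `test_idx`.
#' @export
classify_populations <- function(scores, labels, n_pcs = 10L,
                                 train_frac = 0.7, cv_folds = 10L,
                                 seed = 1L) {
  stopifnot(nrow(scores) == length(labels))
  n_pcs <- min(n_pcs, ncol(scores))
  df <- as.data.frame(scores[, seq_len(n_pcs), drop = FALSE])
  names(df) <- paste0("PC", seq_len(n_pcs))
  df$pop <- factor(labels)
  with_seed(seed, {
    tr <- stratified_split(labels, train_frac)
    te <- setdiff(seq_len(nrow(df)), tr)
    train_df <- df[tr, ]
    depths <- c(3L, 5L, 8L, 30L)
    folds <- sample(rep_len(seq_len(cv_folds), nrow(train_df)))
    cv_acc <- vapply(depths, function(d) {
      acc <- vapply(seq_len(cv_folds), function(f) {
        fit <- rpart::rpart(pop ~ ., data = train_df[folds != f, ],
                            method = "class",
                            control = rpart::rpart.control(
                              maxdepth = d, cp = 0, xval = 0))
        pred <- predict(fit, train_df[folds == f, ], type = "class")
        mean(pred == train_df$pop[folds == f])
      }, numeric(1))
      mean(acc)
    }, numeric(1))
    depth <- depths[which.max(cv_acc)]
    fit <- rpart::rpart(pop ~ ., data = train_df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = depth, cp = 0, xval = 0))
    pred <- predict(fit, df[te, ], type = "class")
    truth <- df$pop[te]
    confusion <- table(truth = truth, predicted = pred)
    recall <- vapply(levels(truth), function(p) {
      idx <- truth == p
      if (!any(idx)) return(NA_real_)
      mean(pred[idx] == p)
    }, numeric(1))
    list(recall = recall, min_recall = min(recall, na.rm = TRUE),
         confusion = confusion, depth = depth, model = fit,
         test_idx = te)
  })
}

# one-sided (over-representation) hypergeometric tail p-value for a 2x2
# carrier table: k carriers among n_in in-population samples, K carriers
# among N total
fisher_onesided_p <- function(k, n_in, K, N) {
  phyper(k - 1L, K, N - K, n_in, lower.tail = FALSE)
}

# sample log2 odds ratio with Haldane-Anscombe 0.5 correction on zero
# cells
log2_odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log2((a * d) / (b * c))
}

#' Population-specific allele markers (one-sided Fisher exact scan)
#'
#' For every (allele, population) pair, tests over-representation of
#' allele carriers in the population versus all others with a one-sided
#' Fisher exact test (exact hypergeometric tail). Odds ratios are the
#' sample estimate with a 0.5 continuity correction on zero cells, log2
#' transformed; p-values are Benjamini-Hochberg adjusted across all
#' tests. A marker requires q < `fdr` and log2 OR > `min_log2or`.
#'
#' @param m Binary allele matrix from [build_allele_matrix()].
#' @param labels Population label per sample (default: the matrix's
#'   `populations` attribute).
#' @param fdr FDR threshold (default 0.05).
#' @param min_log2or log2 odds-ratio threshold (default 1).
#' @return data.frame `allele`, `population`, `carriers_in`, `n_in`,
#'   `carriers_out`, `n_out`, `p`, `q`, `log2_or`, `marker`.
#' @export
population_markers <- function(m, labels = attr(m, "populations"),
                               fdr = 0.05, min_log2or = 1) {
  stopifnot(!is.null(labels), nrow(m) == length(labels))
  pops <- unique(labels)
  if (length(pops) < 2L) stop("need at least 2 populations")
  N <- nrow(m)
  rows <- list()
  for (p in pops) {
    idx <- labels == p
    n_in <- sum(idx)
    if (n_in == 0L) next
    k_in <- colSums(m[idx, , drop = FALSE])
    K <- colSums(m)
    k_out <- K - k_in
    n_out <- N - n_in
    pv <- fisher_onesided_p(k_in, n_in, K, N)
    l2 <- mapply(log2_odds_ratio, k_in, n_in - k_in, k_out,
                 n_out - k_out)
    rows[[p]] <- data.frame(
      allele = colnames(m), population = p,
      carriers_in = as.integer(k_in), n_in = n_in,
      carriers_out = as.integer(k_out), n_out = n_out,
      p = pv, log2_or = l2, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res$marker <- res$q < fdr & res$log2_or > min_log2or
  res <- res[order(res$q, res$p), ]
  rownames(res) <- NULL
  res
}

#' Virtual gel table of allele band lengths
#'
#' Converts each observed allele into the fragment length it would run at
#' on a gel: `pattern_length * (ref_copies + CGL)` bp. One row per
#' sample-allele; plotting (and jitter) is left to the caller.
#'
#' @param cohort A [vntr_cohort()].
#' @param loci Locus ids to render (default: all with calls).
#' @return data.frame `sample`, `population`, `locus`, `cgl`,
#'   `band_bp`.
#' @export
virtual_gel <- function(cohort, loci = NULL) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  calls <- cohort$calls
  if (!is.null(loci)) calls <- calls[calls$locus %in% loci, ]
  lt <- cohort$loci
  pl <- lt$pattern_length[match(calls$locus, lt$locus)]
  rc <- lt$ref_copies[match(calls$locus, lt$locus)]
  pop <- if (!is.null(cohort$samples$population))
    cohort$samples$population[match(calls$sample, cohort$samples$sample)]
  else NA_character_
  out <- data.frame(sample = calls$sample, population = pop,
                    locus = calls$locus, cgl = calls$cgl,
                    band_bp = as.integer(round(pl * (rc + calls$cgl))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
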