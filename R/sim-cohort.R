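## Synthetic diploid cohorts, planted population markers, trios.

#' Sample a diploid multi-population cohort of true genotypes
#'
#' Draws per-haplotype allele CGL values independently per locus (no
#' linkage). At loci named in the config's `marker_allele_spec`, the
#' marker allele is drawn at haplotype frequency `f_in` within the target
#' population and `f_out` elsewhere (remaining mass on the reference
#' allele), which plants clean population-specific signal. All other loci
#' share one frequency model across populations (see [sim_config()]).
#'
#' Sex is assigned alternately (M, F, M, ...) within each population for a
#' deterministic sex balance. Sex chromosomes are haploid where
#' appropriate: males carry one X and one Y allele, females two X alleles
#' and no Y rows.
#'
#' @param ref A `vntr_reference` from [generate_reference()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `vntr_truth`: list with `samples` (data.frame `sample`,
#'   `population`, `sex`) and `genotypes` (data.frame `sample`, `locus`,
#'   `a1`, `a2` as integer CGL; `a2` is `NA` on hemizygous chromosomes).
#' @export
sample_cohort <- function(ref, config, seed = config$seed) {
  validate_sim_config(config)
  loci <- ref$loci
  ms <- config$marker_allele_spec
  if (!is.null(ms) && !all(ms$locus %in% loci$locus))
    stop("marker_allele_spec references unknown locus id(s): ",
         paste(setdiff(ms$locus, loci$locus), collapse = ", "))
  with_seed(seed, {
    pops <- paste0("POP", seq_len(config$n_populations))
    n_s <- config$n_populations * config$samples_per_population
    samples <- data.frame(
      sample = sprintf("S%04d", seq_len(max(n_s, 0L))),
      population = rep(pops, each = config$samples_per_population),
      sex = rep_len(c("M", "F"), max(n_s, 0L)),
      stringsAsFactors = FALSE)
    # within-population alternation: reorder sex per population block
    for (p in pops) {
      i <- which(samples$population == p)
      samples$sex[i] <- rep_len(c("M", "F"), length(i))
    }
    nl <- nrow(loci)
    if (nl == 0L || n_s == 0L) {
      return(structure(list(samples = samples, genotypes = empty_truth_df()),
                       class = "vntr_truth"))
    }
    ctype <- chrom_type(loci$chrom)

    # per-locus background allele machinery: non-reference frequency and
    # the conditional CGL value distribution over the allowed range
    f_bg <- ifelse(runif(nl) < config$mono_frac, 0,
                   stats::rbeta(nl, config$nonref_beta[1],
                                config$nonref_beta[2]))
    value_sets <- lapply(seq_len(nl), function(i) {
      v <- seq(config$allele_cgl_range[1], config$allele_cgl_range[2])
      v <- v[v != 0L & loci$ref_copies[i] + v >= 1]
      if (!length(v)) return(list(values = 0L, prob = 1))
      w <- ifelse(v < 0, config$loss_bias, 1 - config$loss_bias) *
        config$geom_p * (1 - config$geom_p)^(abs(v) - 1)
      list(values = v, prob = w / sum(w))
    })
    marker_at <- if (is.null(ms)) integer(0) else match(ms$locus, loci$locus)

    draw_hap <- function(locus_idx, pop) {
      # vectorized over samples for one locus: returns integer CGL vector
      n <- length(pop)
      mi <- match(locus_idx, marker_at)
      if (!is.na(mi)) {
        f <- ifelse(pop == ms$population[mi], ms$f_in[mi], ms$f_out[mi])
        return(ifelse(runif(n) < f, ms$cgl[mi], 0L))
      }
      f <- f_bg[locus_idx]
      hit <- runif(n) < f
      out <- integer(n)
      if (any(hit)) {
        vs <- value_sets[[locus_idx]]
        out[hit] <- sample(vs$values, sum(hit), replace = TRUE,
                           prob = vs$prob)
      }
      out
    }

    res <- vector("list", nl)
    for (i in seq_len(nl)) {
      ct <- ctype[i]
      pop <- samples$population
      a1 <- draw_hap(i, pop)
      a2 <- draw_hap(i, pop)
      if (ct == "X") {
        a2[samples$sex == "M"] <- NA_integer_
      } else if (ct == "Y") {
        keep <- samples$sex == "M"
        a1[!keep] <- NA_integer_
        a2[] <- NA_integer_
      }
      res[[i]] <- data.frame(sample = samples$sample,
                             locus = loci$locus[i], a1 = a1, a2 = a2,
                             stringsAsFactors = FALSE)
    }
    genotypes <- do.call(rbind, res)
    # drop rows for absent chromosomes (female Y)
    genotypes <- genotypes[!(is.na(genotypes$a1) & is.na(genotypes$a2)), ]
    rownames(genotypes) <- NULL
    structure(list(samples = samples, genotypes = genotypes),
              class = "vntr_truth")
  })
}

empty_truth_df <- function() {
  data.frame(sample = character(0), locus = integer(0),
             a1 = integer(0), a2 = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.vntr_truth <- function(x, ...) {
  cat(sprintf("vntr_truth: %d samples x %d locus rows\n",
              nrow(x$samples), nrow(x$genotypes)))
  invisible(x)
}

#' Generate a child's true genotypes from two cohort parents
#'
#' At each autosomal locus the child receives one uniformly chosen allele
#' from each parent. With per-locus probability `mutation_rate` a de novo
#' change perturbs one of the inherited alleles by +-1 copy (sign flipped
#' when the allele would drop below one copy). A male child inherits his
#' X allele from the mother and his Y allele from the father; a female
#' child receives one maternal X and the paternal X.
#'
#' @param truth A `vntr_truth` containing both parents.
#' @param ref The `vntr_reference` the truth was sampled from.
#' @param mother,father Sample ids of the parents (sexes F and M).
#' @param child_id Sample id for the child.
#' @param child_sex `"M"` or `"F"`.
#' @param mutation_rate Per-locus de novo change probability.
#' @param seed Integer seed.
#' @return A `vntr_truth` with the child appended to `samples` and
#'   `genotypes`.
#' @export
generate_trio <- function(truth, ref, mother, father, child_id = "CHILD",
                          child_sex = "M", mutation_rate = 0, seed = NULL) {
  stopifnot(inherits(truth, "vntr_truth"),
            child_sex %in% c("M", "F"))
  sm <- truth$samples
  if (!(mother %in% sm$sample) || !(father %in% sm$sample))
    stop("parents must be present in the cohort")
  if (sm$sex[sm$sample == mother] != "F") stop("mother must have sex F")
  if (sm$sex[sm$sample == father] != "M") stop("father must have sex M")
  g <- truth$genotypes
  gm <- g[g$sample == mother, ]
  gf <- g[g$sample == father, ]
  loci <- ref$loci
  ids <- loci$locus[loci$locus %in% unique(c(gm$locus, gf$locus))]
  ct <- chrom_type(loci$chrom[match(ids, loci$locus)])
  rc <- loci$ref_copies[match(ids, loci$locus)]
  im <- match(ids, gm$locus)
  fi <- match(ids, gf$locus)
  with_seed(seed, {
    n <- length(ids)
    # maternal pick (a2 falls back to a1 on hemizygous rows)
    m2 <- ifelse(is.na(gm$a2[im]), gm$a1[im], gm$a2[im])
    mat <- ifelse(runif(n) < 0.5, gm$a1[im], m2)
    f2 <- ifelse(is.na(gf$a2[fi]), gf$a1[fi], gf$a2[fi])
    pat <- ifelse(runif(n) < 0.5, gf$a1[fi], f2)
    a1 <- mat
    a2 <- pat
    if (child_sex == "M") {
      a2[ct == "X"] <- NA_integer_            # X from mother only
      a1[ct == "Y"] <- gf$a1[fi][ct == "Y"]   # Y from father
      a2[ct == "Y"] <- NA_integer_
    } else {
      a2[ct == "X"] <- gf$a1[fi][ct == "X"]   # paternal X
    }
    keep <- !(ct == "Y" & child_sex == "F")
    if (mutation_rate > 0) {
      mut <- runif(n) < mutation_rate
      which_allele <- ifelse(is.na(a2), 1L, sample(c(1L, 2L), n,
                                                   replace = TRUE))
      delta <- sample(c(-1L, 1L), n, replace = TRUE)
      for (i in which(mut & keep)) {
        a <- if (which_allele[i] == 1L) a1[i] else a2[i]
        d <- delta[i]
        if (rc[i] + a + d < 1) d <- -d
        if (which_allele[i] == 1L) a1[i] <- a + d else a2[i] <- a + d
      }
    }
    child_g <- data.frame(sample = child_id, locus = ids,
                          a1 = a1, a2 = a2,
                          stringsAsFactors = FALSE)[keep, ]
    child_g <- child_g[!(is.na(child_g$a1) & is.na(child_g$a2)), ]
    truth$samples <- rbind(sm, data.frame(
      sample = child_id, population = sm$population[sm$sample == mother],
      sex = child_sex, stringsAsFactors = FALSE))
    truth$genotypes <- rbind(g, child_g)
    rownames(truth$genotypes) <- NULL
    truth
  })
}

#' Convert true genotypes to an allele-call table
#'
#' Produces the same long call format the genotyper emits (one row per
#' distinct allele per sample-locus), useful for driving cohort-level
#' analyses directly from simulated truth.
#'
#' @param truth A `vntr_truth`.
#' @param sp Read support value recorded per call (truth has no reads).
#' @return data.frame with columns `sample`, `locus`, `cgl`, `sp`.
#' @export
truth_as_calls <- function(truth, sp = 99L) {
  g <- truth$genotypes
  long <- rbind(
    data.frame(sample = g$sample, locus = g$locus, cgl = g$a1),
    data.frame(sample = g$sample, locus = g$locus, cgl = g$a2))
  long <- long[!is.na(long$cgl), ]
  long <- unique(long)
  long$sp <- as.integer(sp)
  long <- long[order(long$sample, long$locus, long$cgl), ]
  rownames(long) <- NULL
  long
}
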