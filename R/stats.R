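#' Pairwise Weir-Cockerham FST
#'
#' Multi-locus Weir & Cockerham (1984) estimator combined across loci as a
#' ratio of averages (sum of per-locus numerator components over sum of
#' denominator components).  For a `sample_set` the full diploid
#' variance-component estimator (a, b, c components including the
#' heterozygosity terms) is used on the sampled genotypes; for a
#' `founder_panel` the haploid analysis-of-variance analogue (no
#' within-individual component) is used on the founder haplotypes.  Loci
#' monomorphic in the pair contribute nothing; if every locus has a zero
#' denominator the value is flagged missing (`NA` with a warning).
#'
#' @param x A `sample_set` or `founder_panel`.
#' @param pop_a,pop_b Population (or source) labels.  If both `NULL`, the
#'   full symmetric matrix over all populations is returned.
#' @return A single FST value, or a symmetric matrix.
#' @export
pairwise_fst <- function(x, pop_a = NULL, pop_b = NULL) {
  UseMethod("pairwise_fst")
}

#' @export
pairwise_fst.founder_panel <- function(x, pop_a = NULL, pop_b = NULL) {
  fst_dispatch(x$source, pop_a, pop_b,
               function(a, b) fst_haploid(x$haplotypes, which(x$source == a),
                                          which(x$source == b)))
}

#' @export
pairwise_fst.sample_set <- function(x, pop_a = NULL, pop_b = NULL) {
  pops <- x$pop_of_individual
  fst_dispatch(pops, pop_a, pop_b, function(a, b) {
    ia <- which(pops == a); ib <- which(pops == b)
    if (length(ia) < 2L || length(ib) < 2L)
      stop("need >= 2 sampled individuals in each population", call. = FALSE)
    fst_diploid(x$alleles, ia, ib)
  })
}

fst_dispatch <- function(groups, pop_a, pop_b, pair_fun) {
  if (is.null(pop_a) != is.null(pop_b))
    stop("supply both `pop_a` and `pop_b`, or neither", call. = FALSE)
  if (!is.null(pop_a)) return(pair_fun(pop_a, pop_b))
  labs <- sort(unique(groups))
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  diag(out) <- 0
  for (i in seq_along(labs)[-1L])
    for (j in seq_len(i - 1L)) {
      v <- pair_fun(labs[i], labs[j])
      out[i, j] <- v; out[j, i] <- v
    }
  out
}

ratio_of_averages <- function(num, den) {
  dsum <- sum(den)
  if (dsum == 0) {
    warning("FST undefined: zero denominator at every locus")
    return(NA_real_)
  }
  sum(num) / dsum
}

# Haploid ANOVA estimator for two groups of chromosome columns.
fst_haploid <- function(X, cols_a, cols_b) {
  n1 <- length(cols_a); n2 <- length(cols_b)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 haplotypes per group", call. = FALSE)
  p1 <- cpp_row_alt_counts(X, cols_a) / n1
  p2 <- cpp_row_alt_counts(X, cols_b) / n2
  n <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / n
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # df = r - 1 = 1
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n - 2)
  nc <- n - (n1^2 + n2^2) / n
  ratio_of_averages(msp - msw, msp + (nc - 1) * msw)
}

# Full diploid Weir & Cockerham (1984) a/b/c components for two populations,
# vectorized over loci. `ia`/`ib` are individual indices into the sample.
fst_diploid <- function(alleles, ia, ib) {
  stats_of <- function(idx) {
    c1 <- 2L * idx - 1L; c2 <- 2L * idx
    alt <- cpp_row_alt_counts(alleles, c1) + cpp_row_alt_counts(alleles, c2)
    het <- cpp_row_het_counts(alleles, c1, c2)
    list(n = length(idx), p = alt / (2 * length(idx)),
         h = het / length(idx))
  }
  A <- stats_of(ia); B <- stats_of(ib)
  r <- 2
  n1 <- A$n; n2 <- B$n
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * A$p + n2 * B$p) / (n1 + n2)
  s2 <- (n1 * (A$p - pbar)^2 + n2 * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * A$h + n2 * B$h) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ratio_of_averages(a, a + b + cc)
}

#' Population heterozygosities
#'
#' Observed heterozygosity is the mean over SNPs of the fraction of
#' heterozygous individuals; expected heterozygosity is the mean over SNPs
#' of `2p(1-p)` with the unbiased small-sample correction `2n/(2n-1)`
#' (`n` diploid individuals, `2n` alleles).
#'
#' @param sample A `sample_set`.
#' @param pop Population label.
#' @return Named vector `c(het_obs, het_exp)`.
#' @export
heterozygosity <- function(sample, pop) {
  stopifnot(inherits(sample, "sample_set"))
  idx <- which(sample$pop_of_individual == pop)
  if (length(idx) < 1L) stop("no sampled individuals in population ", pop,
                             call. = FALSE)
  n <- length(idx)
  c1 <- 2L * idx - 1L; c2 <- 2L * idx
  het <- cpp_row_het_counts(sample$alleles, c1, c2)
  p <- (cpp_row_alt_counts(sample$alleles, c1) +
          cpp_row_alt_counts(sample$alleles, c2)) / (2 * n)
  hexp <- if (n > 1L || 2 * n > 1) 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
          else 2 * p * (1 - p)
  c(het_obs = mean(het / n), het_exp = mean(hexp))
}

#' Ancestry block sizes of the sampled admixed chromosomes
#'
#' Collects the lengths (map fractions; lengths per chromosome sum to 1) of
#' the merged same-source ancestry tracts of every sampled chromosome copy
#' of admixed individuals, grouped by population.
#'
#' @param sample A `sample_set`.
#' @param bp If `TRUE`, also report lengths in base pairs.
#' @return List with `per_population` (list of length vectors) and
#'   `summary` (`data.frame` with n, mean, median and deciles per
#'   population).
#' @export
ancestry_block_stats <- function(sample, bp = FALSE) {
  stopifnot(inherits(sample, "sample_set"))
  adm <- which(sample$is_admixed)
  if (!length(adm)) stop("no admixed individuals in the sample", call. = FALSE)
  pops <- sort(unique(sample$pop_of_individual[adm]))
  per_pop <- lapply(pops, function(p) {
    ids <- adm[sample$pop_of_individual[adm] == p]
    cols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    unlist(lapply(sample$tracts[cols], function(tr) diff(c(0, tr$ends))))
  })
  names(per_pop) <- paste0("pop", pops)
  if (bp) per_pop <- lapply(per_pop, function(v) v * sample$map_length_bp)
  qs <- t(vapply(per_pop, stats::quantile, numeric(11), probs = 0:10 / 10))
  summary <- data.frame(population = pops,
                        n_blocks = vapply(per_pop, length, 1L),
                        mean = vapply(per_pop, mean, 1),
                        median = vapply(per_pop, stats::median, 1),
                        qs, check.names = FALSE, row.names = NULL)
  list(per_population = per_pop, summary = summary)
}

#' Summary statistics of a simulated dataset
#'
#' Pairwise population FST matrix, per-population observed/expected
#' heterozygosity, and ancestry block sizes of the admixed chromosomes.
#'
#' @param sample A `sample_set`.
#' @return A `summary_stats` list.
#' @export
summary_stats <- function(sample) {
  pops <- sort(unique(sample$pop_of_individual))
  het <- t(vapply(pops, function(p) heterozygosity(sample, p), numeric(2)))
  structure(list(pairwise_fst = pairwise_fst(sample),
                 heterozygosity = data.frame(population = pops, het,
                                             row.names = NULL),
                 block_sizes = if (any(sample$is_admixed))
                   ancestry_block_stats(sample)),
            class = "summary_stats")
}

#' Export summary statistics as TSV files
#'
#' @param stats A `summary_stats` object.
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_summary_stats <- function(stats, out_dir) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f1 <- file.path(out_dir, "pairwise_fst.tsv")
  utils::write.table(stats$pairwise_fst, f1, sep = "\t", quote = FALSE)
  f2 <- file.path(out_dir, "heterozygosity.tsv")
  utils::write.table(stats$heterozygosity, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(f1, f2)
  if (!is.null(stats$block_sizes)) {
    f3 <- file.path(out_dir, "block_sizes.tsv")
    utils::write.table(stats$block_sizes$summary, f3, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f3)
  }
  invisible(files)
}
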