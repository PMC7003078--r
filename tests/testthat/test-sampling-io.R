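test_that("sampling is with replacement and respects per-population sizes", {
  p <- tiny_panel(seed = 5, L = 2e5)
  pops <- found_populations(p, rbind(diag(3), rep(1 / 3, 3))[c(1, 2, 3, 4), ],
                            sizes = rep(6L, 4), seed = 2)
  smp <- sample_individuals(pops, c(3, 0, 20, 5),
                            is_admixed = c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(as.vector(table(factor(smp$pop_of_individual,
                                          levels = 1:4))),
                   c(3L, 0L, 20L, 5L))  # o_p = 0 and o_p > n_p both valid
  expect_identical(length(smp$pop_of_individual), 28L)
  expect_identical(ncol(smp$alleles), 56L)
  expect_identical(sum(smp$is_admixed), 5L)
  expect_error(sample_individuals(pops, c(-1, 0, 0, 0)), "non-negative")
})

test_that("ancestry dosage entries are 0/0.5/1 and rows sum to 1", {
  smp <- small_dataset()
  Z <- ancestry_dosage(smp)
  expect_true(all(Z %in% c(0, 0.5, 1)))
  expect_equal(max(abs(apply(Z, c(1, 2), sum) - 1)), 0)
  # and the property survives filtering by construction (smp is filtered)
  expect_true(all(diff(smp$kept_index) > 0))
})

test_that("filter_monomorphic drops exactly the monomorphic columns", {
  # toy: 2 individuals x 3 sites; site 2 is all-reference
  al <- rbind(c(0, 1, 0, 0), c(0, 0, 0, 0), c(1, 1, 1, 0))
  ss <- make_sample_set(al, anc1 = matrix(1, 3, 2), anc2 = matrix(1, 3, 2))
  out <- filter_monomorphic(ss)
  expect_identical(out$kept_index, c(1L, 3L))
  expect_identical(nrow(out$alleles), 2L)
  expect_identical(out$positions, ss$positions[c(1, 3)])
  # identity when every site is polymorphic
  ss2 <- make_sample_set(rbind(c(0, 1, 0, 0), c(1, 1, 0, 0)),
                         matrix(1, 2, 2), matrix(1, 2, 2))
  expect_identical(filter_monomorphic(ss2), ss2)
  # all-monomorphic errors
  ss3 <- make_sample_set(rbind(c(0, 0, 0, 0)), matrix(1, 1, 2),
                         matrix(1, 1, 2))
  expect_error(filter_monomorphic(ss3), "empty dataset")
  # filtering never removes a polymorphic site (on a simulated dataset)
  smp <- small_dataset(seed = 6)
  g <- matrix(as.integer(smp$alleles), nrow(smp$alleles))
  expect_true(all(rowSums(g) > 0 & rowSums(g) < ncol(g)))
})

test_that("bp coordinates follow 1 + floor(pos * L) with collision bumping", {
  ss <- make_sample_set(rbind(c(0, 1), c(1, 0)), matrix(1, 2, 1),
                        matrix(1, 2, 1), positions = c(0.25, 0.75), L = 4e7)
  expect_identical(ss$bp_positions, c(10000001L, 30000001L))
  near <- mosaicsim:::bp_coordinates(c(0.5, 0.5 + 1e-9, 0.5 + 2e-9), 4e7)
  expect_identical(near, c(20000001L, 20000002L, 20000003L))
})

test_that("written outputs round-trip and the manifest is complete", {
  smp <- small_dataset(seed = 13)
  out <- withr::local_tempdir()
  manifest <- write_outputs(smp, out, scenario = "toy", seed = 13)
  expect_setequal(basename(manifest$file),
                  c("dataset.vcf", "dataset.ped", "dataset.map",
                    "truth_dosage.tsv", "truth_tracts.tsv", "summary.json"))
  expect_true(all(file.exists(manifest$file)))
  expect_true(all(nchar(manifest$md5) == 32))

  o <- length(smp$pop_of_individual)
  M <- length(smp$positions)
  # VCF: phased, positions and genotype matrix identical on re-read
  vcf <- read_vcf_genotypes(file.path(out, "dataset.vcf"))
  expect_true(vcf$phased)
  expect_identical(vcf$pos, smp$bp_positions)
  expect_identical(vcf$geno,
                   matrix(as.integer(smp$alleles), M, 2L * o))
  # plink: one .ped row per individual, one .map row per SNP, cM = 100 * pos
  ped <- readLines(file.path(out, "dataset.ped"))
  expect_length(ped, o)
  expect_length(strsplit(ped[1], " ")[[1]], 6L + 2L * M)
  map <- utils::read.table(file.path(out, "dataset.map"))
  expect_identical(nrow(map), M)
  expect_equal(map$V3, 100 * smp$positions)
  expect_identical(map$V4, smp$bp_positions)
  # truth dosage: re-read equals ancestry_dosage
  td <- read_truth_dosage(file.path(out, "truth_dosage.tsv"))
  expect_equal(td$Z, ancestry_dosage(smp))
  expect_identical(td$admixed, smp$is_admixed)
  # tract table: per chromosome copy, intervals tile [0, L)
  tr <- utils::read.table(file.path(out, "truth_tracts.tsv"), header = TRUE)
  for (k in unique(paste(tr$individual, tr$copy))) {
    seg <- tr[paste(tr$individual, tr$copy) == k, ]
    expect_identical(seg$start[1], 0L)
    expect_identical(seg$end[nrow(seg)], as.integer(smp$map_length_bp))
    if (nrow(seg) > 1)
      expect_identical(seg$start[-1], seg$end[-nrow(seg)])
  }
})

test_that("read_dataset rebuilds the sample_set from the written files", {
  smp <- small_dataset(seed = 18)
  out <- withr::local_tempdir()
  write_outputs(smp, out)
  back <- read_dataset(out)
  expect_identical(back$alleles, smp$alleles)
  expect_identical(back$bp_positions, smp$bp_positions)
  expect_identical(back$pop_of_individual, smp$pop_of_individual)
  expect_identical(back$is_admixed, smp$is_admixed)
  expect_identical(back$kept_index, smp$kept_index)
  # ancestry dosages (copy order is arbitrary) agree exactly
  expect_equal(ancestry_dosage(back), ancestry_dosage(smp))
  expect_equal(random_baseline_alpha(back)$alpha_overall,
               random_baseline_alpha(smp)$alpha_overall)
  # statistics recomputed from disk match the in-memory ones;
  # tract endpoints are bp-quantized, so block lengths match to 1/L
  expect_equal(pairwise_fst(back), pairwise_fst(smp))
  expect_equal(heterozygosity(back, 4), heterozygosity(smp, 4))
  b1 <- sort(ancestry_block_stats(back)$per_population[[1]])
  b2 <- sort(ancestry_block_stats(smp)$per_population[[1]])
  expect_lt(max(abs(b1 - b2)), 2 / smp$map_length_bp)
  expect_error(read_dataset(file.path(out, "nope")), "missing dataset")
})

test_that("unphased export uses / separators", {
  smp <- small_dataset(seed = 14)
  out <- withr::local_tempdir()
  write_outputs(smp, out, formats = "vcf", phased = FALSE)
  vcf <- read_vcf_genotypes(file.path(out, "dataset.vcf"))
  expect_false(vcf$phased)
  o <- length(smp$pop_of_individual)
  # genotype content is preserved up to within-individual order
  a <- matrix(as.integer(smp$alleles), nrow(smp$alleles))
  expect_identical(vcf$geno[, seq(1, 2 * o, 2)] + vcf$geno[, seq(2, 2 * o, 2)],
                   a[, seq(1, 2 * o, 2)] + a[, seq(2, 2 * o, 2)])
})

test_that("read_inferred_matrix validates, renormalizes and self-scores", {
  smp <- small_dataset(seed = 15)
  o <- length(smp$pop_of_individual)
  M <- length(smp$positions)
  S <- smp$S
  # uniform file
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(matrix(1 / S, o * M, S), f, row.names = FALSE,
              col.names = FALSE)
  X <- read_inferred_matrix(f, S, M, o)
  expect_identical(X$type, "matrix")
  expect_equal(max(abs(X$X - 1 / S)), 0)
  # the truth itself scores alpha = 1
  Z <- ancestry_dosage(smp)
  Xz <- matrix(aperm(Z, c(2, 1, 3)), o * M, S)
  write.table(Xz, f, row.names = FALSE, col.names = FALSE)
  res <- overall_alpha(smp, read_inferred_matrix(f, S, M, o))
  expect_equal(res$alpha_overall, 1)
  # renormalization with a warning
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("0.6 0.39", f2)
  expect_warning(X2 <- read_inferred_matrix(f2, 2, 1, 1), "renormalizing")
  expect_equal(as.vector(X2$X), c(0.6 / 0.99, 0.39 / 0.99),
               tolerance = 1e-12)
  # dimension and sign errors
  expect_error(read_inferred_matrix(f2, 3, 1, 1), "format error")
  writeLines("0.6 -0.1 0.5", f2)
  expect_error(read_inferred_matrix(f2, 3, 1, 1), "negative")
})
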