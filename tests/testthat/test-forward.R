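test_that("found_populations validates contributions", {
  p <- tiny_panel(seed = 2)
  expect_error(found_populations(p, matrix(c(0.5, 0.4, 0.2), 1), 10),
               "sum to 1")
  expect_error(found_populations(p, matrix(c(0.5, 0.5), 1), 10), "columns")
  expect_error(found_populations(p, rbind(c(1, 0, 0)), c(10, 10)),
               "sizes")
  expect_error(found_populations(p, rbind(c(-0.5, 1.5, 0)), 10),
               "non-negative")
})

test_that("degenerate contribution row puts every tract on one source", {
  p <- tiny_panel(seed = 2)
  pops <- found_populations(p, rbind(c(0, 1, 0)), sizes = 12, seed = 4)
  expect_true(all(vapply(pops$tracts, function(tr)
    identical(tr, list(ends = 1, src = 2L)), TRUE)))
  expect_identical(pops$generation, 0L)
  expect_identical(dim(pops$alleles), c(length(p$positions), 24L))
})

test_that("founding sources follow the contribution multinomial", {
  p <- tiny_panel(seed = 2)
  counts <- c(0, 0, 0)
  for (seed in 1:20) {
    pops <- found_populations(p, rbind(rep(1 / 3, 3)), sizes = 150,
                              seed = seed)
    src <- vapply(pops$tracts, function(tr) tr$src[1], 1L)
    counts <- counts + tabulate(src, 3)
  }
  gof <- stats::chisq.test(counts, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
})

test_that("meiosis_gamete splices alleles and tracts at the breakpoint", {
  M <- 10L
  positions <- (seq_len(M) - 0.5) / M
  c1 <- chromosome_copy(rep(0, M), ends = 1, src = 1L)
  c2 <- chromosome_copy(rep(1, M), ends = 1, src = 2L)
  g <- meiosis_gamete(c1, c2, positions, breakpoint = 0.3,
                      start_first = TRUE)
  expect_identical(g$tracts, list(ends = c(0.3, 1), src = c(1L, 2L)))
  expect_identical(as.integer(g$alleles), c(rep(0L, 3), rep(1L, 7)))
  # same-source parents merge into a single tract
  c2b <- chromosome_copy(rep(1, M), ends = 1, src = 1L)
  g2 <- meiosis_gamete(c1, c2b, positions, breakpoint = 0.3,
                       start_first = TRUE)
  expect_identical(g2$tracts, list(ends = 1, src = 1L))
})

test_that("a homozygous parent transmits itself for any breakpoint", {
  M <- 20L
  positions <- sort(runif(M))
  al <- as.raw(rbinom(M, 1, 0.5))
  c1 <- chromosome_copy(al, ends = c(0.4, 1), src = c(2L, 3L))
  for (b in c(0.1, 0.5, 0.9)) {
    g <- meiosis_gamete(c1, c1, positions, breakpoint = b,
                        start_first = FALSE)
    expect_identical(g$alleles, al)
    expect_identical(g$tracts, c1$tracts)
  }
})

test_that("bulk gamete construction matches single-meiosis replay", {
  set.seed(31)
  p <- tiny_panel(seed = 31, L = 2e5)
  pops <- found_populations(p, rbind(rep(1 / 3, 3), rep(1 / 3, 3)),
                            sizes = c(8, 8))
  nxt <- advance_generation(pops, rbind(c(1, 0, 0, 0), c(0.5, 0.2, 0.2, 0.1)),
                            mu_site = 0, keep_log = TRUE)
  log <- attr(nxt, "log")
  for (j in seq_along(log$acol)) {
    a <- log$acol[j]; b <- log$bcol[j]
    if (log$cut[j] == length(p$positions) && a == b) next  # vegetative copy
    g <- meiosis_gamete(list(alleles = pops$alleles[, a],
                             tracts = pops$tracts[[a]]),
                        list(alleles = pops$alleles[, b],
                             tracts = pops$tracts[[b]]),
                        pops$positions, breakpoint = log$breakpoint[j],
                        start_first = TRUE)
    expect_identical(g$alleles, nxt$alleles[, j])
    expect_identical(g$tracts, nxt$tracts[[j]])
  }
})

test_that("mutate_chromosome handles the rate extremes", {
  M <- 50L
  ch <- chromosome_copy(rbinom(M, 1, 0.5), ends = c(0.2, 1), src = 1:2)
  expect_identical(mutate_chromosome(ch, 0), ch)
  flipped <- mutate_chromosome(ch, 1)
  expect_identical(as.integer(flipped$alleles), 1L - as.integer(ch$alleles))
  expect_identical(flipped$tracts, ch$tracts)
  expect_error(mutate_chromosome(ch, 1.5), "probability")
})

test_that("mutation counts follow the binomial oracle", {
  set.seed(12)
  M <- 10000L
  ch <- chromosome_copy(rep(0, M))
  flips <- replicate(100, {
    sum(as.integer(mutate_chromosome(ch, 1e-3)$alleles))
  })
  # Binomial(1e4, 1e-3): mean 10, sd sqrt(9.99)
  se <- sqrt(M * 1e-3 * (1 - 1e-3) / 100)
  expect_lt(abs(mean(flips) - 10), 3 * se)
})

test_that("100% vegetative reproduction with mu = 0 is clonal", {
  set.seed(40)
  p <- tiny_panel(seed = 40, L = 2e5)
  pops0 <- found_populations(p, rbind(rep(1 / 3, 3)), sizes = 10)
  key <- function(ps) vapply(seq_along(ps$pop), function(i)
    paste(as.integer(ps$alleles[, c(2 * i - 1, 2 * i)]), collapse = ""),
    "")
  pops <- run_forward(pops0, reproduction_schedule(1, 6, within = 0,
                                                   vegetative = 1),
                      mu_site = 0)
  expect_true(all(key(pops) %in% key(pops0)))
  expect_identical(pops$generation, 6L)
})

test_that("selfing halves heterozygosity each generation", {
  set.seed(41)
  p <- tiny_panel(seed = 41, n_h = 40, L = 4e5)
  het_obs_of <- function(ps) {
    n <- length(ps$pop)
    a1 <- matrix(as.integer(ps$alleles[, seq(1, 2 * n, 2)]), ncol = n)
    a2 <- matrix(as.integer(ps$alleles[, seq(2, 2 * n, 2)]), ncol = n)
    mean(rowMeans(a1 != a2))
  }
  ratios <- c()
  for (seed in 1:8) {
    pops <- found_populations(p, rbind(rep(1 / 3, 3)), sizes = 250,
                              seed = seed)
    h <- het_obs_of(pops)
    for (g in 1:4) {
      pops <- advance_generation(pops, cbind(0, 0, 1, 0), mu_site = 0)
      h2 <- het_obs_of(pops)
      ratios <- c(ratios, h2 / h)
      h <- h2
    }
  }
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.5), 3 * se)
})

test_that("G = 0 leaves the population set unchanged", {
  p <- tiny_panel(seed = 50, L = 2e5)
  pops <- found_populations(p, rbind(c(1, 0, 0)), sizes = 5, seed = 1)
  out <- run_forward(pops, reproduction_schedule(1, 0), mu_site = 0)
  expect_identical(out, pops)
})

test_that("identical seeds give bit-identical population sets", {
  p <- tiny_panel(seed = 51, L = 2e5)
  go <- function() {
    set.seed(123)
    pops <- found_populations(p, rbind(rep(1 / 3, 3), c(1, 0, 0)),
                              sizes = c(10, 10))
    run_forward(pops, reproduction_schedule(2, 5, within = 0.6, across = 0.2,
                                            selfing = 0.1, vegetative = 0.1))
  }
  expect_identical(go(), go())
})

test_that("across-population mating requires P >= 2", {
  p <- tiny_panel(seed = 52, L = 2e5)
  pops <- found_populations(p, rbind(c(1, 0, 0)), sizes = 5, seed = 1)
  expect_error(advance_generation(pops, cbind(0.5, 0.5, 0, 0)),
               "at least two populations")
})

test_that("tract tiling holds after every generation under mixed modes", {
  set.seed(60)
  p <- tiny_panel(seed = 60, L = 2e5)
  pops <- found_populations(p, rbind(rep(1 / 3, 3), rep(1 / 3, 3)),
                            sizes = c(12, 12))
  for (g in 1:8) {
    pops <- advance_generation(
      pops, rbind(c(0.5, 0.2, 0.2, 0.1), c(0.8, 0, 0.1, 0.1)), mu_site = 0)
    for (tr in pops$tracts) {
      expect_silent(mosaicsim:::validate_tracts(tr))
      expect_equal(sum(diff(c(0, tr$ends))), 1)
    }
  }
})

test_that("junction counts satisfy the provable bounds and tracts shorten", {
  set.seed(61)
  p <- tiny_panel(seed = 61, L = 2e5)
  mean_len <- c(); mean_j <- c()
  for (g in c(5, 20, 50)) {
    pops <- found_populations(p, rbind(rep(1 / 3, 3), rep(1 / 3, 3)),
                              sizes = c(20, 20))
    pops <- run_forward(pops, reproduction_schedule(2, g), mu_site = 0)
    j <- vapply(pops$tracts, function(tr) length(tr$ends) - 1L, 1L)
    expect_lt(mean(j), g)                     # expected junctions <= g
    expect_true(all(j <= 2^g - 1))            # sharp almost-sure bound
    mean_j <- c(mean_j, mean(j))
    mean_len <- c(mean_len,
                  mean(unlist(lapply(pops$tracts, function(tr)
                    diff(c(0, tr$ends))))))
  }
  expect_true(all(diff(mean_j) > 0))
  expect_true(all(diff(mean_len) < 0))        # blocks shrink with time
})

test_that("tract-derived ancestry equals brute-force pedigree replay", {
  set.seed(70)
  p <- tiny_panel(seed = 70, L = 4e5)
  pops0 <- found_populations(p, rbind(rep(1 / 3, 3), rep(1 / 3, 3)),
                             sizes = c(5, 5))
  M <- length(p$positions)
  # oracle state: per-site source code of every chromosome column
  src <- vapply(pops0$tracts, expand_tract_sources, integer(M),
                positions = p$positions)
  pops <- run_forward(pops0, reproduction_schedule(2, 5, within = 0.7,
                                                   across = 0.1,
                                                   selfing = 0.1,
                                                   vegetative = 0.1),
                      mu_site = 0, keep_log = TRUE)
  for (log in attr(pops, "log")) {
    src <- vapply(seq_along(log$acol), function(j) {
      cut <- log$cut[j]
      c(src[seq_len(cut), log$acol[j]],
        src[seq_len(M - cut) + cut, log$bcol[j]])
    }, integer(M))
  }
  for (k in seq_along(pops$tracts))
    expect_identical(expand_tract_sources(pops$tracts[[k]], p$positions),
                     src[, k])
})

test_that("with mu = 0 tract alleles equal the founder segment", {
  set.seed(71)
  p <- tiny_panel(seed = 71, L = 2e5)
  pops <- found_populations(p, rbind(rep(1 / 3, 3)), sizes = 8)
  # record which founder column each chromosome started as, then follow one
  # generation of pure within mating and spot-check allele identity by tract
  fa <- matrix(as.integer(p$haplotypes), nrow(p$haplotypes))
  founder_col <- integer(16)
  for (k in 1:16)
    founder_col[k] <- which(colSums(fa != as.integer(pops$alleles[, k])) == 0)[1]
  nxt <- advance_generation(pops, cbind(1, 0, 0, 0), mu_site = 0,
                            keep_log = TRUE)
  log <- attr(nxt, "log")
  for (j in seq_len(8)) {
    cut <- log$cut[j]
    from_a <- p$haplotypes[seq_len(cut), founder_col[log$acol[j]]]
    expect_identical(nxt$alleles[seq_len(cut), j], from_a)
  }
})

test_that("vegetative switch freezes the ancestry mosaic", {
  set.seed(80)
  p <- tiny_panel(seed = 80, L = 2e5)
  pops <- found_populations(p, rbind(rep(1 / 3, 3)), sizes = 15)
  pops <- run_forward(pops, reproduction_schedule(1, 10), mu_site = 0)
  key <- function(ps) vapply(ps$tracts, function(tr)
    paste(signif(tr$ends, 12), tr$src, collapse = ";"), "")
  at_switch <- key(pops)
  pops <- run_forward(pops, reproduction_schedule(1, 5, within = 0,
                                                  vegetative = 1),
                      mu_site = 0)
  expect_true(all(key(pops) %in% at_switch))
})
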