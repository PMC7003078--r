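#' Ancestry tracts and chromosome copies
#'
#' A haploid chromosome copy is a plain list with an `alleles` raw vector
#' (0/1 over the panel positions) and a `tracts` element describing its true
#' local ancestry as an ordered tiling of the 1-Morgan map: `tracts$ends` are
#' the strictly increasing right endpoints of the half-open ancestry tracts
#' (the last is exactly 1) and `tracts$src` the source label (1..S) of each
#' tract; adjacent tracts always differ in source.
#'
#' @param alleles Raw (or 0/1 numeric) allele vector.
#' @param ends Right endpoints of the tracts; last must be 1.
#' @param src Integer source labels, one per tract.
#' @return A list with elements `alleles` and `tracts`.
#' @export
chromosome_copy <- function(alleles, ends = 1, src = 1L) {
  tr <- list(ends = as.numeric(ends), src = as.integer(src))
  validate_tracts(tr)
  if (!is.raw(alleles)) alleles <- as.raw(alleles)
  list(alleles = alleles, tracts = tr)
}

validate_tracts <- function(tr) {
  k <- length(tr$ends)
  if (k == 0L || length(tr$src) != k)
    stop("tracts must have matching `ends` and `src`", call. = FALSE)
  if (any(diff(c(0, tr$ends)) <= 0) || abs(tr$ends[k] - 1) > 1e-12)
    stop("tract ends must be strictly increasing and tile [0,1)",
         call. = FALSE)
  if (k > 1L && any(tr$src[-1L] == tr$src[-k]))
    stop("adjacent tracts must differ in source", call. = FALSE)
  invisible(tr)
}

# Ancestry tracts of the recombination product taking [0, b) from t1 and
# [b, 1) from t2, with same-source neighbours merged.
gamete_tracts <- function(t1, t2, b) {
  pre <- t1$ends < b
  n1 <- sum(pre)
  suf <- t2$ends > b
  src <- c(t1$src[seq_len(n1 + 1L)], t2$src[suf])
  ends <- c(t1$ends[pre], b, t2$ends[suf])
  r <- rle(src)
  list(ends = ends[cumsum(r$lengths)], src = r$values)
}

#' Single meiosis with exactly one crossover
#'
#' Gametes carry exactly one crossover, placed uniformly on the 1-Morgan map
#' (no interference, no zero-crossover gametes): the gamete copies one of the
#' two parental chromosomes on `[0, b)` and the other on `[b, 1)`, for both
#' alleles and ancestry tracts; the starting chromosome is chosen with
#' probability 1/2.
#'
#' @param chrom1,chrom2 The parent's two chromosome copies
#'   (see [chromosome_copy()]).
#' @param positions Variant positions (map fractions) shared by both copies.
#' @param breakpoint Crossover position in (0, 1); drawn uniformly if `NULL`.
#' @param start_first If `TRUE` the gamete starts on `chrom1`; drawn with
#'   probability 1/2 if `NULL`.
#' @return A chromosome copy.
#' @export
meiosis_gamete <- function(chrom1, chrom2, positions, breakpoint = NULL,
                           start_first = NULL) {
  if (length(chrom1$alleles) != length(positions) ||
      length(chrom2$alleles) != length(positions))
    stop("allele vectors and `positions` must have the same length",
         call. = FALSE)
  if (is.null(breakpoint)) breakpoint <- runif(1)
  if (is.null(start_first)) start_first <- runif(1) < 0.5
  if (!start_first) { tmp <- chrom1; chrom1 <- chrom2; chrom2 <- tmp }
  cut <- findInterval(breakpoint, positions)
  alleles <- c(chrom1$alleles[seq_len(cut)],
               chrom2$alleles[seq_len(length(positions) - cut) + cut])
  list(alleles = alleles,
       tracts = gamete_tracts(chrom1$tracts, chrom2$tracts, breakpoint))
}

#' Allele-flip mutation of a chromosome copy
#'
#' Each segregating position flips to the other allele independently with
#' probability `mu_site`; no new segregating sites are created after the
#' founder phase, and ancestry tracts are unchanged.
#'
#' @param chrom A chromosome copy.
#' @param mu_site Per-site, per-generation mutation probability in `[0, 1]`.
#' @return The mutated chromosome copy.
#' @export
mutate_chromosome <- function(chrom, mu_site) {
  if (!is.numeric(mu_site) || length(mu_site) != 1L || is.na(mu_site) ||
      mu_site < 0 || mu_site > 1)
    stop("`mu_site` must be a probability in [0, 1]", call. = FALSE)
  if (mu_site > 0 && length(chrom$alleles)) {
    hit <- runif(length(chrom$alleles)) < mu_site
    if (any(hit))
      chrom$alleles[hit] <- as.raw(bitwXor(as.integer(chrom$alleles[hit]), 1L))
  }
  chrom
}

new_population_set <- function(positions, S, map_length_bp, alleles, tracts,
                               sizes, generation = 0L) {
  structure(list(positions = positions, S = as.integer(S),
                 map_length_bp = map_length_bp, alleles = alleles,
                 tracts = tracts, sizes = as.integer(sizes),
                 pop = rep.int(seq_along(sizes), sizes),
                 generation = as.integer(generation)),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("<population_set> ", length(x$pop), " diploid individuals in ",
      length(x$sizes), " populations (sizes: ",
      paste(x$sizes, collapse = ", "), "), generation ", x$generation,
      ", ", length(x$positions), " sites\n", sep = "")
  invisible(x)
}

#' Found diploid populations from the founder panel
#'
#' Each of the `sum(sizes)` diploid individuals receives two whole founder
#' chromosomes drawn independently (without recombination, with replacement):
#' first a source `s` with probability `contributions[p, s]`, then a
#' haplotype uniformly among that source's founders.  Each chromosome copy
#' starts with a single ancestry tract covering the whole map.
#'
#' @param panel A [simulate_founders()] panel.
#' @param contributions `P x S` matrix of source contributions; each row
#'   must sum to 1 (tolerance 1e-9).
#' @param sizes Vector of population sizes `n_p` (diploid individuals).
#' @param seed Optional integer seed.
#' @return A `population_set` at generation 0.
#' @export
found_populations <- function(panel, contributions, sizes, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  contributions <- as.matrix(contributions)
  S <- panel$config$S
  if (ncol(contributions) != S)
    stop("`contributions` must have S = ", S, " columns", call. = FALSE)
  if (any(contributions < 0))
    stop("contributions must be non-negative", call. = FALSE)
  if (any(abs(rowSums(contributions) - 1) > 1e-9))
    stop("each `contributions` row must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  sizes <- as.integer(sizes)
  if (length(sizes) != nrow(contributions) || any(sizes <= 0))
    stop("`sizes` must be positive and match the rows of `contributions`",
         call. = FALSE)
  src_cols <- split(seq_along(panel$source), panel$source)
  used <- colSums(contributions) > 0
  if (any(used & tabulate(panel$source, S) == 0L))
    stop("contribution requested from a source with no founder haplotypes",
         call. = FALSE)
  P <- length(sizes)
  n_chrom <- 2L * sum(sizes)
  src_of <- integer(n_chrom)
  off <- 0L
  for (p in seq_len(P)) {
    k <- 2L * sizes[p]
    src_of[off + seq_len(k)] <- sample.int(S, k, replace = TRUE,
                                           prob = contributions[p, ])
    off <- off + k
  }
  hap_of <- integer(n_chrom)
  for (s in seq_len(S)) {
    w <- which(src_of == s)
    if (length(w))
      hap_of[w] <- src_cols[[s]][sample.int(length(src_cols[[s]]),
                                            length(w), replace = TRUE)]
  }
  alleles <- panel$haplotypes[, hap_of, drop = FALSE]
  tracts <- lapply(src_of, function(s) list(ends = 1, src = s))
  new_population_set(panel$positions, S, panel$config$map_length_bp,
                     alleles, tracts, sizes)
}

#' Reproduction schedule
#'
#' Builds the `P x 4 x G` array of per-population, per-generation
#' proportions of the four reproduction modes, in the fixed order
#' `within` (within-population random mating), `across` (mating with a
#' partner from another population), `selfing` and `vegetative` (clonal
#' copying of the whole chromosome pair).  Every 4-vector must be
#' non-negative and sum to 1.
#'
#' @param P Number of populations.
#' @param G Number of generations.
#' @param within,across,selfing,vegetative Mode proportions, recycled to
#'   length `P` (constant over generations; edit slices of the returned
#'   array for schedules that change through time).
#' @return A `P x 4 x G` array with dimnames on the mode axis.
#' @export
reproduction_schedule <- function(P, G, within = 1, across = 0,
                                  selfing = 0, vegetative = 0) {
  m <- cbind(within = rep_len(within, P), across = rep_len(across, P),
             selfing = rep_len(selfing, P), vegetative = rep_len(vegetative, P))
  sched <- array(m, dim = c(P, 4L, G),
                 dimnames = list(NULL,
                                 c("within", "across", "selfing", "vegetative"),
                                 NULL))
  validate_schedule(sched, P)
  sched
}

validate_schedule <- function(sched, P, G = NULL) {
  if (length(dim(sched)) != 3L || dim(sched)[1] != P || dim(sched)[2] != 4L)
    stop("schedule must be a P x 4 x G array", call. = FALSE)
  if (!is.null(G) && dim(sched)[3] != G)
    stop("schedule must have G = ", G, " generation columns", call. = FALSE)
  if (any(sched < 0) || any(abs(apply(sched, c(1, 3), sum) - 1) > 1e-9))
    stop("each mode 4-vector must be non-negative and sum to 1",
         call. = FALSE)
  invisible(sched)
}

#' Advance a population set by one generation
#'
#' Each of the `n_p` offspring of population `p` draws a reproduction mode
#' from `mode_props[p, ]`.  Within-population mating takes two distinct
#' parents from `p` (one meiosis gamete each); across-population mating takes
#' one parent from `p` and one from a uniformly chosen other population (the
#' offspring stays in `p`); selfing takes two independent gametes from a
#' single parent; vegetative reproduction copies a parent's chromosome pair
#' verbatim.  Allele-flip mutation at rate `mu_site` is applied to every
#' offspring chromosome whatever the reproduction mode.  Population sizes are
#' constant.
#'
#' @param pops A `population_set`.
#' @param mode_props `P x 4` matrix of mode proportions (order
#'   within/across/selfing/vegetative), rows summing to 1.
#' @param mu_site Per-site, per-generation mutation probability
#'   (default `2.5e-8`, matching `theta = 1e-4` at the example scaling).
#' @param allow_incidental_selfing If `TRUE`, within-population mating draws
#'   the two parents independently (so the same individual may be drawn
#'   twice); by default parents are distinct and selfing happens only through
#'   the explicit selfing mode.
#' @param keep_log If `TRUE`, attach the per-offspring event log (parent
#'   chromosome columns, crossover cut index and breakpoint) as attribute
#'   `"log"` of the result; used for pedigree-replay verification.
#' @return The next-generation `population_set`.
#' @export
advance_generation <- function(pops, mode_props, mu_site = 2.5e-8,
                               allow_incidental_selfing = FALSE,
                               keep_log = FALSE) {
  stopifnot(inherits(pops, "population_set"))
  P <- length(pops$sizes)
  mode_props <- matrix(mode_props, nrow = P, ncol = 4L)
  if (any(mode_props < 0) || any(abs(rowSums(mode_props) - 1) > 1e-9))
    stop("mode proportions must be non-negative and sum to 1", call. = FALSE)
  if (P == 1L && any(mode_props[, 2L] > 0))
    stop("across-population mating requires at least two populations",
         call. = FALSE)
  M <- length(pops$positions)
  sizes <- pops$sizes
  off_ind <- c(0L, cumsum(sizes))
  n_out <- 2L * sum(sizes)
  acol <- integer(n_out); bcol <- integer(n_out); cutv <- integer(n_out)
  brk <- numeric(n_out); is_sex <- logical(n_out)
  tracts_new <- vector("list", n_out)
  modes_all <- integer(sum(sizes))

  for (p in seq_len(P)) {
    np <- sizes[p]
    modes <- sample.int(4L, np, replace = TRUE, prob = mode_props[p, ])
    modes_all[off_ind[p] + seq_len(np)] <- modes
    i1 <- off_ind[p] + sample.int(np, np, replace = TRUE)
    i2 <- off_ind[p] + sample.int(np, np, replace = TRUE)
    if (!allow_incidental_selfing) {
      w <- which(modes == 1L & i1 == i2)
      while (length(w)) {
        i2[w] <- off_ind[p] + sample.int(np, length(w), replace = TRUE)
        w <- w[i1[w] == i2[w]]
      }
    }
    wa <- which(modes == 2L)
    if (length(wa)) {
      q <- sample.int(P - 1L, length(wa), replace = TRUE)
      q <- q + (q >= p)  # partner population, uniform among the others
      i2[wa] <- off_ind[q] + pmax(1L, ceiling(runif(length(wa)) * sizes[q]))
    }
    ws <- which(modes == 3L)
    i2[ws] <- i1[ws]

    for (o in seq_len(np)) {
      out1 <- 2L * (off_ind[p] + o) - 1L
      if (modes[o] == 4L) {           # vegetative: verbatim chromosome pair
        pc <- c(2L * i1[o] - 1L, 2L * i1[o])
        acol[out1] <- pc[1L]; acol[out1 + 1L] <- pc[2L]
        bcol[out1] <- pc[1L]; bcol[out1 + 1L] <- pc[2L]
        cutv[out1] <- M; cutv[out1 + 1L] <- M
        brk[out1] <- 1; brk[out1 + 1L] <- 1
        tracts_new[[out1]] <- pops$tracts[[pc[1L]]]
        tracts_new[[out1 + 1L]] <- pops$tracts[[pc[2L]]]
      } else {
        par2 <- c(i1[o], i2[o])
        for (g in 1:2) {
          j <- par2[g]
          b <- runif(1)
          s <- if (runif(1) < 0.5) 0L else 1L
          a <- 2L * j - 1L + s
          bb <- 2L * j - s
          out <- out1 + g - 1L
          acol[out] <- a; bcol[out] <- bb
          brk[out] <- b; is_sex[out] <- TRUE
          tracts_new[[out]] <- gamete_tracts(pops$tracts[[a]],
                                             pops$tracts[[bb]], b)
        }
      }
    }
  }

  cutv[is_sex] <- findInterval(brk[is_sex], pops$positions)
  alleles <- cpp_splice_columns(pops$alleles, acol, bcol, cutv)
  if (mu_site > 0) {
    ncell <- as.double(M) * n_out
    nflip <- rbinom(1L, size = ncell, prob = mu_site)
    if (nflip > 0) {
      idx <- sample(ncell, nflip)
      alleles[idx] <- as.raw(bitwXor(as.integer(alleles[idx]), 1L))
    }
  }
  out <- new_population_set(pops$positions, pops$S, pops$map_length_bp,
                            alleles, tracts_new, sizes,
                            pops$generation + 1L)
  if (keep_log)
    attr(out, "log") <- list(acol = acol, bcol = bcol, cut = cutv,
                             breakpoint = brk, modes = modes_all)
  out
}

#' Run the forward-in-time reproduction over G generations
#'
#' Applies [advance_generation()] once per generation column of `schedule`.
#' With `G = 0` columns the input is returned unchanged.  Deterministic for
#' a fixed RNG state.
#'
#' @inheritParams advance_generation
#' @param schedule A `P x 4 x G` array (see [reproduction_schedule()]).
#' @return The final `population_set`; with `keep_log = TRUE` the attribute
#'   `"log"` holds one per-generation event log.
#' @export
run_forward <- function(pops, schedule, mu_site = 2.5e-8,
                        allow_incidental_selfing = FALSE, keep_log = FALSE) {
  stopifnot(inherits(pops, "population_set"))
  P <- length(pops$sizes)
  validate_schedule(schedule, P)
  G <- dim(schedule)[3]
  logs <- if (keep_log) vector("list", G)
  for (g in seq_len(G)) {
    pops <- advance_generation(pops, schedule[, , g, drop = TRUE],
                               mu_site = mu_site,
                               allow_incidental_selfing = allow_incidental_selfing,
                               keep_log = keep_log)
    if (keep_log) { logs[[g]] <- attr(pops, "log"); attr(pops, "log") <- NULL }
  }
  if (keep_log) attr(pops, "log") <- logs
  pops
}

#' Extract one individual's chromosome copies
#'
#' @param pops A `population_set`.
#' @param i Individual index.
#' @return List of two [chromosome_copy()]-style lists.
#' @export
get_individual <- function(pops, i) {
  stopifnot(inherits(pops, "population_set"), i >= 1, i <= length(pops$pop))
  lapply(c(2L * i - 1L, 2L * i), function(j)
    list(alleles = pops$alleles[, j], tracts = pops$tracts[[j]]))
}
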