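#' Scenario presets
#'
#' Builds a fully resolved configuration for one of the six benchmark
#' scenarios.  All presets share the baseline: 300 founder haplotypes per
#' source, populations of 150 diploid individuals, theta = rho = 1e-4 per
#' site on a 1-Morgan / 4e7 bp chromosome, 50 forward generations,
#' source-representative populations reproducing by within-population
#' random mating, two admixed populations founded with the stated source
#' contributions, and samples of 20 individuals per source-representative
#' population and 40 per admixed population.  Scenario-specific defaults
#' (overridable through the arguments):
#'
#' * `DiffGenSam` - 3 sources; `tau` (default 0.2, range 0.05-0.40) and
#'   `tadm` (default 50, range 5-50; realized as `G = tadm`) control
#'   differentiation and admixture age; `op_src` (5-40) the
#'   source-representative sample size.
#' * `SamBal` - unbalanced sampling: the third source-representative
#'   population is sampled at `op_src_third` (default 2, range 2-20),
#'   the other two at 20.
#' * `SrcNum` - `S` sources (3-6, default 6) contributing equally to the
#'   admixed populations; one representative population per source.
#' * `SrcMiss` - 4 sources simulated but only 3 represented; the missing
#'   source contributes `un` (default 0.15, range 0-0.15) to the admixed
#'   populations, the others contribute `(1 - un)/3` each.
#' * `SrcSelf` - the third source-representative population reproduces
#'   with selfing proportion `slf` (default 0.99, range 0-0.99).
#' * `AdmxVegProp` - 10 admixed populations of 100 individuals (10
#'   sampled each) that switch from random mating to exclusive vegetative
#'   propagation `tveg` generations before sampling
#'   (default `seq(0, 45, by = 5)`, one value per admixed population).
#'
#' @param name Scenario name.
#' @param tau,S,tadm,op_src,op_admx,n_admx Overrides of the shared
#'   parameters (`op_src` may be a vector, one value per
#'   source-representative population).
#' @param op_src_third,un,slf,tveg Scenario-specific parameters (see
#'   above).
#' @param n_h,np,np_admx Founder haplotypes per source and population
#'   sizes (reduce for quick tests).
#' @param theta,rho,map_length_bp Founder-model rates.
#' @param mu_forward Per-site forward mutation rate.
#' @param reps Default number of replicates for [run_replicates()].
#' @param seed Base seed.
#' @return A `scenario_config`.
#' @export
build_scenario <- function(name = c("DiffGenSam", "SamBal", "SrcNum",
                                    "SrcMiss", "SrcSelf", "AdmxVegProp"),
                           tau = NULL, S = NULL, tadm = NULL,
                           op_src = NULL, op_admx = NULL, n_admx = NULL,
                           op_src_third = NULL, un = NULL, slf = NULL,
                           tveg = NULL, n_h = 300L, np = 150L,
                           np_admx = NULL, theta = 1e-4, rho = 1e-4,
                           map_length_bp = 4e7, mu_forward = 2.5e-8,
                           reps = 50L, seed = 1L) {
  name <- match.arg(name)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  tau <- tau %||% 0.2
  G <- 50L
  slf_third <- 0
  missing_source <- NA_integer_
  tveg_vec <- NULL

  switch(name,
    DiffGenSam = {
      S <- S %||% 3L
      G <- as.integer(tadm %||% 50L)
      n_admx <- n_admx %||% 2L
    },
    SamBal = {
      S <- S %||% 3L
      if (!is.null(tadm)) G <- as.integer(tadm)
      n_admx <- n_admx %||% 2L
      op_src <- op_src %||% c(20L, 20L, as.integer(op_src_third %||% 2L))
    },
    SrcNum = {
      S <- S %||% 6L
      if (!is.null(tadm)) G <- as.integer(tadm)
      n_admx <- n_admx %||% 2L
    },
    SrcMiss = {
      S <- S %||% 4L
      if (!is.null(tadm)) G <- as.integer(tadm)
      n_admx <- n_admx %||% 2L
      un <- un %||% 0.15
      if (un < 0 || un >= 1) stop("`un` must be in [0, 1)", call. = FALSE)
      missing_source <- S
    },
    SrcSelf = {
      S <- S %||% 3L
      if (!is.null(tadm)) G <- as.integer(tadm)
      n_admx <- n_admx %||% 2L
      slf_third <- slf %||% 0.99
      if (slf_third < 0 || slf_third > 1)
        stop("`slf` must be in [0, 1]", call. = FALSE)
    },
    AdmxVegProp = {
      S <- S %||% 3L
      if (!is.null(tadm)) G <- as.integer(tadm)
      n_admx <- n_admx %||% 10L
      np_admx <- np_admx %||% 100L
      op_admx <- op_admx %||% 10L
      tveg_vec <- as.integer(tveg %||% seq(0L, 45L, by = 5L))
      tveg_vec <- rep_len(tveg_vec, n_admx)
      if (any(tveg_vec < 0) || any(tveg_vec > G))
        stop("`tveg` must lie in [0, G]", call. = FALSE)
    })

  S <- as.integer(S)
  n_src_rep <- if (is.na(missing_source)) S else S - 1L
  P <- n_src_rep + n_admx
  op_src <- as.integer(rep_len(op_src %||% 20L, n_src_rep))
  op_admx <- as.integer(op_admx %||% 40L)
  np_admx <- as.integer(np_admx %||% np)

  contributions <- matrix(0, P, S)
  for (p in seq_len(n_src_rep)) contributions[p, p] <- 1
  adm_contrib <- if (is.na(missing_source)) rep(1 / S, S)
                 else c(rep((1 - un) / (S - 1L), S - 1L), un)
  for (p in n_src_rep + seq_len(n_admx)) contributions[p, ] <- adm_contrib

  sched <- reproduction_schedule(P, G)
  if (slf_third > 0 && n_src_rep >= 3L) {
    sched[3L, "within", ] <- 1 - slf_third
    sched[3L, "selfing", ] <- slf_third
  }
  if (!is.null(tveg_vec)) {
    for (j in seq_len(n_admx)) {
      if (tveg_vec[j] > 0L) {
        gens <- (G - tveg_vec[j] + 1L):G
        sched[n_src_rep + j, "within", gens] <- 0
        sched[n_src_rep + j, "vegetative", gens] <- 1
      }
    }
  }

  structure(list(
    name = name,
    founder = founder_config(S = S, n_h_per_source = n_h, tau = tau,
                             theta = theta, rho = rho,
                             map_length_bp = map_length_bp),
    P = P, S = S, G = G,
    roles = rep(c("source", "admixed"), c(n_src_rep, n_admx)),
    contributions = contributions,
    schedule = sched,
    sizes = c(rep(as.integer(np), n_src_rep), rep(np_admx, n_admx)),
    o_per_pop = c(op_src, rep(op_admx, n_admx)),
    missing_source = missing_source,
    mu_forward = mu_forward,
    un = if (name == "SrcMiss") un,
    slf = if (name == "SrcSelf") slf_third,
    tveg = tveg_vec,
    reps = as.integer(reps), seed = as.integer(seed)),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, ": S = ", x$S, ", tau = ",
      x$founder$tau, ", G = ", x$G, ", ", sum(x$roles == "source"),
      " source-representative + ", sum(x$roles == "admixed"),
      " admixed populations", sep = "")
  if (!is.na(x$missing_source))
    cat(", missing source ", x$missing_source, " (un = ", x$un, ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Run one scenario replicate end to end
#'
#' Founder coalescent, population founding, forward reproduction, sampling,
#' monomorphic filtering and random-baseline scoring, all under one seed.
#'
#' @param cfg A `scenario_config`.
#' @param seed Integer seed for the replicate.
#' @param compute_stats Also compute [summary_stats()].
#' @param keep_sample Keep the `sample_set` in the result (memory!).
#' @param out_dir If non-`NULL`, write the dataset files there via
#'   [write_outputs()].
#' @return A `replicate_result` list with `seed`, `n_snps` (post-filter),
#'   `n_snps_prefilter`, `alpha_random`, and optionally `stats`, `sample`,
#'   `manifest`.
#' @export
simulate_scenario <- function(cfg, seed = cfg$seed, compute_stats = FALSE,
                              keep_sample = FALSE, out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(as.integer(seed))
  panel <- simulate_founders(cfg$founder)
  pops <- found_populations(panel, cfg$contributions, cfg$sizes)
  rm(panel)
  pops <- run_forward(pops, cfg$schedule, mu_site = cfg$mu_forward)
  smp <- sample_individuals(pops, cfg$o_per_pop,
                            is_admixed = cfg$roles == "admixed")
  rm(pops)
  m0 <- length(smp$positions)
  smp <- filter_monomorphic(smp)
  acc <- random_baseline_alpha(smp, missing_source = cfg$missing_source)
  res <- list(seed = as.integer(seed),
              n_snps = length(smp$positions),
              n_snps_prefilter = m0,
              alpha_random = acc$alpha_overall,
              n_scored_cells = acc$n_included)
  if (compute_stats) res$stats <- summary_stats(smp)
  if (!is.null(out_dir))
    res$manifest <- write_outputs(smp, out_dir, scenario = cfg$name,
                                  seed = seed)
  if (keep_sample) res$sample <- smp
  class(res) <- "replicate_result"
  res
}

#' Run replicated scenario simulations
#'
#' Replicate `r` uses the derived seed `seed + r - 1`, so runs are
#' independent and reproducible from a single base seed.
#'
#' @param cfg A `scenario_config`.
#' @param reps Number of replicates (default `cfg$reps`).
#' @param seed Base seed (default `cfg$seed`).
#' @param compute_stats,out_dir Passed to [simulate_scenario()] (replicate
#'   outputs go to `out_dir/rep<r>/`).
#' @param verbose Print one line per replicate.
#' @return List with `results` (per-replicate `replicate_result`s) and
#'   `aggregate`: a `data.frame` with mean, 95% confidence half-width
#'   (1.96 SE) and sd of the random-baseline accuracy, plus SNP-count
#'   summaries.
#' @export
run_replicates <- function(cfg, reps = NULL, seed = NULL,
                           compute_stats = FALSE, out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  reps <- as.integer(reps %||% cfg$reps)
  seed <- as.integer(seed %||% cfg$seed)
  if (seed + reps - 1 > .Machine$integer.max)
    stop("base seed too large", call. = FALSE)
  results <- vector("list", reps)
  for (r in seq_len(reps)) {
    rdir <- if (!is.null(out_dir)) file.path(out_dir, paste0("rep", r))
    t0 <- proc.time()[3]
    results[[r]] <- simulate_scenario(cfg, seed = seed + r - 1L,
                                      compute_stats = compute_stats,
                                      out_dir = rdir)
    if (verbose)
      message(sprintf("replicate %d/%d: seed %d, M = %d, alpha_random = %.4f (%.1fs)",
                      r, reps, seed + r - 1L, results[[r]]$n_snps,
                      results[[r]]$alpha_random, proc.time()[3] - t0))
  }
  al <- vapply(results, `[[`, 1, "alpha_random")
  ms <- vapply(results, `[[`, 1L, "n_snps")
  aggregate <- data.frame(
    statistic = c("alpha_random", "n_snps"),
    mean = c(mean(al), mean(ms)),
    ci95_halfwidth = 1.96 * c(stats::sd(al), stats::sd(ms)) / sqrt(reps),
    sd = c(stats::sd(al), stats::sd(ms)),
    min = c(min(al), min(ms)),
    max = c(max(al), max(ms)))
  list(results = results, aggregate = aggregate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
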