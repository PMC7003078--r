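#' Configuration of the founder (coalescent) simulation
#'
#' Founder haplotypes are generated for `S` source populations that split
#' simultaneously from a single ancestral population ("star-shaped" history)
#' and then diverge by drift alone: no migration, equal population sizes for
#' the sources and their ancestor.  The effective size is not a free
#' parameter; everything is controlled through the scaled quantities
#' `tau`, `theta` and `rho`.
#'
#' `tau` parameterises the amount of divergence: the expected multi-locus
#' Weir-Cockerham FST between any two sources is `1 - exp(-tau)`
#' (see [expected_fst()]).  `theta = 4*Ne*mu` is the scaled per-site mutation
#' rate (within-source nucleotide diversity per site has expectation `theta`),
#' and `rho = 4*Ne*r` the scaled per-site recombination rate.  The chromosome
#' has a genetic length of exactly 1 Morgan and a physical length of
#' `map_length_bp` base pairs; variant positions are kept as fractions of the
#' map in `[0, 1)` and only converted to base pairs on export.
#'
#' @param S Number of source populations (>= 2).
#' @param n_h_per_source Haplotypes sampled per source (>= 2); either a
#'   single value recycled to all sources or a length-`S` vector.
#' @param tau Divergence time in scaled units; `expected_fst(tau)` is the
#'   expected pairwise FST among sources.
#' @param theta Scaled per-site mutation rate `4*Ne*mu` (> 0).
#' @param rho Scaled per-site recombination rate `4*Ne*r` (>= 0).
#' @param map_length_bp Physical chromosome length in bp; the default
#'   4e7 corresponds to r = 2.5e-8/site on a 1-Morgan map.
#' @param seed Optional integer seed applied by [simulate_founders()].
#' @return An object of class `founder_config`.
#' @seealso [simulate_founders()], [expected_fst()]
#' @export
founder_config <- function(S = 3L, n_h_per_source = 300L, tau = 0.2,
                           theta = 1e-4, rho = 1e-4,
                           map_length_bp = 4e7, seed = NULL) {
  S <- as.integer(S)
  if (is.na(S) || S < 2L)
    stop("`S` must be an integer >= 2", call. = FALSE)
  n_h <- as.integer(rep_len(n_h_per_source, S))
  if (any(is.na(n_h)) || any(n_h < 2L))
    stop("`n_h_per_source` must be >= 2 for every source", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(theta) || theta <= 0)
    stop("`theta` must be > 0", call. = FALSE)
  if (!is.numeric(rho) || rho < 0)
    stop("`rho` must be >= 0", call. = FALSE)
  if (!is.numeric(map_length_bp) || map_length_bp < 1)
    stop("`map_length_bp` must be >= 1", call. = FALSE)
  structure(list(S = S, n_h_per_source = n_h, tau = tau, theta = theta,
                 rho = rho, map_length_bp = as.numeric(map_length_bp),
                 seed = seed),
            class = "founder_config")
}

#' Expected pairwise FST under the star-shaped pure-drift model
#'
#' Closed form for the differentiation produced by `tau` scaled units of
#' drift with no migration: `1 - exp(-tau)`.
#'
#' @param tau Non-negative divergence time(s).
#' @return `1 - exp(-tau)`, in `[0, 1)`.
#' @examples
#' expected_fst(0.4) # ~0.33
#' @export
expected_fst <- function(tau) {
  if (!is.numeric(tau) || any(is.na(tau)) || any(tau < 0))
    stop("`tau` must be non-negative", call. = FALSE)
  -expm1(-tau)
}

# Number of independent coalescent windows used to approximate recombination
# during the founder phase. Windows are completely linked internally and
# unlinked to each other; more windows for larger total scaled recombination.
n_founder_windows <- function(cfg) {
  rho_tot <- cfg$rho * cfg$map_length_bp
  max(1L, min(512L, as.integer(round(rho_tot / 8))))
}

#' Simulate founder haplotypes from diverged source populations
#'
#' Runs a structured coalescent with a star-shaped pure-drift divergence:
#' within each source, lineages coalesce freely; at the (internal) split time
#' all sources merge into the common ancestral population.  Recombination is
#' approximated by cutting the 1-Morgan map into independent windows (one
#' non-recombining coalescent tree per window, completely linked sites within
#' a window); mutations follow the infinite-sites model, so every panel
#' column is polymorphic across the full panel.
#'
#' The internal split time is `exp(tau) - 1` in within-deme pair-coalescence
#' units, which makes the realized multi-locus Weir-Cockerham FST between
#' sources match `expected_fst(tau) = 1 - exp(-tau)` in expectation (the
#' ratio-of-averages estimator converges to `T/(1+T)` for a split at `T`;
#' see the methods vignette).
#'
#' @param cfg A [founder_config()].
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @return An object of class `founder_panel` with elements:
#'   \describe{
#'     \item{positions}{strictly increasing variant positions as map
#'       fractions in `[0, 1)`;}
#'     \item{haplotypes}{raw 0/1 matrix, sites in rows, one column per
#'       founder chromosome;}
#'     \item{source}{integer source label (1..S) of each column;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_founders <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "founder_config"))
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  W <- n_founder_windows(cfg)
  # Haploid-Ne convention: theta = 4*Ne*mu with Ne haploid, so within-source
  # per-site diversity is 2*Ne*mu = theta/2 (the factor 1/2 below; the other
  # 1/2 is the usual per-lineage branch-rate factor applied in the backend).
  theta_window <- cfg$theta * cfg$map_length_bp / W / 2
  split_time <- expm1(cfg$tau)
  res <- cpp_founder_sim(cfg$n_h_per_source, split_time, theta_window, W)
  pos <- res$positions
  if (length(pos) == 0L)
    stop("empty panel: no segregating sites were generated; ",
         "increase `theta` or `map_length_bp`", call. = FALSE)
  keep <- c(TRUE, diff(pos) > 0)  # defensive: positions strictly increasing
  geno <- res$geno
  if (!all(keep)) {
    pos <- pos[keep]
    geno <- geno[keep, , drop = FALSE]
  }
  structure(list(positions = pos, haplotypes = geno,
                 source = rep.int(seq_len(cfg$S), cfg$n_h_per_source),
                 config = cfg),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("<founder_panel> ", ncol(x$haplotypes), " haplotypes from ",
      x$config$S, " sources, ", length(x$positions),
      " segregating sites (tau = ", x$config$tau, ")\n", sep = "")
  invisible(x)
}
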