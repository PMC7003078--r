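#' SNP-specific local-ancestry accuracy
#'
#' For one individual at one SNP, with true diploid ancestry dosages
#' `z` (entries 0, 0.5 or 1, summing to 1 over the S sources) and inferred
#' proportions `x` (non-negative, summing to 1), the accuracy is
#' `1 - sum(|z - x|) / 2`, which lies in `[0, 1]`: 1 for a perfect call and
#' 0 when the supports are disjoint.
#'
#' @param z_row True dosage vector over sources.
#' @param x_row Inferred proportion vector over sources.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' alpha_site(c(1, 0, 0), c(1/3, 1/3, 1/3)) # 1/3
#' @export
alpha_site <- function(z_row, x_row) {
  if (length(z_row) != length(x_row))
    stop("`z_row` and `x_row` must have the same length", call. = FALSE)
  if (abs(sum(z_row) - 1) > 1e-6 || abs(sum(x_row) - 1) > 1e-6)
    stop("ancestry rows must sum to 1", call. = FALSE)
  if (any(x_row < 0) || !all(z_row %in% c(0, 0.5, 1)))
    stop("`z_row` entries must be 0/0.5/1 and `x_row` non-negative",
         call. = FALSE)
  1 - sum(abs(z_row - x_row)) / 2
}

#' Uniform random-inference baseline
#'
#' The calibration floor for the accuracy metric: every cell is assigned
#' `1/S` for each of the `S` sources.  Held lazily (no dense array is
#' materialized).
#'
#' @param S Number of sources (>= 2).
#' @param n_individuals,M Dataset dimensions.
#' @return An `inferred_ancestry` object.
#' @export
random_inference <- function(S, n_individuals, M) {
  if (S < 2L) stop("`S` must be >= 2", call. = FALSE)
  inferred_ancestry("uniform", S = S, M = M, n_individuals = n_individuals)
}

#' Overall local-ancestry accuracy
#'
#' Averages the SNP-specific accuracy [alpha_site()] over all unmasked
#' (individual, SNP) cells of *admixed* individuals; individuals flagged as
#' source representatives are excluded from the average.
#'
#' @param truth A `sample_set` (compact per-site source codes) or a dense
#'   dosage array `oP x M x S` as returned by [ancestry_dosage()].
#' @param inferred An `inferred_ancestry` object (see
#'   [read_inferred_matrix()], [random_inference()]), a matrix
#'   `(oP * M) x S` in individual-major order, or a dense `oP x M x S`
#'   array.
#' @param mask Optional logical `oP x M` matrix; `TRUE` cells are included
#'   (intersected with the admixed-individual restriction).
#' @param admixed Logical per-individual flags; defaults to the flags
#'   carried by the `sample_set` (or all `TRUE` for array truth).
#' @return An `accuracy_result` list with `alpha_site` (oP x M matrix, `NA`
#'   outside the averaged cells), `mask`, `alpha_overall` and `n_included`.
#' @export
overall_alpha <- function(truth, inferred, mask = NULL, admixed = NULL) {
  tz <- truth_codes(truth, admixed)
  o <- tz$o; M <- tz$M; S <- tz$S
  inf <- as_inferred(inferred, S, M, o)
  if (is.null(mask)) mask <- matrix(TRUE, o, M)
  if (!is.logical(mask) || !all(dim(mask) == c(o, M)))
    stop("`mask` must be a logical oP x M matrix", call. = FALSE)
  alpha <- matrix(NA_real_, o, M)
  inc <- mask & tz$admixed
  if (!any(inc)) stop("empty mask: no admixed cells to average",
                      call. = FALSE)
  uniform <- inf$type == "uniform"
  for (i in which(rowSums(inc) > 0)) {
    w <- which(inc[i, ])
    a <- tz$a1[w, i]; b <- tz$a2[w, i]
    if (uniform) {
      xa <- rep(1 / S, length(w)); xb <- xa
    } else {
      Xi <- inf$X[(i - 1L) * M + w, , drop = FALSE]
      xa <- Xi[cbind(seq_along(w), a)]
      xb <- Xi[cbind(seq_along(w), b)]
    }
    hom <- a == b
    v <- numeric(length(w))
    v[hom] <- xa[hom]
    v[!hom] <- 1 - (abs(0.5 - xa[!hom]) + abs(0.5 - xb[!hom]) +
                      1 - xa[!hom] - xb[!hom]) / 2
    alpha[i, w] <- v
  }
  structure(list(alpha_site = alpha, mask = inc,
                 alpha_overall = mean(alpha[inc]),
                 n_included = sum(inc)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat("<accuracy_result> alpha = ", format(x$alpha_overall, digits = 4),
      " over ", x$n_included, " (individual, SNP) cells\n", sep = "")
  invisible(x)
}

# Normalize truth to compact per-site source-code matrices (M x o, integer).
truth_codes <- function(truth, admixed = NULL) {
  if (inherits(truth, "sample_set")) {
    o <- length(truth$pop_of_individual)
    M <- length(truth$positions)
    if (is.null(admixed)) admixed <- truth$is_admixed
    return(list(a1 = matrix(as.integer(truth$anc1), M, o),
                a2 = matrix(as.integer(truth$anc2), M, o),
                o = o, M = M, S = truth$S, admixed = admixed))
  }
  if (is.array(truth) && length(dim(truth)) == 3L) {
    d <- dim(truth)
    o <- d[1]; M <- d[2]; S <- d[3]
    if (any(abs(apply(truth, c(1, 2), sum) - 1) > 1e-6))
      stop("truth dosage rows must sum to 1", call. = FALSE)
    a1 <- matrix(0L, M, o); a2 <- matrix(0L, M, o)
    for (i in seq_len(o)) {
      zi <- matrix(truth[i, , ], M, S)
      a1[, i] <- max.col(zi, ties.method = "first")
      half <- zi == 0.5
      a2[, i] <- ifelse(rowSums(half) == 2L,
                        max.col(half, ties.method = "last"), a1[, i])
    }
    if (is.null(admixed)) admixed <- rep(TRUE, o)
    return(list(a1 = a1, a2 = a2, o = o, M = M, S = S, admixed = admixed))
  }
  stop("`truth` must be a sample_set or an oP x M x S dosage array",
       call. = FALSE)
}

as_inferred <- function(inferred, S, M, o) {
  if (inherits(inferred, "inferred_ancestry")) {
    if (inferred$S != S || inferred$M != M || inferred$n != o)
      stop("inferred dimensions (", inferred$n, " x ", inferred$M, " x ",
           inferred$S, ") do not match the truth (", o, " x ", M, " x ", S,
           ")", call. = FALSE)
    return(inferred)
  }
  if (is.array(inferred) && length(dim(inferred)) == 3L) {
    d <- dim(inferred)
    X <- matrix(aperm(inferred, c(2, 1, 3)), d[1] * d[2], d[3])
    return(as_inferred(inferred_ancestry(X, d[3], d[2], d[1]), S, M, o))
  }
  if (is.matrix(inferred))
    return(as_inferred(inferred_ancestry(inferred, ncol(inferred), M, o),
                       S, M, o))
  stop("unsupported `inferred` type", call. = FALSE)
}

#' Mask cells carrying ancestry from a missing source
#'
#' For datasets where one simulated source has no representative
#' population, excludes every (individual, SNP) cell whose true dosage of
#' the missing source is positive, and drops the missing source's column
#' from the truth (remaining rows of included cells already sum to 1).
#' Masking is per cell by default; `per_site = TRUE` instead drops a SNP
#' for all individuals as soon as any admixed individual carries the
#' missing ancestry there.
#'
#' @param truth A `sample_set` or dosage array.
#' @param missing_source Source label to remove.
#' @param per_site Use the site-global masking variant.
#' @return List with `truth` (reduced to S-1 sources) and logical `mask`
#'   (`oP x M`, `TRUE` = keep).
#' @export
missing_source_mask <- function(truth, missing_source, per_site = FALSE) {
  if (inherits(truth, "sample_set")) {
    S <- truth$S
    if (S < 2L) stop("need S >= 2", call. = FALSE)
    k <- as.integer(missing_source)
    if (k < 1L || k > S) stop("invalid `missing_source`", call. = FALSE)
    kr <- as.raw(k)
    hit <- truth$anc1 == kr | truth$anc2 == kr
    mask <- t(!hit)
    if (per_site) {
      bad_site <- apply(hit[, truth$is_admixed, drop = FALSE], 1, any)
      mask <- matrix(rep(!bad_site, each = nrow(mask)), nrow(mask))
    }
    if (!any(mask[truth$is_admixed, , drop = FALSE]))
      stop("masking removed every admixed cell", call. = FALSE)
    remap <- function(a) {
      ai <- matrix(as.integer(a), nrow(a), ncol(a))
      ai[ai == k] <- 1L  # arbitrary; always masked out
      ai[ai > k] <- ai[ai > k] - 1L
      matrix(as.raw(ai), nrow(a), ncol(a))
    }
    truth$anc1 <- remap(truth$anc1)
    truth$anc2 <- remap(truth$anc2)
    truth$S <- S - 1L
    truth$tracts <- NULL  # tract sources no longer match the relabeling
    return(list(truth = truth, mask = mask))
  }
  if (is.array(truth) && length(dim(truth)) == 3L) {
    k <- as.integer(missing_source)
    mask <- truth[, , k] == 0
    if (length(dim(mask)) != 2L) mask <- matrix(mask, dim(truth)[1])
    if (per_site) {
      bad_site <- apply(!mask, 2, any)
      mask <- matrix(rep(!bad_site, each = nrow(mask)), nrow(mask))
    }
    if (!any(mask)) stop("masking removed every cell", call. = FALSE)
    Zr <- truth[, , -k, drop = FALSE]
    # renormalize the (masked-out) carrier rows so Zr stays a valid dosage
    # array; included rows already sum to 1
    rs <- apply(Zr, c(1, 2), sum)
    Sr <- dim(Zr)[3]
    for (s in seq_len(Sr)) {
      zs <- Zr[, , s]
      zs[rs > 0] <- zs[rs > 0] / rs[rs > 0]
      zs[rs == 0] <- 1 / Sr
      Zr[, , s] <- zs
    }
    return(list(truth = Zr, mask = mask))
  }
  stop("`truth` must be a sample_set or dosage array", call. = FALSE)
}

#' Random-inference accuracy of a simulated dataset
#'
#' Convenience wrapper: scores the uniform 1/S baseline against the
#' simulated truth, with optional missing-source masking (the baseline then
#' spreads 1/(S-1) over the represented sources).
#'
#' @param sample A `sample_set`.
#' @param missing_source Optional source label absent from the dataset.
#' @param per_site Masking variant, see [missing_source_mask()].
#' @return An `accuracy_result`.
#' @export
random_baseline_alpha <- function(sample, missing_source = NULL,
                                  per_site = FALSE) {
  stopifnot(inherits(sample, "sample_set"))
  mask <- NULL
  if (!is.null(missing_source) && !is.na(missing_source)) {
    mm <- missing_source_mask(sample, missing_source, per_site = per_site)
    sample <- mm$truth
    mask <- mm$mask
  }
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  overall_alpha(sample, random_inference(sample$S, o, M), mask = mask)
}

#' Additional agreement metrics (desk scale)
#'
#' Coefficient of determination (squared correlation between true and
#' inferred dosages over all included cells and sources) and mean squared
#' error.  Provided for completeness next to the headline accuracy metric;
#' operates on dense arrays.
#'
#' @param Z,X Dense `o x M x S` truth and inference arrays.
#' @param mask Optional logical `o x M` inclusion matrix.
#' @return Named vector `c(r2, mse)`.
#' @export
accuracy_metrics <- function(Z, X, mask = NULL) {
  stopifnot(is.array(Z), all(dim(Z) == dim(X)))
  if (is.null(mask)) mask <- matrix(TRUE, dim(Z)[1], dim(Z)[2])
  idx <- which(rep(mask, dim(Z)[3]))
  z <- Z[idx]; x <- X[idx]
  c(r2 = suppressWarnings(stats::cor(z, x))^2, mse = mean((z - x)^2))
}

#' Score an external local-ancestry inference against the written truth
#'
#' File-level entry point used by the `score` command-line tool: reads the
#' truth dosage table written by [write_outputs()] and a plain-text
#' inferred matrix (see [read_inferred_matrix()]), optionally excludes a
#' missing source, and reports overall, per-individual and per-SNP
#' accuracies.
#'
#' @param truth_file Path to `truth_dosage.tsv`.
#' @param inferred Path to the inferred matrix, or an `inferred_ancestry`
#'   object (the inferred matrix always has one column per *represented*
#'   source).
#' @param exclude_source Optional label (in the full truth numbering) of a
#'   source with no representatives.
#' @param per_site Masking variant, see [missing_source_mask()].
#' @return List with `alpha_overall`, `n_included`, `per_individual` and
#'   `per_site` data frames.
#' @export
score_inference <- function(truth_file, inferred, exclude_source = NULL,
                            per_site = FALSE) {
  td <- read_truth_dosage(truth_file)
  Z <- td$Z
  o <- dim(Z)[1]; M <- dim(Z)[2]; S <- dim(Z)[3]
  mask <- NULL
  if (!is.null(exclude_source)) {
    mm <- missing_source_mask(Z, exclude_source, per_site = per_site)
    Z <- mm$truth; mask <- mm$mask; S <- S - 1L
  }
  if (is.character(inferred))
    inferred <- read_inferred_matrix(inferred, S, M, o)
  res <- overall_alpha(Z, inferred, mask = mask, admixed = td$admixed)
  list(alpha_overall = res$alpha_overall,
       n_included = res$n_included,
       per_individual = data.frame(
         individual = seq_len(o), admixed = td$admixed,
         alpha = rowMeans(res$alpha_site, na.rm = TRUE)),
       per_site = data.frame(
         snp = seq_len(M),
         alpha = suppressWarnings(colMeans(res$alpha_site, na.rm = TRUE))))
}
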