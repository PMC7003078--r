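#' Sample genotyped individuals from the simulated populations
#'
#' Draws `o_per_pop[p]` individuals uniformly *with replacement* from
#' population `p` at the current generation (duplicates are permitted and
#' `o_p > n_p` is valid).  The true local ancestry of every sampled
#' chromosome is expanded from its tracts to a per-site source code, from
#' which the ancestry dosage matrix Z derives.
#'
#' @param pops A `population_set`.
#' @param o_per_pop Non-negative sample size per population.
#' @param is_admixed Logical flag per population (`TRUE` = admixed);
#'   carried to the sampled individuals and used when averaging the
#'   accuracy metric.  Defaults to all `TRUE`.
#' @param seed Optional integer seed.
#' @return A `sample_set` (unfiltered; see [filter_monomorphic()]) with
#'   elements `alleles` (raw 0/1, sites x 2*oP, columns `2i-1`, `2i` for
#'   individual `i`), `anc1`/`anc2` (raw per-site source codes of the two
#'   copies, sites x oP), `tracts`, `positions`, `bp_positions`,
#'   `pop_of_individual`, `is_admixed`, `S`, `kept_index`.
#' @export
sample_individuals <- function(pops, o_per_pop, is_admixed = NULL,
                               seed = NULL) {
  stopifnot(inherits(pops, "population_set"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  P <- length(pops$sizes)
  o_per_pop <- as.integer(rep_len(o_per_pop, P))
  if (any(o_per_pop < 0)) stop("`o_per_pop` must be non-negative",
                               call. = FALSE)
  if (is.null(is_admixed)) is_admixed <- rep(TRUE, P)
  off <- c(0L, cumsum(pops$sizes))
  ind <- unlist(lapply(seq_len(P), function(p)
    off[p] + sample.int(pops$sizes[p], o_per_pop[p], replace = TRUE)))
  o <- length(ind)
  if (o == 0L) stop("no individuals sampled", call. = FALSE)
  cols <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  M <- length(pops$positions)
  anc <- matrix(as.raw(0), M, 2L * o)
  for (k in seq_along(cols)) {
    tr <- pops$tracts[[cols[k]]]
    anc[, k] <- as.raw(tr$src[findInterval(pops$positions, tr$ends) + 1L])
  }
  structure(list(
    alleles = pops$alleles[, cols, drop = FALSE],
    anc1 = anc[, seq(1L, 2L * o, by = 2L), drop = FALSE],
    anc2 = anc[, seq(2L, 2L * o, by = 2L), drop = FALSE],
    tracts = pops$tracts[cols],
    positions = pops$positions,
    bp_positions = bp_coordinates(pops$positions, pops$map_length_bp),
    pop_of_individual = pops$pop[ind],
    is_admixed = is_admixed[pops$pop[ind]],
    S = pops$S,
    map_length_bp = pops$map_length_bp,
    generation = pops$generation,
    kept_index = seq_len(M)),
    class = "sample_set")
}

# Map fractions -> 1-based bp coordinates; duplicate collisions are resolved
# by bumping to the next free coordinate (positions stay strictly increasing).
bp_coordinates <- function(positions, L) {
  bp <- 1 + floor(positions * L)
  if (length(bp) > 1L)
    for (k in 2:length(bp)) if (bp[k] <= bp[k - 1L]) bp[k] <- bp[k - 1L] + 1
  as.integer(bp)
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", length(x$pop_of_individual), " individuals (",
      sum(x$is_admixed), " admixed), ", length(x$positions), " SNPs, S = ",
      x$S, "\n", sep = "")
  invisible(x)
}

#' Remove SNPs monomorphic in the sample
#'
#' Drops columns where all sampled alleles (over all individuals jointly)
#' are identical; positions, coordinates and ancestry codes are subset
#' consistently.  The `kept_index` field of the result maps the kept SNPs
#' back to the indices of the input object.
#'
#' @param sample A `sample_set`.
#' @return The filtered `sample_set`.
#' @export
filter_monomorphic <- function(sample) {
  stopifnot(inherits(sample, "sample_set"))
  n_chrom <- ncol(sample$alleles)
  cnt <- cpp_row_alt_counts(sample$alleles, seq_len(n_chrom))
  keep <- cnt > 0L & cnt < n_chrom
  if (!any(keep))
    stop("empty dataset: every SNP is monomorphic in the sample",
         call. = FALSE)
  if (all(keep)) return(sample)
  sample$alleles <- sample$alleles[keep, , drop = FALSE]
  sample$anc1 <- sample$anc1[keep, , drop = FALSE]
  sample$anc2 <- sample$anc2[keep, , drop = FALSE]
  sample$positions <- sample$positions[keep]
  sample$bp_positions <- sample$bp_positions[keep]
  sample$kept_index <- sample$kept_index[keep]
  sample
}

#' True ancestry dosage array
#'
#' Expands the per-site source codes into the dosage array
#' `Z[i, m, s] in {0, 0.5, 1}`: the proportion of individual `i`'s two
#' chromosome copies deriving from source `s` at SNP `m`.  Rows always sum
#' to 1 over sources.  Dense; intended for desk-scale data (the scoring
#' functions work from the compact codes directly).
#'
#' @param sample A `sample_set`.
#' @return Numeric array `oP x M x S`.
#' @export
ancestry_dosage <- function(sample) {
  stopifnot(inherits(sample, "sample_set"))
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  S <- sample$S
  a1 <- matrix(as.integer(sample$anc1), M, o)
  a2 <- matrix(as.integer(sample$anc2), M, o)
  Z <- array(0, c(o, M, S))
  for (s in seq_len(S))
    Z[, , s] <- 0.5 * (t(a1 == s) + t(a2 == s))
  Z
}

#' Diploid genotype matrix (alternate-allele dosage)
#'
#' @param sample A `sample_set`.
#' @return Integer matrix, individuals x SNPs, entries 0/1/2.
#' @export
genotype_matrix <- function(sample) {
  stopifnot(inherits(sample, "sample_set"))
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  a <- matrix(as.integer(sample$alleles), M, 2L * o)
  t(a[, seq(1L, 2L * o, 2L), drop = FALSE] +
      a[, seq(2L, 2L * o, 2L), drop = FALSE])
}

sample_ids <- function(sample) {
  paste0("pop", sample$pop_of_individual, "_ind",
         seq_along(sample$pop_of_individual))
}

#' Write the analysis-ready dataset to disk
#'
#' Writes any of: a VCF v4.2 (`dataset.vcf`; phased `|` separators by
#' default since the simulated truth is phased, `/` with
#' `phased = FALSE`), plink text files (`dataset.ped`/`dataset.map`, map
#' distance in cM = 100 x map fraction, alleles coded 1/2 by default), the
#' truth files (`truth_dosage.tsv`, long format with one row per
#' individual x SNP and one dosage column per source; `truth_tracts.tsv`,
#' BED-like with 0-based half-open bp intervals per sampled chromosome
#' copy), and a JSON run summary.  Returns a manifest listing every file
#' with its MD5 checksum.
#'
#' @param sample A filtered `sample_set`.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("vcf", "plink", "truth", "json")`.
#' @param phased Write phased GT separators in the VCF.
#' @param ped_allele_coding `"12"` (default) or `"ACGT"` (A = reference,
#'   T = alternate, matching the VCF REF/ALT).
#' @param scenario Optional scenario/config metadata stored in the JSON
#'   summary.
#' @param seed Optional seed recorded in the JSON summary.
#' @return `data.frame` manifest with columns `file` and `md5`.
#' @export
write_outputs <- function(sample, out_dir,
                          formats = c("vcf", "plink", "truth", "json"),
                          phased = TRUE,
                          ped_allele_coding = c("12", "ACGT"),
                          scenario = NULL, seed = NULL) {
  stopifnot(inherits(sample, "sample_set"))
  formats <- match.arg(formats, several.ok = TRUE)
  ped_allele_coding <- match.arg(ped_allele_coding)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  ids <- sample_ids(sample)
  files <- character(0)

  if ("vcf" %in% formats) {
    f <- file.path(out_dir, "dataset.vcf")
    write_vcf(sample, f, phased = phased, ids = ids)
    files <- c(files, f)
  }
  if ("plink" %in% formats) {
    fp <- file.path(out_dir, "dataset.ped")
    fm <- file.path(out_dir, "dataset.map")
    write_plink(sample, fp, fm, ids = ids, coding = ped_allele_coding)
    files <- c(files, fp, fm)
  }
  if ("truth" %in% formats) {
    fd <- file.path(out_dir, "truth_dosage.tsv")
    ft <- file.path(out_dir, "truth_tracts.tsv")
    write_truth(sample, fd, ft)
    files <- c(files, fd, ft)
  }
  if ("json" %in% formats) {
    fj <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(n_individuals = o, n_snps = M, S = sample$S,
           map_length_bp = sample$map_length_bp,
           generation = sample$generation,
           populations = as.vector(table(sample$pop_of_individual)),
           admixed = unname(tapply(sample$is_admixed,
                                   sample$pop_of_individual, all)),
           scenario = scenario, seed = seed),
      fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, fj)
  }
  data.frame(file = files, md5 = unname(tools::md5sum(files)),
             row.names = NULL, stringsAsFactors = FALSE)
}

write_vcf <- function(sample, path, phased = TRUE, ids = sample_ids(sample)) {
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  sep <- if (phased) "|" else "/"
  a <- matrix(as.integer(sample$alleles), M, 2L * o)
  gt <- paste0(a[, seq(1L, 2L * o, 2L), drop = FALSE], sep,
               a[, seq(2L, 2L * o, 2L), drop = FALSE])
  gt_cols <- lapply(seq_len(o), function(j) gt[(j - 1L) * M + seq_len(M)])
  header <- c("##fileformat=VCFv4.2",
              "##source=mosaicsim",
              sprintf("##contig=<ID=1,length=%d>",
                      as.integer(sample$map_length_bp)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- do.call(paste, c(list("1", sample$bp_positions,
                                paste0("snp", sample$kept_index),
                                "A", "T", ".", "PASS", ".", "GT"),
                           gt_cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

write_plink <- function(sample, ped_path, map_path,
                        ids = sample_ids(sample), coding = "12") {
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  a <- matrix(as.integer(sample$alleles), M, 2L * o)
  code <- if (coding == "12") c("1", "2") else c("A", "T")
  lines <- vapply(seq_len(o), function(i) {
    al <- as.vector(rbind(code[a[, 2L * i - 1L] + 1L],
                          code[a[, 2L * i] + 1L]))
    paste(c(paste0("pop", sample$pop_of_individual[i]), ids[i],
            "0", "0", "0", "-9", al), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  map <- data.frame(chr = 1L, id = paste0("snp", sample$kept_index),
                    cM = 100 * sample$positions, bp = sample$bp_positions)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

write_truth <- function(sample, dosage_path, tracts_path) {
  o <- length(sample$pop_of_individual)
  M <- length(sample$positions)
  S <- sample$S
  a1 <- matrix(as.integer(sample$anc1), M, o)
  a2 <- matrix(as.integer(sample$anc2), M, o)
  dt <- data.table::data.table(
    individual = rep(seq_len(o), each = M),
    snp = rep(seq_len(M), o),
    admixed = rep(as.integer(sample$is_admixed), each = M))
  for (s in seq_len(S))
    dt[[paste0("src_", s)]] <- 0.5 * (as.vector(a1 == s) + as.vector(a2 == s))
  data.table::fwrite(dt, dosage_path, sep = "\t")

  L <- sample$map_length_bp
  rows <- lapply(seq_len(2L * o), function(k) {
    tr <- sample$tracts[[k]]
    ends <- tr$ends
    data.table::data.table(chrom = "1",
                           start = as.integer(floor(c(0, ends[-length(ends)]) * L)),
                           end = as.integer(floor(ends * L)),
                           individual = (k + 1L) %/% 2L,
                           copy = 2L - (k %% 2L),
                           source = tr$src)
  })
  data.table::fwrite(data.table::rbindlist(rows), tracts_path, sep = "\t")
  invisible(dosage_path)
}

#' Re-read genotypes from a written VCF
#'
#' Minimal reader for the VCFs produced by [write_outputs()] (GT-only,
#' biallelic, single contig); used for round-trip verification.
#'
#' @param path VCF path.
#' @return List with `pos` (bp), `geno` (integer matrix sites x 2*o of
#'   alleles, copy pairs in adjacent columns) and `phased` flag.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  ids <- strsplit(header, "\t", fixed = TRUE)[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  snp_id <- vapply(fields, `[[`, "", 3L)
  gts <- t(vapply(fields, function(f) f[-(1:9)], character(length(fields[[1]]) - 9L)))
  phased <- grepl("|", gts[1L, 1L], fixed = TRUE)
  o <- ncol(gts)
  geno <- matrix(0L, length(pos), 2L * o)
  for (j in seq_len(o)) {
    parts <- strsplit(gts[, j], "[|/]")
    geno[, 2L * j - 1L] <- as.integer(vapply(parts, `[[`, "", 1L))
    geno[, 2L * j] <- as.integer(vapply(parts, `[[`, "", 2L))
  }
  list(pos = pos, geno = geno, phased = phased, ids = ids,
       snp_id = snp_id)
}

#' Rebuild a sample_set from a written dataset directory
#'
#' Re-assembles an analysis-ready `sample_set` from the files produced by
#' [write_outputs()] (`dataset.vcf`, `truth_dosage.tsv`,
#' `truth_tracts.tsv`, `summary.json`): alleles and sample identities come
#' from the VCF, ancestry codes from the truth dosage table, tracts from
#' the tract table (endpoints quantized to base pairs), and dimensions
#' from the JSON summary.  Supports recomputing summary statistics or
#' scoring without rerunning the simulation.
#'
#' @param dir Directory written by [write_outputs()].
#' @return A `sample_set`.
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("dataset.vcf", "truth_dosage.tsv",
                           "truth_tracts.tsv", "summary.json"))
  if (!all(file.exists(need)))
    stop("missing dataset files: ",
         paste(basename(need[!file.exists(need)]), collapse = ", "),
         call. = FALSE)
  info <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  vcf <- read_vcf_genotypes(file.path(dir, "dataset.vcf"))
  M <- length(vcf$pos)
  o <- ncol(vcf$geno) / 2L
  L <- as.numeric(info$map_length_bp)
  S <- as.integer(info$S)
  td <- read_truth_dosage(file.path(dir, "truth_dosage.tsv"))
  # per-copy source codes from the dosage entries (copy order is arbitrary)
  a1 <- matrix(0L, M, o); a2 <- matrix(0L, M, o)
  for (i in seq_len(o)) {
    zi <- matrix(td$Z[i, , ], M, S)
    a1[, i] <- max.col(zi, ties.method = "first")
    half <- zi == 0.5
    a2[, i] <- ifelse(rowSums(half) == 2L,
                      max.col(half, ties.method = "last"), a1[, i])
  }
  tr <- data.table::fread(file.path(dir, "truth_tracts.tsv"))
  key <- 2L * (tr$individual - 1L) + tr$copy
  tracts <- lapply(split(tr, key), function(seg)
    list(ends = pmin(seg$end / L, 1), src = as.integer(seg$source)))
  tracts <- tracts[order(as.integer(names(tracts)))]
  structure(list(
    alleles = matrix(as.raw(vcf$geno), M, 2L * o),
    anc1 = matrix(as.raw(a1), M, o),
    anc2 = matrix(as.raw(a2), M, o),
    tracts = unname(tracts),
    positions = (vcf$pos - 1) / L,
    bp_positions = vcf$pos,
    pop_of_individual = as.integer(sub("^pop([0-9]+)_.*$", "\\1", vcf$ids)),
    is_admixed = td$admixed,
    S = S,
    map_length_bp = L,
    generation = as.integer(info$generation),
    kept_index = as.integer(sub("^snp", "", vcf$snp_id))),
    class = "sample_set")
}

#' Read the long-format truth dosage table
#'
#' @param path Path written by [write_outputs()] (`truth_dosage.tsv`).
#' @return List with dosage array `Z` (`o x M x S`) and logical
#'   `admixed` flag per individual.
#' @export
read_truth_dosage <- function(path) {
  dt <- data.table::fread(path)
  scols <- grep("^src_", names(dt), value = TRUE)
  o <- max(dt$individual); M <- max(dt$snp); S <- length(scols)
  Z <- array(0, c(o, M, S))
  for (s in seq_len(S))
    Z[cbind(dt$individual, dt$snp, s)] <- dt[[scols[s]]]
  admixed <- as.logical(dt$admixed[match(seq_len(o), dt$individual)])
  list(Z = Z, admixed = admixed)
}

#' Read an externally produced local-ancestry dosage matrix
#'
#' Plain-text matrix with one row per (individual, SNP) cell in
#' individual-major order (all `M` SNPs of individual 1, then individual 2,
#' ...) and one column per source; whitespace- or tab-separated, no header
#' or a header starting with `#`.  Rows must be non-negative and are
#' renormalized to sum to 1 (with a warning) when they deviate by more than
#' 1e-6.
#'
#' @param path File path.
#' @param S Number of sources (columns expected).
#' @param M SNPs per individual.
#' @param n_individuals Number of individuals.
#' @return An `inferred_ancestry` object.
#' @export
read_inferred_matrix <- function(path, S, M, n_individuals) {
  X <- as.matrix(data.table::fread(path, header = FALSE))
  mode(X) <- "numeric"
  if (any(is.na(X)))
    stop("format error: non-numeric entries in inferred matrix",
         call. = FALSE)
  if (nrow(X) != M * n_individuals || ncol(X) != S)
    stop("format error: expected ", M * n_individuals, " x ", S,
         " matrix, got ", nrow(X), " x ", ncol(X), call. = FALSE)
  inferred_ancestry(X, S = S, M = M, n_individuals = n_individuals)
}

#' Construct an inferred-ancestry object
#'
#' @param X Matrix `(n_individuals * M) x S` of inferred ancestry
#'   proportions in individual-major order, or the string `"uniform"` for
#'   the lazy uniform-1/S baseline.
#' @param S,M,n_individuals Dimensions.
#' @return An object of class `inferred_ancestry`.
#' @export
inferred_ancestry <- function(X, S, M, n_individuals) {
  if (identical(X, "uniform"))
    return(structure(list(type = "uniform", S = S, M = M,
                          n = n_individuals), class = "inferred_ancestry"))
  if (any(X < 0))
    stop("format error: negative ancestry proportions", call. = FALSE)
  rs <- rowSums(X)
  if (any(rs == 0))
    stop("format error: zero-sum ancestry row", call. = FALSE)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("renormalizing ", sum(abs(rs - 1) > 1e-6),
            " inferred rows whose proportions did not sum to 1")
    X <- X / rs
  }
  structure(list(type = "matrix", X = X, S = S, M = M, n = n_individuals),
            class = "inferred_ancestry")
}

#' @export
print.inferred_ancestry <- function(x, ...) {
  cat("<inferred_ancestry> ", x$n, " individuals x ", x$M, " SNPs x ",
      x$S, " sources (", x$type, ")\n", sep = "")
  invisible(x)
}
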