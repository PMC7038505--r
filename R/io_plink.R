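# PLINK 1.9 binary trio I/O and genotype-table utilities.
#
# Genotypes are stored as minor-allele (A1) dosages in {0, 1, 2}; missing
# calls are NA until impute_missing_mode() fills them.

#' Construct a genotype dataset
#'
#' Container for an `n x p` dosage matrix together with variant and sample
#' metadata, the in-memory representation of a PLINK binary fileset.  Dosages
#' count copies of the A1 allele; missing calls are `NA`.
#'
#' @param genotypes Numeric `n x p` matrix with entries in `{0, 1, 2, NA}`.
#' @param variants Data frame with columns `id`, `chr`, `pos`, `a1`, `a2`
#'   (one row per column of `genotypes`).  Generated automatically when
#'   omitted.
#' @param samples Data frame with columns `fid`, `iid`, `phenotype_raw`
#'   (one row per row of `genotypes`).  Generated automatically when omitted.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `variants` (tibble) and `samples` (tibble).
#' @export
genotype_dataset <- function(genotypes, variants = NULL, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (is.null(variants)) {
    variants <- tibble::tibble(
      id = sprintf("snp%0*d", max(4L, nchar(p)), seq_len(p)),
      chr = 1L, pos = seq_len(p), a1 = "A", a2 = "B"
    )
  }
  variants <- tibble::as_tibble(variants)
  if (is.null(samples)) {
    samples <- tibble::tibble(
      fid = sprintf("F%0*d", max(3L, nchar(n)), seq_len(n)),
      iid = sprintf("I%0*d", max(3L, nchar(n)), seq_len(n)),
      phenotype_raw = NA_real_
    )
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(variants) != p) {
    stop("variant table has ", nrow(variants), " rows but genotypes have ",
         p, " columns", call. = FALSE)
  }
  if (nrow(samples) != n) {
    stop("sample table has ", nrow(samples), " rows but genotypes have ",
         n, " rows", call. = FALSE)
  }
  if (anyDuplicated(variants$id)) {
    stop("variant ids are not unique: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(genotypes) & !(genotypes %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  structure(
    list(genotypes = genotypes, variants = variants, samples = samples),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$genotypes))
  cat("<genotype_dataset> ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " variants (", n_miss, " missing calls)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Construct a phenotype vector
#'
#' @param values Numeric vector, one value per sample.  For a case/control
#'   trait values must be 0 (control) or 1 (case).
#' @param trait_kind Either `"quantitative"` or `"case_control"`.
#'
#' @return A numeric vector of class `phenotype_vector` with a `trait_kind`
#'   attribute.
#' @export
phenotype_vector <- function(values,
                             trait_kind = c("quantitative", "case_control")) {
  trait_kind <- match.arg(trait_kind)
  values <- as.numeric(values)
  if (trait_kind == "case_control" &&
      !all(values[!is.na(values)] %in% c(0, 1))) {
    stop("case_control phenotype values must be 0 or 1", call. = FALSE)
  }
  structure(values, trait_kind = trait_kind, class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat("<phenotype_vector> ", length(x), " samples, ",
      attr(x, "trait_kind"), "\n", sep = "")
  print(unclass(x)[seq_len(min(10, length(x)))])
  invisible(x)
}

# Two-bit PLINK codes (SNP-major .bed): 00 = hom A1 (dosage 2),
# 01 = missing, 10 = het (dosage 1), 11 = hom A2 (dosage 0).
.plink_code_to_dosage <- c(2, NA, 1, 0)

# 256 x 4 lookup: byte value -> dosages of the 4 samples packed in it,
# low-order bit pair first.
.plink_byte_lut <- local({
  b <- 0:255
  sapply(0:3, function(s) .plink_code_to_dosage[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L])
})

#' Read a PLINK binary fileset
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam` into a
#' [genotype_dataset]. Only SNP-major .bed files (the PLINK 1 default,
#' mode byte `0x01`) are supported.  Dosage counts the A1 allele of the
#' `.bim` file; missing calls become `NA`.
#'
#' @param prefix Path stem of the fileset (without extension).
#'
#' @return A [genotype_dataset].  The sixth `.fam` column is kept in
#'   `samples$phenotype_raw` (`-9` and `0` are treated as missing).
#' @seealso [write_plink_binary()], [as_phenotype()]
#' @export
read_plink_binary <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (pth in paths) {
    if (!file.exists(pth)) {
      stop("input file not found: ", pth, call. = FALSE)
    }
  }
  bim <- utils::read.table(paths[2], header = FALSE, sep = "",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"),
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paths[3], header = FALSE, sep = "",
                           colClasses = c("character", "character", "character",
                                          "character", "character", "numeric"),
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  n <- nrow(fam)
  p <- nrow(bim)
  bpv <- ceiling(n / 4)  # bytes per variant
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]) + 1L)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1], call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported (mode byte ",
         as.integer(raw[3]), ")", call. = FALSE)
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * p) {
    stop(".bed payload has ", length(payload), " bytes but .bim/.fam imply ",
         bpv * p, " (", n, " samples x ", p, " variants)", call. = FALSE)
  }
  bytes <- matrix(as.integer(payload), nrow = bpv, ncol = p)
  geno <- matrix(NA_real_, nrow = 4 * bpv, ncol = p)
  for (s in 1:4) {
    geno[seq(s, by = 4, length.out = bpv), ] <- .plink_byte_lut[bytes + 1L, s]
  }
  geno <- geno[seq_len(n), , drop = FALSE]
  pheno <- fam$pheno
  pheno[pheno %in% c(-9, 0)] <- NA_real_
  genotype_dataset(
    geno,
    variants = tibble::tibble(id = bim$id, chr = bim$chr, pos = bim$pos,
                              a1 = bim$a1, a2 = bim$a2),
    samples = tibble::tibble(fid = fam$fid, iid = fam$iid,
                             phenotype_raw = pheno)
  )
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink_binary()]: writes a SNP-major `.bed` (PLINK 1.9
#' two-bit encoding) plus `.bim` and `.fam`.  `NA` dosages become missing
#' calls and survive a round trip.
#'
#' @param data A [genotype_dataset].
#' @param prefix Output path stem.
#' @param phenotype Optional numeric vector written to the sixth `.fam`
#'   column; defaults to `samples$phenotype_raw` (missing written as `-9`).
#'
#' @return `prefix`, invisibly.
#' @export
write_plink_binary <- function(data, prefix, phenotype = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  geno <- data$genotypes
  n <- nrow(geno)
  p <- ncol(geno)
  if (is.null(phenotype)) phenotype <- data$samples$phenotype_raw
  phenotype <- as.numeric(phenotype)
  phenotype[is.na(phenotype)] <- -9
  dir <- dirname(prefix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  # dosage -> two-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(3L, nrow = n, ncol = p)
  codes[!is.na(geno) & geno == 2] <- 0L
  codes[is.na(geno)] <- 1L
  codes[!is.na(geno) & geno == 1] <- 2L
  bpv <- ceiling(n / 4)
  pad <- 4 * bpv - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = p))
  weight <- 4L^((seq_len(4 * bpv) - 1L) %% 4L)
  packed <- rowsum(codes * weight, group = rep(seq_len(bpv), each = 4))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)

  v <- data$variants
  utils::write.table(
    data.frame(v$chr, v$id, 0, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  s <- data$samples
  utils::write.table(
    data.frame(s$fid, s$iid, 0, 0, 0, phenotype),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Interpret the raw .fam phenotype column
#'
#' PLINK codes case/control traits as 1 (control) / 2 (case).  When every
#' non-missing value is 1 or 2 the trait is recoded to 0/1; otherwise it is
#' taken as quantitative.
#'
#' @param data A [genotype_dataset] read from disk.
#'
#' @return A [phenotype_vector].
#' @export
as_phenotype <- function(data) {
  raw <- data$samples$phenotype_raw
  if (all(is.na(raw))) {
    stop("no phenotype present in the .fam file", call. = FALSE)
  }
  obs <- raw[!is.na(raw)]
  if (all(obs %in% c(1, 2))) {
    phenotype_vector(raw - 1, trait_kind = "case_control")
  } else {
    phenotype_vector(raw, trait_kind = "quantitative")
  }
}

#' Impute missing genotypes by the per-variant mode
#'
#' Each missing call is replaced by the most frequent observed dosage of the
#' same variant.  Frequency ties are broken toward the smaller dosage, which
#' is conservative toward the major allele.
#'
#' @param data A [genotype_dataset].
#'
#' @return The dataset with every dosage in `{0, 1, 2}`.
#' @export
impute_missing_mode <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  geno <- data$genotypes
  miss_cols <- which(colSums(is.na(geno)) > 0)
  if (length(miss_cols) == 0) return(data)
  all_missing <- miss_cols[colSums(!is.na(geno[, miss_cols, drop = FALSE])) == 0]
  if (length(all_missing) > 0) {
    stop("variant(s) entirely missing, cannot impute: ",
         paste(data$variants$id[all_missing], collapse = ", "), call. = FALSE)
  }
  for (j in miss_cols) {
    x <- geno[, j]
    counts <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    mode_val <- which.max(counts) - 1L  # which.max -> first max = smallest dosage
    x[is.na(x)] <- mode_val
    geno[, j] <- x
  }
  data$genotypes <- geno
  data
}

#' Minor allele frequencies
#'
#' Folded allele frequency of the A1 allele per variant:
#' `min(f, 1 - f)` with `f = sum(dosage) / (2n)`, so values lie in
#' `[0, 0.5]`.  Missing calls are excluded from the denominator; impute
#' first for the conventional estimate.
#'
#' @param data A [genotype_dataset].
#'
#' @return Numeric vector of length `p`, named by variant id.
#' @export
minor_allele_frequency <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  f <- colMeans(data$genotypes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  names(maf) <- data$variants$id
  maf
}

#' Construct a known-association set
#'
#' The set of variants whose association with the trait is already
#' established; their fixed effects are fitted first and conditioned on
#' when scanning for weaker signals.
#'
#' @param data A [genotype_dataset].
#' @param ids Character vector of variant ids, or `NULL` if `indices` given.
#' @param indices Integer column indices into `data`, or `NULL`.
#'
#' @return An object of class `known_set` with elements `indices`, `ids`,
#'   `coefficients` (NA until fitted) and `intercept`.
#' @export
known_set <- function(data, ids = NULL, indices = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(indices)) {
    if (is.null(ids)) stop("supply ids or indices", call. = FALSE)
    indices <- match(ids, data$variants$id)
    if (anyNA(indices)) {
      stop("known variant id(s) not present in the dataset: ",
           paste(ids[is.na(indices)], collapse = ", "), call. = FALSE)
    }
  }
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) {
    warning("duplicate known variants collapsed", call. = FALSE)
    indices <- unique(indices)
  }
  if (length(indices) < 1) {
    stop("a known-association set needs at least one variant", call. = FALSE)
  }
  if (any(indices < 1 | indices > ncol(data$genotypes))) {
    stop("known variant index out of range", call. = FALSE)
  }
  structure(
    list(indices = indices, ids = data$variants$id[indices],
         coefficients = rep(NA_real_, length(indices)), intercept = NA_real_),
    class = "known_set"
  )
}

#' @export
print.known_set <- function(x, ...) {
  cat("<known_set> ", length(x$indices), " variant(s): ",
      paste(x$ids, collapse = ", "), "\n", sep = "")
  if (!anyNA(x$coefficients)) {
    cat("  fitted coefficients: ",
        paste(signif(x$coefficients, 4), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read known-association variant ids from a file
#'
#' One variant id per line; `#` starts a comment; blank lines are ignored.
#' Duplicated ids are collapsed with a warning; ids absent from the dataset
#' are an error.
#'
#' @param path Path to the text file.
#' @param data A [genotype_dataset] used to resolve ids to columns.
#'
#' @return A `known_set`.
#' @export
read_known_variants <- function(path, data) {
  if (!file.exists(path)) {
    stop("known-variants file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) {
    stop("no known variants in ", path,
         "; use the Wald fallback to pick a prior instead", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    warning("duplicate ids in ", path, " collapsed", call. = FALSE)
    ids <- unique(ids)
  }
  known_set(data, ids = ids)
}

#' Write a ranked association result table
#'
#' Rows are sorted by absolute coefficient (descending, ties by chromosome
#' then position ascending), ranks reassigned 1..m, and written as a
#' tab-separated file with header `rank snp chr pos coef maf source`.
#'
#' @param table Data frame with columns `snp`, `chr`, `pos`, `coef`, `maf`,
#'   `source` (a `rank` column, if present, is recomputed).
#' @param path Output file path.
#'
#' @return The sorted table with ranks, invisibly.
#' @export
write_results <- function(table, path) {
  table <- rank_results(table)
  out <- data.frame(rank = table$rank, snp = table$snp, chr = table$chr,
                    pos = table$pos, coef = table$coef, maf = table$maf,
                    source = table$source)
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(table)
}

# Sort by |coef| descending, ties by (chr, pos) ascending; assign ranks.
rank_results <- function(table) {
  table <- tibble::as_tibble(table)
  ord <- order(-abs(table$coef), table$chr, table$pos)
  table <- table[ord, , drop = FALSE]
  table$rank <- seq_len(nrow(table))
  dplyr::relocate(table, "rank")
}
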