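#' Read genotypes from VCF, PLINK text, or TSV
#'
#' Reads diploid biallelic SNP genotypes into a [genotype_matrix()].
#' Supported formats:
#' \describe{
#'   \item{`vcf`}{VCF v4.x, GT field only (read with `vcfR`). Multiallelic
#'     and non-SNP records are skipped, with a message giving the count.}
#'   \item{`plink`}{PLINK text `.ped`/`.map` pair with ACGT or 1/2 allele
#'     codes (pass either file path); binary `.bed` is not supported.
#'     Dosage counts the minor allele (ties broken alphabetically) —
#'     polarity is irrelevant for every statistic in this package.}
#'   \item{`tsv`}{internal dialect: header row of locus ids, first column
#'     sample id, cells in `{0, 1, 2, NA}`.}
#' }
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, `"plink"` or `"tsv"`.
#' @return a [genotype_matrix()]; skipped-record count (VCF) available as
#'   attribute `"n_skipped"`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path) && format != "plink" &&
      !(format == "auto" && grepl("\\.(ped|map)$", path)))
    stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
      else if (grepl("\\.(ped|map)$", path)) "plink"
      else "tsv"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  is_snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0L)
    message(n_skip, " multiallelic/non-SNP record(s) skipped")
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  ids <- fix[is_snp, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[is_snp, "CHROM"], ":", fix[is_snp, "POS"])[noid]
  dosage <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }
  calls <- t(apply(gt, c(1, 2), dosage))  # samples x loci
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("non-diploid genotype call in ", path)
  G <- genotype_matrix(calls, samples = colnames(gt), loci = ids)
  attr(G, "n_skipped") <- n_skip
  G
}

read_genotypes_plink <- function(path) {
  stem <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(stem, ".ped")
  map_path <- paste0(stem, ".map")
  if (!file.exists(ped_path)) stop("PLINK .ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("PLINK .map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4L) stop("malformed .map file (need 4 columns)")
  loci <- map[[2L]]
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- length(loci)
  if (ncol(ped) != 6L + 2L * m)
    stop(sprintf("malformed .ped file: %d columns, expected %d (6 + 2 x %d loci)",
                 ncol(ped), 6L + 2L * m, m))
  samples <- ped[[2L]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  al[al %in% c("0", "-9", "N", ".")] <- NA
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, m)
  for (l in seq_len(m)) {
    a1 <- al[, 2L * l - 1L]
    a2 <- al[, 2L * l]
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    if (length(alleles) > 2L)
      stop(sprintf("locus '%s' has %d alleles; only biallelic loci supported",
                   loci[l], length(alleles)))
    if (length(alleles) == 0L) next
    # count the rarer allele; alphabetical tie-break
    cnt <- table(factor(c(a1, a2), levels = alleles))
    minor <- alleles[which.min(cnt)]
    calls[, l] <- (a1 == minor) + (a2 == minor)
  }
  genotype_matrix(calls, samples = samples, loci = loci)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = "NA",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("genotype TSV needs sample-id column plus loci")
  samples <- tab[[1L]]
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- !is.na(calls) & !(calls %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype cell '%s' at sample '%s', locus '%s' (allowed: 0, 1, 2, NA)",
                 calls[bad][1L], samples[idx[1L]], colnames(calls)[idx[2L]]))
  }
  storage.mode(calls) <- "integer"
  genotype_matrix(calls, samples = samples, loci = colnames(tab)[-1L])
}

#' Write genotypes to the internal TSV dialect
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  if (!inherits(G, "genotype_matrix")) G <- genotype_matrix(G)
  tab <- data.frame(sample = rownames(G), unclass(G), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a dissimilarity matrix as TSV
#'
#' Square tab-separated layout with sample ids as both first row and first
#' column; values printed with 17 significant digits so that a round trip
#' reproduces them to full double precision. On read, row/column id
#' mismatch, asymmetry and negative diagonals are validation errors.
#'
#' @param matrix a [dissim_matrix()] (or plain symmetric matrix).
#' @param path file path.
#' @param role role tag to attach on read (`"auto"` keeps the role stored
#'   in the file header comment if present).
#' @return `write_matrix`: `path`, invisibly; `read_matrix`: a
#'   [dissim_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  m <- as_dissim_values(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#role\t", matrix_role(matrix)), con)
  writeLines(paste(c("sample", rownames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, role = "auto") {
  lines <- readLines(path)
  stored_role <- "generic"
  if (length(lines) > 0L && startsWith(lines[1L], "#role")) {
    stored_role <- sub("^#role\t", "", lines[1L])
    lines <- lines[-1L]
  }
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column sample ids do not match in ", path)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix in ", path, " is not symmetric")
  if (any(diag(m) < 0)) stop("matrix in ", path, " has a negative diagonal")
  if (role == "auto") role <- stored_role
  dissim_matrix(m, role = role, samples = rownames(m))
}

#' Write / read a partition as TSV
#'
#' One row per sample: `sample_id <TAB> cluster`. Cluster indices are
#' canonicalized to be contiguous from 1 before writing.
#'
#' @param partition integer assignment vector (named by sample, or paired
#'   with `samples`).
#' @param samples sample ids (default: names of `partition`).
#' @param path file path.
#' @return `write_partition`: `path`, invisibly; `read_partition`: named
#'   integer vector.
#' @export
write_partition <- function(partition, path, samples = names(partition)) {
  if (length(partition) == 0L) stop("empty partition")
  if (is.null(samples)) samples <- paste0("S", seq_along(partition))
  p <- canonicalize_partition(partition)
  utils::write.table(data.frame(sample = samples, cluster = p),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  if (nrow(tab) == 0L) stop("empty partition file: ", path)
  stats::setNames(tab$cluster, tab$sample)
}

#' Read a sample-to-population label table
#'
#' Two-column TSV (`sample`, `population`), with or without a header row.
#'
#' @param path file path.
#' @return named character vector of labels.
#' @export
read_labels <- function(path) {
  first <- utils::read.table(path, header = FALSE, sep = "\t", nrows = 1L,
                             colClasses = "character")
  header <- identical(tolower(first[[1L]]), "sample")
  tab <- utils::read.table(path, header = header, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label table needs two columns: sample, population")
  if (anyDuplicated(tab[[1L]])) stop("duplicate sample in label table")
  stats::setNames(tab[[2L]], tab[[1L]])
}
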