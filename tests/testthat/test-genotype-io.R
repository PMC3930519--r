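vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1\tind2")

write_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header, records), path)
  path
}

test_that("VCF genotypes map to alternate-allele dosage", {
  path <- write_vcf(c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0|1",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t./."))
  G <- read_genotypes(path)
  expect_identical(unname(unclass(G)[1, ]), c(0L, 1L, 2L))
  expect_identical(unname(unclass(G)[2, ]), c(2L, 1L, NA))
  expect_identical(rownames(G), c("ind1", "ind2"))
  expect_identical(colnames(G), c("rs1", "rs2", "rs3"))
})

test_that("multiallelic and non-SNP VCF records are skipped and counted", {
  path <- write_vcf(c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t150\trs_tri\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/1",
    "1\t200\trs_indel\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t300\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/0"))
  expect_message(G <- read_genotypes(path), "2 multiallelic/non-SNP")
  expect_equal(ncol(G), 2L)
  expect_identical(colnames(G), c("rs1", "rs2"))
  expect_equal(attr(G, "n_skipped"), 2L)
})

test_that("TSV dialect round-trips and validates", {
  G <- genotype_matrix(rbind(c(0, 1, 2), c(2, 1, NA)),
                       samples = c("a", "b"), loci = c("l1", "l2", "l3"))
  path <- tempfile(fileext = ".tsv")
  write_genotypes(G, path)
  G2 <- read_genotypes(path, format = "tsv")
  expect_identical(unclass(G2), unclass(G))
  # cell outside the code set is named in the error
  writeLines(c("sample\tl1\tl2", "a\t0\t3", "b\t1\t2"), path)
  expect_error(read_genotypes(path, format = "tsv"), "invalid genotype cell '3'")
  # NA cell becomes a missing call
  writeLines(c("sample\tl1\tl2", "a\t0\tNA", "b\t1\t2"), path)
  expect_true(is.na(unclass(read_genotypes(path, format = "tsv"))[1, 2]))
})

test_that("VCF and TSV fixtures with the same genotypes load identically", {
  vcf <- write_vcf(c(
    "1\t100\tl1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\tl2\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t300\tl3\tG\tA\t.\tPASS\t.\tGT\t1/1\t./."))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tl1\tl2\tl3", "ind1\t0\t1\t2", "ind2\t1\t2\tNA"), tsv)
  expect_identical(bare(unclass(read_genotypes(vcf))),
                   bare(unclass(read_genotypes(tsv))))
})

test_that("PLINK text .ped/.map loads biallelic dosages", {
  map <- tempfile(fileext = ".map")
  ped <- sub("\\.map$", ".ped", map)
  writeLines(c("1\tl1\t0\t100", "1\tl2\t0\t200"), map)
  writeLines(c("f1 s1 0 0 1 -9 A A A C",
               "f2 s2 0 0 1 -9 A G C C",
               "f3 s3 0 0 1 -9 G G 0 0"), ped)
  G <- read_genotypes(ped)
  expect_identical(rownames(G), c("s1", "s2", "s3"))
  # l1: alleles A (3) and G (3) tie -> alphabetical tie-break counts A
  expect_identical(unname(unclass(G)[, 1]), c(2L, 1L, 0L))
  # l2: alleles A (1) and C (3) -> A minor; dosages 1, 0, NA
  expect_identical(unname(unclass(G)[, 2]), c(1L, 0L, NA))
  # a triallelic locus is rejected
  writeLines(c("f1 s1 0 0 1 -9 A A", "f2 s2 0 0 1 -9 C G"), ped)
  writeLines("1\tl1\t0\t100", map)
  expect_error(read_genotypes(ped), "biallelic")
})

test_that("matrix writer/reader round-trips to full precision", {
  z <- dissim_matrix(matrix(0, 2, 2), samples = c("a", "b"))
  path <- tempfile(fileext = ".tsv")
  write_matrix(z, path)
  z2 <- read_matrix(path)
  expect_identical(unwrap <- unclass(z2)[, ], unclass(z)[, ])

  set.seed(26)
  m <- random_sym_matrix(5)
  write_matrix(dissim_matrix(m), path)
  m2 <- read_matrix(path)
  expect_lt(max(abs(unclass(m2) - m)), 1e-12)
  expect_identical(rownames(m2), rownames(m))

  # role survives the round trip
  V <- v_matrix(random_sym_matrix(5))
  write_matrix(V, path)
  expect_identical(attr(read_matrix(path), "role"), "V")
})

test_that("malformed matrix files are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\ta\tb", "a\t0\t1", "c\t1\t0"), path)
  expect_error(read_matrix(path), "ids do not match")
  writeLines(c("sample\ta\tb", "a\t0\t1", "b\t2\t0"), path)
  expect_error(read_matrix(path), "not symmetric")
})

test_that("partition writer/reader round-trips and rejects empties", {
  path <- tempfile(fileext = ".tsv")
  p <- c(s1 = 2L, s2 = 2L, s3 = 5L)
  write_partition(p, path)
  p2 <- read_partition(path)
  expect_identical(p2, c(s1 = 1L, s2 = 1L, s3 = 2L))  # canonicalized
  expect_error(write_partition(integer(0), path), "empty")
  writeLines("sample\tcluster", path)
  expect_error(read_partition(path), "empty")
})

test_that("duplicate sample ids are a validation error", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tl1", "a\t0", "a\t1"), tsv)
  expect_error(read_genotypes(tsv, format = "tsv"), "duplicate sample")
})
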