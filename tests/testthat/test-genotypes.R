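test_that("allele frequencies, call rate and monomorphic flags", {
  d <- cbind(c(0, 1, 2, 1), c(0, 0, 0, 0), c(2, 2, 1, 1), c(NA, NA, NA, NA))
  fr <- compute_allele_freqs(d)
  expect_equal(fr$freq[1:3], c(0.5, 0, 0.75))
  expect_true(fr$monomorphic[2])
  expect_true(fr$monomorphic[4])  # all-missing column flagged
  expect_equal(fr$call_rate, c(1, 1, 1, 0))

  # missing calls excluded from the frequency denominator
  fr2 <- compute_allele_freqs(matrix(c(2, 2, NA, 0), ncol = 1))
  expect_equal(fr2$freq, 4 / 6)
})

test_that("standardization matches the (Z - 2p)/sqrt(2p(1-p)) formula", {
  z1 <- standardize_genotypes(matrix(c(0, 1, 2, 1), ncol = 1))
  expect_equal(z1[2, 1], 0)                      # dosage 1 at p = 0.5
  expect_equal(z1[3, 1], 1 / sqrt(0.5))          # dosage 2 at p = 0.5
  # external frequency: p = 0.1, dosage 0
  z2 <- standardize_genotypes(matrix(c(0, 1), ncol = 1), freq = 0.1)
  expect_equal(z2[1, 1], -0.2 / sqrt(0.18), tolerance = 1e-12)
  # mean imputation contributes exactly zero after centring
  z3 <- standardize_genotypes(matrix(c(0, 2, NA, 2), ncol = 1))
  expect_equal(z3[3, 1], 0)
  # monomorphic columns dropped (or an error when not allowed)
  d <- cbind(a = c(0, 1), b = c(2, 2))
  expect_equal(ncol(standardize_genotypes(d)), 1L)
  expect_error(standardize_genotypes(d, drop_monomorphic = FALSE),
               "monomorphic")
})

test_that("standardized columns have mean 0 and near-unit variance", {
  g <- simulate_genotypes(1500, 80, maf = 0.1, seed = 99)
  Zs <- standardize_genotypes(g)
  expect_lt(max(abs(colMeans(Zs))), 1e-10)
  v <- apply(Zs, 2, var)
  expect_lt(max(abs(v - 1)), 0.12)   # HWE sampling noise at n = 1500
  expect_lt(abs(mean(v) - 1), 0.05)
})

test_that("TSV and PLINK round-trips preserve dosages", {
  g <- simulate_genotypes(12, 7, maf = 0.2, seed = 4)
  td <- withr::local_tempdir()
  # dosage TSV
  tsv <- file.path(td, "d.tsv")
  write.table(data.frame(animal_id = g$animal_ids, g$dosages,
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_dosage_tsv(tsv)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  # PLINK .bed written byte-by-byte from the same dosages
  pre <- file.path(td, "p")
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  codes <- matrix(0L, n, m)                  # A1 dosage 2,1,0 -> 0,2,3
  codes[g$dosages == 1] <- 2L
  codes[g$dosages == 0] <- 3L
  codes[is.na(g$dosages)] <- 1L
  bpv <- ceiling(n / 4)
  bytes <- raw(0)
  for (j in seq_len(m)) {
    cj <- c(codes[, j], integer(4 * bpv - n))
    by <- vapply(seq_len(bpv), function(b) {
      i <- (b - 1) * 4
      sum(cj[i + 1:4] * c(1L, 4L, 16L, 64L))
    }, numeric(1))
    bytes <- c(bytes, as.raw(by))
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(pre, ".bed"))
  write.table(data.frame(1, g$variant_ids, 0, g$pos_bp, "A", "B"),
              paste0(pre, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame("F", g$animal_ids, 0, 0, 0, -9),
              paste0(pre, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g3 <- read_plink(pre)
  expect_equal(unname(g3$dosages), unname(g$dosages))
  expect_equal(g3$variant_ids, g$variant_ids)
})

test_that("VCF dosage extraction counts ALT alleles", {
  skip_if_not_installed("vcfR")
  td <- withr::local_tempdir()
  vcf <- file.path(td, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t1|1\t./.\t0|1"), vcf)
  g <- read_vcf_dosages(vcf)
  expect_equal(unname(g$dosages[, "v1"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "v2"]), c(2, NA, 1))
  expect_equal(g$pos_bp, c(100L, 200L))
})

test_that("invalid dosage values are rejected", {
  expect_error(geno_matrix(matrix(c(0, 3), ncol = 1)), "dosages")
})
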