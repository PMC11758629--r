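# a tiny hand-written HipSTR-dialect VCF used by the parsing tests
write_mini_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=PERIOD,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GB,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=Q,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DSTUTTER,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DFLANKINDEL,Number=1,Type=Integer,Description=\"x\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("sc1", "100", "L1", "ACACACAC", "ACACACACAC,ACACAC", ".", ".",
          "PERIOD=2", "GT:GB:Q:DP:DSTUTTER:DFLANKINDEL",
          "1|0:4|0:0.99:20:0:0",     # (+4, 0) bp -> copies (+2, 0)
          "0|0:0|0:0.95:18:1:1",     # reference-identical
          ".",                        # missing
          sep = "\t"),
    paste("sc1", "500", "L2", "ACACAC", "ACACACA", ".", ".",
          "PERIOD=2", "GT:GB:Q:DP:DSTUTTER:DFLANKINDEL",
          "1|0:3|0:0.98:20:0:0",     # +3 bp at period 2 -> 1.5 copies
          "0|0:0|0:0.89:20:0:0",     # low posterior
          "0|0:0|0:0.95:20:0:4",     # 20% flank indel reads
          sep = "\t")), path)
  path
}

test_that("read_str_vcf decodes GB pairs into relative copies and dosage", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"))
  calls <- read_str_vcf(vcf)
  expect_equal(calls$samples, c("s1", "s2", "s3"))
  expect_equal(calls$loci$period, c(2L, 2L))
  dm <- dosage_matrix(calls)
  expect_equal(dm$dosage["L1", "s1"], 2)      # (+4 + 0) / 2
  expect_equal(dm$dosage["L1", "s2"], 0)      # homozygous reference
  expect_true(is.na(dm$dosage["L1", "s3"]))   # absent genotype
  expect_equal(dm$dosage["L2", "s1"], 1.5)    # partial-unit indel
  expect_true(dm$loci$non_integral[dm$loci$locus_id == "L2"])
  expect_false(dm$loci$non_integral[dm$loci$locus_id == "L1"])
  unlink(vcf)
})

test_that("call filters drop low-posterior and artifact-heavy calls only", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"))
  calls <- filter_calls(read_str_vcf(vcf))
  cc <- calls$calls
  # posterior 0.89 < 0.90 -> removed
  expect_true(is.na(cc$bp1[cc$locus_id == "L2" & cc$sample_id == "s2"]))
  # flank fraction 4/20 = 0.20 > 0.15 -> removed
  expect_true(is.na(cc$bp1[cc$locus_id == "L2" & cc$sample_id == "s3"]))
  # clean calls survive
  expect_false(is.na(cc$bp1[cc$locus_id == "L1" & cc$sample_id == "s1"]))
  expect_false(is.na(cc$bp1[cc$locus_id == "L1" & cc$sample_id == "s2"]))
  # boundary: posterior exactly 0.90 and fractions exactly 0.15 survive
  calls2 <- read_str_vcf(vcf)
  calls2$calls$posterior[] <- 0.90
  calls2$calls$flank_indel_frac[] <- 0.15
  calls2$calls$stutter_frac[] <- 0.15
  kept <- filter_calls(calls2)
  expect_equal(sum(!is.na(kept$calls$bp1)), sum(!is.na(calls2$calls$bp1)))
  unlink(vcf)
})

test_that("call and locus filtering are idempotent", {
  co <- tiny_cohort()
  vcf <- tempfile(fileext = ".vcf")
  simulate_str_vcf(co, vcf,
                   noise = list(low_posterior_rate = 0.1,
                                high_flank_rate = 0.05,
                                high_stutter_rate = 0.05,
                                missing_rate = 0.05))
  once <- filter_calls(read_str_vcf(vcf))
  twice <- filter_calls(once)
  expect_identical(once$calls, twice$calls)
  dm <- dosage_matrix(once)
  f1 <- filter_loci(dm, "gwas")
  expect_identical(f1, filter_loci(f1, "gwas"))
  g1 <- filter_loci(dm, "grm")
  expect_identical(g1, filter_loci(g1, "grm"))
  unlink(vcf)
})

test_that("locus filters apply presence, missingness and monomorphy rules", {
  loci <- data.frame(locus_id = c("a", "b", "c", "d"),
                     scaffold = "s", pos = 1:4, period = 1L,
                     stringsAsFactors = FALSE)
  n <- 326L
  d <- matrix(NA_real_, 4L, n,
              dimnames = list(loci$locus_id, paste0("i", 1:n)))
  d["a", 1:65] <- rep(c(0, 1), length.out = 65)   # presence 65/326 = 0.199
  d["b", 1:80] <- rep(c(0, 2), length.out = 80)   # presence 0.245
  d["c", 1:300] <- rep(c(0, 1), length.out = 300) # missing 8%
  d["d", ] <- 0                                   # monomorphic
  dm <- structure(list(loci = loci, samples = colnames(d), dosage = d),
                  class = "dosage_matrix")
  gw <- filter_loci(dm, "gwas")
  expect_setequal(gw$loci$locus_id, c("b", "c"))  # 0.199 fails strict > 0.2
  gr <- filter_loci(dm, "grm")
  expect_equal(gr$loci$locus_id, "c")             # only c has missing < 0.1
  dm_mono <- dm
  dm_mono$dosage["a", ] <- 0
  dm_mono$dosage["b", ] <- 0
  dm_mono$dosage["c", ] <- 0
  expect_error(filter_loci(dm_mono, "gwas"), "no loci survive")
})

test_that("dosage is symmetric in the order of the two alleles", {
  co <- tiny_cohort()
  vcf <- tempfile(fileext = ".vcf")
  simulate_str_vcf(co, vcf)
  calls <- read_str_vcf(vcf)
  swapped <- calls
  tmp <- swapped$calls$bp1
  swapped$calls$bp1 <- swapped$calls$bp2
  swapped$calls$bp2 <- tmp
  expect_equal(dosage_matrix(calls)$dosage, dosage_matrix(swapped)$dosage)
  unlink(vcf)
})

test_that("PIC matches direct evaluation and its bounds", {
  expect_equal(pic(c(1)), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  # relabeling invariance and the 1 - 1/k ceiling for equifrequent alleles
  set.seed(2)
  for (k in 2:8) {
    p <- rdir <- rgamma(k, 1); p <- p / sum(p)
    expect_equal(pic(p), pic(sample(p)))
    expect_lt(pic(rep(1 / k, k)), 1 - 1 / k)
  }
  # monotone approach to the ceiling with k
  vals <- vapply(2:12, function(k) pic(rep(1 / k, k)) - (1 - 1 / k),
                 numeric(1))
  expect_true(all(diff(abs(vals)) < 0))
})

test_that("polymorphism classes follow the 0.25 / 0.5 boundaries", {
  expect_equal(polymorphism_class(c(0, 0.375, 0.51)),
               c("low", "medium", "high"))
  expect_equal(polymorphism_class(0.25), "medium")
  expect_equal(polymorphism_class(0.5), "medium")
})

test_that("allele frequencies equal a brute-force tally", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"))
  calls <- read_str_vcf(vcf)
  # L1: s1 (2,0), s2 (0,0) observed -> freq{0: 0.75, 2: 0.25}
  af <- allele_frequencies(calls, "L1")
  expect_equal(af[["0"]], 0.75)
  expect_equal(af[["2"]], 0.25)
  unlink(vcf)

  co <- tiny_cohort()
  lid <- co$loci$locus_id[5]
  af <- allele_frequencies(
    structure(list(loci = co$loci, samples = co$dosage$samples,
                   calls = data.frame(
                     locus_id = rep(co$loci$locus_id, ncol(co$alleles$a1)),
                     sample_id = rep(colnames(co$alleles$a1),
                                     each = nrow(co$loci)),
                     bp1 = as.vector(co$alleles$a1 * co$loci$period),
                     bp2 = as.vector(co$alleles$a2 * co$loci$period),
                     posterior = 1, flank_indel_frac = 0, stutter_frac = 0)),
              class = "str_calls"), lid)
  tally <- table(c(co$alleles$a1[5, ], co$alleles$a2[5, ]))
  expect_equal(unname(af[names(tally)]),
               unname(as.numeric(tally) / sum(tally)))
})

test_that("chi-square HWE test hits the closed-form cases", {
  # exactly at HWE expectation: statistic 0, p = 1
  at_hwe <- c("A/A" = 25, "A/a" = 50, "a/a" = 25)
  res <- hwe_test(at_hwe, method = "chisq")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1L)
  # all heterozygotes: strongly out of HWE by both methods
  all_het <- c("A/A" = 0, "A/a" = 100, "a/a" = 0)
  expect_lt(hwe_test(all_het, method = "chisq")$p_value, 0.05)
  expect_lt(hwe_test(all_het, method = "montecarlo", n_perm = 500,
                     seed = 4)$p_value, 0.05)
  # single allele: degenerate, p = 1
  mono <- c("A/A" = 30)
  res <- hwe_test(mono)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo HWE p matches exhaustive enumeration on a tiny table", {
  counts <- c("0/0" = 1, "0/1" = 1, "1/2" = 1)   # 6 alleles -> 720 orderings
  exact <- oracle_hwe_exact(counts)
  mc <- hwe_test(counts, method = "montecarlo", n_perm = 4000, seed = 8)
  expect_lt(abs(mc$p_value - exact),
            3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)
})

test_that("Monte-Carlo HWE test is calibrated under the null", {
  # multiallelic tables (3-6 alleles), where the permutation distribution is
  # rich enough for near-nominal behaviour; biallelic small-sample tables
  # are conservative by discreteness, as exact-style tests are
  set.seed(77)
  n_loci <- 400
  n_ind <- 100
  rej <- 0
  for (l in seq_len(n_loci)) {
    k <- sample(3:6, 1)
    p <- rgamma(k, 2); p <- p / sum(p)
    a1 <- sample(seq_len(k), n_ind, replace = TRUE, prob = p)
    a2 <- sample(seq_len(k), n_ind, replace = TRUE, prob = p)
    key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    tab <- table(key)
    pv <- hwe_test(setNames(as.numeric(tab), names(tab)),
                   method = "montecarlo", n_perm = 199, seed = l)$p_value
    if (pv < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_loci, 0.03)
  expect_lt(rej / n_loci, 0.07)
})

test_that("locus_qc summarises presence, PIC class and HWE", {
  co <- tiny_cohort()
  vcf <- tempfile(fileext = ".vcf")
  simulate_str_vcf(co, vcf, noise = list(low_posterior_rate = 0,
                                         high_flank_rate = 0,
                                         high_stutter_rate = 0,
                                         missing_rate = 0.1))
  qc <- locus_qc(filter_calls(read_str_vcf(vcf)))
  expect_equal(nrow(qc), nrow(co$loci))
  expect_true(all(qc$presence_rate >= 0 & qc$presence_rate <= 1))
  expect_true(all(qc$pic >= 0 & qc$pic < 1, na.rm = TRUE))
  expect_true(all(qc$polymorphism_class %in% c("low", "medium", "high") |
                  is.na(qc$polymorphism_class)))
  unlink(vcf)
})
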