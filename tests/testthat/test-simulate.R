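test_that("the generator is deterministic: same config, same bytes", {
  cfg <- sim_config(seed = 91, n_families = 6, offspring_per_family = 3,
                    n_loci = 40)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$dosage$dosage, b$dosage$dosage)
  v1 <- tempfile(fileext = ".vcf")
  v2 <- tempfile(fileext = ".vcf")
  simulate_str_vcf(a, v1)
  simulate_str_vcf(b, v2)
  expect_identical(readLines(v1), readLines(v2))
  # a different seed changes the output
  c2 <- simulate_cohort(sim_config(seed = 92, n_families = 6,
                                   offspring_per_family = 3, n_loci = 40))
  expect_false(identical(a$phenotypes$hbw, c2$phenotypes$hbw))
  unlink(c(v1, v2))
})

test_that("planted genome loci are recovered exactly by the scanner", {
  planted <- data.frame(scaffold = c(1L, 1L, 2L),
                        motif = c("AT", "CAG", "A"),
                        n_repeats = c(8L, 6L, 15L),
                        position = c(1001L, 5000L, 2500L))
  g <- simulate_genome(n_scaffolds = 2, scaffold_bp = 10000,
                       planted = planted, seed = 93)
  got <- do.call(rbind, lapply(names(g$sequences), function(sc) {
    scan_sequence(g$sequences[[sc]], scaffold = sc)
  }))
  rownames(got) <- NULL
  expect_equal(got[, c("scaffold", "start", "end", "motif", "period",
                       "n_repeats")],
               g$truth[, c("scaffold", "start", "end", "motif", "period",
                           "n_repeats")])
  # the (AT, 8) plant sits exactly at 1001..1016
  expect_true(any(got$start == 1001 & got$end == 1016 & got$motif == "AT"))
})

test_that("a genome with no plants scans empty, and FASTA round-trips", {
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  g <- simulate_genome(n_scaffolds = 2, scaffold_bp = 5000, seed = 94,
                       fasta = fa)
  cat0 <- scan_fasta(fa)
  expect_equal(nrow(cat0$loci), 0L)
  expect_equal(unname(cat0$genome_lengths), c(5000, 5000))

  planted <- data.frame(scaffold = 1L, motif = "TG", n_repeats = 10L,
                        position = 2000L)
  simulate_genome(n_scaffolds = 1, scaffold_bp = 5000, planted = planted,
                  seed = 95, fasta = fa, bed = bed)
  cat1 <- scan_fasta(fa)
  truth <- read.table(bed, sep = "\t")
  expect_equal(nrow(cat1$loci), 1L)
  expect_equal(cat1$loci$start, truth[[2]] + 1L)
  expect_equal(cat1$loci$end, truth[[3]])
  unlink(c(fa, bed))
})

test_that("many planted loci give scanner recall and precision of 1", {
  set.seed(96)
  rows <- list()
  for (sc in 1:5) {
    starts <- seq(500, 9000, by = 900)
    for (k in seq_along(starts)) {
      p <- sample(1:4, 1)
      motif <- c("A", "AT", "CAG", "AATG")[p]
      reps <- max(ceiling(10 / nchar(motif)), c(10, 5, 4, 3)[p]) +
        sample(0:3, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, motif = motif, n_repeats = reps, position = starts[k])
    }
  }
  planted <- do.call(rbind, rows)[sample(50), ]
  g <- simulate_genome(n_scaffolds = 5, scaffold_bp = 10000,
                       planted = planted, seed = 97)
  got <- do.call(rbind, lapply(names(g$sequences), function(sc) {
    scan_sequence(g$sequences[[sc]], scaffold = sc)
  }))
  key <- function(df) paste(df$scaffold, df$start, df$end, df$motif)
  expect_setequal(key(got), key(g$truth))
})

test_that("founder allele frequencies are recovered from a large draw", {
  co <- simulate_cohort(sim_config(seed = 98, n_families = 1000,
                                   offspring_per_family = 1, n_loci = 12,
                                   causal_effects = numeric(0)))
  # founders: resimulate their genotypes through the offspring draw is
  # indirect; instead tally offspring alleles, whose expected frequencies
  # equal the founder (configured) frequencies under Mendelian transmission
  for (j in c(1L, 5L, 9L)) {
    tally <- table(c(co$alleles$a1[j, ], co$alleles$a2[j, ]))
    freq <- as.numeric(tally) / sum(tally)
    conf <- co$truth$allele_freqs[[j]]
    conf_sub <- conf[names(tally)]
    expect_true(all(abs(freq - conf_sub) < 0.03))
  }
})

test_that("full sibs share more dosage than unrelated individuals", {
  co <- simulate_cohort(sim_config(seed = 99, n_families = 30,
                                   offspring_per_family = 4, n_loci = 500,
                                   causal_effects = numeric(0)))
  d <- co$dosage$dosage
  fam <- rep(seq_len(30), each = 4)
  cors <- cor(d)
  sib <- outer(fam, fam, "==") & upper.tri(cors)
  non <- (!outer(fam, fam, "==")) & upper.tri(cors)
  expect_gt(mean(cors[sib]), mean(cors[non]) + 0.1)
})

test_that("phenotype regression on true dosage recovers the causal effect", {
  # one offspring per family: individuals are unrelated, so the naive OLS
  # standard error is an honest yardstick for the recovery check
  co <- simulate_cohort(sim_config(seed = 100, n_families = 1000,
                                   offspring_per_family = 1, n_loci = 100,
                                   causal_effects = c(2)))
  cl <- co$truth$causal
  s <- co$dosage$dosage[cl$locus_index[1], ]
  ph <- co$phenotypes
  fit <- summary(lm(hbw ~ s + factor(sex) + factor(tank):ibw,
                    data = cbind(ph, s = s)))
  est <- fit$coefficients["s", ]
  expect_lt(abs(est["Estimate"] - 2), 2 * est["Std. Error"])
})

test_that("zero-noise VCFs round-trip the truth dosage losslessly", {
  co <- tiny_cohort(seed = 101)
  vcf <- tempfile(fileext = ".vcf")
  simulate_str_vcf(co, vcf)
  dm <- dosage_matrix(filter_calls(read_str_vcf(vcf)))
  expect_equal(dm$dosage[co$dosage$loci$locus_id, co$dosage$samples],
               co$dosage$dosage)
  unlink(vcf)
})

test_that("planted noisy calls are exactly the ones the filters remove", {
  co <- tiny_cohort(seed = 102)
  vcf <- tempfile(fileext = ".vcf")
  out <- simulate_str_vcf(co, vcf,
                          noise = list(low_posterior_rate = 0.1,
                                       high_flank_rate = 0.05,
                                       high_stutter_rate = 0.05,
                                       missing_rate = 0))
  calls <- read_str_vcf(vcf)
  filtered <- filter_calls(calls)
  removed <- filtered$calls[is.na(filtered$calls$bp1) &
                            !is.na(calls$calls$bp1), c("locus_id", "sample_id")]
  planted <- out$planted[out$planted$kind != "missing",
                         c("locus_id", "sample_id")]
  key <- function(df) sort(paste(df$locus_id, df$sample_id))
  expect_identical(key(removed), key(planted))
  unlink(vcf)
})

test_that("the missing rate shows up as the expected presence rate", {
  co <- tiny_cohort(seed = 103)
  vcf <- tempfile(fileext = ".vcf")
  simulate_str_vcf(co, vcf, noise = list(low_posterior_rate = 0,
                                         high_flank_rate = 0,
                                         high_stutter_rate = 0,
                                         missing_rate = 0.05))
  calls <- read_str_vcf(vcf)
  presence <- mean(!is.na(calls$calls$bp1))
  expect_gt(presence, 0.93)
  expect_lt(presence, 0.97)
  unlink(vcf)
})

test_that("an infeasible heritability-causal combination errors usefully", {
  expect_error(
    simulate_cohort(sim_config(seed = 104, n_families = 4,
                               offspring_per_family = 2, n_loci = 20,
                               causal_effects = c(6, 6), h2 = 0.9)),
    "feasible|below")
})

test_that("expression truth tables drive detectable fold changes", {
  sim <- simulate_expression(n_genes = 50, n_per_group = 15,
                             de_genes = c(3, 7), fold_change = 5,
                             seed = 105)
  expect_equal(sum(sim$truth$is_de), 2L)
  f <- fpkm_normalize(sim$counts, sim$gene_lengths)
  res <- de_ttest(f, sim$groups)
  expect_true(all(res$significant[c(3, 7)]))
  # zero-count gene: FPKM 0 everywhere, degenerate DE record
  sim$counts[1, ] <- 0
  f0 <- fpkm_normalize(sim$counts, sim$gene_lengths)
  expect_true(all(f0[1, ] == 0))
  r0 <- de_ttest(f0, sim$groups)
  expect_true(r0$degenerate[1])
})
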