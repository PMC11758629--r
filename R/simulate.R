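#' Configuration for the synthetic STR cohort generator
#'
#' Describes a pedigreed aquaculture cohort genotyped at multiallelic STR
#' loci: families of full sibs from unrelated founder pairs, per-locus allele
#' sets of signed relative copy numbers with Dirichlet-drawn frequencies, a
#' polygenic additive background simulated through the pedigree, a handful of
#' causal STR dosage effects, and sex/tank/initial-body-weight fixed effects.
#' The defaults emulate a cohort of sixty families with six genotyped
#' offspring each.
#'
#' @param seed integer seed; fully determines every downstream output.
#' @param n_families number of unrelated founder-pair families.
#' @param offspring_per_family genotyped and phenotyped offspring per family.
#' @param n_loci number of STR loci.
#' @param max_abs_copy allele relative copy numbers are drawn from
#'   `-max_abs_copy..max_abs_copy`.
#' @param n_alleles_range range of allele counts per locus.
#' @param dirichlet_alpha concentration of the per-locus allele frequency
#'   draw.
#' @param causal_effects named or plain numeric vector of causal dosage
#'   effects in grams per copy; loci are assigned evenly across the map and
#'   receive a fixed symmetric five-allele model (relative copies -2..2,
#'   frequencies 0.1/0.2/0.4/0.2/0.1, dosage variance 2.4) so the planted
#'   effect size alone sets their variance contribution.
#' @param h2 narrow-sense heritability of the polygenic background relative
#'   to total phenotypic variance.
#' @param sigma_p2 total phenotypic variance target (g^2).
#' @param mu population mean harvest body weight (g).
#' @param sex_effect additive effect of the male sex class (g).
#' @param n_tanks number of rearing tanks.
#' @param ibw_mean,ibw_sd per-sex mean and sd of initial body weight (g),
#'   length-2 vectors (female, male).
#' @param ibw_slope per-tank regression slope of harvest weight on IBW.
#' @param noise list of call-noise rates for the VCF emitter:
#'   `low_posterior_rate`, `high_flank_rate`, `high_stutter_rate`,
#'   `missing_rate`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 60L,
                       offspring_per_family = 6L,
                       n_loci = 2000L,
                       max_abs_copy = 3L,
                       n_alleles_range = c(2L, 6L),
                       dirichlet_alpha = 1.5,
                       causal_effects = c(1.5, 2, 3),
                       h2 = 0.3,
                       sigma_p2 = 60,
                       mu = 30,
                       sex_effect = 2,
                       n_tanks = 2L,
                       ibw_mean = c(6.5, 5.5),
                       ibw_sd = c(1, 1),
                       ibw_slope = c(1.0, 1.4),
                       noise = list(low_posterior_rate = 0.03,
                                    high_flank_rate = 0.02,
                                    high_stutter_rate = 0.02,
                                    missing_rate = 0.05)) {
  stopifnot(h2 >= 0, h2 <= 1, n_families >= 1, offspring_per_family >= 1,
            n_loci >= 1, length(ibw_slope) >= n_tanks || n_tanks >= 1)
  if (length(ibw_slope) < n_tanks)
    ibw_slope <- rep_len(ibw_slope, n_tanks)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 offspring_per_family = as.integer(offspring_per_family),
                 n_loci = as.integer(n_loci), max_abs_copy = max_abs_copy,
                 n_alleles_range = n_alleles_range,
                 dirichlet_alpha = dirichlet_alpha,
                 causal_effects = causal_effects, h2 = h2,
                 sigma_p2 = sigma_p2, mu = mu, sex_effect = sex_effect,
                 n_tanks = as.integer(n_tanks), ibw_mean = ibw_mean,
                 ibw_sd = ibw_sd, ibw_slope = ibw_slope, noise = noise),
            class = "sim_config")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Simulate a pedigreed cohort with multiallelic STR genotypes
#'
#' Founders draw two alleles per locus from the locus allele frequencies
#' (Hardy-Weinberg); offspring inherit one allele from each parent with no
#' mutation. The polygenic breeding value is generated through the pedigree
#' (founders `N(0, sigma_a^2)`, offspring midparent plus Mendelian sampling),
#' so a marker-based relationship matrix is a genuine estimate of the
#' simulated structure. Phenotype:
#' `hbw = mu + sex + slope_tank * ibw + sum(effect * dosage) + a + e`.
#' The residual variance is chosen so that polygenic, causal and residual
#' variance sum to `sigma_p2`; an infeasible combination (causal variance
#' exceeding the non-polygenic budget) is an error reporting the feasible
#' `h2` range.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `pedigree` (id, sire, dam),
#'   `phenotypes` (id, sex, tank, ibw, hbw; offspring only), `dosage` (a
#'   `dosage_matrix` of true offspring dosages), `alleles` (two loci x
#'   offspring matrices of relative copies), `loci` (locus metadata:
#'   locus_id, scaffold, pos, period, motif, ref_repeats), `truth` (allele
#'   frequencies, causal loci and effects, breeding values, variance
#'   components, realised h2).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  nf <- config$n_families
  no <- config$offspring_per_family
  nl <- config$n_loci
  n_off <- nf * no

  # locus map: loci spread over scaffolds, dinucleotide-dominated periods
  n_scaf <- max(1L, min(40L, nl %/% 10L + 1L))
  scafs <- sprintf("scaf%03d", seq_len(n_scaf))
  loc_scaf <- sort(sample(seq_len(n_scaf), nl, replace = TRUE))
  pos <- integer(nl)
  for (s in unique(loc_scaf)) {
    k <- sum(loc_scaf == s)
    pos[loc_scaf == s] <- sort(sample.int(2e6, k))
  }
  period <- sample(1:6, nl, replace = TRUE,
                   prob = c(0.20, 0.50, 0.15, 0.08, 0.04, 0.03))
  motif <- vapply(period, random_primitive_motif, character(1))
  loci <- data.frame(locus_id = paste0(scafs[loc_scaf], "_", pos),
                     scaffold = scafs[loc_scaf], pos = pos, period = period,
                     motif = motif,
                     ref_repeats = ifelse(period == 1L, 12L, 8L),
                     stringsAsFactors = FALSE)

  # per-locus allele sets (signed relative copies) and frequencies
  allele_values <- vector("list", nl)
  allele_freqs <- vector("list", nl)
  rng <- seq(-config$max_abs_copy, config$max_abs_copy)
  for (j in seq_len(nl)) {
    k <- sample(config$n_alleles_range[1L]:config$n_alleles_range[2L], 1L)
    vals <- sort(sample(rng, k))
    allele_values[[j]] <- vals
    allele_freqs[[j]] <- stats::setNames(
      rdirichlet1(k, config$dirichlet_alpha), vals)
  }

  # causal loci: evenly spaced across the map; they get a fixed symmetric
  # five-allele model (dosage variance 2.4) so the planted effect alone
  # controls their phenotypic contribution
  n_causal <- length(config$causal_effects)
  causal_idx <- if (n_causal > 0L)
    round(seq(1, nl, length.out = n_causal + 2L))[2:(n_causal + 1L)]
  else integer(0)
  for (j in causal_idx) {
    allele_values[[j]] <- -2:2
    allele_freqs[[j]] <- stats::setNames(c(0.1, 0.2, 0.4, 0.2, 0.1), -2:2)
  }
  causal <- data.frame(locus_id = loci$locus_id[causal_idx],
                       locus_index = causal_idx,
                       effect = as.numeric(config$causal_effects),
                       stringsAsFactors = FALSE)

  # variance bookkeeping
  allele_var <- vapply(seq_len(nl), function(j) {
    v <- allele_values[[j]]
    p <- allele_freqs[[j]]
    sum(p * v^2) - sum(p * v)^2
  }, numeric(1))
  causal_var <- if (n_causal > 0L)
    sum(causal$effect^2 * 2 * allele_var[causal_idx]) else 0
  sigma_a2 <- config$h2 * config$sigma_p2
  sigma_e2 <- config$sigma_p2 - sigma_a2 - causal_var
  if (sigma_e2 <= 0) {
    h2_max <- 1 - causal_var / config$sigma_p2
    stop(sprintf(paste0("infeasible h2: causal variance %.2f leaves no ",
                        "residual budget; h2 must be below %.3f"),
                 causal_var, h2_max))
  }

  # pedigree: founder pairs, full-sib families
  sires <- sprintf("S%03d", seq_len(nf))
  dams <- sprintf("D%03d", seq_len(nf))
  off <- sprintf("F%03dI%02d", rep(seq_len(nf), each = no),
                 rep(seq_len(no), nf))
  ped <- data.frame(id = c(sires, dams, off),
                    sire = c(rep(NA, 2L * nf), rep(sires, each = no)),
                    dam = c(rep(NA, 2L * nf), rep(dams, each = no)),
                    stringsAsFactors = FALSE)

  # founder genotypes under HWE; offspring Mendelian inheritance
  founder_ids <- c(sires, dams)
  fa1 <- matrix(0, nl, 2L * nf)
  fa2 <- matrix(0, nl, 2L * nf)
  for (j in seq_len(nl)) {
    v <- allele_values[[j]]
    p <- allele_freqs[[j]]
    fa1[j, ] <- sample(v, 2L * nf, replace = TRUE, prob = p)
    fa2[j, ] <- sample(v, 2L * nf, replace = TRUE, prob = p)
  }
  oa1 <- matrix(0, nl, n_off)   # paternal allele
  oa2 <- matrix(0, nl, n_off)   # maternal allele
  for (i in seq_len(n_off)) {
    f <- (i - 1L) %/% no + 1L
    pick_s <- stats::runif(nl) < 0.5
    pick_d <- stats::runif(nl) < 0.5
    oa1[, i] <- ifelse(pick_s, fa1[, f], fa2[, f])
    oa2[, i] <- ifelse(pick_d, fa1[, nf + f], fa2[, nf + f])
  }
  dimnames(oa1) <- dimnames(oa2) <- list(loci$locus_id, off)
  dose <- oa1 + oa2

  # polygenic values through the pedigree
  a_founder <- stats::rnorm(2L * nf, 0, sqrt(sigma_a2))
  names(a_founder) <- founder_ids
  a_off <- numeric(n_off)
  for (i in seq_len(n_off)) {
    f <- (i - 1L) %/% no + 1L
    a_off[i] <- 0.5 * (a_founder[f] + a_founder[nf + f]) +
      stats::rnorm(1L, 0, sqrt(0.5 * sigma_a2))
  }
  names(a_off) <- off

  # fixed effects and phenotype (offspring only)
  sex <- sample(rep_len(c("F", "M"), n_off))
  tank <- sample(rep_len(seq_len(config$n_tanks), n_off))
  ibw <- ifelse(sex == "F",
                stats::rnorm(n_off, config$ibw_mean[1L], config$ibw_sd[1L]),
                stats::rnorm(n_off, config$ibw_mean[2L], config$ibw_sd[2L]))
  gvalue <- if (n_causal > 0L)
    drop(crossprod(dose[causal_idx, , drop = FALSE], causal$effect))
  else numeric(n_off)
  e <- stats::rnorm(n_off, 0, sqrt(sigma_e2))
  hbw <- config$mu + config$sex_effect * (sex == "M") +
    config$ibw_slope[tank] * ibw + gvalue + a_off + e
  pheno <- data.frame(id = off, sex = sex, tank = tank, ibw = ibw, hbw = hbw,
                      stringsAsFactors = FALSE)

  dm <- structure(list(loci = loci, samples = off, dosage = dose),
                  class = "dosage_matrix")
  truth <- list(allele_values = allele_values, allele_freqs = allele_freqs,
                causal = causal, breeding_values = c(a_founder, a_off),
                sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                causal_var = causal_var,
                realized_h2 = stats::var(a_off) / stats::var(hbw),
                residuals = e)
  structure(list(pedigree = ped, phenotypes = pheno, dosage = dm,
                 alleles = list(a1 = oa1, a2 = oa2), loci = loci,
                 truth = truth, config = config),
            class = "sim_cohort")
}

random_primitive_motif <- function(p) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
               collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

#' Write a HipSTR-style STR VCF for a simulated cohort
#'
#' Emits a VCF 4.1 file with `PERIOD`/`START`/`END` INFO keys and per-sample
#' `GT:GB:Q:DP:DSTUTTER:DFLANKINDEL` fields. A configurable fraction of
#' calls is planted with a low posterior or an excess flank-indel/stutter
#' read fraction — exactly the calls [filter_calls()] must remove — and a
#' further fraction is written as missing.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output VCF path.
#' @param noise noise-rate list; defaults to the cohort config's.
#' @param seed seed for the noise placement (defaults to config seed + 1).
#' @param depth simulated read depth per call.
#' @return invisibly, a list with `path` and `planted` — a data.frame of
#'   deliberately corrupted calls (`locus_id`, `sample_id`, `kind`).
#' @export
simulate_str_vcf <- function(cohort, path, noise = NULL, seed = NULL,
                             depth = 20L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(noise)) noise <- cohort$config$noise
  if (is.null(seed)) seed <- cohort$config$seed + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  loci <- cohort$loci
  a1 <- cohort$alleles$a1
  a2 <- cohort$alleles$a2
  samples <- colnames(a1)
  nl <- nrow(loci)
  ns <- length(samples)

  pick <- function(rate) {
    m <- matrix(stats::runif(nl * ns) < rate, nl, ns)
    m
  }
  miss <- pick(noise$missing_rate)
  lowq <- pick(noise$low_posterior_rate) & !miss
  hifl <- pick(noise$high_flank_rate) & !miss & !lowq
  hist <- pick(noise$high_stutter_rate) & !miss & !lowq & !hifl

  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##source=strdose-simulate",
    "##INFO=<ID=PERIOD,Number=1,Type=Integer,Description=\"Repeat unit length\">",
    "##INFO=<ID=START,Number=1,Type=Integer,Description=\"Repeat region start\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Repeat region end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GB,Number=1,Type=String,Description=\"Base pair differences of genotype from reference\">",
    "##FORMAT=<ID=Q,Number=1,Type=Float,Description=\"Posterior probability of unphased genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=DSTUTTER,Number=1,Type=Integer,Description=\"Reads with a stutter artifact\">",
    "##FORMAT=<ID=DFLANKINDEL,Number=1,Type=Integer,Description=\"Reads with a flank indel\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (j in seq_len(nl)) {
    p <- loci$period[j]
    motif <- loci$motif[j]
    nref <- loci$ref_repeats[j]
    copies <- sort(unique(c(a1[j, ], a2[j, ])))
    alts <- setdiff(copies, 0)
    ref_seq <- strrep(motif, nref)
    alt_seq <- if (length(alts) > 0L)
      paste(vapply(alts, function(cp) strrep(motif, nref + cp), character(1)),
            collapse = ",") else "."
    gt_index <- stats::setNames(seq_along(alts), alts)    # 1-based ALT index
    allele_code <- function(cp) ifelse(cp == 0, 0L, gt_index[as.character(cp)])
    fields <- character(ns)
    for (i in seq_len(ns)) {
      if (miss[j, i]) {
        fields[i] <- "."
        next
      }
      c1 <- a1[j, i]; c2 <- a2[j, i]
      q <- if (lowq[j, i]) stats::runif(1, 0.4, 0.89)
           else stats::runif(1, 0.95, 1.0)
      nfl <- if (hifl[j, i]) ceiling(depth * stats::runif(1, 0.2, 0.5))
             else sample(0:2, 1L)
      nst <- if (hist[j, i]) ceiling(depth * stats::runif(1, 0.2, 0.5))
             else sample(0:2, 1L)
      fields[i] <- sprintf("%d|%d:%d|%d:%.3f:%d:%d:%d",
                           allele_code(c1), allele_code(c2),
                           c1 * p, c2 * p, q, depth, nst, nfl)
    }
    writeLines(paste(c(loci$scaffold[j], loci$pos[j], loci$locus_id[j],
                       ref_seq, alt_seq, ".", ".",
                       sprintf("PERIOD=%d;START=%d;END=%d", p, loci$pos[j],
                               loci$pos[j] + nchar(ref_seq) - 1L),
                       "GT:GB:Q:DP:DSTUTTER:DFLANKINDEL", fields),
                     collapse = "\t"), con)
  }
  planted <- rbind(
    planted_df(miss, loci$locus_id, samples, "missing"),
    planted_df(lowq, loci$locus_id, samples, "low_posterior"),
    planted_df(hifl, loci$locus_id, samples, "high_flank"),
    planted_df(hist, loci$locus_id, samples, "high_stutter"))
  invisible(list(path = path, planted = planted))
}

planted_df <- function(m, locus_ids, samples, kind) {
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) == 0L)
    return(data.frame(locus_id = character(), sample_id = character(),
                      kind = character(), stringsAsFactors = FALSE))
  data.frame(locus_id = locus_ids[w[, 1L]], sample_id = samples[w[, 2L]],
             kind = kind, stringsAsFactors = FALSE)
}

#' Simulate a genome with planted STR loci
#'
#' Generates random background sequence free of threshold-passing repeats
#' (found runs are re-randomised until the background scans clean), then
#' writes each planted locus exactly, fixing the flanking bases so the
#' planted run can neither extend nor shift. The truth table lists every
#' planted locus with its exact coordinates.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_bp length of each scaffold.
#' @param planted data.frame with `scaffold` (index or name), `motif`,
#'   `n_repeats`, `position` (1-based start); must be non-overlapping and in
#'   bounds.
#' @param seed integer seed.
#' @param fasta output FASTA path (`NULL` to skip writing).
#' @param bed output truth BED path (`NULL` to skip writing).
#' @param thresholds scanner thresholds used for the background rejection.
#' @return list with `sequences` (named character), `truth` (data.frame in
#'   [scan_sequence()] layout), and the paths written.
#' @export
simulate_genome <- function(n_scaffolds = 1L, scaffold_bp = 10000L,
                            planted = NULL, seed = 1L, fasta = NULL,
                            bed = NULL, thresholds = scan_thresholds()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  scafs <- sprintf("scaf%03d", seq_len(n_scaffolds))
  if (!is.null(planted)) {
    stopifnot(all(c("scaffold", "motif", "n_repeats", "position") %in%
                  names(planted)))
    if (is.numeric(planted$scaffold)) planted$scaffold <- scafs[planted$scaffold]
    planted$length_bp <- nchar(planted$motif) * planted$n_repeats
    planted$end <- planted$position + planted$length_bp - 1L
    if (any(planted$end > scaffold_bp) || any(planted$position < 2L) ||
        any(planted$end > scaffold_bp - 1L))
      stop("planted loci must lie within scaffolds with 1 bp flanks")
    for (sc in unique(planted$scaffold)) {
      pp <- planted[planted$scaffold == sc, , drop = FALSE]
      pp <- pp[order(pp$position), , drop = FALSE]
      if (nrow(pp) > 1L &&
          any(pp$position[-1L] <= pp$end[-nrow(pp)] + 1L))
        stop("planted loci overlap (or touch) on ", sc)
    }
  }
  bases <- c("A", "C", "G", "T")
  seqs <- stats::setNames(vector("character", n_scaffolds), scafs)
  for (s in seq_len(n_scaffolds)) {
    ch <- sample(bases, scaffold_bp, replace = TRUE)
    # background rejection: re-randomise any threshold-passing run
    for (iter in 1:50) {
      found <- scan_sequence(paste(ch, collapse = ""), thresholds)
      if (nrow(found) == 0L) break
      for (r in seq_len(nrow(found))) {
        idx <- found$start[r]:found$end[r]
        ch[idx] <- sample(bases, length(idx), replace = TRUE)
      }
    }
    if (nrow(scan_sequence(paste(ch, collapse = ""), thresholds)) > 0L)
      stop("failed to generate STR-free background on ", scafs[s])
    seqs[s] <- paste(ch, collapse = "")
  }
  truth <- NULL
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (r in seq_len(nrow(planted))) {
      sc <- planted$scaffold[r]
      ch <- strsplit(seqs[[sc]], "", fixed = TRUE)[[1L]]
      p <- nchar(planted$motif[r])
      unit <- strsplit(toupper(planted$motif[r]), "", fixed = TRUE)[[1L]]
      s0 <- planted$position[r]
      e0 <- planted$end[r]
      ch[s0:e0] <- rep(unit, planted$n_repeats[r])
      # block left extension/shift: ch[s0-1] must differ from ch[s0+p-1]
      if (s0 > 1L) {
        alt <- setdiff(bases, ch[s0 + p - 1L])
        if (ch[s0 - 1L] == ch[s0 + p - 1L]) ch[s0 - 1L] <- alt[1L]
      }
      # block right extension: ch[e0+1] must differ from ch[e0+1-p]
      if (e0 < length(ch)) {
        alt <- setdiff(bases, ch[e0 + 1L - p])
        if (ch[e0 + 1L] == ch[e0 + 1L - p]) ch[e0 + 1L] <- alt[1L]
      }
      seqs[sc] <- paste(ch, collapse = "")
    }
    truth <- data.frame(scaffold = planted$scaffold,
                        start = planted$position, end = planted$end,
                        motif = toupper(planted$motif),
                        period = nchar(planted$motif),
                        n_repeats = planted$n_repeats,
                        length_bp = planted$length_bp,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(dss, fasta)
  }
  if (!is.null(bed) && !is.null(truth)) {
    utils::write.table(
      data.frame(truth$scaffold, truth$start - 1L, truth$end, truth$motif,
                 truth$period, truth$n_repeats),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(sequences = seqs, truth = truth, fasta = fasta, bed = bed)
}

#' Simulate a two-group RNA-seq count matrix
#'
#' Negative-binomial counts with per-group means; the listed DE genes have
#' their mean multiplied by the fold change in the first group.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group.
#' @param de_genes integer indices of differentially expressed genes.
#' @param fold_change fold change applied to the first group's mean for the
#'   DE genes (scalar or per-DE-gene vector, > 0).
#' @param base_mean mean count of a non-DE gene.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param seed integer seed.
#' @param group_labels length-2 labels, first group carries the fold change.
#' @return list: `counts` (genes x samples), `gene_lengths`, `groups`,
#'   `truth` (data.frame gene/is_de/fold_change).
#' @export
simulate_expression <- function(n_genes = 200L, n_per_group = 20L,
                                de_genes = integer(0), fold_change = 2,
                                base_mean = 100, dispersion = 0.1,
                                seed = 1L, group_labels = c("HBW", "LBW")) {
  stopifnot(all(fold_change > 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fc <- rep(1, n_genes)
  fc[de_genes] <- rep_len(fold_change, length(de_genes))
  gene_lengths <- sample(500:5000, n_genes, replace = TRUE)
  base <- base_mean * gene_lengths / 1500   # longer genes collect more reads
  size <- 1 / dispersion
  m1 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = base * fc,
                              size = size), n_genes, n_per_group)
  m2 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = base,
                              size = size), n_genes, n_per_group)
  counts <- cbind(m1, m2)
  rownames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(counts) <- c(sprintf("%s_%02d", group_labels[1L],
                                seq_len(n_per_group)),
                        sprintf("%s_%02d", group_labels[2L],
                                seq_len(n_per_group)))
  list(counts = counts,
       gene_lengths = stats::setNames(gene_lengths, rownames(counts)),
       groups = rep(group_labels, each = n_per_group),
       truth = data.frame(gene_id = rownames(counts),
                          is_de = seq_len(n_genes) %in% de_genes,
                          fold_change = fc, stringsAsFactors = FALSE))
}
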