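#' Read a HipSTR-dialect STR VCF into per-sample calls
#'
#' Parses a VCF whose per-sample FORMAT carries the base-pair length
#' difference of each allele from the reference allele (`GB`, `a|b`), the
#' call posterior (`Q`), read depth (`DP`) and the counts of reads with a
#' stutter artifact (`DSTUTTER`) or a flanking indel (`DFLANKINDEL`). The
#' locus period is taken from the `PERIOD` INFO key.
#'
#' @param path path to the VCF (plain or bgzipped).
#' @return a list of class `str_calls` with `loci` (data.frame: locus_id,
#'   scaffold, pos, period), `samples`, and `calls` — a data.frame in long
#'   format with one row per sample x locus: `locus_id`, `sample_id`,
#'   `bp1`, `bp2` (signed bp differences, NA when missing), `posterior`,
#'   `flank_indel_frac`, `stutter_frac`.
#' @export
read_str_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  period <- suppressWarnings(as.integer(vcfR::extract.info(v, "PERIOD")))
  if (anyNA(period))
    stop("PERIOD INFO field missing or non-integer at VCF record ",
         which(is.na(period))[1L])
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  loci <- data.frame(locus_id = ids, scaffold = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), period = period,
                     stringsAsFactors = FALSE)
  gb <- vcfR::extract.gt(v, element = "GB")
  q <- suppressWarnings(apply(vcfR::extract.gt(v, element = "Q"), 2,
                              as.numeric))
  dp <- suppressWarnings(apply(vcfR::extract.gt(v, element = "DP"), 2,
                               as.numeric))
  dst <- suppressWarnings(apply(vcfR::extract.gt(v, element = "DSTUTTER"), 2,
                                as.numeric))
  dfl <- suppressWarnings(apply(vcfR::extract.gt(v, element = "DFLANKINDEL"),
                                2, as.numeric))
  samples <- colnames(gb)
  nl <- nrow(loci)
  ns <- length(samples)
  gb_v <- as.vector(gb)
  parts <- matrix(NA_real_, length(gb_v), 2L)
  ok <- !is.na(gb_v)
  if (any(ok)) {
    sp <- strsplit(gb_v[ok], "|", fixed = TRUE)
    bad <- lengths(sp) != 2L
    if (any(bad))
      stop("malformed GB field '", gb_v[ok][bad][1L], "' in VCF record ",
           ((which(ok)[bad][1L] - 1L) %% nl) + 1L)
    parts[ok, 1L] <- as.numeric(vapply(sp, `[`, character(1), 1L))
    parts[ok, 2L] <- as.numeric(vapply(sp, `[`, character(1), 2L))
  }
  calls <- data.frame(
    locus_id = rep(loci$locus_id, times = ns),
    sample_id = rep(samples, each = nl),
    bp1 = parts[, 1L], bp2 = parts[, 2L],
    posterior = as.vector(q),
    flank_indel_frac = as.vector(dfl) / as.vector(dp),
    stutter_frac = as.vector(dst) / as.vector(dp),
    stringsAsFactors = FALSE)
  zero_dp <- !is.na(as.vector(dp)) & as.vector(dp) == 0
  calls$flank_indel_frac[zero_dp] <- 0
  calls$stutter_frac[zero_dp] <- 0
  structure(list(loci = loci, samples = samples, calls = calls),
            class = "str_calls")
}

#' Filter STR calls on posterior and read-artifact fractions
#'
#' A call survives iff its posterior is at least `q_min`, at most `flank_max`
#' of its reads carry a flanking indel, and at most `stutter_max` carry a
#' stutter artifact. Removed calls become missing. Idempotent.
#'
#' @param calls an `str_calls` object.
#' @param q_min minimum call posterior (default 0.90).
#' @param flank_max maximum flanking-indel read fraction (default 0.15).
#' @param stutter_max maximum stutter read fraction (default 0.15).
#' @return the `str_calls` object with failing calls set to missing.
#' @export
filter_calls <- function(calls, q_min = 0.90, flank_max = 0.15,
                         stutter_max = 0.15) {
  stopifnot(inherits(calls, "str_calls"),
            q_min >= 0, q_min <= 1, flank_max >= 0, flank_max <= 1,
            stutter_max >= 0, stutter_max <= 1)
  cc <- calls$calls
  present <- !is.na(cc$bp1)
  keep <- present &
    !is.na(cc$posterior) & cc$posterior >= q_min &
    !is.na(cc$flank_indel_frac) & cc$flank_indel_frac <= flank_max &
    !is.na(cc$stutter_frac) & cc$stutter_frac <= stutter_max
  drop <- present & !keep
  cc$bp1[drop] <- NA_real_
  cc$bp2[drop] <- NA_real_
  calls$calls <- cc
  calls
}

#' Build a relative-copy-number dosage matrix from STR calls
#'
#' The relative copy number of an allele is its base-pair difference from the
#' reference divided by the locus period; an individual's dosage at a locus
#' is the sum over its two alleles. A homozygous-reference call has dosage 0.
#' Base-pair differences that are not a multiple of the period (partial-unit
#' indels) are retained as rational copy numbers and flagged.
#'
#' @param calls an `str_calls` object (usually after [filter_calls()]).
#' @return an object of class `dosage_matrix`: list with `loci` (data.frame
#'   incl. `non_integral` flag), `samples`, and `dosage` — a numeric
#'   loci x samples matrix with NA for missing calls.
#' @export
dosage_matrix <- function(calls) {
  stopifnot(inherits(calls, "str_calls"))
  cc <- calls$calls
  loci <- calls$loci
  period <- loci$period[match(cc$locus_id, loci$locus_id)]
  dose <- (cc$bp1 + cc$bp2) / period
  nonint <- (cc$bp1 %% period != 0) | (cc$bp2 %% period != 0)
  d <- matrix(dose, nrow = nrow(loci), ncol = length(calls$samples),
              dimnames = list(loci$locus_id, calls$samples))
  ni <- matrix(nonint, nrow = nrow(loci))
  loci$non_integral <- apply(ni, 1L, function(x) any(x, na.rm = TRUE))
  structure(list(loci = loci, samples = calls$samples, dosage = d),
            class = "dosage_matrix")
}

#' Per-sample allele relative copy numbers from STR calls
#'
#' @param calls an `str_calls` object.
#' @return list of two loci x samples matrices `a1`, `a2` of relative copy
#'   numbers.
#' @keywords internal
allele_copy_matrices <- function(calls) {
  cc <- calls$calls
  loci <- calls$loci
  period <- loci$period[match(cc$locus_id, loci$locus_id)]
  dimn <- list(loci$locus_id, calls$samples)
  list(a1 = matrix(cc$bp1 / period, nrow = nrow(loci), dimnames = dimn),
       a2 = matrix(cc$bp2 / period, nrow = nrow(loci), dimnames = dimn))
}

#' Filter loci of a dosage matrix for an analysis purpose
#'
#' For GWAS input, keeps loci with a presence rate strictly above
#' `min_presence` (default 0.2); for GRM construction, keeps loci with a
#' missing rate strictly below `max_missing` (default 0.1). Monomorphic loci
#' (no dosage variance among observed calls) are dropped for both purposes.
#'
#' @param mat a `dosage_matrix`.
#' @param purpose `"gwas"` or `"grm"`.
#' @param min_presence presence-rate threshold for `purpose = "gwas"`.
#' @param max_missing missing-rate threshold for `purpose = "grm"`.
#' @return the filtered `dosage_matrix`.
#' @export
filter_loci <- function(mat, purpose = c("gwas", "grm"),
                        min_presence = 0.2, max_missing = 0.1) {
  stopifnot(inherits(mat, "dosage_matrix"),
            min_presence >= 0, min_presence <= 1,
            max_missing >= 0, max_missing <= 1)
  purpose <- match.arg(purpose)
  obs <- !is.na(mat$dosage)
  presence <- rowMeans(obs)
  keep <- if (purpose == "gwas") presence > min_presence
          else (1 - presence) < max_missing
  vr <- apply(mat$dosage, 1L, function(x) stats::var(x[!is.na(x)]))
  keep <- keep & !is.na(vr) & vr > 0
  if (!any(keep))
    stop("no loci survive the ", purpose,
         " filter; review the thresholds or input data")
  mat$loci <- mat$loci[keep, , drop = FALSE]
  mat$dosage <- mat$dosage[keep, , drop = FALSE]
  mat
}

#' Allele frequencies at one locus of a dosage-era call set
#'
#' Tallies the two allele relative-copy values of every observed call at the
#' locus; frequencies are over `2 x` the number of observed calls.
#'
#' @param calls an `str_calls` object.
#' @param locus_id locus identifier.
#' @return named numeric vector: allele relative-copy value -> frequency.
#' @export
allele_frequencies <- function(calls, locus_id) {
  stopifnot(inherits(calls, "str_calls"))
  cc <- calls$calls[calls$calls$locus_id == locus_id, , drop = FALSE]
  if (nrow(cc) == 0L) stop("unknown locus: ", locus_id)
  period <- calls$loci$period[match(locus_id, calls$loci$locus_id)]
  alle <- c(cc$bp1, cc$bp2) / period
  alle <- alle[!is.na(alle)]
  if (length(alle) == 0L) stop("locus ", locus_id, " has no observed calls")
  tab <- table(alle)
  stats::setNames(as.numeric(tab) / length(alle), names(tab))
}

#' Polymorphism information content (PIC)
#'
#' Botstein's PIC for a multiallelic marker:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2}
#'
#' @param allele_freqs numeric vector of allele frequencies (must sum to 1).
#' @return PIC value in `[0, 1)`.
#' @export
pic <- function(allele_freqs) {
  p <- as.numeric(allele_freqs)
  stopifnot(all(p >= 0))
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  p2 <- p^2
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))   # sum_{i<j} 2 p_i^2 p_j^2
}

#' Polymorphism class from a PIC value
#'
#' Botstein's convention: low when PIC < 0.25, medium when 0.25 <= PIC <= 0.5,
#' high when PIC > 0.5.
#'
#' @param pic_value PIC in `[0, 1)`.
#' @return `"low"`, `"medium"` or `"high"` (vectorised).
#' @export
polymorphism_class <- function(pic_value) {
  stopifnot(all(pic_value >= 0), all(pic_value < 1))
  ifelse(pic_value < 0.25, "low",
         ifelse(pic_value <= 0.5, "medium", "high"))
}

# genotype_counts: named counts with names "a/b" (unordered allele pair);
# returns list(alleles, geno key matrix, counts)
parse_genotype_counts <- function(genotype_counts) {
  keys <- strsplit(names(genotype_counts), "/", fixed = TRUE)
  if (any(lengths(keys) != 2L))
    stop("genotype names must be 'a/b' allele pairs")
  a1 <- vapply(keys, `[`, character(1), 1L)
  a2 <- vapply(keys, `[`, character(1), 2L)
  cnt <- as.numeric(genotype_counts)
  stopifnot(all(cnt >= 0))
  list(a1 = a1, a2 = a2, counts = cnt,
       alleles = sort(unique(c(a1, a2))))
}

hwe_chisq_stat <- function(a1, a2, counts, alleles) {
  n <- sum(counts)
  # allele counts
  ac <- stats::setNames(numeric(length(alleles)), alleles)
  for (i in seq_along(counts)) {
    ac[a1[i]] <- ac[a1[i]] + counts[i]
    ac[a2[i]] <- ac[a2[i]] + counts[i]
  }
  p <- ac / (2 * n)
  k <- length(alleles)
  stat <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      exp_ij <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
      key_obs <- sum(counts[(a1 == alleles[i] & a2 == alleles[j]) |
                            (a1 == alleles[j] & a2 == alleles[i])])
      if (exp_ij > 0) stat <- stat + (key_obs - exp_ij)^2 / exp_ij
    }
  }
  as.numeric(stat)
}

#' Hardy-Weinberg equilibrium test for a multiallelic locus
#'
#' `method = "chisq"` compares observed genotype counts with the HWE
#' expectations (`n p_i^2`, `2 n p_i p_j`) on `k(k-1)/2` degrees of freedom.
#' `method = "montecarlo"` (default) is an exact-style permutation test: the
#' observed alleles are shuffled into random genotype tables and the p-value
#' is the fraction of tables whose chi-square discrepancy from HWE is at
#' least as extreme as the observed one.
#'
#' @param genotype_counts named numeric vector; names are unordered allele
#'   pairs `"a/b"`, values are genotype counts.
#' @param method `"montecarlo"` or `"chisq"`.
#' @param n_perm number of Monte-Carlo shuffles.
#' @param seed integer seed for the Monte-Carlo method.
#' @return list with `p_value`, `statistic`, `df` (chisq only), `method`,
#'   and `degenerate` (TRUE when fewer than 2 alleles are present, in which
#'   case `p_value` is 1).
#' @export
hwe_test <- function(genotype_counts, method = c("montecarlo", "chisq"),
                     n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  g <- parse_genotype_counts(genotype_counts)
  if (length(g$alleles) < 2L || sum(g$counts) == 0)
    return(list(p_value = 1, statistic = 0, df = 0L, method = method,
                degenerate = TRUE))
  obs <- hwe_chisq_stat(g$a1, g$a2, g$counts, g$alleles)
  if (method == "chisq") {
    k <- length(g$alleles)
    df <- k * (k - 1L) / 2L
    return(list(p_value = stats::pchisq(obs, df, lower.tail = FALSE),
                statistic = obs, df = df, method = method,
                degenerate = FALSE))
  }
  # expand the genotype table into a vector of 2N alleles; under permutation
  # the allele counts (hence the HWE expectations) are invariant, so the
  # expected cell counts are computed once
  reps <- rep(seq_along(g$counts), times = g$counts)
  pool <- c(g$a1[reps], g$a2[reps])
  n_geno <- length(reps)
  k <- length(g$alleles)
  af <- table(factor(pool, levels = g$alleles)) / length(pool)
  cell_i <- integer(0); cell_j <- integer(0)
  for (i in seq_len(k)) for (j in i:k) {
    cell_i <- c(cell_i, i); cell_j <- c(cell_j, j)
  }
  exp_cells <- ifelse(cell_i == cell_j, n_geno * af[cell_i]^2,
                      2 * n_geno * af[cell_i] * af[cell_j])
  cell_key <- paste(g$alleles[cell_i], g$alleles[cell_j], sep = "/")
  pool_idx <- match(pool, g$alleles)
  hits <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  keep <- exp_cells > 0
  for (b in seq_len(n_perm)) {
    perm <- sample(pool_idx)
    pa1 <- perm[seq_len(n_geno)]
    pa2 <- perm[n_geno + seq_len(n_geno)]
    key_idx <- match(paste(g$alleles[pmin(pa1, pa2)],
                           g$alleles[pmax(pa1, pa2)], sep = "/"), cell_key)
    o <- tabulate(key_idx, nbins = length(cell_key))
    stat <- sum((o[keep] - exp_cells[keep])^2 / exp_cells[keep])
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  list(p_value = (hits + 1) / (n_perm + 1), statistic = obs, df = NA_integer_,
       method = method, degenerate = FALSE)
}

#' Genotype counts at one locus from allele copy matrices
#'
#' @param calls an `str_calls` object.
#' @param locus_id locus identifier.
#' @return named numeric vector of genotype counts suitable for [hwe_test()].
#' @export
genotype_counts <- function(calls, locus_id) {
  stopifnot(inherits(calls, "str_calls"))
  cc <- calls$calls[calls$calls$locus_id == locus_id, , drop = FALSE]
  if (nrow(cc) == 0L) stop("unknown locus: ", locus_id)
  period <- calls$loci$period[match(locus_id, calls$loci$locus_id)]
  ok <- !is.na(cc$bp1)
  if (!any(ok)) stop("locus ", locus_id, " has no observed calls")
  a1 <- cc$bp1[ok] / period
  a2 <- cc$bp2[ok] / period
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  tab <- table(key)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Locus-level QC summary
#'
#' Presence rate, allele frequencies, PIC, polymorphism class and HWE p-value
#' for every locus of a call set.
#'
#' @param calls an `str_calls` object (after [filter_calls()]).
#' @param hwe_method passed to [hwe_test()].
#' @param n_perm Monte-Carlo shuffles for the HWE test.
#' @param seed seed for the Monte-Carlo HWE test.
#' @return data.frame with one row per locus: `locus_id`, `presence_rate`,
#'   `n_alleles`, `pic`, `polymorphism_class`, `hwe_p`.
#' @export
locus_qc <- function(calls, hwe_method = "chisq", n_perm = 2000L, seed = 1L) {
  stopifnot(inherits(calls, "str_calls"))
  ns <- length(calls$samples)
  res <- lapply(calls$loci$locus_id, function(lid) {
    cc <- calls$calls[calls$calls$locus_id == lid, , drop = FALSE]
    obs <- sum(!is.na(cc$bp1))
    if (obs == 0L)
      return(data.frame(locus_id = lid, presence_rate = 0,
                        n_alleles = 0L, pic = NA_real_,
                        polymorphism_class = NA_character_,
                        hwe_p = NA_real_, stringsAsFactors = FALSE))
    af <- allele_frequencies(calls, lid)
    p <- pic(af)
    hw <- hwe_test(genotype_counts(calls, lid), method = hwe_method,
                   n_perm = n_perm, seed = seed)
    data.frame(locus_id = lid, presence_rate = obs / ns,
               n_alleles = length(af), pic = p,
               polymorphism_class = polymorphism_class(p),
               hwe_p = hw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
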