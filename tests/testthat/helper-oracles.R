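# Independent oracles used across the test files. These deliberately use
# naive position-by-position enumeration, recursion, or dense linear algebra
# rather than the package's own algorithms.

# Brute-force perfect-repeat enumerator: for every period and start position,
# count full repeat units forward; a candidate is reported iff it passes the
# thresholds, its unit is primitive, and the run cannot extend or shift left
# (the character before the start differs from the one a period later).
oracle_scan <- function(seq, thresholds = strdose::scan_thresholds()) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  min_reps <- thresholds$min_repeats_by_period
  rows <- list()
  primitive <- function(m) {
    p <- nchar(m)
    if (p == 1L) return(TRUE)
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && strrep(substr(m, 1L, d), p / d) == m) return(FALSE)
    }
    TRUE
  }
  for (p in 1:6) {
    for (s in seq_len(max(0L, n - 2L * p + 1L))) {
      unit <- substr(seq, s, s + p - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      if (!primitive(unit)) next
      k <- 1L
      while (s + (k + 1L) * p - 1L <= n &&
             substr(seq, s + k * p, s + (k + 1L) * p - 1L) == unit &&
             !grepl("N", substr(seq, s + k * p, s + (k + 1L) * p - 1L),
                    fixed = TRUE)) {
        k <- k + 1L
      }
      if (k < min_reps[p] || k * p < thresholds$min_region_bp) next
      if (s > 1L && ch[s - 1L] == ch[s + p - 1L] &&
          ch[s - 1L] != "N") next   # run extends/shifts left
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = s + k * p - 1L, motif = unit, period = p,
        n_repeats = k, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), period = integer(),
                      n_repeats = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, with_n = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(pool, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}

revcomp <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch], collapse = "")
}

rotate_motif <- function(m, k) {
  p <- nchar(m)
  k <- k %% p
  if (k == 0L) return(m)
  paste0(substr(m, k + 1L, p), substr(m, 1L, k))
}

# Recursive-kinship oracle: f(i, j) by Malecot's recursion, memoised.
# The numerator relationship matrix equals 2 * kinship.
oracle_kinship_matrix <- function(ped) {
  ped <- strdose::pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else {
      # recurse on the later-born individual (parents precede offspring)
      a <- max(i, j); b <- min(i, j)
      0.5 * (f(si[a], b) + f(di[a], b))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    K[i, j] <- f(i, j)
    K[j, i] <- K[i, j]
  }
  K
}

# Dense joint-GLS oracle for the animal model: fixed effects by GLS under
# V = Z A Z' sa2 + I se2, breeding values by the conditional expectation.
oracle_blup_dense <- function(y, X, Z, A, sigma_a2, sigma_e2) {
  V <- Z %*% A %*% t(Z) * sigma_a2 + diag(sigma_e2, length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sigma_a2 * A %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b_hat = drop(b), a_hat = drop(a))
}

# Dense REML criterion used as the grid-search oracle: straight evaluation
# of the restricted log-likelihood at a given variance ratio delta, using
# full-matrix inverses and determinants.
oracle_reml_loglik <- function(delta, y, X, G) {
  n <- length(y)
  p <- ncol(X)
  V0 <- delta * G + diag(n)
  Vi <- solve(V0)
  XtVX <- t(X) %*% Vi %*% X
  B <- solve(XtVX, t(X) %*% Vi)
  r <- y - X %*% (B %*% y)
  ypy <- drop(t(r) %*% Vi %*% r)
  s2 <- ypy / (n - p)
  as.numeric(
    -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) +
            determinant(V0, logarithm = TRUE)$modulus[1L] +
            determinant(XtVX, logarithm = TRUE)$modulus[1L] -
            determinant(t(X) %*% X, logarithm = TRUE)$modulus[1L]))
}

# Exhaustive enumeration of the permutation HWE test on a tiny table:
# iterates every ordering of the allele pool and pairs consecutive alleles,
# exactly the Monte-Carlo sampling scheme.
oracle_hwe_exact <- function(genotype_counts) {
  keys <- strsplit(names(genotype_counts), "/", fixed = TRUE)
  a1 <- vapply(keys, `[`, character(1), 1L)
  a2 <- vapply(keys, `[`, character(1), 2L)
  cnt <- as.numeric(genotype_counts)
  reps <- rep(seq_along(cnt), times = cnt)
  pool <- c(a1[reps], a2[reps])
  n_geno <- length(reps)
  alleles <- sort(unique(pool))
  af <- table(factor(pool, levels = alleles)) / length(pool)
  k_all <- length(alleles)
  stat_of <- function(pa1, pa2) {
    s <- 0
    for (i in seq_len(k_all)) for (j in i:k_all) {
      e <- if (i == j) n_geno * af[i]^2 else 2 * n_geno * af[i] * af[j]
      if (e <= 0) next
      o <- sum((pa1 == alleles[i] & pa2 == alleles[j]) |
               (pa1 == alleles[j] & pa2 == alleles[i]))
      s <- s + (o - e)^2 / e
    }
    s
  }
  obs <- stat_of(a1[reps], a2[reps])
  perms <- gtools_permutations(length(pool))
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    pm <- pool[perms[r, ]]
    if (stat_of(pm[seq_len(n_geno)], pm[n_geno + seq_len(n_geno)]) >=
        obs - 1e-12) hits <- hits + 1L
  }
  hits / nrow(perms)
}

# all permutations of 1..n as a matrix (n! rows); recursive, for tiny n
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# small full-sib cohort used by several files
tiny_cohort <- function(seed = 11L, ...) {
  strdose::simulate_cohort(strdose::sim_config(
    seed = seed, n_families = 10L, offspring_per_family = 4L, n_loci = 80L,
    causal_effects = c(2.5),
    noise = list(low_posterior_rate = 0, high_flank_rate = 0,
                 high_stutter_rate = 0, missing_rate = 0), ...))
}
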