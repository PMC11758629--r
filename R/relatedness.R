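#' VanRaden-style genomic relationship matrix from STR dosages
#'
#' Centers each locus's dosages by the locus mean (missing dosages are mean
#' imputed, so they contribute zero after centering) and scales the
#' cross-product by the summed per-locus dosage variance:
#' \deqn{G = W W' / s, \quad s = \sum_j var_j}
#' where `var_j` is the population variance (divisor n) of the observed
#' dosages at locus j. For biallelic 0/1/2 codes this reduces to VanRaden's
#' method 1 up to the variance convention, and keeps the expected diagonal
#' near 1 for multiallelic signed dosages.
#'
#' @param mat a `dosage_matrix`, typically after
#'   `filter_loci(purpose = "grm")`.
#' @return an object of class `grm`: list with `sample_ids`, `matrix`
#'   (n x n), `scale_constant`.
#' @export
vanraden_grm <- function(mat) {
  stopifnot(inherits(mat, "dosage_matrix"))
  d <- mat$dosage
  if (ncol(d) < 2L) stop("need at least 2 samples")
  mu <- rowMeans(d, na.rm = TRUE)
  pvar <- apply(d, 1L, function(x) {
    x <- x[!is.na(x)]
    sum((x - mean(x))^2) / length(x)
  })
  s <- sum(pvar)
  if (s <= 0) stop("all loci are monomorphic; GRM scale is zero")
  w <- d - mu
  w[is.na(w)] <- 0
  g <- crossprod(w) / s
  structure(list(sample_ids = colnames(d), matrix = g, scale_constant = s),
            class = "grm")
}

#' Principal-component covariates from a relationship matrix
#'
#' Eigen-decomposes G and returns the top-k component scores (eigenvectors
#' scaled by the square root of their eigenvalues) with a deterministic sign
#' convention: within each component the largest-magnitude loading is
#' positive.
#'
#' @param g a `grm` object.
#' @param k number of components (default 5).
#' @return list of class `pc_covariates` with `sample_ids`, `components`
#'   (n x k matrix, columns `PC1..PCk`), `explained_variance` fractions.
#' @export
grm_pca <- function(g, k = 5L) {
  stopifnot(inherits(g, "grm"), k >= 1L)
  n <- nrow(g$matrix)
  if (k > n) stop("k exceeds the number of samples")
  e <- eigen(g$matrix, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] * sqrt(vals[j])
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- g$sample_ids
  structure(list(sample_ids = g$sample_ids, components = scores,
                 explained_variance = vals[seq_len(k)] / sum(vals)),
            class = "pc_covariates")
}
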