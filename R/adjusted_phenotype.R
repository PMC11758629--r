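#' Validate and order a pedigree
#'
#' Checks acyclicity and returns the records in an order where parents
#' precede offspring. Unknown parents are coded `NA` or `"0"`.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (character or
#'   coercible).
#' @return data.frame of class `pedigree` with character columns, ordered
#'   parents-first.
#' @export
pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped <- data.frame(id = as.character(ped$id),
                    sire = as.character(ped$sire),
                    dam = as.character(ped$dam),
                    stringsAsFactors = FALSE)
  ped$sire[ped$sire %in% c("0", "", "NA")] <- NA
  ped$dam[ped$dam %in% c("0", "", "NA")] <- NA
  if (anyDuplicated(ped$id)) stop("duplicated pedigree ids")
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  if (!all(known %in% ped$id))
    stop("parents absent from the id column: ",
         paste(utils::head(setdiff(known, ped$id)), collapse = ", "))
  # Kahn topological sort; a leftover node means a cycle
  order_ids <- character(0)
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0L) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
             (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready))
      stop("pedigree cycle involving individual ", remaining$id[1L])
    order_ids <- c(order_ids, remaining$id[ready])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  out <- ped[match(order_ids, ped$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds A with the classic recurrence: for individual i with parents s, d
#' (processed parents-first), `a_ii = 1 + 0.5 a_sd` and
#' `a_ij = 0.5 (a_js + a_jd)` for every earlier j; unknown parents
#' contribute 0.
#'
#' @param ped a [pedigree()] (or coercible data.frame).
#' @return object of class `a_matrix`: list with `ids` and `matrix`.
#' @export
pedigree_a_matrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- 0.5 * (as_ + ad_)
      A[i, j] <- A[j, i]
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  structure(list(ids = ped$id, matrix = A), class = "a_matrix")
}

#' Animal-model BLUP via Henderson's mixed model equations
#'
#' Fits the pedigree animal model
#' \deqn{y_{ij} = \mu + Sex_i + \beta_{(Sex_i)} IBW_j + a_j + e_{ij}}
#' with `a ~ N(0, A sigma_a^2)`. Solves the MME
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + A^{-1}\lambda \end{pmatrix}
#'       \begin{pmatrix}\hat b\\ \hat a\end{pmatrix} =
#'       \begin{pmatrix}X'y\\ Z'y\end{pmatrix}}
#' with `lambda = sigma_e^2 / sigma_a^2`. Individuals in the pedigree without
#' a phenotype still receive a breeding value through their relatives.
#' Variance components default to a REML fit of the same model (A in place
#' of G).
#'
#' @param pheno data.frame with columns `id`, `sex`, `ibw`, `hbw` (harvest
#'   body weight, the response).
#' @param ped a [pedigree()] containing every phenotyped id.
#' @param varcomp optional list with `sigma_a2`, `sigma_e2`; estimated by
#'   REML when `NULL`.
#' @return list of class `blup_result`: `b_hat` (named fixed-effect
#'   solutions), `a_hat` (named, all pedigree ids), `e_hat` (named,
#'   phenotyped ids), `varcomp`, `ids_phenotyped`, `fitted_fixed`.
#' @export
animal_model_blup <- function(pheno, ped, varcomp = NULL) {
  stopifnot(all(c("id", "sex", "ibw", "hbw") %in% names(pheno)))
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  ids <- as.character(pheno$id)
  if (!all(ids %in% ped$id))
    stop("phenotyped ids absent from pedigree: ",
         paste(utils::head(setdiff(ids, ped$id)), collapse = ", "))
  y <- as.numeric(pheno$hbw)
  df <- data.frame(sex = factor(pheno$sex), ibw = as.numeric(pheno$ibw))
  X <- stats::model.matrix(~ sex + sex:ibw, data = df)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design; confounded columns: ",
         paste(colnames(X), collapse = ", "))
  am <- pedigree_a_matrix(ped)
  A <- am$matrix
  if (is.null(varcomp)) {
    sub <- match(ids, am$ids)
    spec <- mixed_model_spec(y, X, A[sub, sub, drop = FALSE], ids)
    vc <- reml_fit(spec)
    varcomp <- list(sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2)
  }
  if (varcomp$sigma_a2 <= 0)
    stop("sigma_a2 must be positive to solve the MME; got a boundary fit")
  lambda <- varcomp$sigma_e2 / varcomp$sigma_a2
  nall <- nrow(A)
  Z <- matrix(0, length(y), nall, dimnames = list(ids, am$ids))
  Z[cbind(seq_along(y), match(ids, am$ids))] <- 1
  Ainv <- chol2inv(chol(A))
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + Ainv * lambda))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  p <- ncol(X)
  b_hat <- stats::setNames(sol[seq_len(p)], colnames(X))
  a_hat <- stats::setNames(sol[p + seq_len(nall)], am$ids)
  fitted_fixed <- drop(X %*% b_hat)
  e_hat <- stats::setNames(y - fitted_fixed - a_hat[ids], ids)
  structure(list(b_hat = b_hat, a_hat = a_hat, e_hat = e_hat,
                 varcomp = varcomp, ids_phenotyped = ids,
                 fitted_fixed = stats::setNames(fitted_fixed, ids),
                 y = stats::setNames(y, ids)),
            class = "blup_result")
}

#' Adjusted phenotypes from an animal-model fit
#'
#' The adjusted phenotype of individual j is `y*_j = a_hat_j + e_hat_j`: the
#' phenotype stripped of its fixed-effect fit, retaining genetic and
#' residual deviations.
#'
#' @param blup a [animal_model_blup()] result.
#' @param ids optional id subset; ids without a phenotype are excluded with
#'   a warning.
#' @return named numeric vector `y_star` over phenotyped ids.
#' @export
adjust_phenotypes <- function(blup, ids = NULL) {
  stopifnot(inherits(blup, "blup_result"))
  use <- blup$ids_phenotyped
  if (!is.null(ids)) {
    missing_ids <- setdiff(as.character(ids), use)
    if (length(missing_ids) > 0L)
      warning("ids without phenotype excluded: ",
              paste(utils::head(missing_ids), collapse = ", "))
    use <- intersect(as.character(ids), use)
  }
  blup$a_hat[use] + blup$e_hat[use]
}

#' Pearson correlation of STR dosage with adjusted phenotype
#'
#' For each locus, correlates dosage with `y*` over the individuals having
#' both (pairwise-complete, no imputation); a locus passes when
#' `|r| > threshold`. The p-value of the usual t transform is reported but
#' does not enter the filter.
#'
#' @param mat a `dosage_matrix`.
#' @param adj named `y*` vector from [adjust_phenotypes()].
#' @param loci optional locus_id subset (e.g. the suggestive GWAS hits).
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @return data.frame: `locus_id`, `n`, `r`, `p_value`, `passes`,
#'   `degenerate`.
#' @export
correlate_dosage <- function(mat, adj, loci = NULL, threshold = 0.5) {
  stopifnot(inherits(mat, "dosage_matrix"), !is.null(names(adj)))
  use_loci <- if (is.null(loci)) mat$loci$locus_id
              else intersect(loci, mat$loci$locus_id)
  common <- intersect(names(adj), mat$samples)
  res <- lapply(use_loci, function(lid) {
    s <- mat$dosage[match(lid, mat$loci$locus_id), match(common, mat$samples)]
    ok <- !is.na(s)
    n_ok <- sum(ok)
    rec <- data.frame(locus_id = lid, n = n_ok, r = NA_real_,
                      p_value = NA_real_, passes = FALSE, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    if (n_ok >= 3L && stats::var(s[ok]) > 0 && stats::var(adj[common][ok]) > 0) {
      ct <- stats::cor.test(s[ok], adj[common][ok], method = "pearson")
      rec$r <- unname(ct$estimate)
      rec$p_value <- ct$p.value
      rec$passes <- abs(rec$r) > threshold
      rec$degenerate <- FALSE
    }
    rec
  })
  do.call(rbind, res)
}
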