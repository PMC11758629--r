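#' Mixed linear model specification for STR dosage association
#'
#' Bundles the phenotype vector, fixed-effect design and genomic relationship
#' matrix for the model
#' \deqn{y = 1\mu + Xb + Su + Za + e,\quad a \sim N(0, G\sigma_a^2),\;
#'       e \sim N(0, I\sigma_e^2)}
#' where `S` is the per-locus STR dosage covariate tested by [assoc_scan()].
#'
#' @param y numeric phenotype vector (one record per individual).
#' @param X fixed-effect design matrix including the intercept; rows aligned
#'   with `y`. Use [gwas_design()] to build the standard design (sex factor,
#'   PC covariates, initial body weight nested in tank).
#' @param G relationship matrix aligned with `y` (a `grm` object or a plain
#'   symmetric matrix).
#' @param sample_ids optional ids, used to label results.
#' @return object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(y, X, G, sample_ids = NULL) {
  if (inherits(G, "grm")) {
    if (is.null(sample_ids)) sample_ids <- G$sample_ids
    G <- G$matrix
  }
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient; drop confounded columns")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  structure(list(y = y, X = X, G = G, sample_ids = sample_ids),
            class = "mixed_model_spec")
}

#' Standard fixed-effect design for the dosage GWAS
#'
#' Builds the design: intercept, sex as a two-level factor (reference level
#' dropped), the top principal-component covariates, and one initial body
#' weight (IBW) slope per tank ("IBW nested in tank").
#'
#' @param pheno data.frame with columns `id`, `sex`, `tank`, `ibw`.
#' @param pcs optional matrix/data.frame of PC scores with rows matching
#'   `pheno$id` (e.g. `grm_pca(...)$components`).
#' @return design matrix with rownames `pheno$id`.
#' @export
gwas_design <- function(pheno, pcs = NULL) {
  stopifnot(all(c("id", "sex", "tank", "ibw") %in% names(pheno)))
  df <- data.frame(sex = factor(pheno$sex), tank = factor(pheno$tank),
                   ibw = as.numeric(pheno$ibw))
  X <- stats::model.matrix(~ sex + tank:ibw, data = df)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (!is.null(rownames(pcs))) pcs <- pcs[as.character(pheno$id), , drop = FALSE]
    X <- cbind(X, pcs)
  }
  rownames(X) <- as.character(pheno$id)
  X
}

# REML machinery: V = sigma_e^2 (delta * G + I); after rotating by the
# eigenvectors of G the criterion is a 1-d profile in delta.
reml_profile <- function(log_delta, d, ry, rX) {
  delta <- exp(log_delta)
  w <- delta * d + 1
  n <- length(ry)
  p <- ncol(rX)
  xtwx <- crossprod(rX, rX / w)
  beta <- solve(xtwx, crossprod(rX, ry / w))
  r <- ry - rX %*% beta
  ypy <- sum(r^2 / w)
  df <- n - p
  s2 <- ypy / df
  ll <- -0.5 * (df * log(2 * pi * s2) + df + sum(log(w)) +
                determinant(xtwx, logarithm = TRUE)$modulus[1L] -
                determinant(crossprod(rX), logarithm = TRUE)$modulus[1L])
  list(loglik = as.numeric(ll), sigma_e2 = s2, sigma_a2 = delta * s2,
       beta = beta)
}

#' REML estimation of variance components
#'
#' Maximises the restricted likelihood of
#' `y ~ N(Xb, G sigma_a^2 + I sigma_e^2)` over the two variance components.
#' After eigendecomposition of G the criterion is profiled in the variance
#' ratio `delta = sigma_a^2 / sigma_e^2` and optimised in one dimension;
#' estimates landing on the `delta = 0` (or numerically infinite) boundary
#' are returned with `converged = TRUE` and `boundary = TRUE`.
#'
#' @param spec a [mixed_model_spec()].
#' @param interval search interval for `log(delta)`.
#' @return list of class `variance_components`: `sigma_a2`, `sigma_e2`,
#'   `loglik`, `converged`, `boundary`, `h2`, plus the eigendecomposition
#'   reused by [assoc_scan()].
#' @export
reml_fit <- function(spec, interval = c(-12, 12)) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  e <- eigen(spec$G, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("relationship matrix is not positive semi-definite")
  d <- pmax(e$values, 0)
  U <- e$vectors
  ry <- drop(crossprod(U, spec$y))
  rX <- crossprod(U, spec$X)
  opt <- stats::optimize(function(ld) reml_profile(ld, d, ry, rX)$loglik,
                         interval = interval, maximum = TRUE, tol = 1e-8)
  # compare with the boundary delta -> 0
  lo <- reml_profile(interval[1L] - 20, d, ry, rX)
  best <- reml_profile(opt$maximum, d, ry, rX)
  boundary <- FALSE
  if (lo$loglik >= best$loglik - 1e-8 ||
      opt$maximum <= interval[1L] + 1e-3) {
    best <- lo
    best$sigma_a2 <- 0
    boundary <- TRUE
  } else if (opt$maximum >= interval[2L] - 1e-3) {
    boundary <- TRUE
  }
  structure(list(sigma_a2 = best$sigma_a2, sigma_e2 = best$sigma_e2,
                 loglik = best$loglik, converged = TRUE,
                 boundary = boundary,
                 h2 = best$sigma_a2 / (best$sigma_a2 + best$sigma_e2),
                 eigen_values = d, eigen_vectors = U),
            class = "variance_components")
}

# GLS Wald test of the last column of C under covariance V, where V is given
# through its rotated weights (w, rotation applied already) or a Cholesky.
gls_wald_rotated <- function(rY, rC, w) {
  q <- ncol(rC)
  xtwx <- crossprod(rC, rC / w)
  xtwy <- crossprod(rC, rY / w)
  cov_un <- solve(xtwx)
  beta <- drop(cov_un %*% xtwy)
  r <- rY - rC %*% beta
  df <- length(rY) - q
  s2 <- sum(r^2 / w) / df
  se <- sqrt(s2 * cov_un[q, q])
  t <- beta[q] / se
  list(u_hat = beta[q], se = se, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

#' Genome-wide association scan of STR dosages
#'
#' Tests each locus's dosage covariate in the mixed model by a Wald test
#' under GLS weighting with `V = G sigma_a^2 + I sigma_e^2`. In `"p3d"` mode
#' (default) the variance components are estimated once under the null model
#' and reused for every locus; `"exact"` mode re-estimates them per locus
#' with the dosage in the model. Individuals with a missing dosage are
#' dropped for that locus's test only (the relationship matrix is never
#' subset for the null fit).
#'
#' @param spec a [mixed_model_spec()].
#' @param mat a `dosage_matrix` whose samples match `spec$sample_ids`
#'   (typically after `filter_loci(purpose = "gwas")`).
#' @param mode `"p3d"` or `"exact"`.
#' @param vc optional precomputed [reml_fit()] result (p3d mode).
#' @param alpha suggestive p-value threshold (default 5e-4).
#' @param min_n minimum observed individuals per locus (default 10).
#' @return data.frame with one row per locus: `locus_id`, `n`, `u_hat`,
#'   `se`, `p_value`, `pve`, `suggestive`, `degenerate`.
#' @export
assoc_scan <- function(spec, mat, mode = c("p3d", "exact"), vc = NULL,
                       alpha = 5e-4, min_n = 10L) {
  stopifnot(inherits(spec, "mixed_model_spec"),
            inherits(mat, "dosage_matrix"))
  mode <- match.arg(mode)
  idx <- match(spec$sample_ids, mat$samples)
  if (anyNA(idx))
    stop("dosage matrix is missing samples: ",
         paste(utils::head(spec$sample_ids[is.na(idx)]), collapse = ", "))
  D <- mat$dosage[, idx, drop = FALSE]
  n <- length(spec$y)
  if (mode == "p3d" && is.null(vc)) vc <- reml_fit(spec)
  if (mode == "p3d") {
    w_full <- vc$sigma_a2 * vc$eigen_values + vc$sigma_e2
    U <- vc$eigen_vectors
    rY_full <- drop(crossprod(U, spec$y))
    rX_full <- crossprod(U, spec$X)
    V_full <- NULL
  }
  res <- vector("list", nrow(D))
  for (i in seq_len(nrow(D))) {
    s <- D[i, ]
    obs <- which(!is.na(s))
    rec <- data.frame(locus_id = mat$loci$locus_id[i], n = length(obs),
                      u_hat = NA_real_, se = NA_real_, p_value = NA_real_,
                      pve = NA_real_, suggestive = FALSE, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    if (length(obs) >= min_n && stats::var(s[obs]) > 0) {
      if (mode == "exact") {
        sub <- mixed_model_spec(spec$y[obs],
                                cbind(spec$X[obs, , drop = FALSE],
                                      dose = s[obs]),
                                spec$G[obs, obs, drop = FALSE],
                                spec$sample_ids[obs])
        vc_i <- reml_fit(sub)
        w <- vc_i$sigma_a2 * vc_i$eigen_values + vc_i$sigma_e2
        U_i <- vc_i$eigen_vectors
        wt <- gls_wald_rotated(drop(crossprod(U_i, spec$y[obs])),
                               crossprod(U_i, cbind(spec$X[obs, , drop = FALSE],
                                                    dose = s[obs])), w)
      } else if (length(obs) == n) {
        wt <- gls_wald_rotated(rY_full,
                               cbind(rX_full, dose = drop(crossprod(U, s))),
                               w_full)
      } else {
        if (is.null(V_full))
          V_full <- vc$sigma_a2 * spec$G + diag(vc$sigma_e2, n)
        Vs <- V_full[obs, obs, drop = FALSE]
        L <- chol(Vs)
        # whiten: solve(t(L), .) gives V^{-1/2}-weighted data, weights 1
        rY <- backsolve(L, spec$y[obs], transpose = TRUE)
        rC <- backsolve(L, cbind(spec$X[obs, , drop = FALSE],
                                 dose = s[obs]), transpose = TRUE)
        wt <- gls_wald_rotated(rY, rC, rep(1, length(obs)))
      }
      rec$u_hat <- wt$u_hat
      rec$se <- wt$se
      rec$p_value <- wt$p
      rec$pve <- pve(wt$u_hat, s[obs], spec$y[obs])
      rec$suggestive <- !is.na(wt$p) && wt$p < alpha
      rec$degenerate <- FALSE
    }
    res[[i]] <- rec
  }
  out <- do.call(rbind, res)
  attr(out, "mode") <- mode
  attr(out, "pve_formula") <- "u_hat^2 * var(dosage) / var(y)"
  if (mode == "p3d") attr(out, "varcomp") <-
    vc[c("sigma_a2", "sigma_e2", "h2", "loglik")]
  out
}

#' Phenotypic variance explained by one marker
#'
#' `PVE = u_hat^2 * Var(dosage) / Var(y)`, clipped to `[0, 1]`.
#'
#' @param u_hat estimated dosage effect.
#' @param dosage_values dosage vector of the tested individuals.
#' @param y phenotype vector of the tested individuals.
#' @return PVE fraction.
#' @export
pve <- function(u_hat, dosage_values, y) {
  vy <- stats::var(y)
  if (is.na(vy) || vy == 0) stop("phenotype variance is zero")
  vs <- stats::var(dosage_values)
  if (is.na(vs) || vs == 0) stop("dosage variance is zero")
  min(max(u_hat^2 * vs / vy, 0), 1)
}

#' Genomic inflation factor at the median
#'
#' @param p_values vector of association p-values.
#' @return lambda: median chi-square quantile ratio.
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  stats::qchisq(stats::median(p), df = 1, lower.tail = FALSE) /
    stats::qchisq(0.5, df = 1)
}
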