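## Henderson mixed-model equations for the repeatability animal model, in
## variance-ratio form: the coefficient matrix is
##   [ X'X       X'Z            X'W          ]
##   [ Z'X   Z'Z + Kinv*k_a     Z'W          ]
##   [ W'X       W'Z        W'W + I*k_pe     ]
## with k_a = sigma_e2/sigma_a2, k_pe = sigma_e2/sigma_pe2 and Kinv the
## relationship inverse (A-inverse or H-inverse). The inverse of this matrix
## times sigma_e2 is the prediction error (co)variance of the solutions.

#' Variance components container
#'
#' @param sigma_a2 additive genetic variance.
#' @param sigma_pe2 permanent-environment variance.
#' @param sigma_e2 residual variance.
#' @param se optional named vector of standard errors.
#' @return object of class `variance_components`, with derived `sigma_p2`,
#'   `h2` and `repeatability`.
#' @export
variance_components <- function(sigma_a2, sigma_pe2, sigma_e2, se = NULL) {
  assert_that(sigma_a2 >= 0 && sigma_pe2 >= 0 && sigma_e2 > 0,
              "variances must be non-negative (residual strictly positive)")
  sp <- sigma_a2 + sigma_pe2 + sigma_e2
  structure(list(sigma_a2 = sigma_a2, sigma_pe2 = sigma_pe2,
                 sigma_e2 = sigma_e2, sigma_p2 = sp,
                 h2 = sigma_a2 / sp,
                 repeatability = (sigma_a2 + sigma_pe2) / sp,
                 se = se), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma_a2 = %.4g, sigma_pe2 = %.4g, sigma_e2 = %.4g\n",
              x$sigma_a2, x$sigma_pe2, x$sigma_e2))
  s <- summarize_components(x)
  cat(sprintf("h2 = %.2f, repeatability = %.2f\n", s$h2, s$repeatability))
  invisible(x)
}

## assemble the ratio-form coefficient matrix and rhs
mme_system <- function(design, rel_inv, vc) {
  assert_that(vc$sigma_a2 > 0 && vc$sigma_pe2 > 0,
              "solve_mme needs strictly positive variance components")
  k_a <- vc$sigma_e2 / vc$sigma_a2
  k_pe <- vc$sigma_e2 / vc$sigma_pe2
  T <- cbind(design$X, design$Za, design$W)
  M <- Matrix::crossprod(T)
  p <- design$p; qa <- ncol(design$Za); qt <- ncol(design$W)
  ia <- p + seq_len(qa); it <- p + qa + seq_len(qt)
  Kinv <- rel_inv
  assert_that(nrow(Kinv) == qa, "relationship inverse dimension (", nrow(Kinv),
              ") != number of pedigree animals (", qa, ")",
              class = "ssblup_shape")
  ## block-diagonal addition (subassignment of large sparse blocks is slow)
  add <- Matrix::bdiag(Matrix::Matrix(0, p, p, sparse = TRUE),
                       k_a * Kinv, k_pe * Matrix::Diagonal(qt))
  M <- M + add
  rhs <- as.numeric(Matrix::crossprod(T, design$y))
  list(M = Matrix::forceSymmetric(M), rhs = rhs, T = T,
       idx_fixed = seq_len(p), idx_a = ia, idx_t = it)
}

mme_factor <- function(M) {
  tryCatch(Matrix::Cholesky(M, LDL = FALSE, perm = TRUE, super = TRUE),
           error = function(e)
             stop_ssblup("mixed model equations are singular after ",
                         "constraints: ", conditionMessage(e),
                         class = "ssblup_rank"))
}

## diagonal entries of M^-1 for the requested equation indices, in chunks
mme_inverse_diag <- function(ch, eq_idx, ncol_M, block = 1024L) {
  out <- numeric(length(eq_idx))
  for (start in seq(1L, length(eq_idx), by = block)) {
    cols <- start:min(start + block - 1L, length(eq_idx))
    E <- Matrix::sparseMatrix(i = eq_idx[cols], j = seq_along(cols), x = 1,
                              dims = c(ncol_M, length(cols)))
    Xc <- as.matrix(Matrix::solve(ch, E, system = "A"))
    out[cols] <- Xc[cbind(eq_idx[cols], seq_along(cols))]
  }
  out
}

#' Solve the mixed model equations
#'
#' Assembles and solves Henderson's equations for given variance components,
#' returning fixed-effect solutions, breeding values for every pedigree
#' animal, permanent-environment solutions, and (optionally) prediction
#' error variances.
#'
#' @param design output of [build_design()].
#' @param rel_inv relationship inverse over all pedigree animals
#'   ([a_inverse()] or [h_inverse()]).
#' @param vc a [variance_components()].
#' @param pev_for animal ids for which to return PEV (`NULL` = none,
#'   `"all"` = every pedigree animal).
#' @return list with `b`, `a`, `t` (named solution vectors), `pev` (named,
#'   for `pev_for`), `fitted`, `residuals` and the residual norm of the
#'   solved system.
#' @export
solve_mme <- function(design, rel_inv, vc, pev_for = NULL) {
  sys <- mme_system(design, rel_inv, vc)
  ch <- mme_factor(sys$M)
  sol <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
  b <- setNames(sol[sys$idx_fixed], colnames(design$X))
  a <- setNames(sol[sys$idx_a], design$animal_ids)
  t_ <- setNames(sol[sys$idx_t], design$pe_ids)
  fit <- as.numeric(sys$T %*% sol)
  pev <- NULL
  if (!is.null(pev_for)) {
    ids <- if (identical(pev_for, "all")) design$animal_ids else as.character(pev_for)
    eq <- sys$idx_a[match(ids, design$animal_ids)]
    assert_that(!anyNA(eq), "pev_for contains unknown animal ids",
                class = "ssblup_index")
    pev <- setNames(mme_inverse_diag(ch, eq, ncol(sys$M)) * vc$sigma_e2, ids)
  }
  resid_norm <- sqrt(sum((as.numeric(sys$M %*% sol) - sys$rhs)^2)) /
    max(1, sqrt(sum(sys$rhs^2)))
  list(b = b, a = a, t = t_, pev = pev,
       fitted = fit, residuals = design$y - fit,
       resid_norm = resid_norm, vc = vc)
}
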