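## Bivariate repeatability animal model on the covariance scale:
##   y_t = X b_t + Z a_t + W t_t + e_t,  t = 1,2
## with var(a) = G0 (x) A, var(pe) = P0 (x) I, var(e) = R0 (x) I over
## complete two-trait records. Equations are ordered trait-major:
## [b1 a1 t1 | b2 a2 t2]. The coefficient matrix on this scale is
## kron(R0^-1, T'T) + scatter(G0^-1 (x) Ainv) + scatter(P0^-1 (x) I),
## and its inverse is directly the prediction error covariance.

biv_design <- function(records, traits, ped,
                       fixed = intersect(c("farm_year_month", "parity"),
                                         names(records))) {
  assert_that(length(traits) == 2, "exactly two traits required")
  cc <- !is.na(records[[traits[1]]]) & !is.na(records[[traits[2]]])
  recs <- records[cc, , drop = FALSE]
  des <- build_design(recs, traits[1], ped, fixed = fixed)
  des$y2 <- as.numeric(recs[[traits[2]]])
  des$traits <- traits
  des
}

biv_system <- function(des, rel_inv, G0, P0, R0) {
  T <- cbind(des$X, des$Za, des$W)
  TtT <- Matrix::crossprod(T)
  p <- des$p; qa <- ncol(des$Za); qt <- ncol(des$W)
  m <- p + qa + qt
  R0i <- solve(R0); G0i <- solve(G0); P0i <- solve(P0)
  C <- Matrix::kronecker(Matrix::Matrix(R0i), TtT)
  idx_a <- c(p + seq_len(qa), m + p + seq_len(qa))
  idx_t <- c(p + qa + seq_len(qt), m + p + qa + seq_len(qt))
  Gadd <- Matrix::kronecker(Matrix::Matrix(G0i), rel_inv)
  tri <- Matrix::mat2triplet(as(as(Gadd, "CsparseMatrix"), "generalMatrix"))
  C <- C + Matrix::sparseMatrix(i = idx_a[tri$i], j = idx_a[tri$j], x = tri$x,
                                dims = c(2 * m, 2 * m))
  pe_tri <- list(i = c(seq_len(qt), seq_len(qt), qt + seq_len(qt), qt + seq_len(qt)),
                 j = c(seq_len(qt), qt + seq_len(qt), seq_len(qt), qt + seq_len(qt)),
                 x = c(rep(P0i[1, 1], qt), rep(P0i[1, 2], qt),
                       rep(P0i[2, 1], qt), rep(P0i[2, 2], qt)))
  C <- C + Matrix::sparseMatrix(i = idx_t[pe_tri$i], j = idx_t[pe_tri$j],
                                x = pe_tri$x, dims = c(2 * m, 2 * m))
  Y <- cbind(des$y, des$y2)
  Ry <- Y %*% R0i                      ## n x 2, columns R^-1-weighted data
  rhs <- c(as.numeric(Matrix::crossprod(T, Ry[, 1])),
           as.numeric(Matrix::crossprod(T, Ry[, 2])))
  list(M = Matrix::forceSymmetric(C), rhs = rhs, T = T, TtT = TtT,
       m = m, p = p, qa = qa, qt = qt,
       idx_b = c(seq_len(p), m + seq_len(p)),
       idx_a1 = p + seq_len(qa), idx_a2 = m + p + seq_len(qa),
       idx_t1 = p + qa + seq_len(qt), idx_t2 = m + p + qa + seq_len(qt),
       Y = Y, R0 = R0, G0 = G0, P0 = P0)
}

biv_solve <- function(sys) {
  ch <- mme_factor(sys$M)
  sol <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
  list(ch = ch, sol = sol)
}

## residuals per trait (n x 2)
biv_residuals <- function(sys, des, sol) {
  m <- sys$m
  fit1 <- as.numeric(sys$T %*% sol[seq_len(m)])
  fit2 <- as.numeric(sys$T %*% sol[m + seq_len(m)])
  sys$Y - cbind(fit1, fit2)
}

biv_m2ll <- function(sys, des, sol, log_det_K, ch) {
  n <- des$n; p <- des$p
  E <- biv_residuals(sys, des, sol)
  R0i <- solve(sys$R0)
  ypy <- sum((sys$Y %*% R0i) * sys$Y) - sum(sol * sys$rhs)
  ldM <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  as.numeric(ldM) + n * as.numeric(determinant(sys$R0)$modulus) +
    sys$qa * as.numeric(determinant(sys$G0)$modulus) + 2 * log_det_K +
    sys$qt * as.numeric(determinant(sys$P0)$modulus) + ypy
}

## full dense inverse of the coefficient matrix, computed in column blocks
chunked_inverse <- function(ch, nM, block = 2048L) {
  out <- matrix(0, nM, nM)
  for (start in seq(1L, nM, by = block)) {
    cols <- start:min(start + block - 1L, nM)
    E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(nM, length(cols)))
    out[, cols] <- as.matrix(Matrix::solve(ch, E, system = "A"))
  }
  out
}

## EM updates of (G0, P0, R0) from solutions and the dense C-inverse
biv_em_update <- function(sys, des, sol, Cinv, rel_inv) {
  qa <- sys$qa; qt <- sys$qt; n <- des$n
  a1 <- sol[sys$idx_a1]; a2 <- sol[sys$idx_a2]
  t1 <- sol[sys$idx_t1]; t2 <- sol[sys$idx_t2]
  Ka1 <- as.numeric(rel_inv %*% a1); Ka2 <- as.numeric(rel_inv %*% a2)
  K <- as(rel_inv, "CsparseMatrix")
  trK <- function(I, J) sum(K * Cinv[I, J])
  G0n <- matrix(c(sum(a1 * Ka1) + trK(sys$idx_a1, sys$idx_a1),
                  sum(a1 * Ka2) + trK(sys$idx_a1, sys$idx_a2),
                  sum(a1 * Ka2) + trK(sys$idx_a1, sys$idx_a2),
                  sum(a2 * Ka2) + trK(sys$idx_a2, sys$idx_a2)), 2, 2) / qa
  trI <- function(I, J) sum(Cinv[cbind(I, J)])
  P0n <- matrix(c(sum(t1 * t1) + trI(sys$idx_t1, sys$idx_t1),
                  sum(t1 * t2) + trI(sys$idx_t1, sys$idx_t2),
                  sum(t1 * t2) + trI(sys$idx_t1, sys$idx_t2),
                  sum(t2 * t2) + trI(sys$idx_t2, sys$idx_t2)), 2, 2) / qt
  ## residual: R0_new = (E'E + sum_r Theta_r Cinv Theta_r') / n
  E <- biv_residuals(sys, des, sol)
  Tmat <- sys$T
  ## trace part via indexed lookups: rows of T have few nonzeros
  Tg <- as(Tmat, "TsparseMatrix")
  ord <- order(Tg@i)
  ri <- Tg@i[ord] + 1L; ci <- Tg@j[ord] + 1L; xv <- Tg@x[ord]
  ## per record, list of (column, value) pairs; identical for both traits,
  ## only the equation offset differs
  split_idx <- split(seq_along(ri), ri)
  tr11 <- tr12 <- tr22 <- 0
  m <- sys$m
  for (r in seq_along(split_idx)) {
    ii <- split_idx[[r]]
    cols <- ci[ii]; vals <- xv[ii]
    c1 <- cols; c2 <- m + cols
    B11 <- Cinv[c1, c1, drop = FALSE]
    B12 <- Cinv[c1, c2, drop = FALSE]
    B22 <- Cinv[c2, c2, drop = FALSE]
    tr11 <- tr11 + as.numeric(vals %*% B11 %*% vals)
    tr12 <- tr12 + as.numeric(vals %*% B12 %*% vals)
    tr22 <- tr22 + as.numeric(vals %*% B22 %*% vals)
  }
  R0n <- (crossprod(E) + matrix(c(tr11, tr12, tr12, tr22), 2, 2)) / n
  list(G0 = G0n, P0 = P0n, R0 = R0n)
}

## scores for theta = vech-order (G0_11, G0_12, G0_22, P0_.., R0_..)
## via the EM-gradient relation dl/dG0 = (q/2) G0i (G0_EM - G0) G0i, with
## off-diagonal parameters picking up the factor 2.
biv_scores <- function(sys, des, upd) {
  sc_block <- function(M, Mn, q) {
    Mi <- solve(M)
    D <- (q / 2) * Mi %*% (Mn - M) %*% Mi
    c(D[1, 1], 2 * D[1, 2], D[2, 2])
  }
  c(sc_block(sys$G0, upd$G0, sys$qa),
    sc_block(sys$P0, upd$P0, sys$qt),
    sc_block(sys$R0, upd$R0, des$n))
}

## average-information matrix for the nine covariance parameters
biv_ai_matrix <- function(sys, des, sol, ch) {
  m <- sys$m; n <- des$n
  R0i <- solve(sys$R0); G0i <- solve(sys$G0); P0i <- solve(sys$P0)
  E <- biv_residuals(sys, des, sol)
  Py <- E %*% R0i                      ## n x 2 (trait columns)
  a <- cbind(sol[sys$idx_a1], sol[sys$idx_a2])
  t_ <- cbind(sol[sys$idx_t1], sol[sys$idx_t2])
  basis <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 1, 0), 2),
                matrix(c(0, 0, 0, 1), 2))
  Za <- des$Za; W <- des$W
  fs <- vector("list", 9L)
  for (k in 1:3) {
    mfac <- a %*% t(basis[[k]] %*% G0i)        ## qa x 2
    fs[[k]] <- cbind(as.numeric(Za %*% mfac[, 1]), as.numeric(Za %*% mfac[, 2]))
    tfac <- t_ %*% t(basis[[k]] %*% P0i)
    fs[[3 + k]] <- cbind(as.numeric(W %*% tfac[, 1]), as.numeric(W %*% tfac[, 2]))
    fs[[6 + k]] <- Py %*% t(basis[[k]])
  }
  ## P f = R^-1 (f - T s_f); stack both trait columns per parameter
  AI <- matrix(0, 9, 9)
  Pf <- vector("list", 9L)
  for (k in 1:9) {
    f <- fs[[k]]
    Rf <- f %*% R0i
    rhs_f <- c(as.numeric(Matrix::crossprod(sys$T, Rf[, 1])),
               as.numeric(Matrix::crossprod(sys$T, Rf[, 2])))
    s_f <- as.numeric(Matrix::solve(ch, rhs_f, system = "A"))
    fit <- cbind(as.numeric(sys$T %*% s_f[seq_len(m)]),
                 as.numeric(sys$T %*% s_f[m + seq_len(m)]))
    Pf[[k]] <- (f - fit) %*% R0i
  }
  for (i in 1:9) for (j in i:9) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fs[[i]] * Pf[[j]])
  }
  AI
}

psd_check <- function(M, eps = 1e-10) {
  all(is.finite(M)) && min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >
    eps * max(1, max(abs(M)))
}

theta_to_mats <- function(th) {
  list(G0 = matrix(th[c(1, 2, 2, 3)], 2), P0 = matrix(th[c(4, 5, 5, 6)], 2),
       R0 = matrix(th[c(7, 8, 8, 9)], 2))
}
mats_to_theta <- function(G0, P0, R0) {
  c(G0[1, 1], G0[1, 2], G0[2, 2], P0[1, 1], P0[1, 2], P0[2, 2],
    R0[1, 1], R0[1, 2], R0[2, 2])
}

#' Bivariate REML and the genetic correlation between two traits
#'
#' Fits the two-trait repeatability animal model with unstructured 2x2
#' genetic, permanent-environment and residual covariance matrices by
#' EM-REML with average-information acceleration (AI steps are used when
#' they keep the covariance matrices positive definite and do not decrease
#' the restricted likelihood). Only records with both traits observed enter
#' the analysis. The genetic correlation is
#' `r_g = cov_a / sqrt(var_a1 * var_a2)`; its standard error comes from the
#' delta method on the inverse AI matrix.
#'
#' @param records data frame with `animal`, fixed-effect columns, and both
#'   trait columns.
#' @param traits character vector of the two trait column names.
#' @param ped a [pedigree()].
#' @param rel_inv relationship inverse (defaults to [a_inverse()] of `ped`).
#' @param fixed fixed-effect columns.
#' @param start optional list with `G0`, `P0`, `R0` start matrices.
#' @param max_iter,tol iteration control (relative parameter change).
#' @return object of class `genetic_correlation`: list with `r_g`, `se`,
#'   `class` (magnitude label), `G0`, `P0`, `R0`, `converged`, `iterations`,
#'   `trace` and `cov_theta`.
#' @export
genetic_correlation <- function(records, traits, ped, rel_inv = NULL,
                                fixed = intersect(c("farm_year_month", "parity"),
                                                  names(records)),
                                start = NULL, max_iter = 100L, tol = 1e-5) {
  if (is.null(rel_inv)) rel_inv <- a_inverse(ped)
  des <- biv_design(records, traits, ped, fixed = fixed)
  log_det_K <- attr(rel_inv, "log_det_A") %||%
    -as.numeric(Matrix::determinant(Matrix::forceSymmetric(rel_inv),
                                    logarithm = TRUE)$modulus)
  Sp <- stats::cov(cbind(des$y, des$y2))
  if (is.null(start))
    start <- list(G0 = 0.1 * Sp, P0 = 0.1 * Sp, R0 = 0.8 * Sp)
  G0 <- start$G0; P0 <- start$P0; R0 <- start$R0
  theta <- mats_to_theta(G0, P0, R0)

  eval_state <- function(G0, P0, R0) {
    sys <- biv_system(des, rel_inv, G0, P0, R0)
    sv <- biv_solve(sys)
    m2 <- biv_m2ll(sys, des, sv$sol, log_det_K, sv$ch)
    list(sys = sys, ch = sv$ch, sol = sv$sol, m2ll = m2)
  }

  st <- eval_state(G0, P0, R0)
  trace <- data.frame(iter = 0L, m2ll = st$m2ll, step = "start",
                      rg = G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2]))
  converged <- FALSE
  flagged_psd <- FALSE
  for (iter in seq_len(max_iter)) {
    Cinv <- chunked_inverse(st$ch, length(st$sol))
    upd <- biv_em_update(st$sys, des, st$sol, Cinv, rel_inv)
    rm(Cinv)
    step_kind <- "em"
    prop <- upd
    if (iter > 1L) {
      AI <- biv_ai_matrix(st$sys, des, st$sol, st$ch)
      sc <- biv_scores(st$sys, des, upd)
      dth <- try(solve(AI, sc), silent = TRUE)
      if (!inherits(dth, "try-error")) {
        ## step-halve the AI direction until it stays PSD and improves
        for (stp in c(1, 0.5, 0.25)) {
          mats <- theta_to_mats(theta + stp * dth)
          if (!(psd_check(mats$G0) && psd_check(mats$P0) && psd_check(mats$R0)))
            next
          st_ai <- try(eval_state(mats$G0, mats$P0, mats$R0), silent = TRUE)
          if (!inherits(st_ai, "try-error") && st_ai$m2ll <= st$m2ll + 1e-10) {
            prop <- mats; step_kind <- "ai"; st_new <- st_ai
            break
          }
        }
      }
    }
    ## EM proposals are PSD by construction up to numerical error; project
    ## defensively and flag if a projection was needed
    for (nm in c("G0", "P0", "R0")) {
      if (!psd_check(prop[[nm]], eps = 0)) {
        eg <- eigen(prop[[nm]], symmetric = TRUE)
        prop[[nm]] <- eg$vectors %*% diag(pmax(eg$values, 1e-8)) %*% t(eg$vectors)
        flagged_psd <- TRUE
      }
    }
    if (step_kind == "em") st_new <- eval_state(prop$G0, prop$P0, prop$R0)
    theta_new <- mats_to_theta(prop$G0, prop$P0, prop$R0)
    rel_change <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-12))
    st <- st_new; theta <- theta_new
    G0 <- prop$G0; P0 <- prop$P0; R0 <- prop$R0
    trace <- rbind(trace, data.frame(iter = iter, m2ll = st$m2ll,
                                     step = step_kind,
                                     rg = G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])))
    if (rel_change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("bivariate REML did not reach tolerance in ", max_iter,
            " iterations", call. = FALSE)
  AI <- biv_ai_matrix(st$sys, des, st$sol, st$ch)
  cov_theta <- tryCatch(solve(AI), error = function(e) matrix(NA, 9, 9))
  rg <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  g <- c(-G0[1, 2] / (2 * G0[1, 1]^1.5 * sqrt(G0[2, 2])),
         1 / sqrt(G0[1, 1] * G0[2, 2]),
         -G0[1, 2] / (2 * G0[2, 2]^1.5 * sqrt(G0[1, 1])))
  se <- if (anyNA(cov_theta[1:3, 1:3])) NA_real_ else
    sqrt(max(0, as.numeric(g %*% cov_theta[1:3, 1:3] %*% g)))
  structure(list(r_g = rg, se = se,
                 class = classify_correlation(max(-1, min(1, rg))),
                 G0 = G0, P0 = P0, R0 = R0, traits = traits,
                 converged = converged, iterations = iter,
                 psd_projection = flagged_psd,
                 trace = trace, cov_theta = cov_theta),
            class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("genetic correlation %s ~ %s: %.3f (SE %.3f) [%s]\n",
              x$traits[1], x$traits[2], x$r_g, x$se, x$class))
  if (!x$converged) cat("  (REML not converged)\n")
  invisible(x)
}
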