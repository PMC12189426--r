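## EM-REML (with optional average-information acceleration) for the
## univariate repeatability animal model. Traces of the inverted coefficient
## matrix are computed exactly by solving the sparse Cholesky factor for
## blocks of unit vectors.

## traces needed by EM / AI: tr(Kinv %*% Caa) and tr(Ctt), where C = M^-1
## on the ratio scale. Computed chunk-wise to bound memory.
mme_traces <- function(ch, sys, Kinv, block = 1024L) {
  nM <- length(sys$rhs)
  ia <- sys$idx_a; it <- sys$idx_t
  KinvT <- as(Matrix::t(Kinv), "CsparseMatrix")  ## symmetric, but be explicit
  tr_K_Caa <- 0
  tr_Ctt <- 0
  eq_idx <- c(ia, it)
  col_in_a <- seq_along(ia)
  for (start in seq(1L, length(eq_idx), by = block)) {
    cols <- start:min(start + block - 1L, length(eq_idx))
    E <- Matrix::sparseMatrix(i = eq_idx[cols], j = seq_along(cols), x = 1,
                              dims = c(nM, length(cols)))
    Xc <- as.matrix(Matrix::solve(ch, E, system = "A"))
    acols <- cols[cols <= length(ia)]
    if (length(acols)) {
      ## sum_{r} Kinv[r, j] * C[ia[r], ia[j]] over this chunk of j
      sub <- Xc[ia, match(acols, cols), drop = FALSE]
      Ksub <- KinvT[, acols, drop = FALSE]
      tr_K_Caa <- tr_K_Caa + sum(Ksub * sub)
    }
    tcols <- cols[cols > length(ia)]
    if (length(tcols)) {
      j_local <- match(tcols, cols)
      tr_Ctt <- tr_Ctt + sum(Xc[cbind(eq_idx[tcols], j_local)])
    }
  }
  list(tr_K_Caa = tr_K_Caa, tr_Ctt = tr_Ctt)
}

## -2 restricted logLik (up to a constant): verified against the dense
## V-based expression in the test suite.
reml_m2ll <- function(design, vc, ch, sys, sol, log_det_K) {
  n <- design$n; p <- design$p
  qa <- length(sys$idx_a); qt <- length(sys$idx_t)
  ypy <- (sum(design$y^2) - sum(sol * sys$rhs)) / vc$sigma_e2
  ldM <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  ## log|V| + log|X'VinvX| = log|M_ratio| - (p+qa+qt) log se2 + n log se2
  ##                         + qa log sa2 + log|A| + qt log spe2
  (n - p - qa - qt) * log(vc$sigma_e2) + qa * log(vc$sigma_a2) + log_det_K +
    qt * log(vc$sigma_pe2) + as.numeric(ldM) + ypy
}

## average-information matrix for theta = (sigma_a2, sigma_pe2, sigma_e2).
## f_a = Z a_hat / sigma_a2, f_pe = W t_hat / sigma_pe2, f_e = e_hat/sigma_e2;
## AI_ij = 0.5 * f_i' P f_j with P f = (f - T s_f)/sigma_e2, s_f the MME
## solution with f as data vector.
reml_ai_matrix <- function(design, vc, ch, sys, sol) {
  ia <- sys$idx_a; it <- sys$idx_t
  ahat <- sol[ia]; that <- sol[it]
  ehat <- design$y - as.numeric(sys$T %*% sol)
  f <- cbind(as.numeric(design$Za %*% ahat) / vc$sigma_a2,
             as.numeric(design$W %*% that) / vc$sigma_pe2,
             ehat / vc$sigma_e2)
  rhs_f <- Matrix::crossprod(sys$T, f)
  s_f <- as.matrix(Matrix::solve(ch, rhs_f, system = "A"))
  Pf <- (f - as.matrix(sys$T %*% s_f)) / vc$sigma_e2
  0.5 * crossprod(f, Pf)
}

#' EM-REML variance components for the repeatability animal model
#'
#' Iterates expectation-maximisation REML updates built from the mixed-model
#' solutions and exact traces of the inverted coefficient matrix. By default
#' each iteration first tries an average-information (AI) step and falls
#' back to the plain EM update whenever the AI step would leave the
#' parameter space or decrease the restricted likelihood, so the accepted
#' likelihood sequence is non-decreasing either way.
#'
#' @param design output of [build_design()].
#' @param rel_inv relationship inverse ([a_inverse()] or [h_inverse()]);
#'   its `log_det_A` attribute, when present, enters the likelihood.
#' @param start starting [variance_components()] (default: thirds of the
#'   phenotypic variance with a smaller genetic share).
#' @param max_iter,tol iteration cap and relative-change convergence
#'   tolerance on the components.
#' @param acceleration `"ai"` (default) or `"none"`.
#' @param verbose print the trace.
#' @return a [variance_components()] with standard errors from the inverse
#'   AI matrix, plus attributes `trace` (per-iteration data frame),
#'   `converged`, `iterations` and `cov_theta`. Non-convergence warns and
#'   returns the last iterate.
#' @export
em_reml <- function(design, rel_inv, start = NULL, max_iter = 100L,
                    tol = 1e-6, acceleration = c("ai", "none"),
                    verbose = FALSE) {
  acceleration <- match.arg(acceleration)
  vy <- var(design$y)
  if (is.null(start))
    start <- variance_components(0.1 * vy, 0.1 * vy, 0.8 * vy)
  assert_that(start$sigma_a2 > 0 && start$sigma_pe2 > 0 && start$sigma_e2 > 0,
              "starting values must be strictly positive")
  log_det_K <- attr(rel_inv, "log_det_A") %||%
    -as.numeric(Matrix::determinant(Matrix::forceSymmetric(rel_inv),
                                    logarithm = TRUE)$modulus)
  qa <- ncol(design$Za); qt <- ncol(design$W)
  n <- design$n; p <- design$p
  yy <- sum(design$y^2)

  eval_state <- function(vc) {
    sys <- mme_system(design, rel_inv, vc)
    ch <- mme_factor(sys$M)
    sol <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
    m2ll <- reml_m2ll(design, vc, ch, sys, sol, log_det_K)
    list(vc = vc, sys = sys, ch = ch, sol = sol, m2ll = m2ll)
  }

  ## EM update plus the REML score vector from the same exact traces
  em_update <- function(st) {
    tr <- mme_traces(st$ch, st$sys, rel_inv)
    vc <- st$vc
    ahat <- st$sol[st$sys$idx_a]; that <- st$sol[st$sys$idx_t]
    ehat <- design$y - as.numeric(st$sys$T %*% st$sol)
    aKa <- as.numeric(ahat %*% (rel_inv %*% ahat))
    s_a <- (aKa + tr$tr_K_Caa * vc$sigma_e2) / qa
    s_t <- (sum(that^2) + tr$tr_Ctt * vc$sigma_e2) / qt
    s_e <- (yy - sum(st$sol * st$sys$rhs)) / (n - p)
    k_a <- vc$sigma_e2 / vc$sigma_a2
    k_pe <- vc$sigma_e2 / vc$sigma_pe2
    tr_P <- (n - p - qa + k_a * tr$tr_K_Caa - qt + k_pe * tr$tr_Ctt) /
      vc$sigma_e2
    score <- c(qa / (2 * vc$sigma_a2^2) * (s_a - vc$sigma_a2),
               qt / (2 * vc$sigma_pe2^2) * (s_t - vc$sigma_pe2),
               -0.5 * (tr_P - sum(ehat^2) / vc$sigma_e2^2))
    list(theta = c(s_a, s_t, s_e), score = score)
  }

  st <- eval_state(start)
  trace <- data.frame(iter = 0L, sigma_a2 = start$sigma_a2,
                      sigma_pe2 = start$sigma_pe2, sigma_e2 = start$sigma_e2,
                      m2ll = st$m2ll, step = "start")
  converged <- FALSE
  theta_prev <- c(start$sigma_a2, start$sigma_pe2, start$sigma_e2)
  for (iter in seq_len(max_iter)) {
    step_kind <- "em"
    upd <- em_update(st)
    theta_em <- upd$theta
    theta_new <- theta_em
    if (acceleration == "ai" && iter > 1L) {
      AI <- reml_ai_matrix(design, st$vc, st$ch, st$sys, st$sol)
      theta_ai <- try(theta_prev + solve(AI, upd$score), silent = TRUE)
      if (!inherits(theta_ai, "try-error")) {
        ## clamp at a tiny positive floor so AI can reach the boundary
        theta_ai <- pmax(theta_ai, 1e-8 * sum(theta_prev))
        st_ai <- try(eval_state(variance_components(theta_ai[1], theta_ai[2],
                                                    theta_ai[3])), silent = TRUE)
        if (!inherits(st_ai, "try-error") && st_ai$m2ll <= st$m2ll + 1e-10) {
          theta_new <- theta_ai
          step_kind <- "ai"
          st_new <- st_ai
        }
      }
    }
    ## floor tiny components to stay inside the parameter space
    theta_new <- pmax(theta_new, 1e-12 * sum(theta_new))
    if (step_kind == "em")
      st_new <- eval_state(variance_components(theta_new[1], theta_new[2],
                                               theta_new[3]))
    rel_change <- max(abs(theta_new - theta_prev) / pmax(theta_prev, 1e-12))
    st <- st_new
    theta_prev <- theta_new
    trace <- rbind(trace, data.frame(iter = iter, sigma_a2 = theta_new[1],
                                     sigma_pe2 = theta_new[2],
                                     sigma_e2 = theta_new[3],
                                     m2ll = st$m2ll, step = step_kind))
    if (verbose)
      message(sprintf("iter %3d [%s] sa2=%.5g spe2=%.5g se2=%.5g -2ll=%.6f",
                      iter, step_kind, theta_new[1], theta_new[2],
                      theta_new[3], st$m2ll))
    if (rel_change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("em_reml did not reach tolerance ", tol, " in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)

  AI <- reml_ai_matrix(design, st$vc, st$ch, st$sys, st$sol)
  cov_theta <- tryCatch(solve(AI), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(cov_theta), 0))
  names(se) <- c("sigma_a2", "sigma_pe2", "sigma_e2")
  out <- variance_components(theta_prev[1], theta_prev[2], theta_prev[3], se = se)
  attr(out, "trace") <- trace
  attr(out, "converged") <- converged
  attr(out, "iterations") <- nrow(trace) - 1L
  attr(out, "cov_theta") <- cov_theta
  attr(out, "m2ll") <- st$m2ll
  out
}

#' Heritability and repeatability from variance components
#'
#' `h2 = sigma_a2 / sigma_p2` and `repeatability = (sigma_a2 + sigma_pe2) /
#' sigma_p2`, with `sigma_p2` the sum of the three components. Reported
#' values are rounded to two decimals; full precision is kept in the
#' `unrounded` element. Standard errors, when the component covariance is
#' available, come from the delta method.
#'
#' @param vc a [variance_components()] (or three numbers).
#' @param digits rounding for the reported values.
#' @return list with `h2`, `repeatability`, `unrounded`, and `se` when
#'   available.
#' @export
summarize_components <- function(vc, digits = 2L) {
  if (!inherits(vc, "variance_components"))
    vc <- variance_components(vc[[1]], vc[[2]], vc[[3]])
  sp <- vc$sigma_p2
  assert_that(sp > 0, "phenotypic variance is zero; ratios undefined",
              class = "ssblup_domain")
  h2 <- vc$sigma_a2 / sp
  re <- (vc$sigma_a2 + vc$sigma_pe2) / sp
  se <- NULL
  ct <- attr(vc, "cov_theta")
  if (!is.null(ct) && !anyNA(ct)) {
    gh <- c((sp - vc$sigma_a2) / sp^2, -vc$sigma_a2 / sp^2, -vc$sigma_a2 / sp^2)
    num <- vc$sigma_a2 + vc$sigma_pe2
    gr <- c((sp - num) / sp^2, (sp - num) / sp^2, -num / sp^2)
    se <- c(h2 = sqrt(max(0, gh %*% ct %*% gh)),
            repeatability = sqrt(max(0, gr %*% ct %*% gr)))
  }
  list(h2 = round(h2, digits), repeatability = round(re, digits),
       unrounded = c(h2 = h2, repeatability = re), se = se)
}

#' Classify the magnitude of a genetic correlation
#'
#' Bands: very high `|r| >= 0.80`; high `0.40 <= |r| < 0.80`; low
#' `0.2 < |r| < 0.40`; very low `|r| <= 0.2`. The boundary values 0.2 and
#' 0.40 are assigned to "very low" and "high" respectively (documented
#' closed ends).
#'
#' @param r correlation in `[-1, 1]`.
#' @return character label.
#' @export
classify_correlation <- function(r) {
  assert_that(all(abs(r) <= 1), "correlation outside [-1, 1]",
              class = "ssblup_domain")
  a <- abs(r)
  out <- character(length(a))
  out[a >= 0.80] <- "very high"
  out[a >= 0.40 & a < 0.80] <- "high"
  out[a > 0.2 & a < 0.40] <- "low"
  out[a <= 0.2] <- "very low"
  out
}
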