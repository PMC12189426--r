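test_that("design matrices have the documented incidence structure", {
  ped <- pedigree(c("s", "a1", "a2"), c(NA, "s", "s"), c(NA, NA, NA))
  recs <- data.frame(animal = c("a1", "a1", "a1", "a2"),
                     parity = c(1, 2, 3, 1),
                     farm_year_month = c("f1", "f1", "f2", "f1"),
                     y = c(10, 11, 12, 9))
  des <- build_design(recs, "y", ped)
  expect_equal(dim(des$Za), c(4L, 3L))          ## all pedigree animals
  expect_equal(dim(des$W), c(4L, 2L))           ## only sows with records
  expect_true(all(Matrix::rowSums(des$Za) == 1))
  expect_true(all(Matrix::rowSums(des$W) == 1))
  ## sow a1's three parities share one W column
  expect_equal(sum(des$W[, "a1"]), 3)
  ## single record, single level
  des1 <- build_design(data.frame(animal = "a1", y = 5), "y", ped, fixed = character(0))
  expect_equal(as.matrix(des1$X), matrix(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sum(des1$Za[1, ] != 0), 1L)
  expect_error(build_design(data.frame(animal = "zz", y = 1), "y", ped,
                            fixed = character(0)), class = "ssblup_lookup")
  ## deterministic level order regardless of record order
  des2 <- build_design(recs[c(4, 3, 2, 1), ], "y", ped)
  expect_equal(colnames(des2$X), colnames(des$X))
})

test_that("MME solutions match a dense generic solver", {
  hs <- halfsib_records(n_sires = 4, n_dtrs = 12, seed = 31)
  des <- build_design(hs$records, "y", hs$ped)
  Ainv <- a_inverse(hs$ped)
  vc <- variance_components(1.5, 1.0, 7)
  fit <- solve_mme(des, Ainv, vc, pev_for = "all")
  ## dense assembly oracle
  T <- as.matrix(cbind(des$X, des$Za, des$W))
  ka <- vc$sigma_e2 / vc$sigma_a2; kpe <- vc$sigma_e2 / vc$sigma_pe2
  M <- crossprod(T)
  ia <- des$p + seq_len(ncol(des$Za))
  it <- des$p + ncol(des$Za) + seq_len(ncol(des$W))
  M[ia, ia] <- M[ia, ia] + ka * as.matrix(Ainv)
  M[it, it] <- M[it, it] + kpe * diag(length(it))
  sol <- solve(M, crossprod(T, des$y))
  expect_equal(unname(fit$b), sol[seq_len(des$p)], tolerance = 1e-8)
  expect_equal(unname(fit$a), sol[ia], tolerance = 1e-8)
  expect_equal(unname(fit$t), sol[it], tolerance = 1e-8)
  expect_equal(unname(fit$pev), unname(diag(solve(M))[ia]) * vc$sigma_e2,
               tolerance = 1e-8)
  expect_lt(fit$resid_norm, 1e-10)
})

test_that("breeding values vanish in the infinite-shrinkage limit", {
  hs <- halfsib_records(n_sires = 3, n_dtrs = 10, seed = 32)
  des <- build_design(hs$records, "y", hs$ped)
  Ainv <- a_inverse(hs$ped)
  fit <- solve_mme(des, Ainv, variance_components(1e-8, 1.0, 7))
  expect_lt(max(abs(fit$a)), 1e-5)
})

test_that("unrelated sows with identity A match the closed-form shrinkage", {
  set.seed(33)
  n <- 40; r <- 4
  ped <- pedigree(as.character(1:n), rep(NA, n), rep(NA, n))
  sa <- 2; spe <- 1; se <- 6
  recs <- data.frame(animal = rep(as.character(1:n), each = r),
                     y = rnorm(n * r, 20, 3))
  des <- build_design(recs, "y", ped, fixed = character(0))
  fit <- solve_mme(des, a_inverse(ped), variance_components(sa, spe, se))
  ## balanced case: mu = grand mean; combined sow effect shrunk by
  ## r*sv/(r*sv+se), split a:t as sa:spe
  ybar <- tapply(recs$y, recs$animal, mean)[as.character(1:n)]
  sv <- sa + spe
  vhat <- (r * sv / (r * sv + se)) * (ybar - mean(recs$y))
  expect_equal(unname(fit$b), mean(recs$y), tolerance = 1e-8)
  expect_equal(unname(fit$a), as.numeric(vhat * sa / sv), tolerance = 1e-8)
  expect_equal(unname(fit$t), as.numeric(vhat * spe / sv), tolerance = 1e-8)
})

test_that("REML logLik and trace identities agree with the dense oracle", {
  hs <- halfsib_records(n_sires = 4, n_dtrs = 14, seed = 34)
  des <- build_design(hs$records, "y", hs$ped)
  A <- a_matrix(hs$ped); Ainv <- a_inverse(hs$ped)
  dense_m2ll <- function(vc) {
    X <- as.matrix(des$X); Z <- as.matrix(des$Za); W <- as.matrix(des$W)
    V <- vc$sigma_a2 * Z %*% A %*% t(Z) + vc$sigma_pe2 * tcrossprod(W) +
      vc$sigma_e2 * diag(des$n)
    Vi <- solve(V); XVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
    as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
               t(des$y) %*% P %*% des$y)
  }
  mme_m2ll <- function(vc) {
    sys <- ssblup:::mme_system(des, Ainv, vc)
    ch <- ssblup:::mme_factor(sys$M)
    sol <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
    ssblup:::reml_m2ll(des, vc, ch, sys, sol, attr(Ainv, "log_det_A"))
  }
  v1 <- variance_components(0.8, 0.5, 5); v2 <- variance_components(1.6, 0.9, 4)
  expect_equal(mme_m2ll(v2) - mme_m2ll(v1), dense_m2ll(v2) - dense_m2ll(v1),
               tolerance = 1e-8)
  ## chunked traces equal dense inverse blocks
  sys <- ssblup:::mme_system(des, Ainv, v1)
  ch <- ssblup:::mme_factor(sys$M)
  tr <- ssblup:::mme_traces(ch, sys, Ainv, block = 7L)  ## force chunking
  Ci <- solve(as.matrix(sys$M))
  expect_equal(tr$tr_K_Caa, sum(as.matrix(Ainv) * Ci[sys$idx_a, sys$idx_a]),
               tolerance = 1e-9)
  expect_equal(tr$tr_Ctt, sum(diag(Ci)[sys$idx_t]), tolerance = 1e-9)
})

test_that("EM-REML is monotone, AI agrees with EM, SEs are finite", {
  hs <- halfsib_records(n_sires = 15, n_dtrs = 150, seed = 35)
  des <- build_design(hs$records, "y", hs$ped)
  Ainv <- a_inverse(hs$ped)
  fit_ai <- em_reml(des, Ainv, max_iter = 60, tol = 1e-6)
  tr <- attr(fit_ai, "trace")
  expect_true(all(diff(tr$m2ll) < 1e-8))  ## non-decreasing likelihood
  expect_true(attr(fit_ai, "converged"))
  expect_true(all(is.finite(fit_ai$se)))
  fit_em <- suppressWarnings(em_reml(des, Ainv, acceleration = "none",
                                     max_iter = 400, tol = 1e-6))
  expect_true(all(diff(attr(fit_em, "trace")$m2ll) < 1e-8))
  expect_equal(fit_ai$sigma_e2, fit_em$sigma_e2, tolerance = 0.02)
  expect_equal(fit_ai$sigma_a2 + fit_ai$sigma_pe2,
               fit_em$sigma_a2 + fit_em$sigma_pe2, tolerance = 0.05)
})

test_that("EM-REML reaches the boundary when there is no genetic variance", {
  set.seed(36)
  hs <- halfsib_records(n_sires = 12, n_dtrs = 120, h2 = 0, rep_ = 0.25,
                        seed = 36)
  des <- build_design(hs$records, "y", hs$ped)
  fit <- suppressWarnings(em_reml(des, a_inverse(hs$ped), max_iter = 80,
                                  tol = 1e-5))
  expect_lt(fit$sigma_a2, 0.03 * fit$sigma_p2)
})

test_that("balanced unrelated-sow data match the ANOVA moment estimates", {
  set.seed(37)
  n <- 120; r <- 4
  ped <- pedigree(as.character(1:n), rep(NA, n), rep(NA, n))
  sow_eff <- rnorm(n, 0, sqrt(3))
  recs <- data.frame(animal = rep(as.character(1:n), each = r),
                     y = 15 + rep(sow_eff, each = r) + rnorm(n * r, 0, sqrt(6)))
  des <- build_design(recs, "y", ped, fixed = character(0))
  fit <- suppressWarnings(em_reml(des, a_inverse(ped), max_iter = 200, tol = 1e-7))
  msb <- summary(stats::aov(y ~ animal, data = recs))[[1]]["animal", "Mean Sq"]
  msw <- summary(stats::aov(y ~ animal, data = recs))[[1]]["Residuals", "Mean Sq"]
  sigma_between <- (msb - msw) / r
  ## with unrelated sows only sa+spe is identifiable; compare the sum
  expect_equal(fit$sigma_a2 + fit$sigma_pe2, sigma_between, tolerance = 0.02)
  expect_equal(fit$sigma_e2, msw, tolerance = 0.02)
})

test_that("heritability and repeatability reproduce the reported arithmetic", {
  ## TNB-like variance components
  s1 <- summarize_components(variance_components(0.69, 0.90, 9.70))
  expect_equal(s1$h2, 0.06)
  expect_equal(s1$repeatability, 0.14)
  ## LBWT-like
  s2 <- summarize_components(variance_components(0.81, 1.34, 13.38))
  expect_equal(s2$h2, 0.05)
  expect_equal(s2$repeatability, 0.14)
  ## degenerate: no animal variance at all
  s3 <- summarize_components(variance_components(0, 0, 1))
  expect_equal(s3$h2, 0)
  expect_equal(s3$repeatability, 0)
})

test_that("correlation magnitude classes follow the documented bands", {
  expect_equal(classify_correlation(0.90), "very high")
  expect_equal(classify_correlation(-0.78), "high")
  expect_equal(classify_correlation(0), "very low")
  ## documented boundary handling
  expect_equal(classify_correlation(0.2), "very low")
  expect_equal(classify_correlation(0.40), "high")
  expect_equal(classify_correlation(-0.40), "high")
  expect_equal(classify_correlation(0.8), "very high")
  expect_error(classify_correlation(1.2), class = "ssblup_domain")
})
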