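test_that("QC removes the constructed offender for every criterion", {
  ## 100 animals x 6 SNPs, one SNP violating exactly one criterion each,
  ## two clean SNPs
  set.seed(7)
  n <- 100
  clean <- function() {
    x <- c(rep(0, 30), rep(1, 40), rep(2, 30))  ## p = 0.5, HWE-ish
    sample(x)
  }
  cnt <- cbind(
    clean(),                                   # keeps
    c(rep(0, n - 1), 1),                       # MAF 0.005 (also 0 hom-alt)
    rep(1, n),                                 # all het: HWE + min_hom
    c(rep(0, 30), rep(1, 40), rep(2, 30)),     # call rate 0.97 < 0.99 (below)
    clean(),                                   # keeps
    c(rep(0, 85), rep(2, 15))                  # min_hom (15 < 30) + HWE
  )
  cnt[31:33, 4] <- NA  ## heterozygote rows, so only call rate trips for s4
  rownames(cnt) <- paste0("a", 1:n)
  g <- genotype_set(cnt, data.frame(snp = paste0("s", 1:6), chrom = "1",
                                    pos = (1:6) * 1000))
  ## with only 6 SNPs one missing genotype already fails the default animal
  ## call rate; relax it so the SNP-level rules are isolated
  out <- qc_filter(g, qc_thresholds(animal_call_rate_min = 0.4))
  expect_equal(out$report$n_snps_kept, 2L)
  expect_setequal(colnames(out$genotypes$counts), c("s1", "s5"))
  expect_equal(out$report$n_fail_maf, 1L)          # s2 only
  expect_equal(out$report$n_fail_call_rate, 1L)    # s4 only
  expect_equal(out$report$n_fail_min_hom, 3L)      # s2 (no alt hom), s3, s6
  expect_equal(out$report$n_fail_hwe, 2L)          # s3, s6
  ## the all-heterozygote SNP: hand chi-square = n (all 3 classes off)
  expect_lt(pchisq(2 * n, df = 1, lower.tail = FALSE), 1e-6)
  ## rerunning QC on its own output is a no-op
  out2 <- qc_filter(out$genotypes, qc_thresholds(animal_call_rate_min = 0.4))
  expect_equal(out2$genotypes$counts, out$genotypes$counts)
  expect_equal(out2$report$n_snps_removed, 0L)
})

test_that("animals failing call rate are removed before SNP filters", {
  set.seed(8)
  cnt <- matrix(rbinom(20 * 10, 2, 0.5), 20, 10,
                dimnames = list(paste0("a", 1:20), NULL))
  cnt[1, 1:8] <- NA  ## animal call rate 0.2
  g <- genotype_set(cnt, data.frame(snp = paste0("s", 1:10), chrom = "1",
                                    pos = 1:10 * 100))
  out <- qc_filter(g, qc_thresholds(min_hom_count = 0, snp_call_rate_min = 0.9,
                                    hwe_p_min = 0))
  expect_equal(out$report$animals_removed, "a1")
  expect_false("a1" %in% rownames(out$genotypes$counts))
})

test_that("monomorphic SNPs fail MAF and everything filtered errors", {
  cnt <- matrix(0, 40, 2, dimnames = list(paste0("a", 1:40), NULL))
  g <- genotype_set(cnt, data.frame(snp = c("s1", "s2"), chrom = "1",
                                    pos = c(1, 2)))
  expect_error(qc_filter(g), class = "ssblup_all_filtered")
})

test_that("allele frequencies match hand and brute-force values", {
  mk <- function(counts) genotype_set(
    matrix(counts, ncol = length(counts) / 4,
           dimnames = list(paste0("a", 1:4), NULL)),
    data.frame(snp = paste0("s", seq_len(length(counts) / 4)), chrom = "1",
               pos = seq_len(length(counts) / 4)))
  expect_equal(unname(allele_frequencies(mk(c(0, 1, 2, 1)))), 0.5)
  expect_equal(unname(allele_frequencies(mk(c(2, 2, 2, 0)))), 0.75)
  g <- rand_geno(30, 15, seed = 9)
  expect_equal(unname(allele_frequencies(g)),
               unname(colMeans(g$counts) / 2))
  expect_error(allele_frequencies(mk(c(0, 0, 0, 0))),
               class = "ssblup_monomorphic")
})

test_that("VanRaden G matches the single-SNP hand computation", {
  cnt <- matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(paste0("a", 1:4), NULL))
  g <- genotype_set(cnt, data.frame(snp = "s1", chrom = "1", pos = 1))
  G <- vanraden_g(g, freqs = 0.5)
  expect_equal(attr(G, "lambda"), 0.5)
  z <- c(-1, 0, 1, 0)
  expect_equal(unname(G), outer(z, z) / 0.5, ignore_attr = TRUE)
  expect_equal(unname(diag(G)), c(2, 0, 2, 0))
})

test_that("G has unit mean diagonal under HWE and is bilinear in D", {
  g <- rand_geno(400, 300, seed = 10, freq_range = c(0.1, 0.9))
  G <- vanraden_g(g)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  ## doubling D doubles G* at fixed lambda
  w <- runif(300, 0.5, 2)
  G1 <- vanraden_g(g, weights = w)
  G2 <- vanraden_g(g, weights = 2 * w)
  expect_equal(unname(G2), unname(2 * G1), tolerance = 1e-12)
})

test_that("G is invariant to SNP reordering and allele-label flips", {
  g <- rand_geno(25, 40, seed = 12)
  G <- vanraden_g(g)
  ord <- sample(40)
  g2 <- genotype_set(g$counts[, ord],
                     data.frame(snp = g$map$snp[ord], chrom = "1",
                                pos = sort(g$map$pos)))
  ## columns permuted, map positions fresh: G depends only on the counts
  expect_equal(unname(vanraden_g(g2)), unname(G), tolerance = 1e-12)
  flip <- g
  flip$counts <- 2 - g$counts
  expect_equal(unname(vanraden_g(flip)), unname(G), tolerance = 1e-12)
})

test_that("blending handles degenerate inputs and inverts correctly", {
  set.seed(13)
  n <- 15
  A22 <- diag(n) + 0.1
  dimnames(A22) <- list(paste0("a", 1:n), paste0("a", 1:n))
  B <- matrix(rnorm(n * n), n); G <- crossprod(B) / n
  dimnames(G) <- dimnames(A22)
  ## blend 0 reduces to A22
  Gi0 <- blend_and_invert(G, A22, blend_g = 0, tune = FALSE)
  expect_equal(unname(Gi0 %*% A22), diag(n), tolerance = 1e-8)
  ## G = A22 is a fixed point for any blend
  Gi1 <- blend_and_invert(A22, A22, blend_g = 0.37, tune = FALSE)
  expect_equal(unname(Gi1 %*% A22), diag(n), tolerance = 1e-8)
  ## multiplication oracle at default blend
  Gi <- blend_and_invert(G, A22, blend_g = 0.95, tune = TRUE)
  Gb <- attr(Gi, "Gb")
  expect_lt(max(abs(Gi %*% Gb - diag(n))), 1e-8)
  ## tuning matches first two moments of A22
  Gt <- attr(Gi, "tune_a") + attr(Gi, "tune_b") * G
  expect_equal(mean(diag(Gt)), mean(diag(A22)), tolerance = 1e-10)
  off <- function(M) (sum(M) - sum(diag(M))) / (n * (n - 1))
  expect_equal(off(Gt), off(A22), tolerance = 1e-10)
})

test_that("H-inverse equals the dense block oracle and its degenerate cases", {
  sire <- c(NA, NA, NA, "1", "1", "2", "4", "4", "6", "6")
  dam <- c(NA, NA, NA, "3", "3", "3", "5", "5", "5", "8")
  ped <- pedigree(as.character(1:10), sire, dam)
  Ainv <- a_inverse(ped)
  gids <- c("2", "5", "7", "10")
  A22 <- a_submatrix(ped, gids)
  A22inv <- solve(A22); dimnames(A22inv) <- dimnames(A22)
  g <- rand_geno(4, 60, ids = gids, seed = 14)
  Gi <- blend_and_invert(vanraden_g(g), A22)
  Hinv <- h_inverse(Ainv, A22inv, Gi)
  oracle <- as.matrix(Ainv)
  idx <- match(gids, ped$animal)
  oracle[idx, idx] <- oracle[idx, idx] + (Gi - A22inv)
  expect_equal(as.matrix(Hinv), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## G-inverse = A22-inverse -> H-inverse = A-inverse (exact)
  expect_equal(as.matrix(h_inverse(Ainv, A22inv, A22inv)), as.matrix(Ainv),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## no genotyped animals at all
  expect_equal(as.matrix(h_inverse(Ainv, NULL, NULL)), as.matrix(Ainv))
  ## id misalignment is caught
  bad <- Gi; rownames(bad)[1] <- "unknown_animal"
  expect_error(h_inverse(Ainv, A22inv, bad), class = "ssblup_index")
})

test_that("LD r2 equals the correlation oracle and flags zero variance", {
  cnt <- cbind(c(0, 0, 2, 2), c(2, 2, 0, 0), c(1, 1, 1, 1), c(0, 1, 2, 0))
  rownames(cnt) <- paste0("a", 1:4)
  g <- genotype_set(cnt, data.frame(snp = paste0("s", 1:4), chrom = "1",
                                    pos = c(100, 200, 300, 400)))
  r2 <- ld_r2(g, "1")
  self <- r2[r2$snp1 == "s1" & r2$snp2 == "s1", "r2"]
  expect_equal(self, 1)
  expect_equal(r2[r2$snp1 == "s1" & r2$snp2 == "s2", "r2"], 1)  ## perfect LD
  expect_true(is.na(r2[r2$snp1 == "s3" & r2$snp2 == "s4", "r2"]))
  ## brute-force oracle on a random pair
  g2 <- rand_geno(50, 6, seed = 15)
  r <- ld_r2(g2, "1")
  pick <- r[r$snp1 == "s2" & r$snp2 == "s5", ]
  expect_equal(pick$r2, cor(g2$counts[, 2], g2$counts[, 5])^2)
  expect_error(ld_r2(g2, "1", from_bp = 1, to_bp = 1))
})
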