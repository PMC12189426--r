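#' Genotype container
#'
#' Holds an animals x SNPs allele-count matrix (entries 0/1/2 or `NA` for
#' missing) together with the SNP map (chromosome, 1-based bp position).
#' Positions must be strictly increasing within chromosome.
#'
#' @param counts integer/numeric matrix, rows = animals (rownames = ids),
#'   columns = SNPs.
#' @param map data frame with columns `snp`, `chrom`, `pos` (one row per
#'   column of `counts`).
#' @return object of class `genotype_set` with elements `counts` and `map`.
#' @export
genotype_set <- function(counts, map) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)), "counts must have animal rownames")
  assert_that(all(c("snp", "chrom", "pos") %in% names(map)),
              "map needs columns snp, chrom, pos")
  assert_that(nrow(map) == ncol(counts),
              "map rows (", nrow(map), ") != SNP columns (", ncol(counts), ")")
  bad <- counts[!is.na(counts) & !(counts %in% c(0, 1, 2))]
  assert_that(length(bad) == 0, "allele counts must be 0, 1, 2 or NA")
  map$chrom <- as.character(map$chrom)
  for (ch in unique(map$chrom)) {
    pos <- map$pos[map$chrom == ch]
    assert_that(all(diff(pos) > 0),
                "bp positions must be strictly increasing within chromosome ", ch)
  }
  colnames(counts) <- map$snp
  structure(list(counts = counts, map = map), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$counts), "animals x", ncol(x$counts), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sprintf("%.2f%%", 100 * mean(is.na(x$counts))), "missing\n")
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) dim(x$counts)

#' Genotype quality-control thresholds
#'
#' Defaults mirror routine SNP-chip/GBS editing for pig genomic evaluation:
#' minor allele frequency >= 0.01, Hardy-Weinberg chi-square p >= 1e-6,
#' per-animal call rate >= 0.95, per-SNP call rate >= 0.99, and at least 30
#' animals in each homozygote class.
#'
#' @param maf_min,hwe_p_min,animal_call_rate_min,snp_call_rate_min,min_hom_count
#'   numeric thresholds.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 1e-6,
                          animal_call_rate_min = 0.95,
                          snp_call_rate_min = 0.99, min_hom_count = 30) {
  assert_that(maf_min >= 0 && maf_min < 0.5, "maf_min out of range")
  assert_that(hwe_p_min >= 0 && hwe_p_min < 1, "hwe_p_min out of range")
  assert_that(animal_call_rate_min >= 0 && animal_call_rate_min <= 1 &&
              snp_call_rate_min >= 0 && snp_call_rate_min <= 1,
              "call rates must be in [0,1]")
  assert_that(min_hom_count >= 0, "min_hom_count must be >= 0")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 animal_call_rate_min = animal_call_rate_min,
                 snp_call_rate_min = snp_call_rate_min,
                 min_hom_count = min_hom_count), class = "qc_thresholds")
}

## 1-df chi-square goodness-of-fit test of HWE genotype proportions
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * pmax(n, 1L))
  x2 <- numeric(length(n))
  for (g in 1:3) {
    ee <- switch(g, n * (1 - p)^2, n * 2 * p * (1 - p), n * p^2)
    oo <- switch(g, n0, n1, n2)
    x2 <- x2 + ifelse(ee > 0, (oo - ee)^2 / ee, ifelse(oo > 0, Inf, 0))
  }
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Applies the editing rules in a fixed order: animals with call rate below
#' threshold are removed first; then SNPs are removed if they fail minor
#' allele frequency, Hardy-Weinberg equilibrium (1-df chi-square on genotype
#' counts), per-SNP call rate, or the minimum count of each homozygote class
#' (both classes must reach `min_hom_count`). A SNP may fail several
#' criteria; the report counts every criterion it fails.
#'
#' @param geno a [genotype_set()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `genotypes` (filtered [genotype_set()]) and
#'   `report` (list of per-criterion counts and removed ids).
#' @export
qc_filter <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_set"))
  cnt <- geno$counts
  acr <- rowMeans(!is.na(cnt))
  bad_animals <- acr < thresholds$animal_call_rate_min
  cnt <- cnt[!bad_animals, , drop = FALSE]

  n_called <- colSums(!is.na(cnt))
  n2 <- colSums(cnt == 2, na.rm = TRUE)
  n1 <- colSums(cnt == 1, na.rm = TRUE)
  n0 <- n_called - n1 - n2
  p <- (2 * n2 + n1) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  callr <- n_called / nrow(cnt)
  hwe_p <- hwe_chisq_p(n0, n1, n2)

  fail_maf <- maf < thresholds$maf_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_call <- callr < thresholds$snp_call_rate_min
  fail_hom <- pmin(n0, n2) < thresholds$min_hom_count
  fail_any <- fail_maf | fail_hwe | fail_call | fail_hom

  keep <- which(!fail_any)
  if (length(keep) == 0L || nrow(cnt) == 0L)
    stop_ssblup("quality control removed every SNP or every animal",
                class = "ssblup_all_filtered")
  out <- genotype_set(cnt[, keep, drop = FALSE], geno$map[keep, , drop = FALSE])
  report <- list(
    n_animals_removed = sum(bad_animals),
    animals_removed = rownames(geno$counts)[bad_animals],
    n_snps_removed = sum(fail_any),
    n_fail_maf = sum(fail_maf),
    n_fail_hwe = sum(fail_hwe),
    n_fail_call_rate = sum(fail_call),
    n_fail_min_hom = sum(fail_hom),
    snps_removed = geno$map$snp[fail_any],
    n_snps_kept = length(keep),
    n_animals_kept = nrow(cnt))
  list(genotypes = out, report = report)
}

#' Write a QC report as TSV
#' @param report the `report` element of [qc_filter()] output.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  keys <- c("n_animals_removed", "n_snps_removed", "n_fail_maf", "n_fail_hwe",
            "n_fail_call_rate", "n_fail_min_hom", "n_snps_kept", "n_animals_kept")
  df <- data.frame(criterion = keys, count = unlist(report[keys]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Observed allele frequencies
#'
#' Frequency of the counted allele per SNP: `mean(counts)/2`, ignoring
#' missing genotypes.
#'
#' @param geno a [genotype_set()] (or a bare counts matrix).
#' @return numeric vector of frequencies named by SNP.
#' @export
allele_frequencies <- function(geno) {
  cnt <- if (inherits(geno, "genotype_set")) geno$counts else as.matrix(geno)
  p <- colMeans(cnt, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop_ssblup("monomorphic SNP encountered; run qc_filter() first",
                class = "ssblup_monomorphic")
  p
}

## centered gene-content matrix with mean imputation of missing genotypes
centered_gene_content <- function(geno, freqs) {
  cnt <- if (inherits(geno, "genotype_set")) geno$counts else as.matrix(geno)
  Z <- sweep(cnt, 2L, 2 * freqs)
  Z[is.na(Z)] <- 0  ## missing -> 2p, i.e. 0 after centering
  Z
}

#' VanRaden genomic relationship matrix (optionally SNP-weighted)
#'
#' `G = Z D Z' / lambda` with `Z` the allele counts column-centered by twice
#' the allele frequency (missing genotypes mean-imputed), `D` a diagonal
#' matrix of SNP weights and `lambda = sum_j 2 p_j (1 - p_j)` (VanRaden
#' method 1). With unit weights and frequencies estimated from the data the
#' mean diagonal is close to 1.
#'
#' @param geno a [genotype_set()].
#' @param freqs allele frequencies (defaults to observed).
#' @param weights per-SNP weights d_j (default all 1).
#' @return dense symmetric matrix with animal dimnames; attribute `lambda`.
#' @export
vanraden_g <- function(geno, freqs = allele_frequencies(geno), weights = NULL) {
  cnt <- if (inherits(geno, "genotype_set")) geno$counts else as.matrix(geno)
  m <- ncol(cnt)
  if (is.null(weights)) weights <- rep(1, m)
  assert_that(length(weights) == m, "weights length (", length(weights),
              ") != number of SNPs (", m, ")", class = "ssblup_shape")
  assert_that(length(freqs) == m, "freqs length != number of SNPs",
              class = "ssblup_shape")
  Z <- centered_gene_content(cnt, freqs)
  lambda <- sum(2 * freqs * (1 - freqs))
  G <- tcrossprod(Z * rep(sqrt(weights), each = nrow(Z))) / lambda
  dimnames(G) <- list(rownames(cnt), rownames(cnt))
  attr(G, "lambda") <- lambda
  G
}

#' Blend a genomic relationship matrix with A22 and invert
#'
#' Optionally rescales G so its mean diagonal and mean off-diagonal match
#' those of the pedigree block A22 (`tune = TRUE`), then forms
#' `Gb = blend_g * G + (1 - blend_g) * A22` and returns its inverse. The
#' blend guarantees an invertible matrix when more SNPs than animals are not
#' available or G is otherwise singular.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship block for the same animals (same order).
#' @param blend_g proportion of (tuned) G in the blend, default 0.95.
#' @param tune logical; match first two moments of A22 before blending.
#' @return inverse of the blended matrix; attributes `blend_g`, `tune_a`,
#'   `tune_b` record the adjustment, and `Gb` the blended (uninverted) matrix.
#' @export
blend_and_invert <- function(G, A22, blend_g = 0.95, tune = TRUE) {
  assert_that(all(dim(G) == dim(A22)), "G and A22 not conformable",
              class = "ssblup_shape")
  assert_that(blend_g >= 0 && blend_g <= 1, "blend_g must be in [0,1]")
  a <- 0; b <- 1
  n <- nrow(G)
  if (tune && n > 1L) {
    dG <- mean(diag(G)); oG <- (sum(G) - sum(diag(G))) / (n * (n - 1))
    dA <- mean(diag(A22)); oA <- (sum(A22) - sum(diag(A22))) / (n * (n - 1))
    if (abs(dG - oG) > 1e-12) {
      b <- (dA - oA) / (dG - oG)
      a <- dA - b * dG
    }
  }
  Gb <- blend_g * (a + b * G) + (1 - blend_g) * A22
  ch <- tryCatch(chol(Gb), error = function(e)
    stop_ssblup("blended genomic matrix is not positive definite; ",
                "decrease blend_g", class = "ssblup_conditioning"))
  Ginv <- chol2inv(ch)
  dimnames(Ginv) <- dimnames(G)
  attr(Ginv, "blend_g") <- blend_g
  attr(Ginv, "tune_a") <- a
  attr(Ginv, "tune_b") <- b
  attr(Ginv, "log_det") <- 2 * sum(log(diag(ch)))
  attr(Ginv, "Gb") <- Gb
  Ginv
}

#' Single-step H-inverse
#'
#' The combined pedigree-genomic relationship inverse used by single-step
#' genomic BLUP: `H^-1 = A^-1 + [[0,0],[0, G^-1 - A22^-1]]`, where the
#' correction applies to the genotyped block. Animal ids are matched by the
#' dimnames of `Ginv`/`A22inv` against those of `Ainv`.
#'
#' @param Ainv sparse pedigree relationship inverse (from [a_inverse()]).
#' @param A22inv inverse of the genotyped-block pedigree relationships.
#' @param Ginv inverse (usually blended) genomic relationship matrix.
#' @return sparse symmetric matrix aligned with `Ainv`.
#' @export
h_inverse <- function(Ainv, A22inv, Ginv) {
  ids <- rownames(Ginv)
  if (is.null(ids) && is.null(A22inv)) return(Ainv)
  assert_that(!is.null(ids), "Ginv must carry animal dimnames",
              class = "ssblup_index")
  assert_that(identical(dim(Ginv), dim(A22inv)) &&
              identical(ids, rownames(A22inv)),
              "Ginv and A22inv must cover the same animals in the same order",
              class = "ssblup_index")
  idx <- match(ids, rownames(Ainv))
  if (anyNA(idx))
    stop_ssblup("genotyped animal(s) absent from pedigree: ",
                paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "),
                class = "ssblup_index")
  delta <- Ginv - A22inv
  tr <- which(delta != 0, arr.ind = TRUE)
  Hinv <- Ainv + Matrix::sparseMatrix(i = idx[tr[, 1L]], j = idx[tr[, 2L]],
                                      x = delta[tr], dims = dim(Ainv),
                                      dimnames = dimnames(Ainv))
  Hinv
}

#' Pairwise linkage disequilibrium (r-squared) in a region
#'
#' Squared Pearson correlation of allele counts for every SNP pair in the
#' requested region. Pairs involving a zero-variance SNP get `NA`.
#'
#' @param geno a [genotype_set()].
#' @param chromosome chromosome label.
#' @param from_bp,to_bp region bounds (1-based, inclusive).
#' @return data frame `snp1, snp2, pos1, pos2, dist_bp, r2` for all unordered
#'   pairs (including self-pairs with r2 = 1).
#' @export
ld_r2 <- function(geno, chromosome, from_bp = 0, to_bp = Inf) {
  stopifnot(inherits(geno, "genotype_set"))
  sel <- which(geno$map$chrom == as.character(chromosome) &
               geno$map$pos >= from_bp & geno$map$pos <= to_bp)
  assert_that(length(sel) >= 2L, "region contains fewer than 2 SNPs")
  cnt <- geno$counts[, sel, drop = FALSE]
  suppressWarnings(r <- cor(cnt, use = "pairwise.complete.obs"))
  sdv <- apply(cnt, 2L, sd, na.rm = TRUE)
  r[sdv == 0, ] <- NA; r[, sdv == 0] <- NA
  diag(r)[sdv > 0] <- 1
  pr <- which(upper.tri(r, diag = TRUE), arr.ind = TRUE)
  data.frame(snp1 = geno$map$snp[sel][pr[, 1L]],
             snp2 = geno$map$snp[sel][pr[, 2L]],
             pos1 = geno$map$pos[sel][pr[, 1L]],
             pos2 = geno$map$pos[sel][pr[, 2L]],
             dist_bp = abs(geno$map$pos[sel][pr[, 2L]] - geno$map$pos[sel][pr[, 1L]]),
             r2 = r[pr]^2)
}
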