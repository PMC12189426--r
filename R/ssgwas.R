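#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the GEBV of the genotyped animals into per-SNP allele
#' substitution effects: `u = D Z' Ginv a_g / lambda`, with `Z` the centered
#' gene content, `D` the diagonal SNP weights and `lambda` the variance
#' normalisation constant of the genomic relationship matrix. When `Ginv`
#' is the exact inverse of the unblended `G = Z D Z' / lambda`, the
#' identity `Z u = a_g` holds.
#'
#' @param gebv named vector of GEBV for the genotyped animals (same order
#'   as the rows of `Z`).
#' @param Z centered gene-content matrix (animals x SNPs).
#' @param weights per-SNP weights d_j (diagonal of D).
#' @param Ginv inverse genomic relationship matrix for the same animals.
#' @param lambda the normalisation constant used to build G.
#' @return numeric vector of SNP effects.
#' @export
backsolve_snp_effects <- function(gebv, Z, weights, Ginv, lambda) {
  assert_that(length(gebv) == nrow(Z) && all(dim(Ginv) == nrow(Z)),
              "gebv/Z/Ginv dimensions disagree", class = "ssblup_shape")
  assert_that(length(weights) == ncol(Z), "weights length != SNP count",
              class = "ssblup_shape")
  as.numeric(weights * crossprod(Z, Ginv %*% gebv)) / lambda
}

#' Update SNP weights from back-solved effects
#'
#' Raw weights `d_j = u_j^2 * 2 p_j (1 - p_j)` are rescaled so that
#' `sum_j d_j * 2 p_j (1 - p_j)` is unchanged from its unit-weight value,
#' keeping the total genetic variance represented by the markers constant
#' across weighting iterations.
#'
#' @param effects back-solved SNP effects.
#' @param freqs allele frequencies.
#' @return normalised weight vector.
#' @export
update_weights <- function(effects, freqs) {
  assert_that(length(effects) == length(freqs), "effects/freqs length mismatch",
              class = "ssblup_shape")
  het <- 2 * freqs * (1 - freqs)
  d_raw <- effects^2 * het
  denom <- sum(d_raw * het)
  if (denom <= 0)
    stop_ssblup("all SNP effects are zero; weights cannot be normalised",
                class = "ssblup_degenerate_weights")
  d_raw * sum(het) / denom
}

#' Genetic variance explained by 0.3 Mb SNP windows
#'
#' Every SNP anchors a window containing all SNPs of the same chromosome in
#' `[pos, pos + window_bp)`; windows therefore overlap. The genetic value of
#' a window is the sum of its members' centered gene contents times their
#' effects, and the window's share of genetic variance is the empirical
#' variance of that value across genotyped animals divided by `sigma_a2`
#' (in percent).
#'
#' @param effects per-SNP effects.
#' @param Z centered gene-content matrix (animals x SNPs).
#' @param map data frame `snp`, `chrom`, `pos` (positions sorted within
#'   chromosome).
#' @param sigma_a2 total additive genetic variance (denominator).
#' @param window_bp window span in bp (default 0.3 Mb).
#' @return data frame (class `window_scan`): `chrom`, `start`, `end`
#'   (1-based inclusive, `end = start + window_bp - 1`), `n_snps`, `gvar_pct`,
#'   `top_snp_pos` (= anchor position).
#' @export
window_variance <- function(effects, Z, map, sigma_a2, window_bp = 3e5) {
  assert_that(sigma_a2 > 0, "sigma_a2 must be positive", class = "ssblup_domain")
  assert_that(length(effects) == ncol(Z) && nrow(map) == ncol(Z),
              "effects/Z/map dimensions disagree", class = "ssblup_shape")
  out <- list()
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    pos <- map$pos[j]
    ## per-animal genetic value of each SNP, cumulated left to right
    ZU <- sweep(Z[, j, drop = FALSE], 2L, effects[j], `*`)
    CS <- t(apply(ZU, 1L, cumsum))
    if (length(j) == 1L) CS <- matrix(ZU, ncol = 1L)
    last <- findInterval(pos + window_bp - 1, pos)
    gv <- numeric(length(j)); m <- integer(length(j))
    for (k in seq_along(j)) {
      wsum <- CS[, last[k]] - (if (k > 1L) CS[, k - 1L] else 0)
      gv[k] <- var(wsum)
      m[k] <- last[k] - k + 1L
    }
    out[[ch]] <- data.frame(chrom = ch, start = pos,
                            end = pos + window_bp - 1,
                            n_snps = m, gvar_pct = 100 * gv / sigma_a2,
                            top_snp_pos = pos)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$chrom, res$start), ]
  class(res) <- c("window_scan", "data.frame")
  res
}

#' Call candidate windows and merge overlapping regions
#'
#' Windows explaining more than `threshold` percent of the genetic variance
#' are selected; overlapping selected windows on the same chromosome are
#' merged into one reported region whose top SNP is the anchor of the
#' maximal window.
#'
#' @param scan a [window_variance()] result.
#' @param threshold gVar percentage cut-off (default 1).
#' @return data frame: `chrom`, `region_start`, `region_end`, `gvar_pct`
#'   (max over merged windows), `n_snps` (of the maximal window),
#'   `top_snp_pos`, `n_windows` merged.
#' @export
call_candidate_windows <- function(scan, threshold = 1.0) {
  sel <- scan[scan$gvar_pct > threshold, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(chrom = character(0), region_start = numeric(0),
                      region_end = numeric(0), gvar_pct = numeric(0),
                      n_snps = integer(0), top_snp_pos = numeric(0),
                      n_windows = integer(0)))
  out <- list()
  for (ch in unique(sel$chrom)) {
    s <- sel[sel$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(s$start[-1] > cummax(s$end)[-nrow(s)])))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      best <- which.max(sg$gvar_pct)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, region_start = min(sg$start), region_end = max(sg$end),
        gvar_pct = sg$gvar_pct[best], n_snps = sg$n_snps[best],
        top_snp_pos = sg$top_snp_pos[best], n_windows = nrow(sg))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$region_start), ]
}

#' Assign candidate genes near top SNPs
#'
#' Genes whose interval lies less than `max_dist_bp` from a region's top
#' SNP (gap between the SNP position and the gene boundaries, zero if the
#' SNP falls inside the gene) are assigned to that region.
#'
#' @param candidates output of [call_candidate_windows()].
#' @param genes a `GRanges` (e.g. from [read_gene_table()]) or a data frame
#'   with `chrom`, `start`, `end`, `name`.
#' @param max_dist_bp assignment radius (default 0.3 Mb, strict `<`).
#' @return data frame: one row per (region, gene) assignment with the gap
#'   distance; zero rows when nothing is within reach.
#' @export
map_candidate_genes <- function(candidates, genes, max_dist_bp = 3e5) {
  if (is.data.frame(genes)) {
    assert_that(all(c("chrom", "start", "end", "name") %in% names(genes)),
                "gene table needs chrom, start, end, name")
    genes <- GenomicRanges::GRanges(
      seqnames = as.character(genes$chrom),
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      name = genes$name)
  }
  if (nrow(candidates) == 0L)
    return(data.frame(chrom = character(0), top_snp_pos = numeric(0),
                      gene = character(0), distance_bp = numeric(0)))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  unmatched <- setdiff(unique(as.character(candidates$chrom)), unique(gchr))
  if (length(unmatched) == length(unique(candidates$chrom)))
    stop_ssblup("no chromosome of the gene table matches the genotype map: ",
                paste(unmatched, collapse = ", "), class = "ssblup_join")
  out <- list()
  for (r in seq_len(nrow(candidates))) {
    snp <- GenomicRanges::GRanges(
      seqnames = as.character(candidates$chrom[r]),
      ranges = IRanges::IRanges(start = candidates$top_snp_pos[r], width = 1L))
    d <- suppressWarnings(GenomicRanges::distance(snp, genes))
    hit <- which(!is.na(d) & d < max_dist_bp)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(candidates$chrom[r]),
        top_snp_pos = candidates$top_snp_pos[r],
        gene = as.character(genes$name[hit]),
        distance_bp = d[hit])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), top_snp_pos = numeric(0),
                      gene = character(0), distance_bp = numeric(0)))
  do.call(rbind, out)
}

#' Iteratively weighted single-step GWAS
#'
#' Runs the weighted single-step GWAS loop: start with unit SNP weights,
#' build the (blended, tuned) genomic relationship matrix, solve the
#' single-step GBLUP system for GEBV, back-solve SNP effects, derive the
#' window decomposition of genetic variance, then update and renormalise
#' the SNP weights and repeat. With `n_iterations = 1` the scan is the
#' unweighted single-step GWAS.
#'
#' @param records trait records (already edited).
#' @param trait trait column to analyse.
#' @param ped a [pedigree()].
#' @param geno post-QC [genotype_set()] of the genotyped animals.
#' @param vc converged [variance_components()] for the trait.
#' @param n_iterations weighting iterations (default 2).
#' @param window_bp window span (default 0.3 Mb).
#' @param blend_g,tune passed to [blend_and_invert()].
#' @param fixed fixed-effect columns.
#' @return list of class `ssgwas_result`; element `iterations` holds, per
#'   iteration, `weights`, `effects`, `scan`, `gebv`; `freqs`, `lambda` and
#'   the call parameters are recorded alongside.
#' @export
run_weighted_ssgwas <- function(records, trait, ped, geno, vc,
                                n_iterations = 2L, window_bp = 3e5,
                                blend_g = 0.95, tune = TRUE,
                                fixed = intersect(c("farm_year_month", "parity"),
                                                  names(records))) {
  assert_that(n_iterations >= 1, "need at least one iteration")
  ids <- rownames(geno$counts)
  freqs <- allele_frequencies(geno)
  Z <- centered_gene_content(geno, freqs)
  lambda <- sum(2 * freqs * (1 - freqs))
  A22 <- a_submatrix(ped, ids)
  A22inv <- chol2inv(chol(A22))
  dimnames(A22inv) <- dimnames(A22)
  Ainv <- a_inverse(ped)
  design <- build_design(records, trait, ped, fixed = fixed)

  weights <- rep(1, ncol(Z))
  iters <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    G <- vanraden_g(geno, freqs, weights)
    Ginv <- blend_and_invert(G, A22, blend_g = blend_g, tune = tune)
    Hinv <- h_inverse(Ainv, A22inv, Ginv)
    fit <- solve_mme(design, Hinv, vc)
    gebv <- fit$a[ids]
    effects <- backsolve_snp_effects(gebv, Z, weights, Ginv, lambda)
    scan <- window_variance(effects, Z, geno$map, vc$sigma_a2,
                            window_bp = window_bp)
    iters[[it]] <- list(iteration = it, weights = weights, effects = effects,
                        scan = scan, gebv = gebv)
    if (it < n_iterations) {
      weights <- tryCatch(update_weights(effects, freqs), error = function(e) {
        if (inherits(e, "ssblup_degenerate_weights")) {
          warning("degenerate SNP weights at iteration ", it,
                  "; stopping early", call. = FALSE)
          NULL
        } else stop(e)
      })
      if (is.null(weights)) { iters <- iters[seq_len(it)]; break }
    }
  }
  structure(list(iterations = iters, trait = trait, freqs = freqs,
                 lambda = lambda, window_bp = window_bp,
                 blend_g = blend_g, vc = vc),
            class = "ssgwas_result")
}

#' @export
print.ssgwas_result <- function(x, ...) {
  last <- x$iterations[[length(x$iterations)]]
  top <- last$scan[order(-last$scan$gvar_pct), ][1, ]
  cat(sprintf("weighted ssGWAS for %s: %d iteration(s), %d windows\n",
              x$trait, length(x$iterations), nrow(last$scan)))
  cat(sprintf("top window: chr%s:%d-%d gVar %.2f%% (%d SNPs)\n",
              top$chrom, top$start, top$end, top$gvar_pct, top$n_snps))
  invisible(x)
}

#' Write a window scan as a Manhattan-style TSV
#' @param scan a [window_variance()] result.
#' @param path output path.
#' @export
write_window_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
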