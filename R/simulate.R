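#' Simulation configuration for litter-trait breeding data
#'
#' Defines a discrete-generation nucleus population, an LD-structured
#' genome, and the latent-scale trait architecture of repeated litter-size
#' records. Defaults emulate a large maternal-line pig population: nine
#' correlated litter traits with heritabilities in 0.01-0.06 and
#' repeatabilities in 0.02-0.14, farm-by-year-month and parity fixed
#' effects, a sow permanent-environment effect, and linkage disequilibrium
#' decaying to r2 ~ 0.2 at 0.3 Mb.
#'
#' Six traits are simulated directly on a latent Gaussian scale (TNB, NSB,
#' MUMM, NWB, NDF, LBWT); the composition traits NBA, NHB and rNHB are
#' derived so the identities `TNB = NBA + NSB + MUMM`,
#' `NBA = NHB + NWB + NDF` and `rNHB = 100 NHB / TNB` hold exactly in every
#' record.
#'
#' @param n_generations number of discrete generations (>= 1).
#' @param n_females_per_gen,n_males_per_gen animals entering each generation.
#' @param n_record_gens how many of the last generations of females carry
#'   phenotype records (sows).
#' @param genotyped_fraction_last_gens fraction of the sows of the last two
#'   generations that are genotyped.
#' @param n_chromosomes,chrom_length_bp,n_snps_per_chrom genome layout.
#' @param founder_maf_range interval the founder allele frequencies are
#'   drawn from (within (0, 0.5]).
#' @param ld_decay_mb correlation length (Mb) of the founder-haplotype
#'   latent process; the default is calibrated so marker r2 at 0.3 Mb is
#'   near 0.2.
#' @param n_qtl number of causal markers.
#' @param qtl_var_fraction fraction of the additive variance explained by
#'   the causal markers (the remainder is polygenic).
#' @param trait_names traits simulated directly on the latent scale.
#' @param trait_means,phenotypic_var_targets per-trait mean and phenotypic
#'   variance on the observed scale.
#' @param h2_targets,repeatability_targets per-trait ratios
#'   (`h2 <= repeatability <= 1`).
#' @param genetic_correlation_matrix symmetric PSD correlation matrix
#'   (unit diagonal) among the directly simulated traits; also used for the
#'   permanent-environment and residual correlations unless overridden.
#' @param pe_correlation_matrix,residual_correlation_matrix optional
#'   overrides.
#' @param n_parities_per_sow probability weights for a sow having 1..8
#'   recorded parities.
#' @param n_farms,n_year_months numbers of farms and year-month classes
#'   forming the farm-year-month effect.
#' @param derive_composition derive NBA/NHB/rNHB from the direct traits.
#' @param seed integer seed; every simulation stage derives its stream from
#'   it, so equal configs give bit-identical data.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_generations = 3L,
                       n_females_per_gen = 200L,
                       n_males_per_gen = 20L,
                       n_record_gens = 2L,
                       genotyped_fraction_last_gens = 0.5,
                       n_chromosomes = 3L,
                       chrom_length_bp = 5e7,
                       n_snps_per_chrom = 200L,
                       founder_maf_range = c(0.05, 0.5),
                       ld_decay_mb = 0.7,
                       n_qtl = 20L,
                       qtl_var_fraction = 0.3,
                       trait_names = c("TNB", "NSB", "MUMM", "NWB", "NDF", "LBWT"),
                       trait_means = c(TNB = 13.77, NSB = 1.27, MUMM = 0.42,
                                       NWB = 1.48, NDF = 0.19, LBWT = 15.07),
                       phenotypic_var_targets = c(TNB = 11.29, NSB = 2.55,
                                                  MUMM = 0.76, NWB = 2.17,
                                                  NDF = 0.25, LBWT = 15.53),
                       h2_targets = c(TNB = 0.06, NSB = 0.05, MUMM = 0.01,
                                      NWB = 0.04, NDF = 0.01, LBWT = 0.05),
                       repeatability_targets = c(TNB = 0.14, NSB = 0.08,
                                                 MUMM = 0.03, NWB = 0.10,
                                                 NDF = 0.02, LBWT = 0.14),
                       genetic_correlation_matrix = NULL,
                       pe_correlation_matrix = NULL,
                       residual_correlation_matrix = NULL,
                       n_parities_per_sow = c(0.36, 0.20, 0.13, 0.10,
                                              0.08, 0.06, 0.04, 0.03),
                       n_farms = 5L,
                       n_year_months = 12L,
                       derive_composition = TRUE,
                       seed = 1L) {
  nt <- length(trait_names)
  if (is.null(genetic_correlation_matrix)) {
    genetic_correlation_matrix <- if (identical(trait_names,
        c("TNB", "NSB", "MUMM", "NWB", "NDF", "LBWT"))) {
      m <- matrix(c(
        1.00, 0.41, 0.49, 0.54, 0.36, 0.63,
        0.41, 1.00, 0.57, 0.10, 0.35, -0.07,
        0.49, 0.57, 1.00, 0.17, 0.27, 0.17,
        0.54, 0.10, 0.17, 1.00, 0.27, -0.04,
        0.36, 0.35, 0.27, 0.27, 1.00, 0.23,
        0.63, -0.07, 0.17, -0.04, 0.23, 1.00), 6, 6)
      dimnames(m) <- list(trait_names, trait_names)
      m
    } else diag(nt)
  }
  Rg <- as.matrix(genetic_correlation_matrix)
  cfg <- list(n_generations = as.integer(n_generations),
              n_females_per_gen = as.integer(n_females_per_gen),
              n_males_per_gen = as.integer(n_males_per_gen),
              n_record_gens = as.integer(n_record_gens),
              genotyped_fraction_last_gens = genotyped_fraction_last_gens,
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              founder_maf_range = founder_maf_range,
              ld_decay_mb = ld_decay_mb,
              n_qtl = as.integer(n_qtl),
              qtl_var_fraction = qtl_var_fraction,
              trait_names = trait_names,
              trait_means = trait_means[trait_names],
              phenotypic_var_targets = phenotypic_var_targets[trait_names],
              h2_targets = h2_targets[trait_names],
              repeatability_targets = repeatability_targets[trait_names],
              genetic_correlation_matrix = Rg,
              pe_correlation_matrix = if (is.null(pe_correlation_matrix)) Rg
                                      else as.matrix(pe_correlation_matrix),
              residual_correlation_matrix = if (is.null(residual_correlation_matrix)) Rg
                                            else as.matrix(residual_correlation_matrix),
              n_parities_per_sow = n_parities_per_sow / sum(n_parities_per_sow),
              n_farms = as.integer(n_farms),
              n_year_months = as.integer(n_year_months),
              derive_composition = isTRUE(derive_composition),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    assert_that(n_generations >= 1 && n_females_per_gen >= 1 &&
                n_males_per_gen >= 1 && n_chromosomes >= 1 &&
                n_snps_per_chrom >= 1, "all counts must be positive",
                class = "ssblup_config")
    assert_that(genotyped_fraction_last_gens >= 0 &&
                genotyped_fraction_last_gens <= 1,
                "genotyped fraction must be in [0,1]", class = "ssblup_config")
    assert_that(founder_maf_range[1] > 0 && founder_maf_range[2] <= 0.5 &&
                founder_maf_range[1] <= founder_maf_range[2],
                "founder_maf_range must lie in (0, 0.5]", class = "ssblup_config")
    assert_that(chrom_length_bp >= n_snps_per_chrom,
                "chromosome shorter than the SNP spacing requires",
                class = "ssblup_config")
    nt <- length(trait_names)
    assert_that(length(h2_targets) == nt && length(repeatability_targets) == nt &&
                length(phenotypic_var_targets) == nt && !anyNA(h2_targets) &&
                !anyNA(repeatability_targets) && !anyNA(phenotypic_var_targets),
                "per-trait targets must cover every trait", class = "ssblup_config")
    assert_that(all(h2_targets >= 0) &&
                all(h2_targets <= repeatability_targets + 1e-12) &&
                all(repeatability_targets <= 1),
                "need 0 <= h2 <= repeatability <= 1 per trait",
                class = "ssblup_config")
    for (nm in c("genetic_correlation_matrix", "pe_correlation_matrix",
                 "residual_correlation_matrix")) {
      M <- get(nm)
      assert_that(all(dim(M) == nt) && max(abs(M - t(M))) < 1e-8 &&
                  max(abs(diag(M) - 1)) < 1e-8,
                  nm, " must be symmetric with unit diagonal",
                  class = "ssblup_config")
      ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      assert_that(ev > -1e-8, nm, " is not positive semi-definite",
                  class = "ssblup_config")
    }
    assert_that(length(n_parities_per_sow) <= 8 && all(n_parities_per_sow >= 0),
                "parity distribution must cover at most 8 parities",
                class = "ssblup_config")
  })
  invisible(cfg)
}

#' Simulate a discrete-generation pedigree
#'
#' Generation 0 holds unrelated founders; every later animal draws its sire
#' from the previous generation's males and its dam from its females.
#' Females of the last `n_record_gens` generations are flagged as
#' phenotyped sows; a seeded random subset of the sows of the last two
#' generations (of size `genotyped_fraction_last_gens` times their number)
#' is flagged as genotyped, mimicking a nucleus-herd genotyping scheme.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with metadata columns `sex`, `generation`,
#'   `phenotyped`, `genotyped`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_generations
  nf <- config$n_females_per_gen; nm <- config$n_males_per_gen
  if (nf < 1L || nm < 1L)
    stop_ssblup("a generation without males or females cannot reproduce",
                class = "ssblup_generation_collapse")
  per_gen <- nf + nm
  n <- per_gen * G
  id <- as.character(seq_len(n))
  sex <- character(n); gen <- integer(n)
  sire <- dam <- rep(NA_character_, n)
  for (g in seq_len(G) - 1L) {
    rows <- g * per_gen + seq_len(per_gen)
    sex[rows] <- c(rep("M", nm), rep("F", nf))
    gen[rows] <- g
    if (g > 0L) {
      prev <- (g - 1L) * per_gen + seq_len(per_gen)
      prev_m <- id[prev[sex[prev] == "M"]]
      prev_f <- id[prev[sex[prev] == "F"]]
      sire[rows] <- sample(prev_m, per_gen, replace = TRUE)
      dam[rows] <- sample(prev_f, per_gen, replace = TRUE)
    }
  }
  ped <- pedigree(id, sire, dam, sex = sex, generation = gen)
  ped$phenotyped <- ped$sex == "F" &
    ped$generation >= G - min(config$n_record_gens, G)
  geno_cand <- which(ped$sex == "F" & ped$generation >= G - min(2L, G))
  n_geno <- round(config$genotyped_fraction_last_gens * length(geno_cand))
  ped$genotyped <- FALSE
  if (n_geno > 0L)
    ped$genotyped[sample(geno_cand, n_geno)] <- TRUE
  ped
}

## one meiosis: recombine two parental haplotypes (Haldane crossovers)
recombine_hap <- function(h1, h2, posM, lenM) {
  k <- rpois(1L, lenM)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(runif(k, 0, lenM))
  seg <- findInterval(posM, xo) + start
  ifelse(seg %% 2L == 1L, h1, h2)
}

#' Simulate LD-structured genotypes by gene dropping
#'
#' Founder haplotypes are thresholded Gaussian AR processes along each
#' chromosome (correlation length `ld_decay_mb`), which creates linkage
#' disequilibrium that decays with distance; descendants receive parental
#' haplotypes through Haldane-model recombination at 1 cM per Mb. A set of
#' `n_qtl` markers is designated causal; their allele counts are kept for
#' every animal (the trait simulator needs them), while the returned
#' genotype panel covers the genotyped animals (or everyone when the
#' pedigree carries no `genotyped` flag).
#'
#' @param ped pedigree from [simulate_pedigree()] (or any [pedigree()]).
#' @param config a [sim_config()].
#' @return a [genotype_set()] with extra attributes `qtl_idx` (map rows of
#'   the causal markers), `qtl_geno` (all-animals allele counts at those
#'   markers) and `founder_freqs`.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(ped)
  nchr <- config$n_chromosomes
  m_chr <- config$n_snps_per_chrom
  len_bp <- config$chrom_length_bp
  if (len_bp < m_chr)
    stop_ssblup("chromosome length shorter than SNP spacing",
                class = "ssblup_config")
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)

  map <- do.call(rbind, lapply(seq_len(nchr), function(ch) {
    pos <- sort(sample.int(len_bp, m_chr))
    data.frame(snp = sprintf("snp%d_%d", ch, seq_len(m_chr)),
               chrom = as.character(ch), pos = pos)
  }))
  m <- nrow(map)
  freqs <- runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  thr <- qnorm(freqs)

  H1 <- matrix(0L, m, n); H2 <- matrix(0L, m, n)
  founder <- is.na(si) & is.na(di)
  chr_rows <- split(seq_len(m), map$chrom)
  chr_rows <- chr_rows[as.character(seq_len(nchr))]
  ## AR(1) founder haplotypes, all haplotypes of a batch at once (loop over
  ## SNPs, vector ops across haplotypes)
  draw_founder_haps <- function(rows, nhap) {
    pos_mb <- map$pos[rows] / 1e6
    rho <- exp(-diff(pos_mb) / config$ld_decay_mb)
    mm <- length(rows)
    Z <- matrix(0, mm, nhap)
    Z[1, ] <- rnorm(nhap)
    if (mm > 1L) {
      sdev <- sqrt(1 - rho^2)
      E <- matrix(rnorm((mm - 1L) * nhap), mm - 1L, nhap)
      for (j in 2:mm)
        Z[j, ] <- rho[j - 1] * Z[j - 1, ] + sdev[j - 1] * E[j - 1L, ]
    }
    matrix(as.integer(Z < thr[rows]), mm, nhap)
  }
  fo <- which(founder)
  for (rows in chr_rows) {
    H1[rows, fo] <- draw_founder_haps(rows, length(fo))
    H2[rows, fo] <- draw_founder_haps(rows, length(fo))
  }
  posM <- lapply(chr_rows, function(rows) map$pos[rows] / 1e8)  ## 1 cM/Mb
  lenM <- len_bp / 1e8
  ## gene dropping, batched by generation so parents are already complete
  gen <- if ("generation" %in% names(ped)) ped$generation else {
    g <- integer(n)
    for (i in seq_len(n)) {
      gp <- c(if (!is.na(si[i])) g[si[i]], if (!is.na(di[i])) g[di[i]])
      g[i] <- if (length(gp)) max(gp) + 1L else 0L
    }
    g
  }
  transmit <- function(par_idx, rows, posMk) {
    nb <- length(par_idx)
    out <- matrix(0L, length(rows), nb)
    HA <- H1[rows, par_idx, drop = FALSE]
    HB <- H2[rows, par_idx, drop = FALSE]
    k <- rpois(nb, lenM)
    start <- sample.int(2L, nb, replace = TRUE)
    swap <- start == 2L
    if (any(swap)) {
      tmp <- HA[, swap, drop = FALSE]
      HA[, swap] <- HB[, swap, drop = FALSE]
      HB[, swap] <- tmp
    }
    out[] <- HA
    one <- which(k == 1L)
    if (length(one)) {
      cut <- findInterval(runif(length(one), 0, lenM), posMk)
      for (z in seq_along(one)) {
        j <- one[z]
        if (cut[z] < length(rows))
          out[(cut[z] + 1L):length(rows), j] <- HB[(cut[z] + 1L):length(rows), j]
      }
    }
    for (j in which(k >= 2L)) {
      xo <- sort(runif(k[j], 0, lenM))
      seg <- findInterval(posMk, xo)
      odd <- seg %% 2L == 1L
      out[odd, j] <- HB[odd, j]
    }
    out
  }
  for (g in sort(unique(gen[!founder]))) {
    batch <- which(gen == g & !founder)
    if (!length(batch)) next
    for (kk in seq_along(chr_rows)) {
      rows <- chr_rows[[kk]]
      has_s <- !is.na(si[batch]); has_d <- !is.na(di[batch])
      if (any(has_s))
        H1[rows, batch[has_s]] <- transmit(si[batch[has_s]], rows, posM[[kk]])
      if (any(!has_s))
        H1[rows, batch[!has_s]] <- draw_founder_haps(rows, sum(!has_s))
      if (any(has_d))
        H2[rows, batch[has_d]] <- transmit(di[batch[has_d]], rows, posM[[kk]])
      if (any(!has_d))
        H2[rows, batch[!has_d]] <- draw_founder_haps(rows, sum(!has_d))
    }
  }
  cnt_all <- H1 + H2
  qtl_idx <- sort(sample.int(m, min(config$n_qtl, m)))
  keep <- if ("genotyped" %in% names(ped)) which(ped$genotyped) else seq_len(n)
  if (length(keep) == 0L) keep <- seq_len(n)
  cnt_keep <- t(cnt_all[, keep, drop = FALSE])
  rownames(cnt_keep) <- ped$animal[keep]
  geno <- genotype_set(cnt_keep, map)
  attr(geno, "qtl_idx") <- qtl_idx
  qtl_geno <- t(cnt_all[qtl_idx, , drop = FALSE])
  rownames(qtl_geno) <- ped$animal
  attr(geno, "qtl_geno") <- qtl_geno
  attr(geno, "founder_freqs") <- freqs
  geno
}

#' Simulate repeated multi-trait litter records
#'
#' True breeding values are the sum of a causal-marker part (marker allele
#' counts times effects drawn with the target genetic covariance, rescaled
#' so the causal markers explain `qtl_var_fraction` of the additive
#' variance) and a pedigree-polygenic part gene-flowed down the pedigree
#' with Mendelian-sampling variance. Sows receive a permanent-environment
#' effect; each recorded parity adds a farm-year-month effect, a parity
#' effect and a residual, all on a latent Gaussian scale that is then
#' rounded and truncated to realistic count ranges (LBWT stays continuous;
#' composition traits NBA/NHB/rNHB are derived so the record identities
#' hold exactly).
#'
#' @param ped pedigree with `phenotyped` flags (from [simulate_pedigree()]).
#' @param geno output of [simulate_genotypes()] (or `NULL` for a purely
#'   polygenic simulation).
#' @param config a [sim_config()].
#' @return data frame of records (`animal`, `parity`, `farm_year_month`,
#'   trait columns) of class `trait_dataset`, with attributes `true_bv`
#'   (all animals x traits, latent scale), `true_pe`, `latent` (latent
#'   record values) and `config`.
#' @export
simulate_traits <- function(ped, geno, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(ped)
  tn <- config$trait_names
  nt <- length(tn)
  sp2 <- config$phenotypic_var_targets
  sa2 <- config$h2_targets * sp2
  spe2 <- (config$repeatability_targets - config$h2_targets) * sp2
  se2 <- (1 - config$repeatability_targets) * sp2
  Rg <- config$genetic_correlation_matrix

  chol_psd <- function(M) {
    eg <- eigen(M, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(M)) %*% t(eg$vectors)
  }
  frac <- if (is.null(geno)) 0 else config$qtl_var_fraction

  ## causal-marker component
  g_qtl <- matrix(0, n, nt)
  if (frac > 0) {
    Q <- attr(geno, "qtl_geno")
    Q <- Q[ped$animal, , drop = FALSE]
    Qc <- sweep(Q, 2L, colMeans(Q))
    Sg <- diag(sqrt(sa2), nt) %*% Rg %*% diag(sqrt(sa2), nt)
    alpha <- matrix(rnorm(ncol(Q) * nt), ncol(Q), nt) %*% chol_psd(Sg / ncol(Q))
    g_raw <- Qc %*% alpha
    sdr <- apply(g_raw, 2L, sd)
    scl <- ifelse(sdr > 0, sqrt(frac * sa2) / sdr, 0)
    g_qtl <- sweep(g_raw, 2L, scl, `*`)
  }

  ## polygenic component gene-flowed down the pedigree
  Spoly <- diag(sqrt((1 - frac) * sa2), nt) %*% Rg %*% diag(sqrt((1 - frac) * sa2), nt)
  Lp <- chol_psd(Spoly)
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  g_poly <- matrix(0, n, nt)
  ms <- 1 - 0.25 * (!is.na(si)) - 0.25 * (!is.na(di))
  noise <- matrix(rnorm(n * nt), n, nt) %*% t(Lp)
  for (i in seq_len(n)) {
    par_avg <- numeric(nt)
    if (!is.na(si[i])) par_avg <- par_avg + 0.5 * g_poly[si[i], ]
    if (!is.na(di[i])) par_avg <- par_avg + 0.5 * g_poly[di[i], ]
    g_poly[i, ] <- par_avg + sqrt(ms[i]) * noise[i, ]
  }
  u <- g_qtl + g_poly
  rownames(u) <- ped$animal
  colnames(u) <- tn

  sows <- which(ped$phenotyped %||% rep(TRUE, n))
  assert_that(length(sows) > 0, "no phenotyped sows in pedigree")
  Spe <- diag(sqrt(spe2), nt) %*% config$pe_correlation_matrix %*% diag(sqrt(spe2), nt)
  pe <- matrix(rnorm(length(sows) * nt), length(sows), nt) %*% t(chol_psd(Spe))
  rownames(pe) <- ped$animal[sows]

  np <- sample(seq_along(config$n_parities_per_sow), length(sows),
               replace = TRUE, prob = config$n_parities_per_sow)
  farm <- sample.int(config$n_farms, length(sows), replace = TRUE)
  rec_animal <- rep(ped$animal[sows], np)
  rec_parity <- unlist(lapply(np, seq_len), use.names = FALSE)
  nrec <- length(rec_animal)
  ym <- sample.int(config$n_year_months, nrec, replace = TRUE)
  fym <- sprintf("F%02d_YM%02d", rep(farm, np), ym)

  fym_levels <- sort(unique(fym))
  fym_eff <- matrix(rnorm(length(fym_levels) * nt), length(fym_levels), nt) %*%
    diag(0.3 * sqrt(sp2), nt)
  parity_curve <- c(-1, -0.3, 0, 0.15, 0.15, 0, -0.25, -0.5)
  parity_eff <- outer(parity_curve, 0.1 * sqrt(sp2))

  Se <- diag(sqrt(se2), nt) %*% config$residual_correlation_matrix %*% diag(sqrt(se2), nt)
  eres <- matrix(rnorm(nrec * nt), nrec, nt) %*% t(chol_psd(Se))
  sow_row <- match(rec_animal, ped$animal[sows])
  latent <- matrix(rep(config$trait_means, each = nrec), nrec, nt) +
    fym_eff[match(fym, fym_levels), , drop = FALSE] +
    parity_eff[rec_parity, , drop = FALSE] +
    u[match(rec_animal, ped$animal), , drop = FALSE] +
    pe[sow_row, , drop = FALSE] + eres
  colnames(latent) <- tn

  obs <- as.data.frame(latent)
  for (t in tn) {
    if (t == "LBWT") obs[[t]] <- round(pmax(obs[[t]], 0), 2)
    else obs[[t]] <- pmax(round(obs[[t]]), 0)
  }
  records <- data.frame(animal = rec_animal, parity = rec_parity,
                        farm_year_month = fym, stringsAsFactors = FALSE)
  records <- cbind(records, obs)

  if (config$derive_composition &&
      all(c("TNB", "NSB", "MUMM", "NWB", "NDF") %in% tn)) {
    ## enforce NSB + MUMM <= TNB, then NWB + NDF <= NBA
    over <- pmax(records$NSB + records$MUMM - records$TNB, 0)
    cut1 <- pmin(records$NSB, over)
    records$NSB <- records$NSB - cut1
    records$MUMM <- records$MUMM - (over - cut1)
    records$NBA <- records$TNB - records$NSB - records$MUMM
    over2 <- pmax(records$NWB + records$NDF - records$NBA, 0)
    cut2 <- pmin(records$NWB, over2)
    records$NWB <- records$NWB - cut2
    records$NDF <- records$NDF - (over2 - cut2)
    records$NHB <- records$NBA - records$NWB - records$NDF
    records$rNHB <- round(100 * records$NHB / pmax(records$TNB, 1), 1)
  }

  structure(records, class = c("trait_dataset", "data.frame"),
            true_bv = u, true_pe = pe, latent = latent, config = config)
}

#' Apply litter-record editing rules
#'
#' Removes litters with `TNB <= 3`, caps `TNB` at 22 (reconciling the
#' composition traits so the record identities keep holding, largest
#' components reduced first), and recodes parities above 8 as 8. Returns
#' the edited records with an editing report attached.
#'
#' @param records data frame with at least `parity`; `TNB` and the
#'   composition traits are edited when present.
#' @return edited records, attribute `edit_report` (list of per-rule
#'   counts), class `trait_dataset`.
#' @export
apply_edit_rules <- function(records) {
  cols <- intersect(c("TNB", "NBA", "NHB", "rNHB", "NWB", "NDF", "NSB",
                      "MUMM", "parity"), names(records))
  for (cl in cols)
    if (any(records[[cl]] < 0, na.rm = TRUE))
      stop_ssblup("negative counts in column ", cl, class = "ssblup_validation")
  n_in <- nrow(records)
  n_removed <- 0L; n_capped <- 0L
  if ("TNB" %in% names(records)) {
    drop <- !is.na(records$TNB) & records$TNB <= 3
    n_removed <- sum(drop)
    records <- records[!drop, , drop = FALSE]
    cap <- !is.na(records$TNB) & records$TNB >= 22
    n_capped <- sum(records$TNB > 22, na.rm = TRUE)
    if (any(cap)) {
      excess <- records$TNB[cap] - 22
      has_comp <- all(c("NBA", "NHB", "NWB", "NDF", "NSB", "MUMM") %in% names(records))
      if (has_comp) {
        for (comp in c("NHB", "NWB", "NSB", "MUMM", "NDF")) {
          take <- pmin(records[[comp]][cap], excess)
          records[[comp]][cap] <- records[[comp]][cap] - take
          excess <- excess - take
        }
        records$NBA[cap] <- records$NHB[cap] + records$NWB[cap] + records$NDF[cap]
        records$TNB[cap] <- records$NBA[cap] + records$NSB[cap] + records$MUMM[cap]
        if ("rNHB" %in% names(records))
          records$rNHB[cap] <- round(100 * records$NHB[cap] /
                                     pmax(records$TNB[cap], 1), 1)
      } else {
        records$TNB[cap] <- 22
      }
    }
  }
  n_parity <- 0L
  if ("parity" %in% names(records)) {
    over <- records$parity > 8
    n_parity <- sum(over)
    records$parity[over] <- 8L
  }
  report <- list(n_in = n_in, n_removed_small_tnb = n_removed,
                 n_capped_tnb = n_capped, n_parity_capped = n_parity,
                 n_out = nrow(records))
  structure(records, class = unique(c("trait_dataset", class(records))),
            edit_report = report)
}
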