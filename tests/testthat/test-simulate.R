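test_that("simulation config enforces its invariants", {
  expect_error(tiny_cfg(1, h2 = 0.2, rep_ = 0.1), class = "ssblup_config")
  expect_error(tiny_cfg(1, genotyped_fraction_last_gens = 1.5),
               class = "ssblup_config")
  expect_error(tiny_cfg(1, founder_maf_range = c(0, 0.6)),
               class = "ssblup_config")
  bad_R <- matrix(c(1, 2, 2, 1), 2)  ## not PSD
  expect_error(sim_config(trait_names = c("A", "B"),
                          trait_means = c(A = 1, B = 1),
                          phenotypic_var_targets = c(A = 1, B = 1),
                          h2_targets = c(A = 0.1, B = 0.1),
                          repeatability_targets = c(A = 0.2, B = 0.2),
                          genetic_correlation_matrix = bad_R),
               class = "ssblup_config")
  ## default nine-trait architecture is internally consistent
  expect_s3_class(sim_config(), "sim_config")
})

test_that("pedigree simulation yields founders-only and valid generations", {
  cfg1 <- tiny_cfg(2, n_generations = 1L, n_females_per_gen = 3L,
                   n_males_per_gen = 1L)
  ped <- simulate_pedigree(cfg1)
  expect_equal(nrow(ped), 4L)
  expect_true(all(is.na(ped$sire) & is.na(ped$dam)))
  ## every animal's generation exceeds both parents', exhaustively
  cfg3 <- tiny_cfg(3, n_generations = 3L)
  p3 <- simulate_pedigree(cfg3)
  gen <- setNames(p3$generation, p3$animal)
  for (i in seq_len(nrow(p3))) {
    if (!is.na(p3$sire[i])) expect_gt(gen[i], gen[p3$sire[i]])
    if (!is.na(p3$dam[i])) expect_gt(gen[i], gen[p3$dam[i]])
  }
  ## deterministic under a fixed seed
  expect_identical(simulate_pedigree(cfg3), simulate_pedigree(cfg3))
  ## phenotype/genotype flags are female-only
  expect_true(all(p3$sex[p3$phenotyped] == "F"))
  expect_true(all(p3$sex[p3$genotyped] == "F"))
})

test_that("gene dropping is Mendelian at a single locus", {
  ## one SNP at founder MAF 0.5: offspring of two hets segregates 1:2:1
  cfg <- tiny_cfg(4, n_generations = 2L, n_females_per_gen = 2000L,
                  n_males_per_gen = 2L, n_snps_per_chrom = 1L,
                  founder_maf_range = c(0.5, 0.5),
                  genotyped_fraction_last_gens = 1)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ## find offspring whose two parents are both heterozygous
  qg <- attr(geno, "qtl_geno")  ## single SNP is also the QTL here
  full <- qg[ped$animal, 1]
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  off <- which(!is.na(si) & !is.na(di) & full[si] == 1 & full[di] == 1)
  expect_gt(length(off), 200)
  tab <- tabulate(full[off] + 1L, nbins = 3L) / length(off)
  expect_equal(tab, c(0.25, 0.5, 0.25), tolerance = 0.08)
})

test_that("complete linkage transmits parental haplotypes intact", {
  ## chromosome of 2 Mb -> recombination fraction ~ 0.02; with the map on a
  ## near-zero genetic length, transmitted chromosomes match one parental
  ## haplotype at almost every locus
  cfg <- tiny_cfg(5, n_generations = 2L, n_females_per_gen = 60L,
                  n_males_per_gen = 6L, n_snps_per_chrom = 30L,
                  chrom_length_bp = 1e5,  ## 0.001 Morgan
                  genotyped_fraction_last_gens = 1)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  cnt <- geno$counts
  ## r2 between adjacent SNPs is preserved across generations: compare
  ## founder-haplotype LD with genotype LD in the last generation
  r2 <- ld_r2(geno, "1")
  adj <- r2[r2$dist_bp > 0, ]
  ## no recombination: LD cannot decay with distance on this chromosome
  expect_gt(mean(adj$r2, na.rm = TRUE),
            0.5 * mean(adj$r2[adj$dist_bp < 2e4], na.rm = TRUE))
})

test_that("LD decays monotonically with distance in expectation", {
  cfg <- tiny_cfg(6, n_generations = 2L, n_females_per_gen = 450L,
                  n_males_per_gen = 50L, n_snps_per_chrom = 150L,
                  chrom_length_bp = 5e7, genotyped_fraction_last_gens = 1)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  r2 <- ld_r2(geno, "1")
  r2 <- r2[r2$dist_bp > 0, ]
  bins <- cut(r2$dist_bp, c(0, 1e5, 2e5, 3e5, 5e5, 1e6, 5e7))
  mu <- tapply(r2$r2, bins, mean, na.rm = TRUE)
  expect_true(all(diff(mu) < 0))
  ## calibrated to roughly 0.2 at 0.3 Mb
  expect_gt(mu[3], 0.1); expect_lt(mu[3], 0.35)
})

test_that("trait identities hold for every record before and after editing", {
  cfg <- sim_config(seed = 7, n_generations = 2, n_females_per_gen = 300,
                    n_males_per_gen = 20, genotyped_fraction_last_gens = 0.3,
                    n_chromosomes = 1, n_snps_per_chrom = 30)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  recs <- simulate_traits(ped, geno, cfg)
  expect_true(all(recs$TNB == recs$NBA + recs$NSB + recs$MUMM))
  expect_true(all(recs$NBA == recs$NHB + recs$NWB + recs$NDF))
  expect_equal(recs$rNHB, round(100 * recs$NHB / pmax(recs$TNB, 1), 1))
  ed <- apply_edit_rules(recs)
  expect_true(all(ed$TNB == ed$NBA + ed$NSB + ed$MUMM))
  expect_true(all(ed$NBA == ed$NHB + ed$NWB + ed$NDF))
  expect_true(all(ed$TNB >= 4 & ed$TNB <= 22))
  expect_true(all(ed$parity <= 8))
  rep_ <- attr(ed, "edit_report")
  expect_equal(rep_$n_out, rep_$n_in - rep_$n_removed_small_tnb)
})

test_that("editing rules handle the documented boundary cases", {
  recs <- data.frame(animal = c("a", "b", "c", "d"),
                     parity = c(1, 9, 2, 3),
                     TNB = c(3, 25, 13, 22),
                     NBA = c(2, 22, 11, 20), NHB = c(2, 20, 10, 18),
                     NWB = c(0, 1, 1, 1), NDF = c(0, 1, 0, 1),
                     NSB = c(1, 2, 1, 1), MUMM = c(0, 1, 1, 1),
                     rNHB = c(66.7, 80, 76.9, 81.8))
  ed <- apply_edit_rules(recs)
  expect_false("a" %in% ed$animal)            ## TNB = 3 removed
  expect_equal(ed$TNB[ed$animal == "b"], 22)  ## 25 capped to 22
  expect_equal(ed$parity[ed$animal == "b"], 8)
  expect_equal(ed$TNB[ed$animal == "c"], 13)  ## untouched
  expect_equal(ed$TNB[ed$animal == "d"], 22)  ## boundary stays
  ## identities survive the cap
  expect_true(all(ed$TNB == ed$NBA + ed$NSB + ed$MUMM))
  expect_true(all(ed$NBA == ed$NHB + ed$NWB + ed$NDF))
  r <- attr(ed, "edit_report")
  expect_equal(r$n_removed_small_tnb, 1L)
  expect_equal(r$n_capped_tnb, 1L)
  expect_equal(r$n_parity_capped, 1L)
  expect_error(apply_edit_rules(transform(recs, TNB = c(-1, 5, 5, 5))),
               class = "ssblup_validation")
})

test_that("zero heritability gives zero breeding values", {
  cfg <- tiny_cfg(8, h2 = 0, rep_ = 0.1)
  ped <- simulate_pedigree(cfg)
  recs <- simulate_traits(ped, NULL, cfg)
  expect_equal(max(abs(attr(recs, "true_bv"))), 0)
})

test_that("offspring-midparent regression recovers the target heritability", {
  cfg <- tiny_cfg(9, n_generations = 2L, n_females_per_gen = 5000L,
                  n_males_per_gen = 100L, h2 = 0.06, rep_ = 0.14)
  ped <- simulate_pedigree(cfg)
  recs <- simulate_traits(ped, NULL, cfg)
  u <- attr(recs, "true_bv")[, 1]
  ## latent single-parity phenotype without fixed effects: u + pe + e
  set.seed(99)
  sows <- ped$animal[ped$phenotyped]
  pe <- attr(recs, "true_pe")[sows, 1]
  y_lat <- u[match(sows, ped$animal)] + pe +
    rnorm(length(sows), 0, sqrt((1 - 0.14) * 11.29))
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  rows <- match(sows, ped$animal)
  mid <- (u[si[rows]] + u[di[rows]]) / 2
  ## regression of offspring BV on midparent BV ~ 1 (BV scale) and the
  ## realized additive variance matches the target within 3 SE
  expect_equal(var(u), 0.06 * 11.29, tolerance = 0.1 * 0.06 * 11.29)
  b <- coef(lm(u[rows] ~ mid))[2]
  expect_equal(unname(b), 1, tolerance = 0.15)
})

test_that("simulated genetic correlations match their target", {
  Rg <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  cfg <- sim_config(seed = 10, n_generations = 2, n_females_per_gen = 3000,
                    n_males_per_gen = 60, n_record_gens = 1,
                    genotyped_fraction_last_gens = 0,
                    trait_names = c("A", "B"), trait_means = c(A = 10, B = 10),
                    phenotypic_var_targets = c(A = 10, B = 10),
                    h2_targets = c(A = 0.06, B = 0.05),
                    repeatability_targets = c(A = 0.14, B = 0.13),
                    genetic_correlation_matrix = Rg,
                    derive_composition = FALSE,
                    n_chromosomes = 1, n_snps_per_chrom = 10,
                    qtl_var_fraction = 0)
  ped <- simulate_pedigree(cfg)
  recs <- simulate_traits(ped, NULL, cfg)
  u <- attr(recs, "true_bv")
  expect_equal(cor(u[, 1], u[, 2]), 0.9, tolerance = 0.05)
})

test_that("the full simulation chain is bit-identical under a fixed seed", {
  cfg <- tiny_cfg(11, genotyped_fraction_last_gens = 0.5,
                  qtl_var_fraction = 0.2)
  p1 <- simulate_pedigree(cfg); g1 <- simulate_genotypes(p1, cfg)
  r1 <- simulate_traits(p1, g1, cfg)
  p2 <- simulate_pedigree(cfg); g2 <- simulate_genotypes(p2, cfg)
  r2 <- simulate_traits(p2, g2, cfg)
  expect_identical(p1, p2)
  expect_identical(g1$counts, g2$counts)
  expect_identical(r1, r2)
})
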