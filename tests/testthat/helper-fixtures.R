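## shared fixture builders; everything is generated in code under fixed seeds

## random acyclic pedigree with n animals, the first nf founders
rand_ped <- function(n, nf = max(2L, n %/% 5L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    sire[i] <- as.character(sample(seq_len(i - 1L), 1L))
    dam[i] <- as.character(sample(seq_len(i - 1L), 1L))
  }
  pedigree(as.character(seq_len(n)), sire, dam)
}

## genotype matrix with polymorphic columns (counts 0/1/2), fixed gen freqs
rand_geno <- function(n, m, ids = paste0("a", seq_len(n)), seed = NULL,
                      freq_range = c(0.2, 0.8)) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    p <- runif(m, freq_range[1], freq_range[2])
    cnt <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m,
                  dimnames = list(ids, NULL))
    if (all(colMeans(cnt) > 0 & colMeans(cnt) < 2)) break
  }
  g <- genotype_set(cnt, data.frame(snp = paste0("s", seq_len(m)),
                                    chrom = "1",
                                    pos = sort(sample.int(5e6, m))))
  attr(g, "gen_freqs") <- p
  g
}

## small half-sib population with repeated records for mixed-model tests
halfsib_records <- function(n_sires = 10, n_dtrs = 100, h2 = 0.2, rep_ = 0.3,
                            sp2 = 10, parities = 3, seed = 1) {
  set.seed(seed)
  n <- n_sires + n_dtrs
  sire <- c(rep(NA_character_, n_sires),
            as.character(sample(n_sires, n_dtrs, replace = TRUE)))
  ped <- pedigree(as.character(seq_len(n)), sire, rep(NA_character_, n))
  sa <- h2 * sp2; spe <- (rep_ - h2) * sp2; se <- (1 - rep_) * sp2
  u <- numeric(n)
  u[seq_len(n_sires)] <- rnorm(n_sires, 0, sqrt(sa))
  si <- match(ped$sire, ped$animal)
  for (i in (n_sires + 1):n) u[i] <- 0.5 * u[si[i]] + rnorm(1, 0, sqrt(0.75 * sa))
  pe <- rnorm(n, 0, sqrt(spe))
  recs <- do.call(rbind, lapply((n_sires + 1):n, function(i) {
    data.frame(animal = ped$animal[i], parity = seq_len(parities),
               farm_year_month = sample(paste0("f", 1:4), parities, replace = TRUE),
               y = 10 + u[i] + pe[i] + rnorm(parities, 0, sqrt(se)))
  }))
  list(ped = ped, records = recs, true = list(u = u, sa = sa, spe = spe, se = se))
}

## tiny single-trait sim config used across tests
tiny_cfg <- function(seed, ..., trait = "TNB", h2 = 0.06, rep_ = 0.14,
                     sp2 = 11.29, mean_ = 13.77) {
  args <- list(...)
  defaults <- list(seed = seed, n_generations = 2L, n_females_per_gen = 150L,
                   n_males_per_gen = 15L, n_record_gens = 1L,
                   genotyped_fraction_last_gens = 0,
                   trait_names = trait,
                   trait_means = setNames(mean_, trait),
                   phenotypic_var_targets = setNames(sp2, trait),
                   h2_targets = setNames(h2, trait),
                   repeatability_targets = setNames(rep_, trait),
                   derive_composition = FALSE,
                   n_chromosomes = 1L, n_snps_per_chrom = 20L, n_qtl = 2L,
                   qtl_var_fraction = 0, n_farms = 3L, n_year_months = 4L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
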