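#' Run configuration for the analysis pipeline
#'
#' Collects input paths, stage switches and stage parameters. Can be read
#' from a TOML file written in sections `paths`, `stages` and `params`
#' (see [read_toml()]).
#'
#' @param pedigree,phenotypes path to the pedigree / phenotype CSV.
#' @param genotypes optional VCF (`.vcf`) or counts-table path.
#' @param genes optional BED/GFF gene table.
#' @param out_dir output directory (created if absent).
#' @param stages character subset of
#'   `c("qc", "reml", "blup", "ssgblup", "cv", "ssgwas")`.
#' @param trait trait column analysed by the model stages.
#' @param params named list of stage parameters (`cv_folds`,
#'   `gwas_iterations`, `window_bp`, `blend_g`, `threshold`, REML options).
#' @param seed integer seed used by every stochastic stage.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(pedigree, phenotypes, genotypes = NULL, genes = NULL,
                       out_dir = "ssblup_out",
                       stages = c("qc", "reml", "blup"),
                       trait = "TNB", params = list(), seed = 1L) {
  for (p in c(pedigree, phenotypes, genotypes, genes))
    assert_that(file.exists(p), "input path does not exist: ", p,
                class = "ssblup_config")
  known <- c("qc", "reml", "blup", "ssgblup", "cv", "ssgwas")
  assert_that(all(stages %in% known), "unknown stage(s): ",
              paste(setdiff(stages, known), collapse = ", "),
              class = "ssblup_config")
  defaults <- list(cv_folds = 10L, gwas_iterations = 2L, window_bp = 3e5,
                   blend_g = 0.95, threshold = 1.0, max_iter = 100L,
                   tol = 1e-6)
  params <- utils::modifyList(defaults, params)
  structure(list(pedigree = pedigree, phenotypes = phenotypes,
                 genotypes = genotypes, genes = genes, out_dir = out_dir,
                 stages = stages, trait = trait, params = params,
                 seed = as.integer(seed)), class = "run_config")
}

#' @rdname run_config
#' @param path TOML file with sections `paths`, `stages`, `params` and
#'   top-level `trait`/`seed`.
#' @export
read_run_config <- function(path) {
  tm <- read_toml(path)
  run_config(pedigree = tm$paths$pedigree, phenotypes = tm$paths$phenotypes,
             genotypes = tm$paths$genotypes, genes = tm$paths$genes,
             out_dir = tm$paths$out_dir %||% "ssblup_out",
             stages = tm$stages$enabled %||% c("qc", "reml", "blup"),
             trait = tm$trait %||% "TNB",
             params = tm$params %||% list(), seed = tm$seed %||% 1L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order
#' (qc -> reml -> blup/ssgblup -> cv -> ssgwas), writing one TSV per stage
#' plus a manifest (inputs, parameters, seed, md5 checksums of every
#' output). Stage dependencies are validated up front: enabling `cv`,
#' `blup`, `ssgblup` or `ssgwas` without `reml` (which provides variance
#' components), or `ssgblup`/`ssgwas` without genotypes, is an error before
#' any computation starts.
#'
#' @param config a [run_config()].
#' @return invisible manifest (named list), also written to
#'   `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  needs_reml <- intersect(c("blup", "ssgblup", "cv", "ssgwas"), st)
  if (length(needs_reml) && !"reml" %in% st)
    stop_ssblup("stage(s) ", paste(needs_reml, collapse = ", "),
                " require the reml stage", class = "ssblup_dependency")
  if (any(c("ssgblup", "ssgwas") %in% st) && is.null(config$genotypes))
    stop_ssblup("ssgblup/ssgwas stages require genotypes",
                class = "ssblup_dependency")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  pp <- config$params

  ped <- read_pedigree(config$pedigree)
  recs <- apply_edit_rules(read_phenotypes(config$phenotypes))
  geno <- NULL
  if (!is.null(config$genotypes)) {
    geno <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes))
      read_vcf_genotypes(config$genotypes) else read_counts_table(config$genotypes)
  }

  if ("qc" %in% st && !is.null(geno)) {
    qc <- qc_filter(geno)
    geno <- qc$genotypes
    outputs["qc_report"] <- write_tsv(
      data.frame(criterion = names(unlist(qc$report[c("n_animals_removed",
        "n_snps_removed", "n_fail_maf", "n_fail_hwe", "n_fail_call_rate",
        "n_fail_min_hom", "n_snps_kept", "n_animals_kept")])),
        count = unlist(qc$report[c("n_animals_removed", "n_snps_removed",
        "n_fail_maf", "n_fail_hwe", "n_fail_call_rate", "n_fail_min_hom",
        "n_snps_kept", "n_animals_kept")])),
      file.path(config$out_dir, "qc_report.tsv"))
  }

  vc <- NULL; fit_blup <- NULL; fit_ss <- NULL
  Ainv <- a_inverse(ped)
  fml <- stats::as.formula(paste(config$trait, "~ farm_year_month + parity"))
  if ("reml" %in% st) {
    design <- build_design(recs, config$trait, ped)
    vc <- em_reml(design, Ainv, max_iter = pp$max_iter, tol = pp$tol)
    s <- summarize_components(vc)
    outputs["reml"] <- write_tsv(
      data.frame(parameter = c("sigma_a2", "sigma_pe2", "sigma_e2",
                               "sigma_p2", "h2", "repeatability"),
                 estimate = c(vc$sigma_a2, vc$sigma_pe2, vc$sigma_e2,
                              vc$sigma_p2, s$unrounded["h2"],
                              s$unrounded["repeatability"]),
                 se = c(vc$se, NA, s$se %||% c(NA, NA))),
      file.path(config$out_dir, "reml.tsv"))
  }

  hinv <- NULL
  if (any(c("ssgblup", "cv", "ssgwas") %in% st) && !is.null(geno)) {
    ids <- rownames(geno$counts)
    A22 <- a_submatrix(ped, ids)
    A22inv <- chol2inv(chol(A22)); dimnames(A22inv) <- dimnames(A22)
    G <- vanraden_g(geno)
    Ginv <- blend_and_invert(G, A22, blend_g = pp$blend_g)
    hinv <- h_inverse(Ainv, A22inv, Ginv)
  }

  if ("blup" %in% st) {
    fit_blup <- fit_animal_model(fml, recs, ped, vc = vc)
    outputs["blup_solutions"] <- write_tsv(
      breeding_values(fit_blup), file.path(config$out_dir, "blup_solutions.tsv"))
  }
  if ("ssgblup" %in% st) {
    design <- build_design(recs, config$trait, ped)
    fit <- solve_mme(design, hinv, vc)
    outputs["ssgblup_solutions"] <- write_tsv(
      data.frame(animal = names(fit$a), gebv = unname(fit$a)),
      file.path(config$out_dir, "ssgblup_solutions.tsv"))
  }
  if ("cv" %in% st) {
    cv_b <- kfold_cv(recs, config$trait, ped, Ainv, vc, k = pp$cv_folds,
                     seed = config$seed, method = "BLUP")
    tab <- data.frame(trait = config$trait, rg_blup = cv_b$mean_rg,
                      rg_ssgblup = NA_real_, increase_pct = NA_real_)
    if (!is.null(hinv)) {
      gids <- rownames(geno$counts)
      cv_s <- kfold_cv(recs, config$trait, ped, hinv, vc, k = pp$cv_folds,
                       seed = config$seed, accuracy_ids = gids,
                       method = "ssGBLUP")
      cv_b2 <- kfold_cv(recs, config$trait, ped, Ainv, vc, k = pp$cv_folds,
                        seed = config$seed, accuracy_ids = gids,
                        method = "BLUP")
      imp <- improvement_report(cv_b2, cv_s, trait = config$trait)
      tab <- data.frame(trait = config$trait, rg_blup = imp$rg_base,
                        rg_ssgblup = imp$rg_new,
                        increase_pct = imp$increase_pct)
    }
    outputs["cv"] <- write_tsv(tab, file.path(config$out_dir, "cv.tsv"))
  }
  if ("ssgwas" %in% st) {
    gw <- run_weighted_ssgwas(recs, config$trait, ped, geno, vc,
                              n_iterations = pp$gwas_iterations,
                              window_bp = pp$window_bp, blend_g = pp$blend_g)
    last <- gw$iterations[[length(gw$iterations)]]
    outputs["ssgwas_scan"] <- write_tsv(last$scan,
      file.path(config$out_dir, "ssgwas_scan.tsv"))
    cand <- call_candidate_windows(last$scan, threshold = pp$threshold)
    if (!is.null(config$genes) && nrow(cand)) {
      genes <- read_gene_table(config$genes)
      gmap <- map_candidate_genes(cand, genes)
      cand$genes <- vapply(seq_len(nrow(cand)), function(i) {
        hit <- gmap$gene[gmap$chrom == cand$chrom[i] &
                         gmap$top_snp_pos == cand$top_snp_pos[i]]
        paste(hit, collapse = ",")
      }, "")
    }
    outputs["ssgwas_candidates"] <- write_tsv(cand,
      file.path(config$out_dir, "ssgwas_candidates.tsv"))
  }

  manifest <- data.frame(
    key = c("trait", "seed", paste0("input_", c("pedigree", "phenotypes",
            "genotypes", "genes")), paste0("output_", names(outputs)),
            paste0("md5_", names(outputs))),
    value = c(config$trait, config$seed, config$pedigree, config$phenotypes,
              config$genotypes %||% "", config$genes %||% "",
              unname(outputs),
              unname(tools::md5sum(unname(outputs)))))
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}
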