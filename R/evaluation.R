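#' Expected accuracy from prediction error variance
#'
#' `Rg = sqrt(1 - PEV / sigma_a2)`, the expected accuracy of a predicted
#' breeding value. Values with `PEV > sigma_a2` (possible for animals with
#' almost no information under strong shrinkage) are clipped to 0. Setting
#' `sqrt = FALSE` returns the reliability-style reading `1 - PEV/sigma_a2`
#' instead.
#'
#' @param pev prediction error variance(s), >= 0.
#' @param sigma_a2 additive genetic variance, > 0.
#' @param sqrt take the square root (default TRUE).
#' @return accuracy in `[0, 1]`, same length as `pev`.
#' @export
accuracy_from_pev <- function(pev, sigma_a2, sqrt = TRUE) {
  assert_that(sigma_a2 > 0, "sigma_a2 must be positive", class = "ssblup_domain")
  assert_that(all(pev >= 0), "PEV must be non-negative", class = "ssblup_domain")
  rel <- pmax(0, 1 - pev / sigma_a2)
  if (sqrt) base::sqrt(rel) else rel
}

#' K-fold cross-validated expected accuracy
#'
#' Animals with phenotypes are split into `k` folds (all records of an
#' animal move together, so permanent-environment information cannot leak).
#' For each fold the validation animals' records are removed, the mixed
#' model equations are re-solved with the variance components held fixed,
#' and the validation animals' expected accuracy is computed from their
#' prediction error variance. The per-fold mean accuracy is averaged over
#' folds.
#'
#' @param records trait records.
#' @param trait trait column.
#' @param ped a [pedigree()].
#' @param rel_inv relationship inverse ([a_inverse()] for pedigree BLUP or
#'   [h_inverse()] for single-step GBLUP).
#' @param vc [variance_components()], fixed across folds (conventionally
#'   the full-data REML estimates).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param accuracy_ids optional subset of animal ids over which fold
#'   accuracies are averaged (e.g. only genotyped animals); default all
#'   validation animals.
#' @param method label stored in the result.
#' @return object of class `accuracy_result`: `method`, `fold_mean_rg`
#'   (length k), `mean_rg`, `se`, `per_animal` (data frame animal, fold,
#'   pev, rg).
#' @export
kfold_cv <- function(records, trait, ped, rel_inv, vc, k = 10L,
                     seed = 1L, accuracy_ids = NULL, method = "model") {
  assert_that(k >= 2, "need at least 2 folds")
  keep <- !is.na(records[[trait]])
  animals <- sort(unique(as.character(records$animal[keep])))
  assert_that(length(animals) >= k, "fewer phenotyped animals than folds",
              class = "ssblup_partition")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(animals)))
  names(fold) <- animals
  if (is.null(accuracy_ids)) accuracy_ids <- animals
  accuracy_ids <- intersect(as.character(accuracy_ids), animals)
  assert_that(length(accuracy_ids) > 0, "no accuracy_ids with phenotypes",
              class = "ssblup_partition")

  per_animal <- list()
  fold_means <- numeric(k)
  for (f in seq_len(k)) {
    val <- animals[fold == f]
    train <- records[keep & !(as.character(records$animal) %in% val), ,
                     drop = FALSE]
    des <- build_design(train, trait, ped)
    ids_eval <- intersect(val, accuracy_ids)
    if (length(ids_eval) == 0L) { fold_means[f] <- NA_real_; next }
    fit <- solve_mme(des, rel_inv, vc, pev_for = ids_eval)
    rg <- accuracy_from_pev(fit$pev, vc$sigma_a2)
    fold_means[f] <- mean(rg)
    per_animal[[f]] <- data.frame(animal = ids_eval, fold = f,
                                  pev = unname(fit$pev), rg = unname(rg))
  }
  ok <- !is.na(fold_means)
  structure(list(method = method, k = k, seed = seed,
                 fold_mean_rg = fold_means,
                 mean_rg = mean(fold_means[ok]),
                 se = sd(fold_means[ok]) / sqrt(sum(ok)),
                 per_animal = do.call(rbind, per_animal)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("%s: mean Rg = %.3f (SE %.3f) over %d folds\n",
              x$method, x$mean_rg, x$se, x$k))
  invisible(x)
}

#' Accuracy improvement of one model over another
#'
#' Percentage increase of the cross-validated expected accuracy, reported
#' to two decimals: `100 * (Rg_new - Rg_base) / Rg_base`.
#'
#' @param base,new [kfold_cv()] results (or bare accuracies) for the same
#'   trait and folds; `base` is the reference (pedigree BLUP in the usual
#'   comparison).
#' @param trait optional trait label.
#' @return one-row data frame `trait, rg_base, rg_new, increase_pct`;
#'   `increase_pct` is `NA` when the reference accuracy is 0.
#' @export
improvement_report <- function(base, new, trait = NA_character_) {
  rb <- if (inherits(base, "accuracy_result")) base$mean_rg else as.numeric(base)
  rn <- if (inherits(new, "accuracy_result")) new$mean_rg else as.numeric(new)
  inc <- ifelse(rb == 0, NA_real_, round_half_up(100 * (rn - rb) / rb, 2))
  data.frame(trait = trait, rg_base = rb, rg_new = rn, increase_pct = inc)
}
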