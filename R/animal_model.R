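#' Fit a repeatability animal model (pedigree BLUP or single-step GBLUP)
#'
#' The central fitting function of the package. The model is
#' `y = X b + Z a + W t + e` with fixed effects given by the formula's
#' right-hand side, an additive genetic effect `a` for every pedigree
#' animal (variance `sigma_a2 * A`, or `sigma_a2 * H` when genotypes are
#' supplied), a permanent-environment effect `t` per sow with records, and
#' an iid residual. Variance components are estimated by [em_reml()] unless
#' supplied; solutions come from Henderson's mixed model equations.
#'
#' @param formula e.g. `TNB ~ farm_year_month + parity`; the right-hand
#'   side must name factor columns of `data`.
#' @param data record data frame with an `animal` column.
#' @param ped a [pedigree()] covering every recorded animal.
#' @param genotypes optional post-QC [genotype_set()]; when present the
#'   relationship is the single-step H built from the blended VanRaden G.
#' @param vc optional fixed [variance_components()]; when `NULL` they are
#'   estimated by REML.
#' @param pev compute prediction error variances: `FALSE`, `TRUE` (all
#'   pedigree animals) or a vector of animal ids.
#' @param blend_g,tune genomic blending parameters (see
#'   [blend_and_invert()]).
#' @param ... passed to [em_reml()] (`max_iter`, `tol`, `acceleration`,
#'   `start`, `verbose`).
#' @return object of class `animal_model` with components `vc`,
#'   `solutions` (`b`, `a`, `t`), `pev`, `design` metadata and the REML
#'   trace; supported methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `logLik`, `plot`, `simulate` and
#'   [breeding_values()].
#' @export
fit_animal_model <- function(formula, data, ped, genotypes = NULL,
                             vc = NULL, pev = FALSE,
                             blend_g = 0.95, tune = TRUE, ...) {
  mf <- stats::terms(formula)
  trait <- as.character(attr(mf, "variables"))[2L]
  fixed <- attr(mf, "term.labels")
  assert_that(all(fixed %in% names(data)),
              "fixed effect column(s) missing from data: ",
              paste(setdiff(fixed, names(data)), collapse = ", "))

  rel_kind <- "pedigree"
  Ainv <- a_inverse(ped)
  rel_inv <- Ainv
  if (!is.null(genotypes)) {
    ids <- rownames(genotypes$counts)
    A22 <- a_submatrix(ped, ids)
    A22inv <- chol2inv(chol(A22)); dimnames(A22inv) <- dimnames(A22)
    G <- vanraden_g(genotypes)
    Ginv <- blend_and_invert(G, A22, blend_g = blend_g, tune = tune)
    rel_inv <- h_inverse(Ainv, A22inv, Ginv)
    attr(rel_inv, "log_det_A") <- NULL  ## determinant recomputed when needed
    rel_kind <- "single-step"
  }

  design <- build_design(data, trait, ped, fixed = fixed)
  if (is.null(vc)) vc <- em_reml(design, rel_inv, ...)
  pev_for <- if (isTRUE(pev)) "all" else if (isFALSE(pev)) NULL else pev
  fit <- solve_mme(design, rel_inv, vc, pev_for = pev_for)

  structure(list(call = match.call(), formula = formula, trait = trait,
                 fixed = fixed, relationship = rel_kind, vc = vc,
                 solutions = list(b = fit$b, a = fit$a, t = fit$t),
                 pev = fit$pev, fitted = fit$fitted,
                 residuals = fit$residuals, resid_norm = fit$resid_norm,
                 n = design$n, p = design$p,
                 n_animals = length(fit$a), n_sows = length(fit$t),
                 design = design, rel_inv = rel_inv, ped = ped),
            class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  cat(sprintf("repeatability animal model (%s relationships)\n", x$relationship))
  cat(sprintf("  trait: %s, %d records on %d sows, %d pedigree animals\n",
              x$trait, x$n, x$n_sows, x$n_animals))
  s <- summarize_components(x$vc)
  cat(sprintf("  sigma_a2 %.3f  sigma_pe2 %.3f  sigma_e2 %.3f  h2 %.2f  Re %.2f\n",
              x$vc$sigma_a2, x$vc$sigma_pe2, x$vc$sigma_e2,
              s$h2, s$repeatability))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  s <- summarize_components(object$vc)
  vc_tab <- data.frame(
    component = c("sigma_a2", "sigma_pe2", "sigma_e2", "sigma_p2"),
    estimate = c(object$vc$sigma_a2, object$vc$sigma_pe2,
                 object$vc$sigma_e2, object$vc$sigma_p2),
    se = c(object$vc$se %||% rep(NA_real_, 3), NA_real_))
  structure(list(model = object, vc_table = vc_tab, ratios = s,
                 converged = attr(object$vc, "converged") %||% NA,
                 iterations = attr(object$vc, "iterations") %||% NA),
            class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, ...) {
  print(x$model)
  cat("\nVariance components:\n")
  print(x$vc_table, row.names = FALSE, digits = 4)
  cat(sprintf("\nh2 = %.2f", x$ratios$h2))
  if (!is.null(x$ratios$se)) cat(sprintf(" (SE %.3f)", x$ratios$se["h2"]))
  cat(sprintf("; repeatability = %.2f", x$ratios$repeatability))
  if (!is.null(x$ratios$se))
    cat(sprintf(" (SE %.3f)", x$ratios$se["repeatability"]))
  cat("\n")
  if (!is.na(x$converged))
    cat(sprintf("REML %s after %d iterations\n",
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                x$iterations))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$solutions$b

#' @export
fitted.animal_model <- function(object, ...) object$fitted

#' @export
residuals.animal_model <- function(object, ...) object$residuals

#' @export
logLik.animal_model <- function(object, ...) {
  m2 <- attr(object$vc, "m2ll")
  val <- if (is.null(m2)) NA_real_ else -m2 / 2
  structure(val, df = 3L, class = "logLik")
}

#' Estimated breeding values of a fitted animal model
#'
#' @param object an `animal_model`.
#' @param ids animals to return (default all).
#' @return data frame `animal`, `ebv`, and `pev`/`accuracy` when PEV were
#'   computed at fit time.
#' @export
breeding_values <- function(object, ids = NULL) {
  stopifnot(inherits(object, "animal_model"))
  a <- object$solutions$a
  if (!is.null(ids)) a <- a[as.character(ids)]
  out <- data.frame(animal = names(a), ebv = unname(a))
  if (!is.null(object$pev)) {
    pv <- object$pev[out$animal]
    out$pev <- unname(pv)
    out$accuracy <- accuracy_from_pev(pmax(0, out$pev), object$vc$sigma_a2)
  }
  out
}

#' @export
predict.animal_model <- function(object, newdata = NULL,
                                 type = c("record", "ebv"), ...) {
  type <- match.arg(type)
  if (type == "ebv") {
    ids <- if (is.null(newdata)) names(object$solutions$a) else
      as.character(newdata)
    return(object$solutions$a[ids])
  }
  if (is.null(newdata)) return(object$fitted)
  b <- object$solutions$b
  yhat <- numeric(nrow(newdata)) + b[["(Intercept)"]]
  for (f in object$fixed) {
    lev <- as.character(newdata[[f]])
    cn <- paste0(f, lev)
    contrib <- ifelse(cn %in% names(b), b[cn], 0)
    contrib[is.na(contrib)] <- 0
    yhat <- yhat + contrib
  }
  a <- object$solutions$a[as.character(newdata$animal)]
  t_ <- object$solutions$t[as.character(newdata$animal)]
  t_[is.na(t_)] <- 0
  assert_that(!anyNA(a), "newdata contains animals absent from the pedigree",
              class = "ssblup_index")
  as.numeric(yhat + a + t_)
}

#' @export
plot.animal_model <- function(x, ...) {
  tr <- attr(x$vc, "trace")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(tr)) {
    graphics::plot(tr$iter, tr$m2ll, type = "b", xlab = "REML iteration",
                   ylab = "-2 log L", main = "REML convergence", ...)
  } else {
    graphics::plot.new(); graphics::title("no REML trace (fixed components)")
  }
  graphics::hist(x$solutions$a, breaks = 40, main = "EBV distribution",
                 xlab = "EBV")
  invisible(x)
}

#' @export
simulate.animal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  ped <- object$ped
  vc <- object$vc
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  ms <- 1 - 0.25 * (!is.na(si)) - 0.25 * (!is.na(di))
  Xb <- as.numeric(des$X %*% object$solutions$b)
  n <- des$n
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    a <- numeric(nrow(ped))
    noise <- rnorm(nrow(ped), 0, sqrt(ms * vc$sigma_a2))
    for (i in seq_len(nrow(ped))) {
      pa <- 0
      if (!is.na(si[i])) pa <- pa + 0.5 * a[si[i]]
      if (!is.na(di[i])) pa <- pa + 0.5 * a[di[i]]
      a[i] <- pa + noise[i]
    }
    t_ <- rnorm(length(des$pe_ids), 0, sqrt(vc$sigma_pe2))
    out[, s] <- Xb + as.numeric(des$Za %*% a) + as.numeric(des$W %*% t_) +
      rnorm(n, 0, sqrt(vc$sigma_e2))
  }
  colnames(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}
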