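#' Design matrices for the repeatability animal model
#'
#' Builds the incidence matrices of the model
#' `y = X b + Z a + W t + e`: `X` for the fixed effects (intercept plus
#' treatment-contrast dummies, i.e. the first level of every factor is the
#' reference constrained to zero), `Z` mapping records to all pedigree
#' animals (animals without records keep an all-zero column so their
#' breeding values are still predicted), and `W` mapping records to the
#' permanent-environment effect of each sow with records.
#'
#' Factor levels are ordered by `sort()` so the construction is
#' deterministic regardless of record order.
#'
#' @param records data frame with at least `animal` plus the fixed-effect
#'   columns and the trait column(s).
#' @param trait name of the response column.
#' @param ped a [pedigree()] containing every record's animal.
#' @param fixed character vector of fixed-effect factor columns.
#' @return list with `X`, `Za`, `W` (sparse), response `y`, ids and indexing
#'   helpers. Records with missing response are dropped.
#' @export
build_design <- function(records, trait, ped,
                         fixed = intersect(c("farm_year_month", "parity"),
                                           names(records))) {
  assert_that(trait %in% names(records), "trait column '", trait, "' not found")
  assert_that("animal" %in% names(records), "records need an 'animal' column")
  keep <- !is.na(records[[trait]])
  records <- records[keep, , drop = FALSE]
  assert_that(nrow(records) > 0, "no non-missing records for trait ", trait)
  n <- nrow(records)

  if (length(fixed)) {
    fml <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
    fdat <- records[, fixed, drop = FALSE]
    for (f in fixed) fdat[[f]] <- factor(fdat[[f]], levels = sort(unique(fdat[[f]])))
    X <- Matrix::sparse.model.matrix(fml, data = fdat)
  } else {
    X <- Matrix::Matrix(1, n, 1, sparse = TRUE, dimnames = list(NULL, "(Intercept)"))
  }

  a_idx <- ped_index(ped, records$animal)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = a_idx, x = 1,
                             dims = c(n, nrow(ped)),
                             dimnames = list(NULL, ped$animal))
  pe_ids <- ped$animal[sort(unique(a_idx))]
  W <- Matrix::sparseMatrix(i = seq_len(n), j = match(records$animal, pe_ids),
                            x = 1, dims = c(n, length(pe_ids)),
                            dimnames = list(NULL, pe_ids))
  list(X = as(X, "CsparseMatrix"), Za = Za, W = W,
       y = as.numeric(records[[trait]]),
       n = n, p = ncol(X),
       trait = trait, fixed = fixed,
       animal_ids = ped$animal, pe_ids = pe_ids,
       records = records[, c("animal", fixed), drop = FALSE])
}
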