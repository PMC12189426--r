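#' Pedigree construction and validation
#'
#' Build a validated, topologically sorted pedigree from animal/sire/dam
#' triples. Unknown parents may be given as `NA`, `0` or `""`; they are
#' normalised to `NA`. Rows may arrive in any order: the constructor reorders
#' them so that every parent precedes its offspring, and fails with a
#' `ssblup_pedigree_cycle` error (naming one offending animal) if the parent
#' graph contains a cycle.
#'
#' @param animal,sire,dam vectors of animal identifiers (character or
#'   integer-like). `sire` and `dam` entries that do not appear in `animal`
#'   are added as founders.
#' @param sex optional per-animal sex (`"M"`/`"F"`), kept as metadata.
#' @param generation optional integer generation index per animal.
#' @return An object of class `pedigree` (a data frame with columns
#'   `animal`, `sire`, `dam` in topological order plus optional metadata
#'   columns). Attribute `id_index` maps id to row.
#' @export
pedigree <- function(animal, sire, dam, sex = NULL, generation = NULL) {
  animal <- normalize_id(animal)
  sire <- normalize_id(sire)
  dam <- normalize_id(dam)
  assert_that(length(animal) == length(sire) && length(animal) == length(dam),
              "animal, sire and dam must have the same length")
  assert_that(!anyNA(animal), "animal ids must not be missing")
  if (anyDuplicated(animal))
    stop_ssblup("duplicate animal id: ", animal[duplicated(animal)][1L],
                class = "ssblup_pedigree_duplicate")

  ## parents not listed as animals become founders, prepended
  extra <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
    if (!is.null(sex)) sex <- c(rep(NA_character_, length(extra)), as.character(sex))
    if (!is.null(generation)) generation <- c(rep(NA_integer_, length(extra)), generation)
  }

  ord <- topo_order(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) ped$sex <- as.character(sex)[ord]
  if (!is.null(generation)) ped$generation <- as.integer(generation)[ord]
  attr(ped, "id_index") <- setNames(seq_len(nrow(ped)), ped$animal)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalize_id <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "0", "NA")] <- NA_character_
  x
}

## Kahn topological sort over the parent->offspring DAG.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- setNames(seq_len(n), animal)
  si <- unname(idx[sire]); di <- unname(idx[dam])
  ## in-degree = number of (known) parents
  indeg <- (!is.na(si)) + (!is.na(di))
  ## children adjacency
  childs <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) childs[[si[i]]] <- c(childs[[si[i]]], i)
    if (!is.na(di[i])) childs[[di[i]]] <- c(childs[[di[i]]], i)
  }
  queue <- integer(n)
  roots <- which(indeg == 0L)
  queue[seq_along(roots)] <- roots
  head <- 1L; tail <- length(roots)
  out <- integer(n); nout <- 0L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    nout <- nout + 1L
    out[nout] <- v
    for (ch in childs[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) { tail <- tail + 1L; queue[tail] <- ch }
    }
  }
  if (nout < n) {
    bad <- animal[setdiff(seq_len(n), out[seq_len(nout)])][1L]
    stop_ssblup("pedigree contains a cycle involving animal ", bad,
                class = "ssblup_pedigree_cycle")
  }
  out[seq_len(n)]
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree with", nrow(x), "animals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders )\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

ped_index <- function(ped, ids) {
  idx <- attr(ped, "id_index")[as.character(ids)]
  if (anyNA(idx))
    stop_ssblup("unknown animal id(s): ",
                paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "),
                class = "ssblup_lookup")
  unname(idx)
}

#' Additive relationship matrix by the tabular method
#'
#' Recursively fills Wright's numerator relationship matrix A. Intended for
#' desk-scale pedigrees (dense storage); it is the oracle against which the
#' sparse inverse is checked and the engine behind [a_submatrix()] for small
#' problems.
#'
#' @param ped a [pedigree()].
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
a_matrix <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients (Meuwissen and Luo)
#'
#' Computes per-animal inbreeding coefficients F with the Meuwissen & Luo
#' (1992) algorithm, i.e. diag(A) - 1 without forming A.
#'
#' @param ped a [pedigree()].
#' @return numeric vector of F, named by animal id.
#' @export
inbreeding <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  F <- numeric(n)
  Dvec <- numeric(n)  ## Mendelian sampling variances
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Fs <- if (is.na(s)) -1 else F[s]
    Fd <- if (is.na(d)) -1 else F[d]
    Dvec[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (is.na(s) || is.na(d)) { F[i] <- 0; next }
    ## a_ii = sum over {i and its ancestors} of L_j^2 D_j, accumulated by
    ## popping nodes in decreasing pedigree order (parents precede offspring)
    nodes <- i; lvals <- 1
    aii <- 0
    while (length(nodes)) {
      k <- which.max(nodes)
      j <- nodes[k]; lj <- lvals[k]
      nodes <- nodes[-k]; lvals <- lvals[-k]
      aii <- aii + lj * lj * Dvec[j]
      for (par in c(si[j], di[j])) {
        if (is.na(par)) next
        m <- match(par, nodes)
        if (is.na(m)) { nodes <- c(nodes, par); lvals <- c(lvals, 0.5 * lj) }
        else lvals[m] <- lvals[m] + 0.5 * lj
      }
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$animal
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules. With
#' `with_inbreeding = TRUE` (default) the Mendelian-sampling variances use
#' Meuwissen-Luo inbreeding coefficients of the parents; otherwise parents
#' are treated as non-inbred.
#'
#' @param ped a [pedigree()].
#' @param with_inbreeding logical.
#' @return sparse symmetric `Matrix::dgCMatrix` with dimnames = animal ids,
#'   attribute `log_det_A` = log determinant of A (not of the inverse) and
#'   attribute `inbreeding` (F used).
#' @export
a_inverse <- function(ped, with_inbreeding = TRUE) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  F <- if (with_inbreeding) inbreeding(ped) else setNames(numeric(n), ped$animal)
  Fs <- ifelse(is.na(si), -1, F[ifelse(is.na(si), 1L, si)])
  Fd <- ifelse(is.na(di), -1, F[ifelse(is.na(di), 1L, di)])
  dinv <- 1 / (0.5 - 0.25 * (Fs + Fd))

  ## triplets: for each animal i with parents s,d add
  ##   dinv to (i,i); -dinv/2 to (i,s),(i,d); dinv/4 to (s,s),(d,d),(s,d)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  has_s <- !is.na(si); has_d <- !is.na(di)
  i_all <- seq_len(n)
  add(i_all, i_all, dinv)
  add(i_all[has_s], si[has_s], -0.5 * dinv[has_s])
  add(si[has_s], i_all[has_s], -0.5 * dinv[has_s])
  add(i_all[has_d], di[has_d], -0.5 * dinv[has_d])
  add(di[has_d], i_all[has_d], -0.5 * dinv[has_d])
  add(si[has_s], si[has_s], 0.25 * dinv[has_s])
  add(di[has_d], di[has_d], 0.25 * dinv[has_d])
  b <- has_s & has_d
  add(si[b], di[b], 0.25 * dinv[b])
  add(di[b], si[b], 0.25 * dinv[b])

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- as(Ainv, "CsparseMatrix")
  attr(Ainv, "log_det_A") <- -sum(log(dinv))
  attr(Ainv, "inbreeding") <- F
  Ainv
}

#' Relationship submatrix for a subset of animals (A22)
#'
#' Dense block of the numerator relationship matrix among `ids`. For small
#' pedigrees the tabular method is run on the subset's ancestor closure; for
#' large ones the block is obtained by solving the sparse A-inverse for the
#' subset's unit vectors (Colleau's indirect method), which is algebraically
#' identical.
#'
#' @param ped a [pedigree()].
#' @param ids animal ids (must exist in `ped`).
#' @param method `"auto"`, `"tabular"` or `"solve"`.
#' @return dense symmetric matrix with dimnames = `ids`.
#' @export
a_submatrix <- function(ped, ids, method = c("auto", "tabular", "solve")) {
  method <- match.arg(method)
  ids <- as.character(ids)
  idx <- ped_index(ped, ids)
  anc <- ancestor_closure(ped, idx)
  if (method == "auto")
    method <- if (length(anc) <= 3000L) "tabular" else "solve"
  if (method == "tabular") {
    sub <- ped[anc, , drop = FALSE]
    subped <- pedigree(sub$animal,
                       ifelse(sub$sire %in% sub$animal, sub$sire, NA),
                       ifelse(sub$dam %in% sub$animal, sub$dam, NA))
    A <- a_matrix(subped)
    return(A[ids, ids, drop = FALSE])
  }
  Ainv <- a_inverse(ped)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ainv), LDL = FALSE)
  n <- nrow(ped)
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  blk <- 500L
  for (start in seq(1L, length(ids), by = blk)) {
    cols <- start:min(start + blk - 1L, length(ids))
    E <- Matrix::sparseMatrix(i = idx[cols], j = seq_along(cols),
                              x = 1, dims = c(n, length(cols)))
    X <- as.matrix(Matrix::solve(ch, E, system = "A"))
    out[, cols] <- X[idx, , drop = FALSE]
  }
  (out + t(out)) / 2
}

## indices of ids plus all their ancestors, in pedigree order
ancestor_closure <- function(ped, idx) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  keep <- logical(nrow(ped))
  keep[idx] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  which(keep)
}

#' Read / write pedigree CSV
#'
#' CSV with header `animal,sire,dam` (extra columns such as `sex` and
#' `generation` are preserved). Unknown parents may be coded `0` or empty;
#' both normalise to unknown. The writer codes unknown parents as `0`, so
#' files round-trip.
#'
#' @param path file path.
#' @param unknown code written for unknown parents.
#' @return [read_pedigree()] returns a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("animal", "sire", "dam"))
    if (!col %in% names(df))
      stop_ssblup("pedigree file lacks required column '", col, "'",
                  class = "ssblup_format")
  pedigree(df$animal, df$sire, df$dam,
           sex = if ("sex" %in% names(df)) df$sex else NULL,
           generation = if ("generation" %in% names(df)) as.integer(df$generation) else NULL)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path, unknown = "0") {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- unknown
  out$dam[is.na(out$dam)] <- unknown
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a relationship matrix in coordinate text format
#'
#' Writes the lower triangle (including diagonal) of a symmetric matrix as
#' whitespace-separated `i j value` rows with ids resolved to 1-based row
#' numbers; a header line carries the ids.
#'
#' @param m matrix (dense or sparse) with dimnames.
#' @param path output file.
#' @export
write_relationship_coo <- function(m, path) {
  sm <- Matrix::tril(as(as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                        "generalMatrix"))
  tr <- Matrix::mat2triplet(sm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ids: ", paste(rownames(m), collapse = ",")), con)
  utils::write.table(data.frame(i = tr$i, j = tr$j, x = tr$x), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
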