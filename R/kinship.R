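#' Kinship matrix of a pedigree
#'
#' Computes the matrix of kinship coefficients phi by the standard recursion,
#' evaluated in topological (generation) order: for a founder
#' `phi(i,i) = 1/2` and `phi(i,j) = 0` against every other founder; for a
#' non-founder with sire f and dam m, `phi(i,i) = 1/2 (1 + phi(f,m))` and
#' `phi(i,j) = 1/2 (phi(f,j) + phi(m,j))` for any j that is not a descendant
#' of i. Founders are assumed non-inbred and mutually unrelated. The additive
#' genetic covariance of the polygenic model is `2 * phi` (the numerator
#' relationship matrix).
#'
#' @param ped a `pedigree` (see [as_pedigree()]).
#' @return An object of class `kinship_matrix`: list with `ids` and the dense
#'   symmetric matrix `phi` (dimnames = ids).
#' @export
compute_kinship <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fi <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  mi <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  # rows are already in topological order (as_pedigree sorts by generation)
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    phi[i, i] <- if (f == 0L && m == 0L) 0.5 else 0.5 * (1 + phi[f, m])
    if (i > 1L) {
      js <- seq_len(i - 1L)
      pf <- if (f > 0L) phi[f, js] else 0
      pm <- if (m > 0L) phi[m, js] else 0
      v <- 0.5 * (pf + pm)
      phi[i, js] <- v
      phi[js, i] <- v
    }
  }
  structure(list(ids = ped$id, phi = phi), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", length(x$ids), "individuals; mean off-diagonal phi =",
      signif(mean_pairwise_kinship(x, x$ids), 3), "\n")
  invisible(x)
}

#' Mean pairwise kinship of a subset of individuals
#'
#' Mean of phi over unordered distinct pairs (the diagonal is excluded), the
#' quantity used to summarize how related a study cohort is.
#'
#' @param km a `kinship_matrix`.
#' @param subset character vector of ids (length >= 2).
#' @return Mean kinship coefficient (scalar).
#' @export
mean_pairwise_kinship <- function(km, subset) {
  if (!all(subset %in% km$ids)) stop("subset contains unknown ids")
  if (length(subset) < 2) stop("subset must contain at least 2 ids")
  p <- km$phi[subset, subset, drop = FALSE]
  mean(p[upper.tri(p)])
}

#' Extract the additive relationship matrix 2*phi for a set of individuals
#'
#' @param km a `kinship_matrix`.
#' @param ids ids to extract (default all).
#' @return Dense symmetric matrix `2 * phi[ids, ids]`.
#' @export
relationship_matrix <- function(km, ids = km$ids) {
  if (!all(ids %in% km$ids)) stop("unknown ids")
  2 * km$phi[ids, ids, drop = FALSE]
}

#' Write / read a kinship matrix as TSV with an id header row and column
#'
#' @param km a `kinship_matrix`.
#' @param path file path.
#' @export
write_kinship <- function(km, path) {
  df <- data.frame(id = km$ids, km$phi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df$id)
  phi <- as.matrix(df[, -1, drop = FALSE])
  dimnames(phi) <- list(ids, ids)
  structure(list(ids = ids, phi = phi), class = "kinship_matrix")
}
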