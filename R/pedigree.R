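#' Construct and validate a pedigree
#'
#' A pedigree is a data.frame with columns `id`, `sire`, `dam`, `sex` and
#' `age`. Parent fields are `NA` for founders. Validation enforces the
#' structural invariants the kinship recursion relies on: unique ids, parents
#' present in the table (after phantom-parent completion), sires male and
#' dams female wherever sex is known, and acyclicity.
#'
#' @param df data.frame with columns id, sire, dam, sex (\"F\"/\"M\"), age.
#' @return A validated `pedigree` object (a data.frame) with an added
#'   integer `generation` column (founders are generation 0).
#' @export
as_pedigree <- function(df) {
  req <- c("id", "sire", "dam", "sex")
  if (!all(req %in% names(df)))
    stop("pedigree needs columns: ", paste(req, collapse = ", "))
  df$id   <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam  <- as.character(df$dam)
  df$sire[df$sire %in% c("0", "", "NA")] <- NA_character_
  df$dam[df$dam %in% c("0", "", "NA")]   <- NA_character_
  if (is.null(df$age)) df$age <- NA_real_
  if (anyDuplicated(df$id))
    stop("duplicated individual ids in pedigree")

  df <- complete_parents(df)

  known_sire <- !is.na(df$sire)
  known_dam  <- !is.na(df$dam)
  if (any(bad <- known_sire & !(df$sire %in% df$id)))
    stop("sire id not in pedigree: ", paste(unique(df$sire[bad]), collapse = ", "))
  if (any(bad <- known_dam & !(df$dam %in% df$id)))
    stop("dam id not in pedigree: ", paste(unique(df$dam[bad]), collapse = ", "))

  sex_of <- stats::setNames(df$sex, df$id)
  s <- sex_of[df$sire[known_sire]]
  if (any(!is.na(s) & s != "M"))
    stop("individual used as sire is not male")
  d <- sex_of[df$dam[known_dam]]
  if (any(!is.na(d) & d != "F"))
    stop("individual used as dam is not female")

  df$generation <- pedigree_depth(df)  # errors on cycles
  ord <- order(df$generation)
  out <- df[ord, c("id", "sire", "dam", "sex", "age", "generation")]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

# An individual with exactly one known parent gets a unique phantom founder
# of the proper sex as the other parent, keeping the kinship recursion total.
complete_parents <- function(df) {
  one_sire <- !is.na(df$sire) & is.na(df$dam)
  one_dam  <- is.na(df$sire) & !is.na(df$dam)
  add <- list()
  if (any(one_sire)) {
    ph <- paste0("phantom_dam_", seq_len(sum(one_sire)))
    df$dam[one_sire] <- ph
    add$dams <- data.frame(id = ph, sire = NA_character_, dam = NA_character_,
                           sex = "F", age = NA_real_, stringsAsFactors = FALSE)
  }
  if (any(one_dam)) {
    ph <- paste0("phantom_sire_", seq_len(sum(one_dam)))
    df$sire[one_dam] <- ph
    add$sires <- data.frame(id = ph, sire = NA_character_, dam = NA_character_,
                            sex = "M", age = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(add))
    df <- rbind(df[c("id", "sire", "dam", "sex", "age")],
                do.call(rbind, add))
  df
}

# Generation depth of each individual (founders 0); detects cycles.
pedigree_depth <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  fi <- ifelse(is.na(df$sire), 0L, idx[df$sire])
  mi <- ifelse(is.na(df$dam), 0L, idx[df$dam])
  depth <- ifelse(fi == 0L & mi == 0L, 0L, NA_integer_)
  for (pass in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) return(depth)
    progressed <- FALSE
    for (i in todo) {
      dp <- if (fi[i] > 0L) depth[fi[i]] else 0L
      dm <- if (mi[i] > 0L) depth[mi[i]] else 0L
      if (!is.na(dp) && !is.na(dm)) {
        depth[i] <- max(dp, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cycle detected in pedigree")
  }
  stop("cycle detected in pedigree")
}

#' Read a pedigree from tab-delimited text
#'
#' Expects columns `id`, `sire`, `dam`, `sex`, `age`; a parent coded `0` (or
#' empty) means unknown. Row order is irrelevant: individuals are sorted
#' topologically on read.
#'
#' @param path file path.
#' @return A `pedigree` object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!is.null(df$age)) df$age <- suppressWarnings(as.numeric(df$age))
  as_pedigree(df)
}

#' Write a pedigree as tab-delimited text
#'
#' Unknown parents are written as `0`, so founders have sire = dam = 0.
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[c("id", "sire", "dam", "sex", "age")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a multi-generation random-mating pedigree
#'
#' Simulates a closed breeding colony with discrete, non-overlapping
#' generations. Each generation, a limited pool of breeding males (polygynous
#' mating: each dam is assigned a single sire) is drawn from the previous
#' generation, and offspring are allocated to dams with Poisson-distributed
#' litter weights. The defaults describe a small, six-generation colony whose
#' final two generations have a mean pairwise kinship in the 0.10-0.20 band
#' typical of a closed primate breeding colony (between half and full sibs).
#'
#' @param n_founders number of founder individuals (generation 0).
#' @param n_generations total number of generations including founders.
#' @param gen_sizes optional integer vector of per-generation sizes (length
#'   `n_generations`); defaults to geometric growth from `n_founders` to
#'   `final_size`.
#' @param final_size target size of the last generation when `gen_sizes` is
#'   not given.
#' @param prop_sires fraction of the previous generation's males used as
#'   breeders (minimum 2); smaller values give stronger polygyny and higher
#'   kinship.
#' @param offspring_lambda mean of the Poisson litter-weight distribution
#'   used to allocate offspring among dams.
#' @param age_range ages (years) assigned uniformly to all individuals.
#' @param seed optional RNG seed for reproducibility.
#' @return A `pedigree` object.
#' @export
generate_pedigree <- function(n_founders = 28, n_generations = 6,
                              gen_sizes = NULL, final_size = 130,
                              prop_sires = 0.30, offspring_lambda = 1.5,
                              age_range = c(6, 17), seed = NULL) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (n_generations < 1) stop("need at least 1 generation")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gen_sizes)) {
    gen_sizes <- round(exp(seq(log(n_founders), log(final_size),
                               length.out = n_generations)))
  }
  if (length(gen_sizes) != n_generations)
    stop("gen_sizes must have length n_generations")

  # founders: force both sexes present
  n0 <- gen_sizes[1]
  sex <- sample(rep_len(c("M", "F"), n0))
  rows <- data.frame(id = sprintf("G0_%03d", seq_len(n0)),
                     sire = NA_character_, dam = NA_character_,
                     sex = sex, stringsAsFactors = FALSE)
  prev <- rows
  for (g in seq_len(n_generations - 1L)) {
    males <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    if (length(males) < 1 || length(dams) < 1)
      stop("no available sires/dams in generation ", g - 1L)
    n_sires <- max(2L, min(length(males), round(prop_sires * length(males))))
    sires <- sample(males, n_sires)
    mate <- stats::setNames(sample(sires, length(dams), replace = TRUE), dams)
    nk <- gen_sizes[g + 1L]
    # Poisson litter weights, renormalized to the target generation size
    w <- stats::rpois(length(dams), offspring_lambda) + 0.1
    dam_of <- sample(dams, nk, replace = TRUE, prob = w)
    kid <- data.frame(id = sprintf("G%d_%03d", g, seq_len(nk)),
                      sire = unname(mate[dam_of]), dam = dam_of,
                      sex = sample(c("M", "F"), nk, replace = TRUE),
                      stringsAsFactors = FALSE)
    if (!any(kid$sex == "M")) kid$sex[1] <- "M"
    if (!any(kid$sex == "F")) kid$sex[nrow(kid)] <- "F"
    rows <- rbind(rows, kid)
    prev <- kid
  }
  rows$age <- round(stats::runif(nrow(rows), age_range[1], age_range[2]), 1)
  as_pedigree(rows)
}

#' Ids of the most recent generations of a pedigree
#'
#' @param ped a `pedigree`.
#' @param k number of final generations to include.
#' @return character vector of ids.
#' @export
last_generations <- function(ped, k = 2) {
  gmax <- max(ped$generation)
  ped$id[ped$generation > gmax - k]
}
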