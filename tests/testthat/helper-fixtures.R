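# Small pedigree fixtures and independent oracles used across test files.

ped_df <- function(id, sire, dam, sex, age = 10) {
  data.frame(id = id, sire = sire, dam = dam, sex = sex, age = age,
             stringsAsFactors = FALSE)
}

# sire + dam + one child
ped_trio <- function() {
  as_pedigree(ped_df(c("f", "m", "c"),
                     c(NA, NA, "f"), c(NA, NA, "m"),
                     c("M", "F", "F")))
}

# two unrelated parents with n_off full-sib offspring
ped_fullsibs <- function(n_off = 4) {
  kids <- paste0("k", seq_len(n_off))
  as_pedigree(ped_df(c("s", "d", kids),
                     c(NA, NA, rep("s", n_off)),
                     c(NA, NA, rep("d", n_off)),
                     c("M", "F", rep(c("F", "M"), length.out = n_off))))
}

# one sire, two dams -> half sibs k1, k2
ped_halfsibs <- function() {
  as_pedigree(ped_df(c("s", "d1", "d2", "k1", "k2"),
                     c(NA, NA, NA, "s", "s"),
                     c(NA, NA, NA, "d1", "d2"),
                     c("M", "F", "F", "F", "M")))
}

# offspring of a full-sib mating (inbred, F = 0.25)
ped_inbred <- function() {
  as_pedigree(ped_df(c("s", "d", "b1", "b2", "x"),
                     c(NA, NA, "s", "s", "b1"),
                     c(NA, NA, "d", "d", "b2"),
                     c("M", "F", "M", "F", "F")))
}

# random acyclic pedigree built sequentially: each later individual is a
# founder with prob p_founder, else gets parents drawn from earlier males
# and females (forced founder when none available)
random_pedigree <- function(n, p_founder = 0.35, seed = 1) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) && length(females) && stats::runif(1) > p_founder) {
      sire[i] <- paste0("i", males[sample.int(length(males), 1)])
      dam[i] <- paste0("i", females[sample.int(length(females), 1)])
    }
  }
  as_pedigree(ped_df(paste0("i", seq_len(n)), sire, dam, sex))
}

# Exact kinship oracle: enumerate every possible inheritance vector (each
# non-founder independently picks one of its sire's and one of its dam's
# alleles), compute the realized alleles, and average allele-sharing. This
# brute-force enumeration is independent of the recursive implementation.
kinship_enum <- function(ped) {
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fi <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  mi <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  nonf <- which(fi > 0L)
  k <- length(nonf)
  stopifnot(4^k <= 2^20)
  phi <- matrix(0, n, n)
  a1 <- 2 * seq_len(n) - 1  # founder allele labels
  a2 <- 2 * seq_len(n)
  for (pattern in seq_len(4^k) - 1L) {
    A1 <- a1; A2 <- a2
    bits <- pattern
    for (j in nonf) {  # nonf is in topological order (ped sorted)
      from_sire <- bits %% 2L; bits <- bits %/% 2L
      from_dam <- bits %% 2L; bits <- bits %/% 2L
      A1[j] <- if (from_sire == 0L) A1[fi[j]] else A2[fi[j]]
      A2[j] <- if (from_dam == 0L) A1[mi[j]] else A2[mi[j]]
    }
    share <- 0.25 * ((outer(A1, A1, "==")) + (outer(A1, A2, "==")) +
                       (outer(A2, A1, "==")) + (outer(A2, A2, "==")))
    phi <- phi + share
  }
  phi <- phi / 4^k
  dimnames(phi) <- list(ped$id, ped$id)
  phi
}

# Monte-Carlo gene-dropping kinship estimate: drop founder alleles through
# the pedigree n_drops times; kinship is the probability a random allele
# from i matches a random allele from j identically by descent.
kinship_gene_drop <- function(ped, n_drops = 20000, seed = 1) {
  set.seed(seed)
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fi <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  mi <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A1 <- matrix(0L, n_drops, n)
  A2 <- matrix(0L, n_drops, n)
  for (j in seq_len(n)) {
    if (fi[j] == 0L) {
      A1[, j] <- 2L * j - 1L
      A2[, j] <- 2L * j
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[, j] <- ifelse(pick, A1[, fi[j]], A2[, fi[j]])
      pick <- stats::runif(n_drops) < 0.5
      A2[, j] <- ifelse(pick, A1[, mi[j]], A2[, mi[j]])
    }
  }
  list(est = function(i, j) {
    mean(0.25 * ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                   (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])))
  },
  se = function(i, j) {
    x <- 0.25 * ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                   (A2[, i] == A1[, j]) + (A2[, i] == A2[, j]))
    stats::sd(x) / sqrt(n_drops)
  })
}

# Direct dense multivariate-normal profile log-likelihood: for a given h2,
# profile beta (GLS) and the total variance on the ORIGINAL scale and
# evaluate the Gaussian density with solve()/determinant(). Independent of
# the eigen-rotation implementation.
dense_profile_ll <- function(h2, y, X, K) {
  n <- length(y)
  V <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  s2p <- drop(crossprod(r, Vi %*% r)) / n
  ld <- as.numeric(determinant(s2p * V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + n)
}

# shared slow recovery runs for the acceptance suite (computed on demand)
.recovery_cache <- new.env(parent = emptyenv())
cached_recovery <- function(name, n_reps = 200, seed = 100) {
  key <- paste(name, n_reps, seed, sep = "_")
  if (is.null(.recovery_cache[[key]]))
    .recovery_cache[[key]] <- recover_scenario(name, n_reps = n_reps,
                                               seed = seed)
  .recovery_cache[[key]]
}
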