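# A shared small study used by several blocks
make_small_study <- function(seed = 21, h2 = 0.4, n = 60) {
  ped <- generate_pedigree(gen_sizes = c(14, 25, 40, 60), n_generations = 4,
                           seed = seed)
  sc <- generator_scenario("unit", n_individuals = n, h2 = h2,
                           beta_sex = 0.4, beta_age = -0.06)
  simulate_study(sc, seed = seed, ped = ped)
}

test_that("profiled likelihood equals dense multivariate-normal evaluation", {
  # small fixtures, 20-point h2 grid, tolerance 1e-8
  for (s in 1:3) {
    ped <- random_pedigree(8, p_founder = 0.3, seed = s)
    K <- relationship_matrix(compute_kinship(ped))
    set.seed(s)
    n <- nrow(K)
    X <- cbind(1, rnorm(n))
    y <- drop(t(chol(0.5 * K + 0.5 * diag(n))) %*% rnorm(n)) + X %*% c(1, 0.3)
    eig <- eigen(K, symmetric = TRUE)
    yt <- drop(crossprod(eig$vectors, y))
    Xt <- crossprod(eig$vectors, X)
    for (h2 in seq(0.025, 0.975, length.out = 20)) {
      ours <- telodyn:::pg_profile(h2, yt, Xt, eig$values)$ll
      oracle <- dense_profile_ll(h2, y, X, K)
      expect_equal(ours, oracle, tolerance = 1e-8)
    }
  }
})

test_that("the fitted h2 maximizes the dense likelihood too", {
  study <- make_small_study()
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  fit <- fit_polygenic(dat, "ltl", c("sex", "age"), study$kinship)
  K <- relationship_matrix(study$kinship, fit$ids)
  X <- model.matrix(~ sex + age, dat[match(fit$ids, dat$id), ])
  y <- dat$ltl[match(fit$ids, dat$id)]
  ll_hat <- dense_profile_ll(fit$h2, y, X, K)
  expect_equal(fit$loglik, ll_hat, tolerance = 1e-6)
  for (h2 in c(0.01, fit$h2 / 2, min(fit$h2 * 1.5, 0.99)))
    expect_lte(dense_profile_ll(h2, y, X, K), ll_hat + 1e-6)
})

test_that("variance components respect scale equivariance", {
  study <- make_small_study(seed = 31)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  km <- study$kinship
  f1 <- fit_polygenic(dat, "ltl", c("sex", "age"), km)
  dat$scaled <- 3.7 * dat$ltl
  f2 <- fit_polygenic(dat, "scaled", c("sex", "age"), km)
  expect_equal(f2$sigma2_g, 3.7^2 * f1$sigma2_g, tolerance = 1e-6)
  expect_equal(f2$sigma2_e, 3.7^2 * f1$sigma2_e, tolerance = 1e-6)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
  p1 <- lrt_heritability(dat, "ltl", c("sex", "age"), km)$p_value
  p2 <- lrt_heritability(dat, "scaled", c("sex", "age"), km)$p_value
  expect_equal(p1, p2, tolerance = 1e-6)
  set.seed(1); dat$x <- rnorm(nrow(dat))
  a1 <- covariate_association(dat, "ltl", "x", c("sex", "age"), km)
  a2 <- covariate_association(dat, "scaled", "x", c("sex", "age"), km)
  expect_equal(a1$r, a2$r, tolerance = 1e-6)
  expect_equal(a1$p, a2$p, tolerance = 1e-6)
})

test_that("unrelated individuals give a flat likelihood resolved to h2 = 0", {
  ped <- generate_pedigree(n_founders = 40, n_generations = 1,
                           gen_sizes = 40, seed = 2)
  sc <- generator_scenario("flat", n_individuals = 30, h2 = 0.5)
  study <- simulate_phenotypes(ped, sc, seed = 3)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  fit <- fit_polygenic(dat, "ltl", character(), study$kinship)
  expect_equal(fit$h2, 0)
  expect_true("h2_unidentifiable" %in% fit$flags)
  expect_true("h2_boundary" %in% fit$flags)
})

test_that("nested models never out-likelihood the full model", {
  for (s in 1:4) {
    study <- make_small_study(seed = 40 + s, h2 = 0.3)
    dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
    res <- lrt_covariate(dat, "ltl", c("sex", "age"), study$kinship, "age")
    expect_gte(res$loglik_full, res$loglik_null - 1e-8)
    hres <- lrt_heritability(dat, "ltl", c("sex", "age"), study$kinship)
    expect_gte(hres$loglik_full, hres$loglik_null - 1e-8)
  }
})

test_that("an identically-zero covariate gives Lambda = 0, p = 1", {
  study <- make_small_study(seed = 55)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  dat$zero <- 0
  res <- lrt_covariate(dat, "ltl", c("sex", "age", "zero"), study$kinship,
                       "zero")
  expect_equal(res$lambda, 0)
  expect_equal(res$p_value, 1)
})

test_that("boundary heritability LRT returns p = 0.5 at Lambda = 0", {
  # phenotype with no genetic signal on a related pedigree often lands on
  # the h2 = 0 boundary; construct one deterministic such case
  study <- make_small_study(seed = 77, h2 = 0)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  res <- lrt_heritability(dat, "ltl", c("sex", "age"), study$kinship)
  if (res$lambda == 0) expect_equal(res$p_value, 0.5)
  expect_lte(res$p_value, 0.5)
  expect_gte(res$p_value, 0)
})

test_that("covariate_association reports r2 = r^2 with the sign of beta", {
  study <- make_small_study(seed = 91)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  set.seed(9)
  dat$indep <- rnorm(nrow(dat))
  a <- covariate_association(dat, "ltl", "indep", c("sex", "age"),
                             study$kinship)
  expect_equal(a$r2, a$r^2, tolerance = 1e-12)
  expect_equal(sign(a$r), sign(a$beta))
  expect_lt(abs(a$r), 0.35)  # independent predictor, small n
  expect_gt(a$p, 0.001)
})

test_that("standard errors are returned for interior fits", {
  study <- make_small_study(seed = 101, h2 = 0.5, n = 60)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  fit <- fit_polygenic(dat, "ltl", c("sex", "age"), study$kinship, se = TRUE)
  expect_true(all(is.finite(fit$beta$se)))
  expect_true(all(fit$beta$se > 0))
  if (!"h2_boundary" %in% fit$flags) {
    expect_true(is.finite(fit$h2_se))
    expect_gt(fit$h2_se, 0)
    expect_lt(fit$h2_se, 1)
  }
})

test_that("listwise deletion keeps nested fits on identical rows", {
  study <- make_small_study(seed = 111)
  dat <- study$phenotypes[study$phenotypes$timepoint == "t0", ]
  dat$age[c(3, 9)] <- NA
  res <- lrt_covariate(dat, "ltl", c("sex", "age"), study$kinship, "sex")
  prep_n <- fit_polygenic(dat, "ltl", c("sex", "age"), study$kinship)$n
  expect_equal(prep_n, nrow(dat) - 2)
  expect_gte(res$loglik_full, res$loglik_null - 1e-8)
})
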