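test_that("the scenario library carries the study effect sizes", {
  lib <- scenario_library()
  expect_setequal(names(lib), c("baseline_combined", "combined_2yr",
                                "lesion_assoc", "biomarker_7wk",
                                "control_delta_age"))
  b <- lib$baseline_combined
  expect_equal(b$n_individuals, 211L)
  expect_equal(b$h2, 0.27)
  expect_equal(b$beta_sex, 0.516)
  expect_equal(b$beta_age, -0.089)
  e <- lib$combined_2yr
  expect_equal(e$h2, 0.46)
  expect_equal(e$beta_diet, -0.486)
  expect_equal(lib$lesion_assoc$assoc_r,
               c(descending_aorta = -0.247, common_iliac_delta = -0.202))
  expect_equal(lib$biomarker_7wk$assoc_r[["VLDLC"]], -0.241)
  expect_equal(lib$control_delta_age$r2_delta_age, 0.20)
  expect_equal(lib$control_delta_age$n_individuals, 105L)
  expect_error(get_scenario("nonexistent"), "unknown scenario")
})

test_that("scenario invariants are validated on construction", {
  expect_error(generator_scenario("x", 10, h2 = 1.2), "h2")
  expect_error(generator_scenario("x", 10, assoc_r = c(a = 1.5)), "assoc_r")
  expect_error(generator_scenario("x", 10, assoc_r = c(0.5)), "named")
  expect_error(generator_scenario("x", 10, age_range = c(17, 6)), "age_range")
})

test_that("scenarios round-trip through YAML config files", {
  for (sc in scenario_library()) {
    f <- tempfile(fileext = ".yaml")
    write_scenario(sc, f)
    sc2 <- read_scenario(f)
    expect_equal(sc2, sc)
  }
})

test_that("identical (scenario, seed) pairs reproduce identical studies", {
  s1 <- simulate_study("biomarker_7wk", seed = 12)
  s2 <- simulate_study("biomarker_7wk", seed = 12)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  s3 <- simulate_study("biomarker_7wk", seed = 13)
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("generated LTL is calibrated to unit residual variance", {
  ped <- generate_pedigree(seed = 5)
  km <- compute_kinship(ped)
  sc <- get_scenario("baseline_combined")
  vars <- vapply(1:200, function(i) {
    st <- simulate_study(sc, seed = 300 + i, ped = ped, kinship = km)
    t0 <- st$phenotypes[st$phenotypes$timepoint == "t0", ]
    var(residualize(t0$ltl, t0[c("sex", "age")]))
  }, numeric(1))
  expect_lt(abs(mean(vars) - 1), 0.05)
})

test_that("secondary traits realize their target correlations exactly", {
  st <- simulate_study("biomarker_7wk", seed = 8)
  t2 <- st$phenotypes[st$phenotypes$timepoint == "t2", ]
  for (nm in names(st$truth$assoc_r))
    expect_equal(cor(t2[[nm]], t2$ltl), st$truth$assoc_r[[nm]],
                 tolerance = 1e-10)

  st <- simulate_study("lesion_assoc", seed = 9)
  ph <- st$phenotypes
  t0 <- ph[ph$timepoint == "t0", ]; t2 <- ph[ph$timepoint == "t2", ]
  d <- t0$ltl - t2$ltl[match(t0$id, t2$id)]
  expect_equal(cor(t2$common_iliac_delta, d), -0.202, tolerance = 1e-10)
  expect_equal(cor(t2$descending_aorta, t2$ltl), -0.247, tolerance = 1e-10)
})

test_that("h2 = 0 removes the genetic signal in full sibs", {
  ped <- generate_pedigree(seed = 14)
  sc <- generator_scenario("nog", n_individuals = 200, h2 = 0)
  rs <- vapply(1:30, function(i) {
    st <- simulate_study(sc, seed = 400 + i, ped = ped, kinship = compute_kinship(ped))
    ph <- st$phenotypes[st$phenotypes$timepoint == "t0", ]
    df <- as.data.frame(st$pedigree)
    key <- paste(df$sire, df$dam)[match(ph$id, df$id)]
    fam <- split(ph$ltl, key)
    fam <- fam[lengths(fam) >= 2]
    pairs <- do.call(rbind, lapply(fam, function(v) t(combn(v, 2))))
    cor(pairs[, 1], pairs[, 2])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("h2 = 1 gives unit midparent-offspring regression", {
  # with no environmental variance the offspring phenotype regresses on the
  # midparent value with slope 1 under the additive model
  slopes <- vapply(1:10, function(s) {
    ped <- generate_pedigree(gen_sizes = c(30, 60, 90), n_generations = 3,
                             seed = 500 + s)
    sc <- generator_scenario("allg", n_individuals = 150, h2 = 1,
                             rho_within = 0)
    st <- simulate_study(sc, seed = 600 + s, ped = ped)
    ph <- st$phenotypes[st$phenotypes$timepoint == "t0", ]
    y <- setNames(ph$ltl, ph$id)
    df <- as.data.frame(st$pedigree)
    df <- df[df$id %in% names(y) & df$sire %in% names(y) &
               df$dam %in% names(y), ]
    mid <- (y[df$sire] + y[df$dam]) / 2
    unname(coef(lm(y[df$id] ~ mid))[2])
  }, numeric(1))
  expect_equal(mean(slopes), 1, tolerance = 0.1)
})

test_that("simulated genetic covariance converges to sigma2_g * 2Phi", {
  ped <- generate_pedigree(gen_sizes = c(12, 20, 36), n_generations = 3,
                           seed = 17)
  km <- compute_kinship(ped)
  # phenotype the entire final two generations so every replicate draws the
  # same 56 individuals and rows align across replicates
  m <- length(last_generations(ped, 2))
  sc <- generator_scenario("gcov", n_individuals = m, h2 = 1,
                           rho_within = 0)
  R <- 400
  ys <- vapply(seq_len(R), function(i) {
    st <- simulate_study(sc, seed = 700 + i, ped = ped, kinship = km)
    ph <- st$phenotypes[st$phenotypes$timepoint == "t0", ]
    ph$ltl[order(ph$id)]
  }, numeric(m))
  ids <- sort(last_generations(ped, 2))
  K <- relationship_matrix(km, ids)
  emp <- cov(t(ys))
  set.seed(2)
  pick <- cbind(sample(m, 30, replace = TRUE), sample(m, 30, replace = TRUE))
  for (k in seq_len(nrow(pick))) {
    i <- pick[k, 1]; j <- pick[k, 2]
    se <- sqrt((K[i, i] * K[j, j] + K[i, j]^2) / R)
    expect_lt(abs(emp[i, j] - K[i, j]), 3 * se)
  }
})

test_that("phenotype tables round-trip as CSV and carry the diet design", {
  st <- simulate_study("combined_2yr", seed = 19)
  ph <- st$phenotypes
  # diet indicator only at t2 in the experimental cohort
  expect_true(all(ph$diet[ph$timepoint == "t0"] == 0))
  expect_true(all(ph$diet[ph$timepoint == "t2" &
                            ph$cohort == "experimental"] == 1))
  expect_true(all(ph$diet[ph$timepoint == "t2" & ph$cohort == "control"] == 0))
  expect_true(all(ph$id %in% st$pedigree$id))
  f <- tempfile(fileext = ".csv")
  write_phenotypes(st, f)
  ph2 <- read_phenotypes(f)
  expect_equal(ph2$ltl, ph$ltl, tolerance = 1e-12)
  expect_equal(ph2$cohort, ph$cohort)

  # diet lowers adjusted endpoint LTL in the experimental group
  t2 <- ph[ph$timepoint == "t2", ]
  adj <- residualize(t2$ltl, t2[c("sex", "age")])
  expect_lt(mean(adj[t2$diet == 1]) - mean(adj[t2$diet == 0]), 0)
})

test_that("attrition is larger under the challenge diet (combined_2yr)", {
  deltas <- vapply(1:15, function(i) {
    st <- simulate_study("combined_2yr", seed = 800 + i)
    ph <- st$phenotypes
    t0 <- ph[ph$timepoint == "t0", ]; t2 <- ph[ph$timepoint == "t2", ]
    d <- delta_ltl(setNames(t0$ltl, t0$id), setNames(t2$ltl, t2$id))
    grp <- t0$cohort[match(names(d), t0$id)]
    mean(d[grp == "experimental"]) - mean(d[grp == "control"])
  }, numeric(1))
  expect_gt(mean(deltas), 0)   # HCHF animals lose more
  expect_gt(mean(deltas > 0), 0.9)
})
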