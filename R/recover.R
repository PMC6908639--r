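#' Parameter-recovery runs for a scenario
#'
#' Simulates `n_reps` independent studies from a scenario (fresh pedigree
#' and phenotypes per replicate, seeds `seed + 1 .. seed + n_reps`) and
#' re-estimates the generating quantities with the package's own
#' estimators. Which analysis runs depends on the scenario:
#'
#' * `baseline_combined` — polygenic fit of baseline LTL on sex + age:
#'   returns `h2`, `beta_sex`, `beta_age`, heritability LRT p.
#' * `combined_2yr` — polygenic fit of endpoint LTL on sex + age + diet:
#'   returns `h2`, `beta_sex`, `beta_age`, `beta_diet`, diet LRT p.
#' * `lesion_assoc` — kinship-aware association of endpoint LTL with
#'   descending-aorta lesion extent and of delta-LTL with common-iliac
#'   lesion extent: returns `r`/`r2` for each.
#' * `biomarker_7wk` — association of each biomarker with endpoint LTL.
#' * `control_delta_age` — association of age with delta-LTL.
#'
#' @param scenario a `generator_scenario` or scenario name.
#' @param n_reps number of replicates.
#' @param seed base RNG seed.
#' @param se compute standard errors inside each fit (slower; default off).
#' @return data.frame with one row per replicate (class
#'   `recovery_runs`, attribute `scenario`).
#' @export
recover_scenario <- function(scenario, n_reps = 200, seed = 1L, se = FALSE) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  rows <- lapply(seq_len(n_reps), function(i) {
    study <- simulate_study(scenario, seed = seed + i)
    recover_one(study, se = se)
  })
  out <- do.call(rbind, rows)
  out <- cbind(replicate = seq_len(n_reps), out)
  attr(out, "scenario") <- scenario
  class(out) <- c("recovery_runs", "data.frame")
  out
}

recover_one <- function(study, se = FALSE) {
  sc <- study$truth
  ph <- study$phenotypes
  km <- study$kinship
  has_assoc <- !is.null(sc$assoc_r)
  if (!is.null(sc$r2_delta_age)) {
    d <- study_delta(ph)
    a <- covariate_association(d, "delta_ltl", "age", kinship = km)
    return(data.frame(r2_age = a$r2, r_age = a$r, p_age = a$p))
  }
  if (has_assoc) {
    t2 <- ph[ph$timepoint == "t2", ]
    d <- study_delta(ph)
    t2$delta_ltl <- d$delta_ltl[match(t2$id, d$id)]
    out <- list()
    for (nm in names(sc$assoc_r)) {
      pred <- if (grepl("_delta$", nm)) "delta_ltl" else "ltl"
      a <- covariate_association(t2, trait = nm, predictor = pred,
                                 kinship = km)
      out[[paste0("r_", nm)]] <- a$r
      out[[paste0("r2_", nm)]] <- a$r2
      out[[paste0("p_", nm)]] <- a$p
    }
    return(as.data.frame(out))
  }
  # fixed-effect + heritability scenarios
  tp <- if (sc$beta_diet != 0) "t2" else "t0"
  covs <- c("sex", "age", if (sc$beta_diet != 0) "diet")
  dat <- ph[ph$timepoint == tp, ]
  fit <- fit_polygenic(dat, "ltl", covs, km, se = se)
  b <- stats::setNames(fit$beta$estimate, fit$beta$term)
  hl <- lrt_heritability(dat, "ltl", covs, km)
  res <- data.frame(h2 = fit$h2,
                    beta_sex = sex_female_effect(b),
                    beta_age = unname(b[["age"]]),
                    p_h2 = hl$p_value)
  if (sc$beta_diet != 0) {
    res$beta_diet <- unname(b[["diet"]])
    res$p_diet <- lrt_covariate(dat, "ltl", covs, km, "diet")$p_value
  }
  res
}

# model.matrix codes sex with M as the non-reference level (F < M
# alphabetically), so the female effect is minus the sexM coefficient.
sex_female_effect <- function(b) {
  if ("sexM" %in% names(b)) return(-unname(b[["sexM"]]))
  if ("sexF" %in% names(b)) return(unname(b[["sexF"]]))
  stop("no sex coefficient in model")
}

# delta-LTL per animal on the i-normalized scale, returned as a data.frame
# with the time-invariant covariates attached.
study_delta <- function(ph) {
  t0 <- ph[ph$timepoint == "t0", ]
  t2 <- ph[ph$timepoint == "t2", ]
  d <- delta_ltl(stats::setNames(t0$ltl, t0$id),
                 stats::setNames(t2$ltl, t2$id), mode = "raw_inormal")
  out <- t0[match(names(d), t0$id),
            setdiff(names(t0), c("ltl", "ts_ratio", "timepoint", "diet"))]
  out$delta_ltl <- as.numeric(d)
  out
}

#' Summarize recovery runs against the generating scenario
#'
#' @param object a `recovery_runs` data.frame.
#' @param ... unused.
#' @return data.frame of estimate means, Monte-Carlo SEs, and generating
#'   values where defined.
#' @export
summary.recovery_runs <- function(object, ...) {
  sc <- attr(object, "scenario")
  est <- object[setdiff(names(object), "replicate")]
  truth <- c(h2 = sc$h2, beta_sex = sc$beta_sex, beta_age = sc$beta_age,
             beta_diet = sc$beta_diet)
  if (!is.null(sc$assoc_r))
    truth <- c(truth, stats::setNames(sc$assoc_r, paste0("r_", names(sc$assoc_r))))
  if (!is.null(sc$r2_delta_age))
    truth <- c(truth, r2_age = sc$r2_delta_age)
  data.frame(
    quantity = names(est),
    mean = vapply(est, mean, numeric(1)),
    mc_se = vapply(est, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    generating = unname(truth[names(est)]),
    row.names = NULL)
}
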