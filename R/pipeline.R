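#' Descriptive statistics by cohort, time point and sex
#'
#' Means, medians, SDs, minima, maxima and ranges of a raw trait, grouped by
#' cohort x timepoint x sex, with a `Total` row per cohort x timepoint
#' (the layout of a study's first descriptive table). Groups of one get a
#' missing SD; empty groups are emitted with missing markers.
#'
#' @param pheno phenotype data.frame (columns cohort, timepoint, sex, and
#'   the value column).
#' @param value name of the value column (default the raw T/S ratio).
#' @return data.frame: cohort, timepoint, sex (F/M/Total), n, mean, median,
#'   sd, min, max, range.
#' @export
run_descriptives <- function(pheno, value = "ts_ratio") {
  need <- c("cohort", "timepoint", "sex", value)
  if (!all(need %in% names(pheno)))
    stop("phenotypes need columns: ", paste(need, collapse = ", "))
  combos <- expand.grid(cohort = unique(pheno$cohort),
                        timepoint = unique(pheno$timepoint),
                        sex = c("F", "M", "Total"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    co <- combos$cohort[k]; tp <- combos$timepoint[k]; sx <- combos$sex[k]
    v <- pheno[[value]][pheno$cohort == co & pheno$timepoint == tp &
                          (sx == "Total" | pheno$sex == sx)]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(cohort = co, timepoint = tp, sex = sx, n = n,
               mean = if (n) mean(v) else NA_real_,
               median = if (n) stats::median(v) else NA_real_,
               sd = if (n > 1) stats::sd(v) else NA_real_,
               min = if (n) min(v) else NA_real_,
               max = if (n) max(v) else NA_real_,
               range = if (n) max(v) - min(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$cohort, out$timepoint, out$sex), ]
}

#' Configure a full study run
#'
#' @param mode `"simulate"` (generate data from a scenario) or `"real"`
#'   (read pedigree/phenotype files).
#' @param scenario scenario name or `generator_scenario` (simulation mode).
#' @param seed RNG seed (mandatory in simulation mode; drives everything).
#' @param out_dir output directory for the report tables.
#' @param pedigree_path,phenotype_path input files (real mode).
#' @param biomarkers character vector of biomarker columns; default: every
#'   secondary trait column not recognized as a lesion.
#' @param lesions character vector of lesion-extent columns; default: any
#'   column matching aorta/iliac/arch.
#' @param n_mc Monte-Carlo permutations for large-sample median tests.
#' @return list of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "real"),
                         scenario = "combined_2yr", seed = NULL,
                         out_dir = tempfile("telodyn_run_"),
                         pedigree_path = NULL, phenotype_path = NULL,
                         biomarkers = NULL, lesions = NULL, n_mc = 1e5) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(seed))
    stop("seed is mandatory in simulation mode")
  if (mode == "real" &&
      (is.null(pedigree_path) || !file.exists(pedigree_path) ||
       is.null(phenotype_path) || !file.exists(phenotype_path)))
    stop("real mode requires existing pedigree_path and phenotype_path")
  structure(list(mode = mode, scenario = scenario, seed = seed,
                 out_dir = out_dir, pedigree_path = pedigree_path,
                 phenotype_path = phenotype_path, biomarkers = biomarkers,
                 lesions = lesions, n_mc = n_mc), class = "study_config")
}

#' Run the full study pipeline
#'
#' Executes the end-to-end analysis in order: descriptive statistics;
#' exact-permutation median tests (between cohorts at each time point,
#' between sexes within cohorts, between time points within cohorts, and on
#' raw attrition); per-cohort models of i-normalized LTL with sex, age and
#' age x sex; the combined-cohort baseline model (sex + age + heritability);
#' the combined endpoint model adding diet; delta-LTL construction from
#' sex- and age-adjusted residuals with a diet test; biomarker association
#' rows; and lesion association rows for LTL and delta-LTL (per artery plus
#' sum and mean of the per-artery extents). Tables are written as TSV into
#' `cfg$out_dir` (table1_descriptives.tsv .. table5_delta_lesions.tsv plus
#' per-cohort models and median tests), together with a YAML metadata file
#' recording the seed and config, and a plain-text per-stage log. With a
#' fixed seed in simulation mode two runs are byte-identical.
#'
#' @param cfg a `study_config`.
#' @return `study_report` list with all tables and run metadata (invisibly).
#' @export
run_full_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-22s %.2fs", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }

  # --- data -----------------------------------------------------------
  if (cfg$mode == "simulate") {
    study <- stage("simulate", simulate_study(cfg$scenario, seed = cfg$seed))
    ped <- study$pedigree; pheno <- study$phenotypes; km <- study$kinship
  } else {
    ped <- stage("read_pedigree", read_pedigree(cfg$pedigree_path))
    pheno <- stage("read_phenotypes", read_phenotypes(cfg$phenotype_path))
    km <- stage("kinship", compute_kinship(ped))
  }
  base_cols <- c("id", "cohort", "timepoint", "diet", "sex", "age",
                 "ltl", "ts_ratio")
  secondary <- setdiff(names(pheno), base_cols)
  lesions <- cfg$lesions
  if (is.null(lesions))
    lesions <- grep("aorta|iliac|arch", secondary, value = TRUE)
  biomarkers <- cfg$biomarkers
  if (is.null(biomarkers)) biomarkers <- setdiff(secondary, lesions)

  # --- descriptives ---------------------------------------------------
  tab1 <- stage("descriptives", run_descriptives(pheno))

  # --- median tests ---------------------------------------------------
  med <- stage("median_tests",
               pipeline_median_tests(pheno, n_mc = cfg$n_mc))

  # --- i-normalized traits -------------------------------------------
  # i-normalize the raw T/S per cohort x timepoint analysis set
  pheno$ltl_inorm <- NA_real_
  for (tp in unique(pheno$timepoint)) {
    sel <- pheno$timepoint == tp
    pheno$ltl_inorm[sel] <- inverse_normal_transform(pheno$ts_ratio[sel])
  }

  # --- per-cohort models ---------------------------------------------
  percohort <- stage("per_cohort_models", {
    rows <- list()
    for (co in unique(pheno$cohort)) for (tp in unique(pheno$timepoint)) {
      dat <- pheno[pheno$cohort == co & pheno$timepoint == tp, ]
      covs <- c("sex", "age", "age:sex")
      fit <- fit_polygenic(dat, "ltl_inorm", covs, km)
      for (cv in covs) {
        p <- lrt_covariate(dat, "ltl_inorm", covs, km, cv)$p_value
        rows[[length(rows) + 1L]] <- data.frame(
          model = paste(co, tp, sep = "_"), parameter = cv, p = p)
      }
    }
    do.call(rbind, rows)
  })

  # --- combined models (baseline; endpoint + diet) --------------------
  tab2 <- stage("combined_models", {
    rows <- list()
    for (tp in c("t0", "t2")) {
      dat <- pheno[pheno$timepoint == tp, ]
      # diet enters the endpoint model only when both diets are present
      covs <- c("sex", "age",
                if (tp == "t2" && length(unique(dat$diet)) > 1) "diet")
      fit <- fit_polygenic(dat, "ltl_inorm", covs, km)
      b <- stats::setNames(fit$beta$estimate, fit$beta$term)
      s <- stats::setNames(fit$beta$se, fit$beta$term)
      for (cv in covs) {
        term <- if (cv == "sex") "sexM" else cv
        est <- if (cv == "sex") sex_female_effect(b) else unname(b[[term]])
        rows[[length(rows) + 1L]] <- data.frame(
          model = tp, parameter = paste0("beta_", cv), mle = est,
          se = unname(s[[term]]),
          p = lrt_covariate(dat, "ltl_inorm", covs, km, cv)$p_value)
      }
      hl <- lrt_heritability(dat, "ltl_inorm", covs, km)
      rows[[length(rows) + 1L]] <- data.frame(
        model = tp, parameter = "h2", mle = fit$h2, se = fit$h2_se,
        p = hl$p_value)
    }
    do.call(rbind, rows)
  })

  # --- delta-LTL ------------------------------------------------------
  dl <- stage("delta_ltl", {
    res <- lapply(c("t0", "t2"), function(tp) {
      sel <- pheno$timepoint == tp
      r <- residualize(pheno$ltl_inorm[sel],
                       pheno[sel, c("sex", "age"), drop = FALSE])
      stats::setNames(r, pheno$id[sel])
    })
    d <- delta_ltl(res[[1]], res[[2]], mode = "adjusted_residual")
    t0 <- pheno[pheno$timepoint == "t0", ]
    out <- t0[match(names(d), t0$id), c("id", "cohort", "sex", "age")]
    out$diet <- as.numeric(out$cohort == "experimental")
    out$delta_ltl <- as.numeric(d)
    for (nm in secondary) out[[nm]] <- t0[[nm]][match(out$id, t0$id)]
    out
  })
  delta_diet <- stage("delta_diet_test", {
    if (length(unique(dl$cohort)) < 2)
      data.frame(test = character(), p = numeric())
    else {
      p_lrt <- lrt_covariate(dl, "delta_ltl", c("diet"), km, "diet")$p_value
      raw0 <- pheno[pheno$timepoint == "t0", ]
      raw2 <- pheno[pheno$timepoint == "t2", ]
      draw <- delta_ltl(stats::setNames(raw0$ts_ratio, raw0$id),
                        stats::setNames(raw2$ts_ratio, raw2$id))
      grp <- raw0$cohort[match(names(draw), raw0$id)]
      mt <- exact_mwu_test(draw[grp == "experimental"], draw[grp == "control"],
                           n_mc = cfg$n_mc, seed = cfg$seed %||% 1L)
      data.frame(test = c("delta_diet_lrt", "delta_diet_median"),
                 p = c(p_lrt, mt$p_value))
    }
  })

  # --- association tables --------------------------------------------
  t2 <- pheno[pheno$timepoint == "t2", ]
  t2$delta_ltl <- dl$delta_ltl[match(t2$id, dl$id)]
  assoc_table <- function(traits, predictor) {
    rows <- lapply(traits, function(tr)
      covariate_association(t2, trait = tr, predictor = predictor,
                            kinship = km))
    do.call(rbind, rows)
  }
  tab3 <- stage("biomarkers", {
    if (length(biomarkers)) {
      rows <- lapply(biomarkers, function(bm)
        covariate_association(t2, trait = "ltl_inorm", predictor = bm,
                              kinship = km))
      cbind(trait = biomarkers, do.call(rbind, rows))
    } else empty_assoc()
  })
  if (length(lesions) >= 2) {
    t2$lesion_sum <- rowSums(t2[lesions])
    t2$lesion_mean <- rowMeans(t2[lesions])
    lesion_set <- c(lesions, "lesion_sum", "lesion_mean")
  } else lesion_set <- lesions
  tab4 <- stage("ltl_lesions", {
    if (length(lesion_set)) cbind(trait = lesion_set,
                                  assoc_table(lesion_set, "ltl_inorm"))
    else empty_assoc()
  })
  tab5 <- stage("delta_lesions", {
    if (length(lesion_set)) cbind(trait = lesion_set,
                                  assoc_table(lesion_set, "delta_ltl"))
    else empty_assoc()
  })

  # --- write report ---------------------------------------------------
  wt <- function(df, f) utils::write.table(
    df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(tab1, "table1_descriptives.tsv")
  wt(tab2, "table2_models.tsv")
  wt(tab3, "table3_biomarkers.tsv")
  wt(tab4, "table4_ltl_lesions.tsv")
  wt(tab5, "table5_delta_lesions.tsv")
  wt(med, "median_tests.tsv")
  wt(percohort, "per_cohort_models.tsv")
  wt(delta_diet, "delta_diet_tests.tsv")
  n_tests <- nrow(med) + nrow(percohort) + nrow(tab2) + nrow(delta_diet) +
    nrow(tab3) + nrow(tab4) + nrow(tab5)
  meta <- list(package_version = as.character(utils::packageVersion("telodyn")),
               mode = cfg$mode,
               scenario = if (is.character(cfg$scenario)) cfg$scenario
                          else cfg$scenario$name,
               seed = cfg$seed, n_tests_performed = n_tests,
               note = "no multiple-testing adjustment applied")
  yaml::write_yaml(meta, file.path(cfg$out_dir, "run_metadata.yaml"))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(structure(list(descriptives = tab1, median_tests = med,
                           per_cohort_models = percohort, models = tab2,
                           delta_tests = delta_diet, biomarkers = tab3,
                           ltl_lesions = tab4, delta_lesions = tab5,
                           metadata = meta, out_dir = cfg$out_dir),
                      class = "study_report"))
}

empty_assoc <- function() {
  data.frame(trait = character(), predictor = character(), r2 = numeric(),
             r = numeric(), p = numeric(), beta = numeric(), n = integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The battery of raw-data median comparisons: between cohorts and between
# sexes at each time point, and between time points within each cohort.
pipeline_median_tests <- function(pheno, n_mc = 1e5, value = "ts_ratio") {
  rows <- list()
  push <- function(label, a, b) {
    if (length(a) < 1 || length(b) < 1) return()
    mt <- exact_mwu_test(a, b, n_mc = n_mc, seed = 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, n_a = mt$n_a, n_b = mt$n_b,
      median_a = mt$median_a, median_b = mt$median_b,
      statistic = mt$statistic, p = mt$p_value, method = mt$method)
  }
  v <- function(co, tp, sx = NULL) {
    sel <- pheno$cohort == co & pheno$timepoint == tp
    if (!is.null(sx)) sel <- sel & pheno$sex == sx
    pheno[[value]][sel]
  }
  for (tp in unique(pheno$timepoint)) {
    push(paste0("control_vs_experimental_", tp),
         v("control", tp), v("experimental", tp))
    for (sx in c("F", "M"))
      push(paste0("control_vs_experimental_", tp, "_", sx),
           v("control", tp, sx), v("experimental", tp, sx))
    for (co in unique(pheno$cohort))
      push(paste0(co, "_F_vs_M_", tp), v(co, tp, "F"), v(co, tp, "M"))
  }
  for (co in unique(pheno$cohort)) {
    push(paste0(co, "_t0_vs_t2"), v(co, "t0"), v(co, "t2"))
    for (sx in c("F", "M"))
      push(paste0(co, "_t0_vs_t2_", sx), v(co, "t0", sx), v(co, "t2", sx))
  }
  do.call(rbind, rows)
}
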