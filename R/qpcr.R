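#' Read a qPCR plate export
#'
#' Plate CSVs carry one row per well with columns `well`, `sample`, `target`
#' (`TEL` for the telomere assay, `SCG` for the single-copy gene), `role`
#' (`standard`, `unknown` or `reference`), `ct`, and `quantity_ng` (the known
#' input quantity for standards, empty for unknowns).
#'
#' @param path CSV file path.
#' @return data.frame of wells (class `plate_data`).
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_plate(df)
}

#' @rdname read_plate
#' @param df data.frame with the plate columns.
#' @export
as_plate <- function(df) {
  req <- c("well", "sample", "target", "role", "ct")
  if (!all(req %in% names(df)))
    stop("plate needs columns: ", paste(req, collapse = ", "))
  if (is.null(df$quantity_ng)) df$quantity_ng <- NA_real_
  df$ct <- as.numeric(df$ct)
  df$quantity_ng <- as.numeric(df$quantity_ng)
  if (!all(df$target %in% c("TEL", "SCG")))
    stop("target must be TEL or SCG")
  if (!all(df$role %in% c("standard", "unknown", "reference")))
    stop("role must be standard, unknown or reference")
  std <- df$role == "standard"
  if (any(std & (is.na(df$quantity_ng) | df$quantity_ng <= 0)))
    stop("standard wells must carry a positive quantity_ng")
  class(df) <- c("plate_data", "data.frame")
  df
}

#' Aggregate replicate Ct values for one sample/target
#'
#' Replicates (expected in triplicate) are screened against the replicate
#' median: any Ct more than `outlier_threshold` cycles from the median is
#' dropped, and the mean of the survivors is returned. Flags report dropped
#' outliers and low replication (< 2 surviving wells).
#'
#' @param ct numeric vector of replicate Ct values.
#' @param outlier_threshold cycles from the replicate median beyond which a
#'   replicate is discarded.
#' @return list with `ct` (aggregated mean) and `qc_flags` (character).
#' @export
aggregate_replicates <- function(ct, outlier_threshold = 0.5) {
  ct <- ct[is.finite(ct)]
  if (!length(ct)) stop("no finite Ct values for this sample/target")
  flags <- character()
  keep <- abs(ct - stats::median(ct)) <= outlier_threshold
  if (any(!keep)) flags <- c(flags, "ct_outlier_dropped")
  ct <- ct[keep]
  if (length(ct) < 2) flags <- c(flags, "low_replication")
  list(ct = mean(ct), qc_flags = flags)
}

#' Fit a standard curve for one target
#'
#' Ordinary least squares of aggregated standard Ct on log10(quantity):
#' `Ct = slope * log10(ng) + intercept`. Amplification efficiency is
#' `10^(-1/slope) - 1` (a perfect doubling per cycle gives slope -3.3219 and
#' efficiency 1). The standard design of the assay is five 3-fold dilutions
#' spanning 2.22-180 ng (81-fold overall).
#'
#' @param plate `plate_data` (or subset); wells with `role == "standard"` and
#'   the requested target are used.
#' @param target `"TEL"` or `"SCG"`.
#' @param outlier_threshold passed to [aggregate_replicates()].
#' @return Object of class `standard_curve`: list with `target`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n_levels`, `quantity_range`.
#' @export
fit_standard_curve <- function(plate, target = c("TEL", "SCG"),
                               outlier_threshold = 0.5) {
  target <- match.arg(target)
  std <- plate[plate$role == "standard" & plate$target == target, , drop = FALSE]
  qs <- sort(unique(std$quantity_ng))
  if (length(qs) < 3)
    stop("need at least 3 distinct standard quantities for ", target)
  agg <- vapply(qs, function(q) {
    aggregate_replicates(std$ct[std$quantity_ng == q], outlier_threshold)$ct
  }, numeric(1))
  fit <- stats::lm(agg ~ log10(qs))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve for ", target, " has non-negative slope")
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    max(sum((agg - mean(agg))^2), .Machine$double.eps)
  r2 <- min(max(r2, 0), 1)
  structure(list(target = target, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = 10^(-1 / slope) - 1,
                 n_levels = length(qs), quantity_range = range(qs)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve [%s]: Ct = %.4f*log10(ng) + %.3f  (R2 = %.4f, eff = %.3f)\n",
    x$target, x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Interpolate a quantity from a standard curve
#'
#' Inverts the curve: `quantity = 10^((ct - intercept)/slope)`. Values
#' outside the calibrated quantity range (with a relative tolerance) are
#' returned with an extrapolation flag.
#'
#' @param curve a `standard_curve`.
#' @param ct Ct value(s).
#' @param tol relative tolerance on the calibrated range before flagging.
#' @return list with `quantity` (ng-equivalents) and `qc_flags`.
#' @export
quantify <- function(curve, ct, tol = 0.1) {
  if (any(!is.finite(ct))) stop("non-finite Ct")
  q <- 10^((ct - curve$intercept) / curve$slope)
  lo <- curve$quantity_range[1] * (1 - tol)
  hi <- curve$quantity_range[2] * (1 + tol)
  flags <- if (any(q < lo | q > hi)) "extrapolated" else character()
  list(quantity = q, qc_flags = flags)
}

#' Compute T/S ratios for a plate
#'
#' Fits one standard curve per target, aggregates the replicate Cts of every
#' non-standard sample, interpolates the matching standard-DNA quantity for
#' the telomere (T) and single-copy-gene (S) signals, and reports
#' `ts = T / S`, which is proportional to mean telomere length. If
#' `reference` names a sample (or a well has `role == "reference"`), all T/S
#' values are divided by the reference sample's T/S; by default ratios are
#' reported as raw standard-matched quantity ratios.
#'
#' @param plate a `plate_data`.
#' @param reference optional reference sample id for renormalization.
#' @param outlier_threshold replicate QC threshold (cycles), see
#'   [aggregate_replicates()].
#' @return data.frame with columns sample, t_quantity, s_quantity, ts,
#'   qc_flags (comma-separated).
#' @export
compute_ts <- function(plate, reference = NULL, outlier_threshold = 0.5) {
  plate <- as_plate(as.data.frame(plate))
  curve_tel <- fit_standard_curve(plate, "TEL", outlier_threshold)
  curve_scg <- fit_standard_curve(plate, "SCG", outlier_threshold)
  unk <- plate[plate$role != "standard", , drop = FALSE]
  if (is.null(reference) && any(unk$role == "reference"))
    reference <- unique(unk$sample[unk$role == "reference"])[1]
  samples <- unique(unk$sample)
  rows <- lapply(samples, function(s) {
    flags <- character()
    res <- lapply(c("TEL", "SCG"), function(tg) {
      ct <- unk$ct[unk$sample == s & unk$target == tg]
      ct <- ct[is.finite(ct)]
      if (!length(ct)) return(NULL)
      aggregate_replicates(ct, outlier_threshold)
    })
    if (is.null(res[[1]]) || is.null(res[[2]])) {
      warning("sample ", s, " missing a target; skipped")
      return(data.frame(sample = s, t_quantity = NA_real_,
                        s_quantity = NA_real_, ts = NA_real_,
                        qc_flags = "missing_target"))
    }
    qt <- quantify(curve_tel, res[[1]]$ct)
    qs <- quantify(curve_scg, res[[2]]$ct)
    flags <- unique(c(res[[1]]$qc_flags, res[[2]]$qc_flags,
                      qt$qc_flags, qs$qc_flags))
    data.frame(sample = s, t_quantity = qt$quantity, s_quantity = qs$quantity,
               ts = qt$quantity / qs$quantity,
               qc_flags = paste(flags, collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    ref_ts <- out$ts[out$sample == reference]
    if (length(ref_ts) != 1 || is.na(ref_ts))
      stop("reference sample not found or unquantifiable: ", reference)
    out$ts <- out$ts / ref_ts
  }
  attr(out, "curves") <- list(TEL = curve_tel, SCG = curve_scg)
  out
}

#' Forward-simulate a qPCR plate from known T/S ratios
#'
#' Generates wells from the standard-curve model: each sample contributes
#' `s_quantity` ng-equivalents of the single-copy signal and
#' `ts * s_quantity` of the telomere signal, and every well's Ct is drawn
#' from the appropriate curve plus Gaussian noise. Standards follow the
#' five-level 3-fold dilution design spanning 2.22-180 ng. Used for fixture
#' construction and round-trip validation.
#'
#' @param ts named numeric vector of true T/S ratios (names = sample ids).
#' @param s_quantity single-copy-gene input quantity per sample (ng).
#' @param curve_tel,curve_scg lists with `slope` and `intercept`.
#' @param ct_sd Gaussian Ct noise standard deviation (cycles).
#' @param n_rep replicate wells per sample/target.
#' @param standards vector of standard quantities (ng).
#' @param reference optional sample id to mark with `role = "reference"`.
#' @param seed RNG seed.
#' @return `plate_data` data.frame.
#' @export
simulate_plate <- function(ts, s_quantity = 20,
                           curve_tel = list(slope = -3.3219, intercept = 22),
                           curve_scg = list(slope = -3.3219, intercept = 25),
                           ct_sd = 0, n_rep = 3,
                           standards = 180 / 3^(0:4),
                           reference = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(ts))) names(ts) <- paste0("S", seq_along(ts))
  s_quantity <- rep_len(s_quantity, length(ts))
  ct_of <- function(curve, q) curve$slope * log10(q) + curve$intercept
  rows <- list()
  for (tg in c("TEL", "SCG")) {
    curve <- if (tg == "TEL") curve_tel else curve_scg
    for (q in standards) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("STD_%s_%g", tg, q), target = tg, role = "standard",
        ct = ct_of(curve, q) + stats::rnorm(n_rep, 0, ct_sd), quantity_ng = q)
    }
    for (i in seq_along(ts)) {
      q <- if (tg == "TEL") ts[i] * s_quantity[i] else s_quantity[i]
      role <- if (!is.null(reference) && names(ts)[i] == reference)
        "reference" else "unknown"
      rows[[length(rows) + 1L]] <- data.frame(
        sample = names(ts)[i], target = tg, role = role,
        ct = ct_of(curve, q) + stats::rnorm(n_rep, 0, ct_sd),
        quantity_ng = NA_real_)
    }
  }
  df <- do.call(rbind, rows)
  df <- cbind(well = sprintf("W%03d", seq_len(nrow(df))), df)
  as_plate(df)
}

#' Write T/S results as TSV
#'
#' @param ts_table output of [compute_ts()].
#' @param path file path.
#' @export
write_ts <- function(ts_table, path) {
  utils::write.table(ts_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
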