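#' Sample quartiles (linear interpolation)
#'
#' Quartiles under the linear-interpolation convention
#' (`stats::quantile(type = 7)`), fixed package-wide so that dispersion
#' statistics are reproducible across tools: the convention materially
#' shifts QCD values on small samples.
#'
#' @param values numeric vector with at least one finite value.
#' @return Named numeric vector `c(Q1, median, Q3)`.
#' @export
quartiles <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty sample: no finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(Q1 = q[1], median = q[2], Q3 = q[3])
}

#' Quartile coefficient of dispersion
#'
#' `QCD = (Q3 - Q1) / (Q3 + Q1)`, a robust relative-spread measure suited to
#' skewed, outlier-prone dose distributions. Lies in `[0, 1]` for strictly
#' positive samples and is invariant to positive rescaling.
#'
#' @param values numeric vector (intended use: positive absorbed doses).
#' @return The QCD as a fraction (multiply by 100 to report percent).
#' @export
qcd <- function(values) {
  q <- quartiles(values)
  s <- q[["Q3"]] + q[["Q1"]]
  if (s == 0) stop("QCD undefined: Q1 + Q3 = 0", call. = FALSE)
  (q[["Q3"]] - q[["Q1"]]) / s
}

#' Subset-size-weighted QCD
#'
#' When a cohort splits into two VOI-format subsets (RTStruct and binary
#' mask) whose doses differ systematically, the pooled QCD conflates format
#' and segmentation variability. The weighted QCD averages the per-subset
#' QCDs by subset size:
#' `QCDw = (n_rtstruct * qcd_rtstruct + n_mask * qcd_mask) / n_total`.
#'
#' @param qcd_rtstruct,qcd_mask per-subset QCDs (a subset with `n = 0` may
#'   pass `NA`).
#' @param n_rtstruct,n_mask subset sizes, >= 0 with a positive total.
#' @return The weighted QCD.
#' @export
qcd_weighted <- function(qcd_rtstruct, n_rtstruct, qcd_mask, n_mask) {
  if (n_rtstruct < 0 || n_mask < 0)
    stop("subset sizes must be >= 0", call. = FALSE)
  n_total <- n_rtstruct + n_mask
  if (n_total == 0) stop("empty cohort: n_total = 0", call. = FALSE)
  a <- if (n_rtstruct > 0) n_rtstruct * qcd_rtstruct else 0
  b <- if (n_mask > 0) n_mask * qcd_mask else 0
  (a + b) / n_total
}

# weighted IQR across format subsets, analogous to the weighted QCD
iqr_weighted <- function(iqr_rtstruct, n_rtstruct, iqr_mask, n_mask) {
  qcd_weighted(iqr_rtstruct, n_rtstruct, iqr_mask, n_mask)
}

#' Paired percent dose difference between tasks
#'
#' For a participant who segmented independently (task 1) and also used the
#' provided reference VOIs (task 4):
#' `delta = 100 * (AD_task1 - AD_task4) / mean_AD_task4`, where the
#' denominator is the cohort-mean task-4 dose for that region. Positive
#' values indicate a higher dose with the participant's own segmentation;
#' magnitudes may exceed 100%.
#'
#' @param ad_task1,ad_task4 the participant's absorbed doses, Gy.
#' @param mean_ad_task4 cohort-mean task-4 dose for the region, Gy, > 0.
#' @return Percent difference.
#' @export
delta_ad <- function(ad_task1, ad_task4, mean_ad_task4) {
  if (any(mean_ad_task4 <= 0))
    stop("mean_ad_task4 must be > 0", call. = FALSE)
  100 * (ad_task1 - ad_task4) / mean_ad_task4
}

#' Dispersion summary of a cohort of dose submissions
#'
#' Computes, per region: the task-1 QCD, per-VOI-format task-4 QCDs, the
#' weighted task-4 QCD, and their difference (task 1 minus weighted task 4
#' -- the segmentation-induced variability); and per segmentation method:
#' median, IQR, range (max minus min) and n of the paired percent dose
#' differences, plus a format-weighted IQR per region.
#'
#' @param records data.frame with columns `participant`, `region`, `task`
#'   (`"task1"`/`"task4"`), `voi_format` (`"RTStruct"`/`"mask"`, `NA` for
#'   task 1), `method`, `dose_Gy`.
#' @param low_n minimum records per region/task for QCD reporting; regions
#'   below it are flagged (`low_n = TRUE`) but still summarised.
#' @return List with `summary` (one row per region), `deltas` (one row per
#'   paired participant/region) and `by_method` (one row per region/method).
#' @export
summarize_cohort <- function(records, low_n = 3L) {
  need <- c("participant", "region", "task", "voi_format", "method", "dose_Gy")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop(sprintf("records missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (any(records$dose_Gy <= 0))
    stop("doses must be > 0", call. = FALSE)
  records <- records[order(records$region, records$task, records$participant), ]

  summary_rows <- list(); delta_rows <- list()
  for (reg in sort(unique(records$region))) {
    r <- records[records$region == reg, ]
    t1 <- r[r$task == "task1", ]
    t4 <- r[r$task == "task4", ]
    if (!nrow(t1) || !nrow(t4)) {
      warning(sprintf("region '%s' has no paired records; excluded", reg),
              call. = FALSE)
      next
    }
    t4_rt <- t4[t4$voi_format == "RTStruct", ]
    t4_mk <- t4[t4$voi_format == "mask", ]
    qcd_rt <- if (nrow(t4_rt)) qcd(t4_rt$dose_Gy) else NA_real_
    qcd_mk <- if (nrow(t4_mk)) qcd(t4_mk$dose_Gy) else NA_real_
    qcdw <- qcd_weighted(qcd_rt, nrow(t4_rt), qcd_mk, nrow(t4_mk))
    qcd1 <- qcd(t1$dose_Gy)

    # paired deltas against the pooled task-4 mean
    mean_t4 <- mean(t4$dose_Gy)
    paired <- intersect(t1$participant, t4$participant)
    d1 <- t1[match(paired, t1$participant), ]
    d4 <- t4[match(paired, t4$participant), ]
    dd <- data.frame(participant = paired, region = reg,
                     method = d1$method, voi_format = d4$voi_format,
                     AD_task1 = d1$dose_Gy, AD_task4 = d4$dose_Gy,
                     mean_AD_task4 = mean_t4,
                     delta_pct = delta_ad(d1$dose_Gy, d4$dose_Gy, mean_t4),
                     stringsAsFactors = FALSE)
    delta_rows[[reg]] <- dd

    iqr_of <- function(x) unname(diff(quartiles(x)[c("Q1", "Q3")]))
    d_rt <- dd$delta_pct[dd$voi_format == "RTStruct"]
    d_mk <- dd$delta_pct[dd$voi_format == "mask"]
    iqrw <- iqr_weighted(if (length(d_rt)) iqr_of(d_rt) else NA_real_,
                         length(d_rt),
                         if (length(d_mk)) iqr_of(d_mk) else NA_real_,
                         length(d_mk))
    summary_rows[[reg]] <- data.frame(
      region = reg,
      n_task1 = nrow(t1), n_RTStruct = nrow(t4_rt), n_mask = nrow(t4_mk),
      n_total = nrow(t4),
      QCD_task1 = qcd1, QCD_RTStruct = qcd_rt, QCD_mask = qcd_mk,
      QCDw_task4 = qcdw, QCD_difference = qcd1 - qcdw,
      median_delta_pct = unname(quartiles(dd$delta_pct)["median"]),
      IQR_delta_pct = iqr_of(dd$delta_pct), IQRw_delta_pct = iqrw,
      low_n = nrow(t1) < low_n || nrow(t4) < low_n,
      stringsAsFactors = FALSE)
  }
  deltas <- do.call(rbind, c(delta_rows, list(make.row.names = FALSE)))
  summary <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))

  by_method <- NULL
  if (!is.null(deltas) && nrow(deltas)) {
    sp <- split(deltas, list(deltas$region, deltas$method), drop = TRUE)
    by_method <- do.call(rbind, lapply(sp, function(g) {
      q <- quartiles(g$delta_pct)
      data.frame(region = g$region[1], method = g$method[1],
                 median_delta_pct = unname(q["median"]),
                 IQR_delta_pct = unname(q["Q3"] - q["Q1"]),
                 range_delta_pct = max(g$delta_pct) - min(g$delta_pct),
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
    by_method <- by_method[order(by_method$region, by_method$method), ]
    rownames(by_method) <- NULL
  }
  list(summary = summary, deltas = deltas, by_method = by_method)
}
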