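#' Local-deposition dose factor for Lu-177
#'
#' Mean electron (beta plus conversion/Auger) energy emitted per Lu-177
#' decay, expressed as absorbed energy per unit cumulated activity under the
#' assumption of complete local deposition: 147.9 keV/decay = 8.53e-2
#' Gy.g.MBq^-1.h^-1. Photon cross-dose is deliberately not included; organ
#' self-dose from Lu-177 is dominated by the electron component.
#'
#' @format A single number, Gy.g.MBq^-1.h^-1.
#' @export
LU177_ELECTRON_DOSE_FACTOR <- 8.53e-2

#' Recover a time-activity curve from an image series
#'
#' Activity at each time point is the sum of voxel concentrations inside the
#' VOI times the voxel volume. No partial-volume correction is applied.
#'
#' @param series an `activity_series`.
#' @param vois a single [voi] (broadcast to every time point) or a list with
#'   one VOI per time point.
#' @param region label carried into the curve (for reporting).
#' @return A `time_activity_curve`: `times_h`, `activity_MBq`, `region`,
#'   `provenance`, and `empty_voi` flag (TRUE if any VOI was empty; those
#'   time points contribute zero activity).
#' @export
measure_activity <- function(series, vois, region = NA_character_) {
  stopifnot(inherits(series, "activity_series"))
  nt <- length(series$times_h)
  if (inherits(vois, "voi")) vois <- rep(list(vois), nt)
  if (length(vois) != nt)
    stop("need one VOI per time point (or a single VOI to broadcast)",
         call. = FALSE)
  vv <- voxel_volume_ml(series$grid)
  empty <- FALSE
  act <- vapply(seq_len(nt), function(k) {
    v <- vois[[k]]
    stopifnot(inherits(v, "voi"))
    stop_if_grid_mismatch(series$grid, v$grid)
    if (!any(v$mask)) { empty <<- TRUE; return(0) }
    sum(series$volumes[[k]][v$mask]) * vv
  }, numeric(1))
  if (empty) warning("empty VOI: zero activity recorded", call. = FALSE)
  structure(list(times_h = series$times_h, activity_MBq = act,
                 region = region, provenance = vois[[1]]$method,
                 empty_voi = empty),
            class = "time_activity_curve")
}

#' Mono-exponential time-activity fit
#'
#' Least-squares fit of `A(t) = A0 * exp(-lambda * t)` by the
#' Levenberg-Marquardt algorithm, initialised from a log-linear regression
#' on the positive activities; `lambda` is constrained positive. Data whose
#' log-linear slope is nonnegative (non-decaying) are rejected rather than
#' clamped, to surface degenerate segmentations.
#'
#' @param tac a `time_activity_curve` (or list with `times_h`,
#'   `activity_MBq`).
#' @return A `tac_fit`: `A0_MBq`, `lambda_eff_per_h`, `residual_norm`,
#'   `model = "monoexp"`.
#' @export
fit_tac <- function(tac) {
  t <- tac$times_h; A <- tac$activity_MBq
  if (length(t) != length(A)) stop("length mismatch", call. = FALSE)
  pos <- A > 0
  if (all(A == 0)) stop("empty curve: all activities are zero", call. = FALSE)
  if (sum(pos) < 2L)
    stop("need at least 2 positive activities to fit", call. = FALSE)
  # log-linear initialisation on the positive samples
  lf <- stats::lm.fit(cbind(1, t[pos]), log(A[pos]))
  slope <- lf$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    stop("non-physical kinetics: activity does not decay", call. = FALSE)
  start <- list(A0 = exp(lf$coefficients[[1]]), lambda = -slope[[1]])
  fit <- minpack.lm::nlsLM(A ~ A0 * exp(-lambda * t),
                           data = list(A = A, t = t),
                           start = start,
                           lower = c(A0 = 0, lambda = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(A0_MBq = unname(cf["A0"]),
                 lambda_eff_per_h = unname(cf["lambda"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 model = "monoexp"),
            class = "tac_fit")
}

#' Time-integrated activity coefficient
#'
#' Analytic 0-to-infinity integral of the fitted mono-exponential,
#' normalised by the injected activity: `TIAC = (A0 / lambda) / A_injected`,
#' in hours.
#'
#' @param fit a `tac_fit`.
#' @param injected_activity_MBq administered activity, MBq, > 0.
#' @return TIAC in hours.
#' @export
tiac <- function(fit, injected_activity_MBq) {
  if (injected_activity_MBq <= 0)
    stop("injected_activity_MBq must be > 0", call. = FALSE)
  if (!is.finite(fit$lambda_eff_per_h) || fit$lambda_eff_per_h <= 0)
    stop("non-physical fit: lambda <= 0", call. = FALSE)
  (fit$A0_MBq / fit$lambda_eff_per_h) / injected_activity_MBq
}

#' Absorbed dose under local electron deposition
#'
#' `D = TIAC * A_injected * Delta / mass`, with `Delta` in
#' Gy.g.MBq^-1.h^-1. The default `Delta` is the Lu-177 mean electron energy
#' per decay ([LU177_ELECTRON_DOSE_FACTOR]); photon cross-dose is not
#' modelled, so doses are slight underestimates of a full S-value
#' calculation.
#'
#' @param tiac_h time-integrated activity coefficient, hours.
#' @param injected_activity_MBq administered activity, MBq.
#' @param mass_g region mass, g, > 0.
#' @param dose_factor energy deposition per cumulated activity,
#'   Gy.g.MBq^-1.h^-1.
#' @return Absorbed dose in Gy.
#' @export
absorbed_dose <- function(tiac_h, injected_activity_MBq, mass_g,
                          dose_factor = LU177_ELECTRON_DOSE_FACTOR) {
  if (any(mass_g <= 0)) stop("mass_g must be > 0", call. = FALSE)
  tiac_h * injected_activity_MBq * dose_factor / mass_g
}

#' Percent difference from a reference value
#'
#' `100 * (variant - reference) / reference`, the convention used for
#' scenario reporting (positive means the variant is larger).
#'
#' @param variant,reference numeric values; `reference` must be nonzero.
#' @return Percent difference.
#' @export
percent_difference <- function(variant, reference) {
  if (any(reference == 0))
    stop("percent difference undefined for zero reference", call. = FALSE)
  100 * (variant - reference) / reference
}

#' Tumour-to-background ratio
#'
#' Lesion SUVmax divided by healthy-liver SUVmean at one time point. The SUV
#' normalisation (injected activity per body weight) cancels, so the ratio
#' equals max lesion concentration over mean liver concentration; the
#' arguments are retained to make the cancellation explicit.
#'
#' @param series an `activity_series`.
#' @param lesion_voi,liver_voi nonempty [voi] objects.
#' @param injected_activity_MBq,body_weight_kg SUV normalisation inputs
#'   (cancel in the ratio).
#' @param time_index which time point to evaluate (default 2, the second
#'   scan).
#' @return The TBR (dimensionless).
#' @export
compute_tbr <- function(series, lesion_voi, liver_voi,
                        injected_activity_MBq = NULL, body_weight_kg = NULL,
                        time_index = 2L) {
  stopifnot(inherits(series, "activity_series"))
  if (!any(lesion_voi$mask) || !any(liver_voi$mask))
    stop("lesion and liver VOIs must be nonempty", call. = FALSE)
  stop_if_grid_mismatch(series$grid, lesion_voi$grid)
  stop_if_grid_mismatch(series$grid, liver_voi$grid)
  v <- series$volumes[[time_index]]
  liver_mean <- mean(v[liver_voi$mask])
  if (liver_mean <= 0)
    stop("TBR undefined: liver mean concentration is zero", call. = FALSE)
  max(v[lesion_voi$mask]) / liver_mean
}
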