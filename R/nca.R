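#' Linear trapezoidal AUC
#'
#' Area under the concentration-time curve from the first sampling time to
#' `t_end` by the linear trapezoidal rule. When a BLQ indicator is given,
#' BLQ points before the (non-BLQ) Cmax are treated as zero and BLQ points
#' after it are excluded; if `t_end` is not an observed time the curve is
#' interpolated linearly to it.
#'
#' @param times sorted sampling times, h.
#' @param concs concentrations, ng/mL (nonnegative; NA only where `blq`).
#' @param t_end upper integration limit, h (default: last time).
#' @param blq optional 0/1 BLQ flags aligned with `times`.
#' @return AUC in ng h/mL.
#' @examples
#' auc_trapz(c(0, 1), c(100, 50))  # one trapezoid: 75
#' @export
auc_trapz <- function(times, concs, t_end = max(times), blq = NULL) {
  if (length(times) != length(concs))
    stop("times and concs lengths differ", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (t_end > max(times))
    stop("t_end exceeds the last observation", call. = FALSE)
  if (!is.null(blq)) {
    stopifnot(length(blq) == length(times))
    q <- which(blq == 0L & !is.na(concs))
    if (!length(q)) stop("no quantifiable points", call. = FALSE)
    tmax <- times[q[which.max(concs[q])]]
    pre <- blq == 1L & times <= tmax
    concs[pre] <- 0
    keep <- blq == 0L | pre
    times <- times[keep]; concs <- concs[keep]
    # a censored tail truncates the integral at the last usable point
    t_end <- min(t_end, max(times))
  }
  keep <- times <= t_end
  if (t_end > 0 && !(t_end %in% times)) {
    i <- max(which(times < t_end))
    if (i == length(times)) stop("cannot interpolate past the data",
                                 call. = FALSE)
    c_end <- concs[i] + (concs[i + 1L] - concs[i]) *
      (t_end - times[i]) / (times[i + 1L] - times[i])
    times <- c(times[keep], t_end); concs <- c(concs[keep], c_end)
  } else {
    times <- times[keep]; concs <- concs[keep]
  }
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(is.na(concs)) || any(concs < 0))
    stop("concs must be nonnegative and non-missing", call. = FALSE)
  sum(diff(times) * (utils::head(concs, -1L) + utils::tail(concs, -1L)) / 2)
}

#' Terminal half-life from the last points
#'
#' Log-linear least squares on the last `n_tail` positive concentrations;
#' `t_half = ln 2 / |slope|`. Flagged unreliable (but still returned) when
#' the slope is nonnegative or the regression R-squared is below 0.8 —
#' with strong enterohepatic recycling the tail still fluctuates, so this
#' NCA half-life understates the true terminal phase.
#'
#' @param times sampling times, h.
#' @param concs concentrations, ng/mL.
#' @param n_tail number of terminal points (default 3).
#' @return List: `t_half` (h; `Inf` when the slope is zero, negative
#'   slope of the log-concentration fit gives a finite value), `slope`,
#'   `r_squared`, `reliable`.
#' @export
terminal_half_life <- function(times, concs, n_tail = 3L) {
  pos <- which(is.finite(concs) & concs > 0)
  if (length(pos) < n_tail)
    stop("need at least ", n_tail, " positive concentrations",
         call. = FALSE)
  idx <- utils::tail(pos, n_tail)
  t <- times[idx]; y <- log(concs[idx])
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2L])
  if (abs(slope) < 1e-12) slope <- 0
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  t_half <- if (slope < 0) log(2) / abs(slope) else Inf
  list(t_half = t_half, slope = slope, r_squared = r2,
       reliable = slope < 0 && r2 >= 0.8)
}

#' Absolute bioavailability
#'
#' `F_abs (%) = 100 * (mean AUC_test * dose_iv) /
#'              (mean AUC_iv * dose_test)`, comparing an extravascular
#' route's exposure with the IV reference.
#'
#' @param mean_auc_test,mean_auc_iv mean AUC of the test and IV routes,
#'   ng h/mL.
#' @param dose_test,dose_iv doses, same units for both.
#' @return Percentage.
#' @examples
#' f_abs(1570, 2170)  # oral: ~72.4
#' f_abs(165, 2170)   # supralingual: ~7.60
#' @export
f_abs <- function(mean_auc_test, mean_auc_iv, dose_test = 0.5,
                  dose_iv = 0.5) {
  for (v in c(mean_auc_test, mean_auc_iv, dose_test, dose_iv))
    if (!(is.finite(v) && v > 0))
      stop("all inputs must be strictly positive", call. = FALSE)
  100 * (mean_auc_test * dose_iv) / (mean_auc_iv * dose_test)
}

#' Dose fraction released from the patch
#'
#' @param residue_percent percentage of the nominal dose still in the
#'   patch after wear, in \[0, 100\].
#' @return Percentage released, `100 - residue_percent`.
#' @examples
#' released_dose_fraction(20.6)  # 79.4
#' @export
released_dose_fraction <- function(residue_percent) {
  if (!(is.finite(residue_percent) && residue_percent >= 0 &&
        residue_percent <= 100))
    stop("residue_percent must be in [0, 100]", call. = FALSE)
  100 - residue_percent
}

#' Tongue-tissue amount as a percentage of dose
#'
#' @param tongue_amount drug amount recovered from tongue tissue, ug.
#' @param nominal_dose_amount nominal dose amount, ug (per-animal:
#'   `dose_mg_kg * body_weight_g`, since mg/kg x g = ug).
#' @return Percentage of the nominal dose.
#' @examples
#' tongue_dose_percent(7.3, 192)   # ~3.8
#' tongue_dose_percent(0.21, 192)  # ~0.11
#' @export
tongue_dose_percent <- function(tongue_amount, nominal_dose_amount) {
  if (!(is.finite(tongue_amount) && tongue_amount > 0) ||
      !(is.finite(nominal_dose_amount) && nominal_dose_amount > 0))
    stop("amounts must be strictly positive", call. = FALSE)
  100 * tongue_amount / nominal_dose_amount
}

#' Non-compartmental summary for one subject
#'
#' AUC from 0 to `t_end` (linear trapezoids, BLQ rule of [auc_trapz()]),
#' terminal half-life from the last `n_tail` non-BLQ points, Cmax and
#' Tmax.
#'
#' @param data one subject's records (`time_h`, `conc_ng_ml`, `blq`).
#' @param t_end AUC upper limit, h (default 48).
#' @param n_tail terminal points for the half-life (default 3).
#' @return `data.frame` row: `auc_0_48`, `t_half`, `t_half_reliable`,
#'   `cmax`, `tmax`, `n_points_used`.
#' @export
nca_subject <- function(data, t_end = 48, n_tail = 3L) {
  stopifnot(all(c("time_h", "conc_ng_ml", "blq") %in% names(data)))
  data <- data[order(data$time_h), ]
  q <- data[data$blq == 0L & !is.na(data$conc_ng_ml), ]
  if (nrow(q) < 2L) stop("need at least 2 quantifiable points",
                         call. = FALSE)
  auc <- auc_trapz(data$time_h, data$conc_ng_ml, t_end = t_end,
                   blq = data$blq)
  th <- terminal_half_life(q$time_h, q$conc_ng_ml, n_tail = n_tail)
  data.frame(auc_0_48 = auc, t_half = th$t_half,
             t_half_reliable = th$reliable,
             cmax = max(q$conc_ng_ml),
             tmax = q$time_h[which.max(q$conc_ng_ml)],
             n_points_used = nrow(q))
}

#' Per-subject NCA table for a dataset
#'
#' @param dataset a concentration dataset ([generate_cohort()] /
#'   [read_dataset()] layout).
#' @param t_end,n_tail see [nca_subject()].
#' @return `data.frame`, one row per subject, with `subject_id`, `route`.
#' @export
nca_table <- function(dataset, t_end = 48, n_tail = 3L) {
  split_d <- split(dataset, dataset$subject_id)
  rows <- lapply(names(split_d), function(id) {
    d <- split_d[[id]]
    cbind(data.frame(subject_id = id, route = d$route[1L]),
          nca_subject(d, t_end = t_end, n_tail = n_tail))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
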