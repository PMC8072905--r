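#' Individual weighted residual
#'
#' Under the proportional error model, `IWRES = (obs - pred) /
#' (sigma * pred)`; for a well-specified model these are approximately
#' standard normal, so about 95.4% fall in \[-2, 2\].
#'
#' @param observed,predicted concentrations, ng/mL (`predicted > 0`).
#' @param sigma proportional residual SD (> 0).
#' @return Dimensionless residuals.
#' @examples
#' compute_iwres(110, 100, 0.1)  # 1
#' @export
compute_iwres <- function(observed, predicted, sigma) {
  if (!(is.numeric(sigma) && length(sigma) == 1L && is.finite(sigma) &&
        sigma > 0))
    stop("sigma must be strictly positive", call. = FALSE)
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("predicted must be strictly positive", call. = FALSE)
  (observed - predicted) / (sigma * predicted)
}

#' Goodness-of-fit tables for a fitted subject
#'
#' Pairs observations with individual predictions and summarises the fit:
#' fraction of |IWRES| <= 2, mean IWRES, and the slope/intercept of the
#' observed-on-predicted regression (unity and zero for a perfect fit).
#' The IWRES uses the subject's fitted ML sigma. Record order is
#' normalised internally, so the summary is permutation-invariant; data
#' whose values do not match the fit's observations raise an error.
#'
#' @param fit an `"ehr_fit"` object.
#' @param data the records the fit was produced from.
#' @return List with `records` (`subject_id`, `time`, `observed`,
#'   `predicted`, `iwres`) and `summary` (`n`, `frac_iwres_within_2`,
#'   `mean_iwres`, `slope`, `intercept`).
#' @export
gof_tables <- function(fit, data) {
  stopifnot(inherits(fit, "ehr_fit"))
  obs <- data[data$blq == 0L & !is.na(data$conc_ng_ml), ]
  obs <- obs[order(obs$time_h), ]
  rec <- fit$predictions[order(fit$predictions$time), ]
  if (nrow(obs) != nrow(rec) ||
      !isTRUE(all.equal(obs$time_h, rec$time)) ||
      !isTRUE(all.equal(obs$conc_ng_ml, rec$observed)))
    stop("data are not the records this fit was produced from",
         call. = FALSE)
  iw <- rec$iwres
  reg <- lm(rec$observed ~ rec$predicted)
  list(records = rec,
       summary = list(n = nrow(rec),
                      frac_iwres_within_2 = mean(abs(iw) <= 2),
                      mean_iwres = mean(iw),
                      slope = unname(coef(reg)[2L]),
                      intercept = unname(coef(reg)[1L])))
}
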