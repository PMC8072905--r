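#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @useDynLib ehrpk
#' @importFrom stats lm coef optimize rnorm rlnorm runif sd setNames nlminb
#' @importFrom utils read.csv write.csv
## usethis namespace: end
NULL

#' Administration routes
#'
#' The three routes modelled: intravenous bolus (`"IV"`), oral gavage
#' (`"ORAL"`), and the 4-h supralingual mucoadhesive patch
#' (`"SUPRALINGUAL"`). The route determines which compartments and
#' parameters are active.
#'
#' @export
ROUTES <- c("IV", "ORAL", "SUPRALINGUAL")

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_route <- function(route) {
  if (!(is.character(route) && length(route) == 1L && route %in% ROUTES))
    stop("route must be one of ", paste(ROUTES, collapse = ", "),
         call. = FALSE)
  route
}

.pos <- function(x, nm) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0))
    stop(nm, " must be a single strictly positive number", call. = FALSE)
  x
}

#' Disposition parameters of the EHR models
#'
#' Clearances, volumes and the recycling rate constants shared by all three
#' route-specific models. The supralingual model has no peripheral
#' compartment, so `CL2` and `V2` must both be absent (`NULL`) for that
#' route.
#'
#' @param CL apparent clearance from the central compartment, mL/(kg h).
#' @param V  apparent central volume of distribution, mL/kg.
#' @param CL2 apparent inter-compartmental clearance, mL/(kg h), or `NULL`.
#' @param V2 apparent peripheral volume, mL/kg, or `NULL`.
#' @param K_cb first-order rate constant, central to bile, 1/h.
#' @param K_gc first-order re-absorption rate constant, gut to central, 1/h.
#' @param Tau bile-emptying duration, h; the bile-to-gut transfer
#'   coefficient is `gbr(Tau) = 1/Tau`.
#' @return A list of class `"disposition_params"`.
#' @export
disposition_params <- function(CL, V, CL2 = NULL, V2 = NULL, K_cb, K_gc,
                               Tau) {
  .pos(CL, "CL"); .pos(V, "V"); .pos(K_gc, "K_gc"); .pos(Tau, "Tau")
  # K_cb = 0 switches the recycling loop off entirely (the nested
  # non-EHR model used in structure comparisons)
  if (!(is.numeric(K_cb) && length(K_cb) == 1L && is.finite(K_cb) &&
        K_cb >= 0))
    stop("K_cb must be a single nonnegative number", call. = FALSE)
  if (is.null(CL2) != is.null(V2))
    stop("CL2 and V2 must both be present or both absent", call. = FALSE)
  if (!is.null(CL2)) { .pos(CL2, "CL2"); .pos(V2, "V2") }
  structure(list(CL = CL, V = V, CL2 = CL2, V2 = V2, K_cb = K_cb,
                 K_gc = K_gc, Tau = Tau),
            class = "disposition_params")
}

#' Absorption parameters
#'
#' Dual-path depot absorption: a fast first-order path straight to the
#' central compartment (`Ka1`) in parallel with a slow path through a chain
#' of `n_transit` identical transit compartments (`Ka2` into the chain,
#' `K_tr` along it). The implied fast-release fraction of absorbed drug is
#' `Ka1/(Ka1 + Ka2)`; no separate dose split is introduced. For the patch
#' route the dose enters the depot as a zero-order release of
#' `released_fraction` of the nominal dose over
#' `[t_lag, patch_duration]`.
#'
#' @param Ka1 fast depot-to-central rate constant, 1/h.
#' @param Ka2 depot-to-transit-chain rate constant, 1/h.
#' @param K_tr transit chain rate constant, 1/h.
#' @param n_transit number of transit compartments (default 5).
#' @param t_lag absorption lag, h (0 for oral, 0.5 for supralingual).
#' @param patch_duration patch wear time, h (4 for supralingual, else 0).
#' @param released_fraction fraction of the nominal dose released from the
#'   dosage form, in (0, 1]; 1 for IV/oral, 0.794 for the patch.
#' @return A list of class `"absorption_params"`.
#' @export
absorption_params <- function(Ka1 = NULL, Ka2 = NULL, K_tr = NULL,
                              n_transit = 5L, t_lag = 0,
                              patch_duration = 0, released_fraction = 1) {
  for (nm in c("Ka1", "Ka2", "K_tr")) {
    v <- get(nm)
    if (!is.null(v)) .pos(v, nm)
  }
  if (!(is.numeric(n_transit) && length(n_transit) == 1L &&
        n_transit >= 1 && n_transit == round(n_transit)))
    stop("n_transit must be an integer >= 1", call. = FALSE)
  if (t_lag < 0) stop("t_lag must be >= 0", call. = FALSE)
  if (patch_duration < 0) stop("patch_duration must be >= 0", call. = FALSE)
  if (!(released_fraction > 0 && released_fraction <= 1))
    stop("released_fraction must be in (0, 1]", call. = FALSE)
  structure(list(Ka1 = Ka1, Ka2 = Ka2, K_tr = K_tr,
                 n_transit = as.integer(n_transit), t_lag = t_lag,
                 patch_duration = patch_duration,
                 released_fraction = released_fraction),
            class = "absorption_params")
}

#' Full parameter vector for one route's EHR model
#'
#' @param route one of [ROUTES].
#' @param disp [disposition_params()].
#' @param absorp [absorption_params()]; ignored for IV.
#' @param sigma proportional residual standard deviation (dimensionless),
#'   the SD of the multiplicative error `C_obs = C_pred * (1 + eps)`,
#'   `eps ~ N(0, sigma^2)`.
#' @return A list of class `"model_params"`.
#' @export
model_params <- function(route, disp, absorp = absorption_params(),
                         sigma = 0.15) {
  .check_route(route)
  stopifnot(inherits(disp, "disposition_params"),
            inherits(absorp, "absorption_params"))
  .pos(sigma, "sigma")
  if (route == "SUPRALINGUAL" && !is.null(disp$CL2))
    stop("the supralingual model has no peripheral compartment: ",
         "CL2/V2 must be absent", call. = FALSE)
  if (route %in% c("IV", "ORAL") && is.null(disp$CL2))
    stop("IV and oral models require CL2 and V2", call. = FALSE)
  if (route != "IV" &&
      (is.null(absorp$Ka1) || is.null(absorp$Ka2) || is.null(absorp$K_tr)))
    stop("Ka1, Ka2 and K_tr are required for route ", route, call. = FALSE)
  structure(list(route = route, disp = disp, absorp = absorp,
                 sigma = sigma),
            class = "model_params")
}

#' Count of estimated parameters
#'
#' Every estimated structural parameter plus sigma; fixed design quantities
#' (`n_transit`, `t_lag`, `patch_duration`, `released_fraction`, dose) are
#' not counted. This is the `p` used in `AIC = -2LL + 2p`.
#'
#' @param route one of [ROUTES].
#' @return Integer: 8 for IV, 11 for oral, 9 for supralingual.
#' @export
n_params <- function(route) {
  .check_route(route)
  length(free_param_names(route)) + 1L  # + sigma
}

#' Names of the structural parameters estimated for a route
#'
#' @param route one of [ROUTES].
#' @return Character vector of parameter names (sigma excluded; it is
#'   profiled analytically during fitting).
#' @export
free_param_names <- function(route) {
  .check_route(route)
  switch(route,
    IV = c("CL", "V", "CL2", "V2", "K_cb", "K_gc", "Tau"),
    ORAL = c("CL", "V", "CL2", "V2", "K_cb", "K_gc", "Tau",
             "Ka1", "Ka2", "K_tr"),
    SUPRALINGUAL = c("CL", "V", "K_cb", "K_gc", "Tau",
                     "Ka1", "Ka2", "K_tr"))
}

#' Dose schedule
#'
#' @param nominal_dose nominal dose, mg/kg (study design: 0.5).
#' @param route one of [ROUTES].
#' @param body_weight body weight in g; used only when reporting absolute
#'   amounts (micrograms), never in the per-kg simulation itself.
#' @return A list of class `"dose_schedule"`.
#' @export
dose_schedule <- function(nominal_dose = 0.5, route, body_weight = 379.8) {
  .check_route(route)
  .pos(nominal_dose, "nominal_dose")
  .pos(body_weight, "body_weight")
  structure(list(nominal_dose = nominal_dose, route = route,
                 body_weight = body_weight),
            class = "dose_schedule")
}

# Mean parameter estimates for MPA in male Sprague-Dawley rats at
# 0.5 mg/kg, one set per route. These are the package's built-in reference
# values: simulation defaults, fitting start values, and the generating
# means of the synthetic cohorts.
.REF_MEANS <- list(
  IV = list(CL = 117, V = 110, CL2 = 224, V2 = 1740,
            K_cb = 1.37, K_gc = 1.97, Tau = 1.46),
  ORAL = list(CL = 132, V = 29.3, CL2 = 274, V2 = 3000,
              K_cb = 10.3, K_gc = 7.78, Tau = 4.54,
              Ka1 = 0.997, Ka2 = 1.53, K_tr = 1.25),
  SUPRALINGUAL = list(CL = 250, V = 3090,
                      K_cb = 2.28, K_gc = 32.4, Tau = 31.5,
                      Ka1 = 21.6, Ka2 = 37.3, K_tr = 0.193)
)

# Reported between-animal standard deviations matching .REF_MEANS.
.REF_SDS <- list(
  IV = list(CL = 92.2, V = 10.8, CL2 = 65.5, V2 = 508,
            K_cb = 1.02, K_gc = 2.02, Tau = 0.535),
  ORAL = list(CL = 73.2, V = 9.82, CL2 = 162, V2 = 1690,
              K_cb = 0.832, K_gc = 8.52, Tau = 4.69,
              Ka1 = 0.313, Ka2 = 0.366, K_tr = 0.118),
  SUPRALINGUAL = list(CL = 333, V = 49.1,
                      K_cb = 3.62, K_gc = 52.3, Tau = 11.6,
                      Ka1 = 14.6, Ka2 = 22.7, K_tr = 0.040)
)

#' Built-in mean MPA parameter estimates per route
#'
#' Mean per-animal parameter estimates for mycophenolic acid in rats
#' (0.5 mg/kg), assembled into a full [model_params()] object with the
#' route's fixed design constants (`n_transit = 5`; supralingual
#' `t_lag = 0.5` h, `patch_duration = 4` h, `released_fraction = 0.794`).
#'
#' @param route one of [ROUTES].
#' @param sigma proportional residual SD to attach (default 0.15).
#' @return A [model_params()] object.
#' @seealso [reference_sds()] for the matching between-animal SDs.
#' @export
reference_params <- function(route, sigma = 0.15) {
  .check_route(route)
  m <- .REF_MEANS[[route]]
  disp <- disposition_params(CL = m$CL, V = m$V, CL2 = m$CL2, V2 = m$V2,
                             K_cb = m$K_cb, K_gc = m$K_gc, Tau = m$Tau)
  absorp <- switch(route,
    IV = absorption_params(),
    ORAL = absorption_params(Ka1 = m$Ka1, Ka2 = m$Ka2, K_tr = m$K_tr),
    SUPRALINGUAL = absorption_params(Ka1 = m$Ka1, Ka2 = m$Ka2,
                                     K_tr = m$K_tr, t_lag = 0.5,
                                     patch_duration = 4,
                                     released_fraction = 0.794))
  model_params(route, disp, absorp, sigma = sigma)
}

#' Between-animal standard deviations matching [reference_params()]
#'
#' @param route one of [ROUTES].
#' @return Named list of SDs for each structural parameter.
#' @export
reference_sds <- function(route) {
  .check_route(route)
  .REF_SDS[[route]]
}

# Flat named-vector view of the free structural parameters.
.params_to_vector <- function(params, names = free_param_names(params$route)) {
  vapply(names, function(nm) {
    v <- params$disp[[nm]]
    if (is.null(v)) v <- params$absorp[[nm]]
    if (is.null(v)) stop("unknown parameter: ", nm, call. = FALSE)
    v
  }, numeric(1))
}

# Rebuild a model_params from a template with some free parameters replaced.
.set_params <- function(template, values) {
  stopifnot(!is.null(names(values)))
  d <- template$disp
  a <- template$absorp
  for (nm in names(values)) {
    if (nm %in% names(d)) d[[nm]] <- values[[nm]]
    else if (nm %in% names(a)) a[[nm]] <- values[[nm]]
    else stop("unknown parameter: ", nm, call. = FALSE)
  }
  class(d) <- "disposition_params"
  class(a) <- "absorption_params"
  model_params(template$route, d, a, sigma = template$sigma)
}

#' @export
print.model_params <- function(x, ...) {
  cat("EHR model parameters (", x$route, ")\n", sep = "")
  v <- .params_to_vector(x)
  for (nm in names(v)) cat(sprintf("  %-5s %g\n", nm, v[[nm]]))
  cat(sprintf("  sigma %g (proportional residual SD)\n", x$sigma))
  if (x$route != "IV")
    cat(sprintf("  fixed: n_transit=%d t_lag=%g patch_duration=%g released_fraction=%g\n",
                x$absorp$n_transit, x$absorp$t_lag,
                x$absorp$patch_duration, x$absorp$released_fraction))
  invisible(x)
}
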