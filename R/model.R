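#' Zero-order bile-emptying coefficient
#'
#' Bile-to-gut transfer is parameterised by the emptying duration `Tau`
#' (h); its transfer coefficient is `GBr = 1/Tau` (1/h). In the default
#' continuous mode the bile compartment empties as
#' `R_bile(t) = GBr * A_bile(t)`.
#'
#' @param Tau bile-emptying duration, h; must be strictly positive.
#' @return `1/Tau`, in 1/h.
#' @examples
#' gbr(1.46)   # IV mean
#' gbr(31.5)   # supralingual mean
#' @export
gbr <- function(Tau) {
  if (!(is.numeric(Tau) && all(is.finite(Tau)) && all(Tau > 0)))
    stop("Tau must be strictly positive", call. = FALSE)
  1 / Tau
}

#' Solver configuration
#'
#' Defaults chosen for the on/off zero-order inputs of the patch model:
#' the integration is segmented at the release discontinuities, and
#' tolerances are tight enough that mass-balance holds to ~1e-9 relative.
#'
#' @param rtol relative tolerance (default 1e-8).
#' @param atol absolute tolerance, ng/kg (default 1e-10).
#' @param maxsteps maximum internal steps per output interval.
#' @param bile_mode `"continuous"` (default): bile empties first-order with
#'   time constant `Tau`. `"windowed"`: the bile amount accumulated at
#'   `empty_start` is discharged at constant rate over `[empty_start,
#'   empty_start + Tau]`, clamped at zero (sensitivity analysis only).
#' @param empty_start start of the emptying window (h), windowed mode only.
#' @return A list of class `"solver_config"`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-10, maxsteps = 50000,
                          bile_mode = c("continuous", "windowed"),
                          empty_start = 1) {
  bile_mode <- match.arg(bile_mode)
  structure(list(rtol = rtol, atol = atol, maxsteps = maxsteps,
                 bile_mode = bile_mode, empty_start = empty_start),
            class = "solver_config")
}

# --- internal state layout -------------------------------------------------
# Uniform engine state: depot, transit[1..nt], central, peripheral, bile,
# gut (length nt + 5, nt = 0 for IV). Route-facing states drop the unused
# slots.

.n_transit_of <- function(params) {
  if (params$route == "IV") 0L else params$absorp$n_transit
}

.state_names_internal <- function(nt) {
  c("depot", if (nt > 0) paste0("transit", seq_len(nt)),
    "central", "peripheral", "bile", "gut")
}

#' Route-facing compartment names
#'
#' @param params a [model_params()] object.
#' @return Character vector of the compartments active for the route.
#' @export
state_names <- function(params) {
  nt <- .n_transit_of(params)
  switch(params$route,
    IV = c("central", "peripheral", "bile", "gut"),
    ORAL = c("depot", paste0("transit", seq_len(nt)), "central",
             "peripheral", "bile", "gut"),
    SUPRALINGUAL = c("depot", paste0("transit", seq_len(nt)), "central",
                     "bile", "gut"))
}

# Engine parameter vector matching src/ehr_model.c.
.engine_parms <- function(params, release_rate = 0, windowed_rate = 0,
                          bile_coef = NULL) {
  d <- params$disp
  a <- params$absorp
  nt <- .n_transit_of(params)
  has_per <- !is.null(d$CL2)
  if (is.null(bile_coef)) bile_coef <- gbr(d$Tau)
  c(nt = nt,
    has_per = as.numeric(has_per),
    k10 = d$CL / d$V,
    k12 = if (has_per) d$CL2 / d$V else 0,
    k21 = if (has_per) d$CL2 / d$V2 else 0,
    kcb = d$K_cb,
    kgc = d$K_gc,
    bile_coef = bile_coef,
    ka1 = if (params$route == "IV") 0 else a$Ka1,
    ka2 = if (params$route == "IV") 0 else a$Ka2,
    ktr = if (params$route == "IV") 0 else a$K_tr,
    release_rate = release_rate,
    windowed_rate = windowed_rate)
}

# Reference RHS in R, same parms/state convention as the C code.
.rhs_r <- function(t, y, p) {
  nt <- as.integer(p[["nt"]])
  depot <- y[1L]
  central <- y[nt + 2L]; periph <- y[nt + 3L]
  bile <- y[nt + 4L]; gut <- y[nt + 5L]
  dy <- numeric(nt + 5L)
  dy[1L] <- p[["release_rate"]] - (p[["ka1"]] + p[["ka2"]]) * depot
  into_central <- 0
  if (nt > 0L) {
    dy[2L] <- p[["ka2"]] * depot - p[["ktr"]] * y[2L]
    if (nt > 1L)
      for (k in 3L:(nt + 1L))
        dy[k] <- p[["ktr"]] * (y[k - 1L] - y[k])
    into_central <- p[["ka1"]] * depot + p[["ktr"]] * y[nt + 1L]
  }
  bile_out <- p[["bile_coef"]] * bile
  if (p[["windowed_rate"]] > 0 && bile > 0)
    bile_out <- bile_out + p[["windowed_rate"]]
  dy[nt + 2L] <- into_central -
    (p[["k10"]] + p[["k12"]] + p[["kcb"]]) * central +
    p[["k21"]] * periph + p[["kgc"]] * gut
  dy[nt + 3L] <- if (p[["has_per"]] > 0)
    p[["k12"]] * central - p[["k21"]] * periph else 0
  dy[nt + 4L] <- p[["kcb"]] * central - bile_out
  dy[nt + 5L] <- bile_out - p[["kgc"]] * gut
  dy
}

#' EHR model right-hand side (reference implementation)
#'
#' Evaluates the derivative of the route-appropriate state vector. This is
#' the readable reference of the model equations; [simulate_profile()] uses
#' a compiled equivalent which is cross-checked against this function in
#' the test suite.
#'
#' @param t time after dose, h.
#' @param state named numeric vector over [state_names()] (amounts, ng/kg).
#' @param params a [model_params()] object.
#' @param schedule a [dose_schedule()] object (drives the patch's
#'   zero-order release term).
#' @return Named numeric vector of derivatives, ng/(kg h).
#' @export
ehr_rhs <- function(t, state, params, schedule) {
  nms <- state_names(params)
  if (length(state) != length(nms) || is.null(names(state)) ||
      !identical(sort(names(state)), sort(nms)))
    stop("state must be a named vector over: ",
         paste(nms, collapse = ", "), call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  state <- state[nms]
  nt <- .n_transit_of(params)
  y <- setNames(numeric(nt + 5L), .state_names_internal(nt))
  y[names(state)] <- state
  rel <- 0
  if (params$route == "SUPRALINGUAL") {
    a <- params$absorp
    window <- a$patch_duration - a$t_lag
    if (t >= a$t_lag && t < a$patch_duration && window > 0)
      rel <- a$released_fraction * schedule$nominal_dose * 1e6 / window
  }
  dy <- .rhs_r(t, y, .engine_parms(params, release_rate = rel))
  setNames(dy[match(nms, .state_names_internal(nt))], nms)
}

# Initial engine state (ng/kg). IV: bolus in central; oral: dose in depot;
# patch: everything enters later through the zero-order release.
.initial_state <- function(params, schedule) {
  nt <- .n_transit_of(params)
  y <- setNames(numeric(nt + 5L), .state_names_internal(nt))
  dose <- schedule$nominal_dose * 1e6  # mg/kg -> ng/kg
  released <- params$absorp$released_fraction * dose
  if (params$route == "IV") y[["central"]] <- released
  if (params$route == "ORAL") y[["depot"]] <- released
  y
}

# Piecewise-constant input segments: (t0, t1, release_rate, windowed?).
.segments <- function(params, schedule, t_end, solver) {
  a <- params$absorp
  brk <- c(0, t_end)
  if (params$route == "SUPRALINGUAL")
    brk <- c(brk, a$t_lag, a$patch_duration)
  windowed <- solver$bile_mode == "windowed"
  if (windowed)
    brk <- c(brk, solver$empty_start, solver$empty_start + params$disp$Tau)
  brk <- sort(unique(brk[brk >= 0 & brk <= t_end]))
  if (length(brk) < 2L) brk <- c(0, t_end)
  segs <- data.frame(t0 = brk[-length(brk)], t1 = brk[-1L])
  segs$release_rate <- 0
  if (params$route == "SUPRALINGUAL") {
    window <- a$patch_duration - a$t_lag
    if (window <= 0) stop("patch_duration must exceed t_lag", call. = FALSE)
    rate <- a$released_fraction * schedule$nominal_dose * 1e6 / window
    inside <- segs$t0 >= a$t_lag & segs$t1 <= a$patch_duration
    segs$release_rate[inside] <- rate
  }
  segs$in_window <- if (windowed)
    segs$t0 >= solver$empty_start &
      segs$t1 <= solver$empty_start + params$disp$Tau
  else FALSE
  segs
}

#' Simulate a noise-free concentration-time profile
#'
#' Integrates the route's EHR model and returns the plasma concentration
#' `C(t) = A_central(t)/V` (ng/mL, with amounts in ng/kg and `V` in
#' mL/kg). The integration is segmented at the input discontinuities
#' (patch release start/stop, and the emptying window in windowed bile
#' mode).
#'
#' @param params a [model_params()] object.
#' @param schedule a [dose_schedule()] object for the same route.
#' @param times sorted, nonnegative output times, h.
#' @param solver a [solver_config()].
#' @param amounts if `TRUE`, also return the compartment amounts (ng/kg).
#' @param engine `"c"` (compiled, default) or `"r"` (reference R RHS).
#' @return `data.frame` with columns `time`, `conc`, and, when
#'   `amounts = TRUE`, one column per route compartment.
#' @examples
#' p <- reference_params("IV")
#' s <- dose_schedule(0.5, "IV")
#' head(simulate_profile(p, s, c(0, 0.5, 1, 2, 4, 8, 24, 48)))
#' @export
simulate_profile <- function(params, schedule, times,
                             solver = solver_config(), amounts = FALSE,
                             engine = c("c", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "dose_schedule"))
  if (params$route != schedule$route)
    stop("params and schedule routes differ", call. = FALSE)
  if (length(times) < 1L || is.unsorted(times) || any(times < 0))
    stop("times must be sorted and nonnegative", call. = FALSE)

  nt <- .n_transit_of(params)
  y <- .initial_state(params, schedule)
  t_end <- max(times)
  res <- matrix(NA_real_, nrow = length(times), ncol = nt + 5L,
                dimnames = list(NULL, .state_names_internal(nt)))
  if (times[1L] == 0) res[times == 0, ] <- rep(y, each = sum(times == 0))

  if (t_end > 0) {
    segs <- .segments(params, schedule, t_end, solver)
    bile_coef <- if (solver$bile_mode == "windowed") 0 else NULL
    win_rate <- 0
    for (i in seq_len(nrow(segs))) {
      sg <- segs[i, ]
      if (sg$in_window && (i == 1L || !segs$in_window[i - 1L])) {
        # entering the emptying window: fix the discharge rate from the
        # bile amount accumulated so far
        win_rate <- y[["bile"]] / params$disp$Tau
      }
      parms <- .engine_parms(params, release_rate = sg$release_rate,
                             windowed_rate = if (sg$in_window) win_rate else 0,
                             bile_coef = bile_coef)
      want <- times[times > sg$t0 & times <= sg$t1]
      seg_times <- sort(unique(c(sg$t0, want, sg$t1)))
      out <- if (engine == "c")
        deSolve::lsoda(y, seg_times, func = "ehr_derivs", parms = parms,
                       dllname = "ehrpk", initfunc = "ehr_init",
                       rtol = solver$rtol, atol = solver$atol,
                       maxsteps = solver$maxsteps)
      else
        deSolve::lsoda(y, seg_times,
                       func = function(t, y, p) list(.rhs_r(t, y, p)),
                       parms = parms, rtol = solver$rtol,
                       atol = solver$atol, maxsteps = solver$maxsteps)
      if (attr(out, "istate")[1L] < 0)
        stop(sprintf(
          "ODE solver failed in segment [%g, %g]; last successful time %g",
          sg$t0, sg$t1, max(out[, 1L])), call. = FALSE)
      if (length(want))
        res[match(want, times), ] <- out[match(want, out[, 1L]), -1L,
                                         drop = FALSE]
      y <- setNames(out[nrow(out), -1L], .state_names_internal(nt))
    }
  }

  conc <- res[, "central"] / params$disp$V
  ans <- data.frame(time = times, conc = conc)
  if (amounts) {
    keep <- state_names(params)
    ans <- cbind(ans, as.data.frame(res[, keep, drop = FALSE]))
  }
  ans
}

#' Enterohepatic recycling percentage
#'
#' Fraction of central-compartment efflux that leaves through the biliary
#' route, as a percentage. With a peripheral compartment (IV, oral):
#' `100 * K_cb / (K_cb + CL/V + CL2/V2)`; without one (supralingual):
#' `100 * K_cb / (K_cb + CL/V)`.
#'
#' @param params a [model_params()] object.
#' @return EHR percentage in (0, 100).
#' @examples
#' ehr_fraction(reference_params("SUPRALINGUAL"))  # ~96.6
#' @export
ehr_fraction <- function(params) {
  stopifnot(inherits(params, "model_params"))
  d <- params$disp
  if (params$route %in% c("IV", "ORAL")) {
    if (is.null(d$CL2) || is.null(d$V2))
      stop("CL2 and V2 required for IV/oral EHR%", call. = FALSE)
    100 * d$K_cb / (d$K_cb + d$CL / d$V + d$CL2 / d$V2)
  } else {
    100 * d$K_cb / (d$K_cb + d$CL / d$V)
  }
}
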