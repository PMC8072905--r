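#' Minus twice the log-likelihood under the proportional error model
#'
#' For non-BLQ observations `C_obs,j` with model predictions `C_pred,j`,
#' the proportional-error Gaussian likelihood gives
#' `-2LL = sum_j [ log(2 pi sigma^2 C_pred,j^2) +
#'                 (C_obs,j - C_pred,j)^2 / (sigma^2 C_pred,j^2) ]`.
#' With `sigma = NULL` (default) sigma is profiled at its closed-form ML
#' value `sigma^2 = mean(((C_obs - C_pred)/C_pred)^2)`, so the returned
#' value is the joint ML objective.
#'
#' @param params a [model_params()] object.
#' @param data subject data: `data.frame` with `time_h`, `conc_ng_ml`,
#'   `blq` (BLQ rows are excluded from the likelihood).
#' @param schedule a [dose_schedule()] for the subject.
#' @param sigma fixed residual SD, or `NULL` to profile.
#' @param solver a [solver_config()].
#' @return `-2LL` (dimensionless), with attributes `sigma` (the SD used)
#'   and `n` (points used). `+Inf` if any prediction at an observation
#'   time is nonpositive.
#' @export
neg2_loglik <- function(params, data, schedule, sigma = NULL,
                        solver = solver_config()) {
  obs <- data[data$blq == 0L & !is.na(data$conc_ng_ml), ]
  if (nrow(obs) < 1L) stop("no quantifiable observations", call. = FALSE)
  times <- sort(unique(obs$time_h))
  pred <- simulate_profile(params, schedule, times, solver = solver)$conc
  cp <- pred[match(obs$time_h, times)]
  if (any(!is.finite(cp)) || any(cp <= 0)) return(Inf)
  res <- (obs$conc_ng_ml - cp) / cp
  n <- length(res)
  if (is.null(sigma)) {
    s2 <- mean(res^2)
    if (s2 <= 0) s2 <- .Machine$double.xmin  # exact fit: bounded objective
    val <- n * log(2 * pi * s2) + sum(log(cp^2)) + n
    sigma <- sqrt(s2)
  } else {
    .pos(sigma, "sigma")
    val <- sum(log(2 * pi * sigma^2 * cp^2)) + sum(res^2) / sigma^2
  }
  structure(val, sigma = sigma, n = n)
}

#' Akaike information criterion
#'
#' @param neg2ll minus twice the maximised log-likelihood.
#' @param p number of estimated parameters (structural + sigma).
#' @return `neg2ll + 2 p`.
#' @export
aic <- function(neg2ll, p) {
  if (!(is.numeric(p) && length(p) == 1L && p >= 1 && p == round(p)))
    stop("p must be an integer >= 1", call. = FALSE)
  neg2ll + 2 * p
}

#' Fitting configuration
#'
#' @param estimate names of structural parameters to estimate; default
#'   [free_param_names()] for the route. sigma is always profiled.
#' @param fix named list of parameter values to hold fixed (overrides the
#'   start).
#' @param lower,upper box bounds on each parameter's natural scale.
#' @param multi_start number of warm-start optimisation runs (default
#'   10); the first start is the supplied/default initial guess, the rest
#'   are log-uniform perturbations of it.
#' @param perturb maximum multiplicative perturbation of a start (default
#'   3: each parameter multiplied by a factor in \[1/3, 3\]).
#' @param rel_tol optimizer relative tolerance on the objective.
#' @param max_iter optimizer iteration cap per start.
#' @param polish_top how many of the best warm starts get the full ML
#'   polish (default 3).
#' @param polish_cycles maximum simplex-restart cycles per polish
#'   (default 8).
#' @param nm_maxit Nelder-Mead iterations per polish cycle (default 700).
#' @param seed RNG seed for the start perturbations.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(estimate = NULL, fix = list(), lower = 1e-4,
                       upper = 1e4, multi_start = 10L, perturb = 3,
                       rel_tol = 1e-10, max_iter = 500L, polish_top = 3L,
                       polish_cycles = 8L, nm_maxit = 700L, seed = 1L) {
  if (multi_start < 1L) stop("multi_start must be >= 1", call. = FALSE)
  if (lower <= 0 || upper <= lower)
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  if (perturb < 1) stop("perturb must be >= 1", call. = FALSE)
  structure(list(estimate = estimate, fix = fix, lower = lower,
                 upper = upper, multi_start = as.integer(multi_start),
                 perturb = perturb, rel_tol = rel_tol,
                 max_iter = as.integer(max_iter),
                 polish_top = as.integer(polish_top),
                 polish_cycles = as.integer(polish_cycles),
                 nm_maxit = as.integer(nm_maxit),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Objective closure over log-scale free parameters.
.make_objective <- function(template, free, data, schedule, solver) {
  force(template); force(free)
  function(ltheta) {
    th <- exp(ltheta)
    names(th) <- free
    p <- try(.set_params(template, as.list(th)), silent = TRUE)
    if (inherits(p, "try-error")) return(1e12)
    utils::capture.output(val <- suppressWarnings(try(
      neg2_loglik(p, data, schedule, solver = solver), silent = TRUE)))
    if (inherits(val, "try-error") || !is.finite(val)) return(1e12)
    as.numeric(val)
  }
}

# Relative-residual vector on the log scale, for the least-squares warm
# start: log(C_obs/C_pred), which for small residuals equals the
# proportional residual and whose exact zero is the ML optimum of
# noise-free data.
.make_resfun <- function(template, free, obs, schedule, solver) {
  force(template); force(free)
  n <- nrow(obs)
  function(ltheta) {
    th <- exp(ltheta)
    names(th) <- free
    p <- try(.set_params(template, as.list(th)), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e6, n))
    utils::capture.output(cp <- suppressWarnings(try(
      simulate_profile(p, schedule, sort(unique(obs$time_h)),
                       solver = solver)$conc, silent = TRUE)))
    if (inherits(cp, "try-error")) return(rep(1e6, n))
    cp <- cp[match(obs$time_h, sort(unique(obs$time_h)))]
    if (any(!is.finite(cp)) || any(cp <= 0)) return(rep(1e6, n))
    log(obs$conc_ng_ml / cp)
  }
}

# Descend the ML objective from a warm start: alternating Nelder-Mead
# simplex restarts and bounded quasi-Newton until the objective stops
# improving. The profiled-sigma surface has long curved valleys (the
# recycling loop trades off against distribution), which the simplex
# restarts traverse better than a single gradient run.
.polish_ml <- function(obj, ltheta, lb, ub, max_cycles = 8L,
                       tol = 1e-6, nm_maxit = 700L) {
  cur <- pmin(pmax(ltheta, lb), ub)
  best <- obj(cur)
  converged <- FALSE
  for (cyc in seq_len(max_cycles)) {
    f1 <- suppressWarnings(stats::optim(cur, obj, method = "Nelder-Mead",
      control = list(maxit = nm_maxit, reltol = 1e-13)))
    f2 <- suppressWarnings(nlminb(pmin(pmax(f1$par, lb), ub), obj,
      lower = lb, upper = ub,
      control = list(rel.tol = 1e-12, iter.max = 300, eval.max = 1200)))
    val <- min(f1$value, f2$objective)
    par <- if (f2$objective <= f1$value) f2$par else f1$par
    improvement <- best - val
    if (val < best) { best <- val; cur <- pmin(pmax(par, lb), ub) }
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(par = cur, objective = best, converged = converged, cycles = cyc)
}

#' Fit one subject by maximum likelihood
#'
#' Minimises the profiled-sigma `-2LL` over log-transformed structural
#' parameters in two stages: a multistart bounded Levenberg-Marquardt run
#' on the log-residual vector (a fast valley-follower across the
#' multimodal recycling surface), then a Nelder-Mead plus quasi-Newton
#' polish of the best warm starts against the full ML objective. Returns
#' the best result; deterministic given the data, start, and `cfg$seed`.
#'
#' @param data one subject's records (`time_h`, `conc_ng_ml`, `blq`;
#'   optionally `dose_mg_kg`, `body_weight_g` used to build the schedule).
#' @param route one of [ROUTES].
#' @param cfg a [fit_config()].
#' @param start a [model_params()] initial guess; default
#'   [reference_params()] for the route. Fixed design constants
#'   (`n_transit`, `t_lag`, `patch_duration`, `released_fraction`) are
#'   taken from it.
#' @param schedule a [dose_schedule()]; default built from the data.
#' @param solver a [solver_config()].
#' @return An object of class `"ehr_fit"`: list with `params` (estimates,
#'   sigma at its ML value), `neg2ll`, `aic`, `p`, `convergence` (0 = ok),
#'   `predictions` (per-point observed/predicted/IWRES), `starts` and
#'   `polish` (per-start objective traces of the two stages), `flat`
#'   (named flags: profile flat within +/-10% perturbation), `route`,
#'   `data`.
#' @export
fit_subject <- function(data, route, cfg = fit_config(), start = NULL,
                        schedule = NULL, solver = solver_config()) {
  .check_route(route)
  stopifnot(inherits(cfg, "fit_config"))
  if ("route" %in% names(data) && !all(data$route == route))
    stop("data contains records from a different route", call. = FALSE)
  if (is.null(start)) start <- reference_params(route)
  if (is.null(schedule)) {
    dose <- if ("dose_mg_kg" %in% names(data)) data$dose_mg_kg[1L] else 0.5
    bw <- if ("body_weight_g" %in% names(data)) data$body_weight_g[1L]
          else 379.8
    schedule <- dose_schedule(dose, route, body_weight = bw)
  }
  free <- if (is.null(cfg$estimate)) free_param_names(route)
          else cfg$estimate
  free <- setdiff(free, names(cfg$fix))
  template <- if (length(cfg$fix)) .set_params(start, cfg$fix) else start

  n_obs <- sum(data$blq == 0L & !is.na(data$conc_ng_ml))
  p <- length(free) + 1L  # + sigma
  if (n_obs < p)
    stop(sprintf("under-determined fit: %d quantifiable points for %d parameters",
                 n_obs, p), call. = FALSE)

  obs_data <- data[data$blq == 0L & !is.na(data$conc_ng_ml), ]
  obj <- .make_objective(template, free, data, schedule, solver)
  resfun <- .make_resfun(template, free, obs_data, schedule, solver)
  theta0 <- log(.params_to_vector(template, free))
  lb <- rep(log(cfg$lower), length(free))
  ub <- rep(log(cfg$upper), length(free))
  theta0 <- pmin(pmax(theta0, lb), ub)

  result <- .with_seed(cfg$seed, {
    # stage 1: multistart bounded Levenberg-Marquardt on the log-residual
    # vector — a fast valley-follower that supplies warm starts
    lm_runs <- lapply(seq_len(cfg$multi_start), function(k) {
      lt0 <- if (k == 1L) theta0
             else pmin(pmax(theta0 + runif(length(free),
                                           -log(cfg$perturb),
                                           log(cfg$perturb)), lb), ub)
      lmfit <- suppressWarnings(try(minpack.lm::nls.lm(
        lt0, fn = resfun, lower = lb, upper = ub,
        control = minpack.lm::nls.lm.control(
          maxiter = cfg$max_iter, ftol = 1e-15, ptol = 1e-15)),
        silent = TRUE))
      if (inherits(lmfit, "try-error"))
        list(start_id = k, par = lt0, deviance = Inf)
      else
        list(start_id = k, par = lmfit$par, deviance = lmfit$deviance)
    })
    devs <- vapply(lm_runs, `[[`, numeric(1), "deviance")
    if (all(!is.finite(devs)))
      stop("no optimisation start produced a usable fit", call. = FALSE)
    # stage 2: polish the best warm starts against the full ML objective
    top <- lm_runs[order(devs)][seq_len(min(cfg$polish_top,
                                            sum(is.finite(devs))))]
    polished <- lapply(top, function(cand)
      c(.polish_ml(obj, cand$par, lb, ub,
                   max_cycles = cfg$polish_cycles,
                   tol = cfg$rel_tol * 1e4 + 1e-6,
                   nm_maxit = cfg$nm_maxit),
        start_id = cand$start_id))
    objectives <- vapply(polished, `[[`, numeric(1), "objective")
    list(best = polished[[which.min(objectives)]],
         starts = data.frame(
           start_id = vapply(lm_runs, `[[`, numeric(1), "start_id"),
           lm_deviance = devs),
         polish = data.frame(
           start_id = vapply(polished, `[[`, numeric(1), "start_id"),
           objective = objectives,
           converged = vapply(polished, `[[`, logical(1), "converged")))
  })
  best <- result$best
  if (best$objective >= 1e12)
    stop("no start converged; per-start log-residual deviances: ",
         paste(signif(result$starts$lm_deviance, 3), collapse = ", "),
         call. = FALSE)

  th <- exp(best$par); names(th) <- free
  params_hat <- .set_params(template, as.list(th))
  n2 <- neg2_loglik(params_hat, data, schedule, solver = solver)
  sigma_hat <- attr(n2, "sigma")
  params_hat$sigma <- sigma_hat

  # flatness probe: +/-10% perturbation moving -2LL by < 0.01 marks an
  # uninformative (flat) profile direction
  flat <- vapply(seq_along(free), function(j) {
    d <- vapply(c(log(1.1), log(0.9)), function(sh) {
      th2 <- best$par; th2[j] <- th2[j] + sh
      abs(obj(th2) - best$objective)
    }, numeric(1))
    all(d < 0.01)
  }, logical(1))
  names(flat) <- free

  obs <- data[data$blq == 0L & !is.na(data$conc_ng_ml), ]
  times <- sort(unique(obs$time_h))
  pred <- simulate_profile(params_hat, schedule, times, solver = solver)$conc
  cp <- pred[match(obs$time_h, times)]
  predictions <- data.frame(
    subject_id = if ("subject_id" %in% names(obs)) obs$subject_id else NA,
    time = obs$time_h, observed = obs$conc_ng_ml, predicted = cp,
    iwres = compute_iwres(obs$conc_ng_ml, cp, sigma_hat))

  structure(list(
    params = params_hat, neg2ll = as.numeric(n2),
    aic = aic(as.numeric(n2), p), p = p,
    convergence = if (best$converged) 0L else 1L,
    best_start = best$start_id,
    starts = result$starts, polish = result$polish,
    flat = flat, predictions = predictions, route = route,
    schedule = schedule, data = obs[, c("time_h", "conc_ng_ml")]),
    class = "ehr_fit")
}

#' @export
print.ehr_fit <- function(x, ...) {
  cat(sprintf("EHR model fit (%s): -2LL = %.4g, AIC = %.4g (p = %d), sigma = %.4g\n",
              x$route, x$neg2ll, x$aic, x$p, x$params$sigma))
  print(round(.params_to_vector(x$params), 5))
  if (any(x$flat))
    cat("flat profile directions:", paste(names(x$flat)[x$flat],
                                          collapse = ", "), "\n")
  invisible(x)
}

#' Rank candidate model fits of one dataset by AIC
#'
#' Implements the delta-AIC >= 2 significance rule: the lowest-AIC
#' candidate is `selected` only when it beats the runner-up by at least 2;
#' otherwise the candidates within 2 of the best are flagged
#' indistinguishable and the most parsimonious of them (fewest parameters,
#' ties broken by AIC) is selected.
#'
#' @param fits named list of `"ehr_fit"` objects fitted to identical data.
#' @return `data.frame` ranked by AIC with `delta_aic`, `p`, `selected`,
#'   `indistinguishable` columns.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L)
    stop("need at least 2 candidate fits", call. = FALSE)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ref <- fits[[1L]]$data
  for (f in fits[-1L])
    if (!isTRUE(all.equal(f$data, ref, check.attributes = FALSE)))
      stop("candidates were fitted on different data", call. = FALSE)
  tab <- data.frame(
    model = names(fits),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    neg2ll = vapply(fits, `[[`, numeric(1), "neg2ll"),
    p = vapply(fits, `[[`, integer(1), "p"))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  close_set <- tab$delta_aic < 2
  tab$indistinguishable <- sum(close_set) > 1L
  tab$selected <- FALSE
  if (sum(close_set) == 1L) {
    tab$selected[1L] <- TRUE
  } else {
    cand <- which(close_set)
    pick <- cand[order(tab$p[cand], tab$aic[cand])][1L]
    tab$selected[pick] <- TRUE
  }
  rownames(tab) <- NULL
  tab
}

#' Scan the number of transit compartments
#'
#' Refits the model with `n_transit` fixed at each value in `n_range` and
#' tabulates the AIC, mirroring the structure search that fixed the chain
#' length at 5.
#'
#' @param data one subject's records.
#' @param route `"ORAL"` or `"SUPRALINGUAL"` (the IV model has no
#'   absorption chain).
#' @param n_range integer vector of chain lengths to try (default 1:10).
#' @param cfg,start,solver passed to [fit_subject()].
#' @return `data.frame` with `n_transit`, `aic`, `neg2ll`, `convergence`,
#'   `error`; attribute `best` holds the argmin `n_transit`.
#' @export
scan_transit_number <- function(data, route, n_range = 1:10,
                                cfg = fit_config(), start = NULL,
                                solver = solver_config()) {
  .check_route(route)
  if (route == "IV")
    stop("transit scan applies to absorption routes only", call. = FALSE)
  if (is.null(start)) start <- reference_params(route)
  rows <- lapply(n_range, function(n) {
    st <- start
    st$absorp$n_transit <- as.integer(n)
    fit <- try(fit_subject(data, route, cfg = cfg, start = st,
                           solver = solver), silent = TRUE)
    if (inherits(fit, "try-error"))
      data.frame(n_transit = n, aic = NA_real_, neg2ll = NA_real_,
                 convergence = NA_integer_,
                 error = as.character(attr(fit, "condition")$message))
    else
      data.frame(n_transit = n, aic = fit$aic, neg2ll = fit$neg2ll,
                 convergence = fit$convergence, error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$aic))
  attr(tab, "best") <- if (length(ok)) tab$n_transit[ok[which.min(tab$aic[ok])]]
                       else NA_integer_
  tab
}

#' Summarise per-subject fits as mean +/- SD
#'
#' Arithmetic mean and sample SD of every estimated parameter across a
#' route's animals, with the EHR percentage computed per animal and then
#' averaged (mean of per-animal ratios, not the ratio of means).
#'
#' @param fits list of `"ehr_fit"` objects, all from the same route.
#' @return `data.frame` with `parameter`, `mean`, `sd` (NA for a single
#'   subject), `n`.
#' @export
summarize_cohort <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit", call. = FALSE)
  routes <- vapply(fits, `[[`, character(1), "route")
  if (length(unique(routes)) != 1L)
    stop("cannot summarise fits from mixed routes", call. = FALSE)
  nms <- c(free_param_names(routes[1L]), "sigma", "EHR_pct")
  mat <- vapply(fits, function(f) {
    c(.params_to_vector(f$params), sigma = f$params$sigma,
      EHR_pct = ehr_fraction(f$params))
  }, numeric(length(nms)))
  mat <- matrix(mat, nrow = length(nms),
                dimnames = list(nms, NULL))
  data.frame(parameter = nms,
             mean = apply(mat, 1L, mean),
             sd = if (length(fits) > 1L) apply(mat, 1L, sd) else NA_real_,
             n = length(fits), row.names = NULL)
}
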