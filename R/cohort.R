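#' Blood-sampling schedules of the rat study design
#'
#' Default post-dose sampling times per route (hours): IV and oral start
#' with early minute-scale draws; the patch route samples through the 4-h
#' wear period and after removal. All schedules include the pre-dose time
#' 0 and extend to 48 h.
#'
#' @param route one of [ROUTES].
#' @return Strictly increasing numeric vector of times, h.
#' @export
sampling_schedule <- function(route) {
  .check_route(route)
  switch(route,
    IV = c(0, 2/60, 5/60, 15/60, 30/60, 1, 2, 3, 4, 6, 8, 10, 24, 28,
           32, 48),
    ORAL = c(0, 5/60, 10/60, 15/60, 30/60, 1, 2, 3, 4, 6, 8, 10, 12, 24,
             28, 32, 48),
    SUPRALINGUAL = c(0, 1, 2, 3, 4, 4.5, 5, 6, 7, 8, 9, 10, 24, 28, 32,
                     48))
}

#' Synthetic cohort specification
#'
#' Describes a simulated rat PK study: group sizes per route (study
#' design: IV n = 5, oral n = 3, supralingual n = 3, all at 0.5 mg/kg),
#' the generating parameter means and between-animal SDs (defaults:
#' [reference_params()] / [reference_sds()]), the between-animal
#' distribution, the proportional residual SD, and the assay's lower limit
#' of quantification.
#'
#' @param routes routes to include.
#' @param n named group sizes per route.
#' @param means named list (per route) of parameter means; defaults to the
#'   built-in reference means.
#' @param sds named list (per route) of between-animal SDs; an SD of 0
#'   makes every animal share the mean.
#' @param distribution `"lognormal"` (method-of-moments matched, default)
#'   or `"truncnormal"` (normal rejected at zero).
#' @param sigma proportional residual SD (default 0.15, a typical
#'   bioanalytical CV within the +/-15% assay acceptance band).
#' @param lloq lower limit of quantification, ng/mL (assay range starts at
#'   0.5).
#' @param dose nominal dose, mg/kg.
#' @param body_weight_mean,body_weight_sd body-weight distribution, g
#'   (study animals: 379.8 +/- 44.3 g).
#' @param seed integer RNG seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(routes = ROUTES,
                        n = c(IV = 5L, ORAL = 3L, SUPRALINGUAL = 3L),
                        means = NULL, sds = NULL,
                        distribution = c("lognormal", "truncnormal"),
                        sigma = 0.15, lloq = 0.5, dose = 0.5,
                        body_weight_mean = 379.8, body_weight_sd = 44.3,
                        seed = 1L) {
  distribution <- match.arg(distribution)
  routes <- vapply(routes, .check_route, character(1))
  n <- unlist(n)
  if (is.null(means))
    means <- lapply(setNames(routes, routes),
                    function(r) as.list(.params_to_vector(reference_params(r))))
  if (is.null(sds))
    sds <- lapply(setNames(routes, routes), reference_sds)
  stopifnot(all(routes %in% names(n)), all(routes %in% names(means)),
            all(routes %in% names(sds)))
  if (any(n[routes] < 1)) stop("n must be >= 1 per route", call. = FALSE)
  for (r in routes)
    if (any(unlist(sds[[r]]) < 0))
      stop("SDs must be >= 0", call. = FALSE)
  .pos(sigma, "sigma"); .pos(lloq, "lloq"); .pos(dose, "dose")
  structure(list(routes = routes, n = n, means = means, sds = sds,
                 distribution = distribution, sigma = sigma, lloq = lloq,
                 dose = dose, body_weight_mean = body_weight_mean,
                 body_weight_sd = body_weight_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One lognormal draw with moments matched to (mean m, sd s); s = 0
# degenerates to m.
.rlnorm_mm <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog2 <- log(1 + (s / m)^2)
  if (!is.finite(sdlog2) || sdlog2 <= 0)
    stop("invalid (mean, SD) for lognormal moment matching", call. = FALSE)
  rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

.rtruncnorm0 <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  x <- numeric(0)
  while (length(x) < n) {
    cand <- rnorm(2L * (n - length(x)) + 10L, m, s)
    x <- c(x, cand[cand > 0])
  }
  x[seq_len(n)]
}

#' Draw one animal's parameters from a cohort specification
#'
#' Each structural parameter is drawn independently from a positive-support
#' distribution with the configured mean and between-animal SD (lognormal
#' by method of moments, by default). Fixed design quantities (`n_transit`,
#' `t_lag`, `patch_duration`, `released_fraction`) and the residual
#' `sigma` are not sampled. Uses the current RNG stream; seed management
#' belongs to the caller ([generate_cohort()] seeds once per cohort).
#'
#' @param spec a [cohort_spec()].
#' @param route one of the spec's routes.
#' @return A [model_params()] object for one animal.
#' @export
sample_subject_params <- function(spec, route) {
  stopifnot(inherits(spec, "cohort_spec"))
  .check_route(route)
  m <- spec$means[[route]]
  s <- spec$sds[[route]]
  draw <- switch(spec$distribution, lognormal = .rlnorm_mm,
                 truncnormal = .rtruncnorm0)
  vals <- vapply(names(m), function(nm) draw(1L, m[[nm]], s[[nm]]),
                 numeric(1))
  .set_params(reference_params(route, sigma = spec$sigma),
              as.list(vals))
}

#' Generate a synthetic concentration-time dataset
#'
#' For every animal: draw parameters, simulate the noise-free profile on
#' the route's sampling schedule, apply multiplicative proportional error
#' `C_obs = C_pred * (1 + eps)`, `eps ~ N(0, sigma^2)`, then flag as BLQ
#' every record whose noise-applied value falls below the LLOQ (negative
#' values are clamped to 0 and flagged). The pre-dose record at t = 0 is
#' emitted as a BLQ zero. Output is sorted by subject then time.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `subject_id`, `route`, `time_h`,
#'   `conc_ng_ml` (NA when BLQ), `blq` (0/1), `dose_mg_kg`,
#'   `body_weight_g`, plus a hidden noise-free prediction column
#'   `conc_true` (dropped on write; kept for calibration tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    out <- list()
    for (route in spec$routes) {
      times <- sampling_schedule(route)
      for (i in seq_len(spec$n[[route]])) {
        params <- sample_subject_params(spec, route)
        bw <- .rtruncnorm0(1L, spec$body_weight_mean, spec$body_weight_sd)
        sched <- dose_schedule(spec$dose, route, body_weight = bw)
        pred <- simulate_profile(params, sched, times)$conc
        eps <- rnorm(length(times), 0, spec$sigma)
        obs <- pred * (1 + eps)
        obs[times == 0] <- 0
        blq <- as.integer(obs < spec$lloq)
        obs[obs < 0] <- 0
        obs[blq == 1L] <- ifelse(obs[blq == 1L] > 0, obs[blq == 1L], 0)
        df <- data.frame(
          subject_id = sprintf("%s-%02d", route, i),
          route = route, time_h = times,
          conc_ng_ml = ifelse(blq == 1L, NA_real_, obs),
          blq = blq, dose_mg_kg = spec$dose, body_weight_g = bw,
          conc_true = pred)
        out[[length(out) + 1L]] <- df
      }
    }
    res <- do.call(rbind, out)
    res <- res[order(res$subject_id, res$time_h), ]
    rownames(res) <- NULL
    res
  })
}
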