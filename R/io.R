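# Dataset CSV dialect: one row per sampling record, times in hours,
# concentrations in ng/mL, BLQ rows carry an empty concentration field.

.DATASET_COLS <- c("subject_id", "route", "time_h", "conc_ng_ml", "blq",
                   "dose_mg_kg", "body_weight_g")

.validate_dataset <- function(d, where = "dataset") {
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    line <- i + 1L  # header is line 1
    fail <- function(field, why)
      stop(sprintf("%s line %d, field '%s': %s", where, line, field, why),
           call. = FALSE)
    if (!(row$route %in% ROUTES)) fail("route", "unknown route")
    if (!is.finite(row$time_h) || row$time_h < 0)
      fail("time_h", "must be a nonnegative number")
    if (!(row$blq %in% c(0L, 1L))) fail("blq", "must be 0 or 1")
    if (is.na(row$conc_ng_ml) && row$blq != 1L)
      fail("conc_ng_ml", "empty concentration requires blq=1")
    if (!is.na(row$conc_ng_ml) && row$conc_ng_ml < 0)
      fail("conc_ng_ml", "must be nonnegative")
    if (!is.finite(row$dose_mg_kg) || row$dose_mg_kg <= 0)
      fail("dose_mg_kg", "must be positive")
    if (!is.finite(row$body_weight_g) || row$body_weight_g <= 0)
      fail("body_weight_g", "must be positive")
  }
  key <- paste(d$subject_id, d$time_h)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (subject, time) at line %d", where,
                 which(duplicated(key))[1L] + 1L), call. = FALSE)
  per_subj <- tapply(d$route, d$subject_id,
                     function(r) length(unique(r)))
  if (any(per_subj > 1L))
    stop(where, ": a subject appears under more than one route",
         call. = FALSE)
  invisible(d)
}

#' Write a concentration-time dataset CSV
#'
#' Columns: `subject_id`, `route`, `time_h`, `conc_ng_ml` (empty when
#' BLQ), `blq` (0/1), `dose_mg_kg`, `body_weight_g`. Rows are sorted by
#' subject then time before writing, so a fixed dataset always produces
#' byte-identical files.
#'
#' @param dataset `data.frame` with the columns above (extra columns such
#'   as the generator's `conc_true` are dropped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  miss <- setdiff(.DATASET_COLS, names(dataset))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- dataset[order(dataset$subject_id, dataset$time_h), .DATASET_COLS]
  .validate_dataset(d)
  d$time_h <- formatC(d$time_h, digits = 17, format = "g")
  d$conc_ng_ml <- ifelse(is.na(d$conc_ng_ml), "",
                         formatC(d$conc_ng_ml, digits = 17, format = "g"))
  d$body_weight_g <- formatC(d$body_weight_g, digits = 17, format = "g")
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a concentration-time dataset CSV
#'
#' Validates every row (malformed rows are reported with their line number
#' and field) and returns records ordered by subject then time.
#'
#' @param path CSV file in the [write_dataset()] layout.
#' @return Validated `data.frame`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(hdr, .DATASET_COLS))
    stop("header mismatch: expected ",
         paste(.DATASET_COLS, collapse = ","), call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(subject_id = "character",
                               route = "character", time_h = "numeric",
                               conc_ng_ml = "numeric", blq = "integer",
                               dose_mg_kg = "numeric",
                               body_weight_g = "numeric"))
  .validate_dataset(d, where = basename(path))
  d <- d[order(d$subject_id, d$time_h), ]
  rownames(d) <- NULL
  d
}

# Run-configuration schema: key -> "scalar" or a nested schema list.
.CONFIG_SCHEMA <- list(
  seed = "scalar", output_dir = "scalar", routes = "vector",
  bile_mode = "scalar",
  cohort = list(n = "vector", sigma = "scalar", lloq = "scalar",
                dose = "scalar", distribution = "scalar",
                body_weight_mean = "scalar", body_weight_sd = "scalar"),
  fit = list(multi_start = "scalar", perturb = "scalar",
             rel_tol = "scalar", max_iter = "scalar", lower = "scalar",
             upper = "scalar"),
  solver = list(rtol = "scalar", atol = "scalar", maxsteps = "scalar",
                empty_start = "scalar")
)

.check_keys <- function(x, schema, path = "") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown config key: ", paste0(path, unknown[1L]), call. = FALSE)
  for (nm in names(x))
    if (is.list(schema[[nm]])) {
      if (!is.list(x[[nm]]))
        stop("config key ", path, nm, " must be a mapping", call. = FALSE)
      .check_keys(x[[nm]], schema[[nm]], paste0(path, nm, "."))
    }
  invisible(x)
}

#' Read and validate a YAML run configuration
#'
#' The configuration ties a whole simulate/fit/NCA run together: seed,
#' output directory, routes, cohort settings, fit settings, solver
#' settings, and the bile-emptying mode. Unknown keys are rejected before
#' any computation.
#'
#' @param path YAML file.
#' @return Validated named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  .check_keys(cfg, .CONFIG_SCHEMA)
  defaults <- list(seed = 1L, output_dir = "results",
                   routes = ROUTES, bile_mode = "continuous",
                   cohort = list(), fit = list(), solver = list())
  out <- utils::modifyList(defaults, cfg)
  if (!out$bile_mode %in% c("continuous", "windowed"))
    stop("bile_mode must be 'continuous' or 'windowed'", call. = FALSE)
  for (r in out$routes) .check_route(r)
  out
}

#' Assemble package objects from a run configuration
#'
#' @param cfg a list from [read_run_config()].
#' @return List with `spec` ([cohort_spec()]), `fit_cfg` ([fit_config()]),
#'   and `solver` ([solver_config()]).
#' @export
config_objects <- function(cfg) {
  spec <- do.call(cohort_spec, c(list(routes = cfg$routes,
                                      seed = cfg$seed),
                                 cfg$cohort))
  fit_cfg <- do.call(fit_config, c(cfg$fit, list(seed = cfg$seed)))
  solver <- do.call(solver_config,
                    c(cfg$solver, list(bile_mode = cfg$bile_mode)))
  list(spec = spec, fit_cfg = fit_cfg, solver = solver)
}
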