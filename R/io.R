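.known_variables <- c("OB", "OC", "B", "pro_mono", "pro_mac", "anti_mac",
                      "anti_mono")

#' Read a time-course dataset from CSV
#'
#' Long-format CSV with header `variable,time_day,replicate,value`.  Values
#' must be non-negative and finite; malformed rows are reported with their
#' line number.  Unknown variable labels are skipped with a warning by
#' default.
#'
#' @param path CSV file path.
#' @param on_unknown_variable `"skip"` (default; warn and drop), `"keep"`,
#'   or `"error"`.
#' @param sigma_floor_frac forwarded to [bone_dataset()].
#' @return A [bone_dataset()].
#' @export
read_dataset <- function(path, on_unknown_variable = c("skip", "keep", "error"),
                         sigma_floor_frac = 0.05) {
  on_unknown_variable <- match.arg(on_unknown_variable)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "time_day", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: header must contain %s", path, paste(need, collapse = ",")))
  }
  if (nrow(df) == 0L) stop(sprintf("%s: no data (empty table)", path))
  for (col in c("time_day", "value")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("%s: malformed '%s' at line %d", path, col, bad[1L] + 1L))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  neg <- which(df$value < 0)
  if (length(neg)) {
    stop(sprintf("%s: negative value at line %d (variable %s, day %g)",
                 path, neg[1L] + 1L, df$variable[neg[1L]], df$time_day[neg[1L]]))
  }
  unknown <- setdiff(unique(df$variable), .known_variables)
  if (length(unknown)) {
    msg <- sprintf("unknown variable label(s): %s", paste(unknown, collapse = ", "))
    if (on_unknown_variable == "error") stop(msg)
    if (on_unknown_variable == "skip") {
      warning(paste(msg, "- skipped"))
      df <- df[!(df$variable %in% unknown), , drop = FALSE]
      if (nrow(df) == 0L) stop(sprintf("%s: no data after dropping unknown variables", path))
    }
  }
  bone_dataset(df, sigma_floor_frac = sigma_floor_frac)
}

#' Write a time-course dataset to CSV
#'
#' The long-format inverse of [read_dataset()]; a write/read round trip
#' reproduces the dataset to full double precision.
#'
#' @param data a [bone_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "bone_dataset"))
  out <- data$replicates
  out$value <- format(out$value, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Columns `time_day,OB,OC,B` (plus `P,A` for the expanded model).
#'
#' @param traj a `"bone_trajectory"` from [simulate_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bone_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.serialize_params <- function(params) {
  if (inherits(params, "expanded_model_params")) {
    list(variant = "expanded",
         base = unclass(params$base)[names(unclass(params$base))],
         alpha = params$alpha, beta = params$beta,
         pro_driver = list(name = params$pro_driver$name,
                           pulses = params$pro_driver$pulses),
         anti_driver = list(name = params$anti_driver$name,
                            pulses = params$anti_driver$pulses))
  } else {
    c(list(variant = "initial"), unclass(params))
  }
}

.deserialize_params <- function(x) {
  if (identical(x$variant, "expanded")) {
    base <- do.call(initial_parameters, x$base)
    expanded_parameters(base, alpha = x$alpha, beta = x$beta,
                        pro_driver = driver_curve(x$pro_driver$pulses,
                                                  x$pro_driver$name),
                        anti_driver = driver_curve(x$anti_driver$pulses,
                                                   x$anti_driver$name))
  } else {
    do.call(initial_parameters, x[setdiff(names(x), "variant")])
  }
}

#' Write a run configuration (YAML)
#'
#' Serializes a parameter set, baseline, solver tolerances and optional
#' driver curves so a run is reproducible from its config plus a seed.
#'
#' @param path output YAML path.
#' @param params an [initial_parameters()] or [expanded_parameters()] set.
#' @param baseline a [homeostatic_baseline()].
#' @param solver list with `rtol`, `atol`.
#' @param drivers optional named list of [driver_curve()]s.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, params, baseline,
                         solver = list(rtol = 1e-8, atol = 1e-10),
                         drivers = NULL) {
  cfg <- list(model = .serialize_params(params),
              baseline = unclass(baseline), solver = solver)
  if (!is.null(drivers)) {
    cfg$drivers <- lapply(drivers, function(d) {
      list(name = d$name, pulses = d$pulses)
    })
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' @param path YAML path written by [write_config()].
#' @return A list with `params`, `baseline`, `solver` and (if present)
#'   `drivers`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(params = .deserialize_params(cfg$model),
              baseline = do.call(homeostatic_baseline, cfg$baseline),
              solver = cfg$solver)
  if (!is.null(cfg$drivers)) {
    out$drivers <- lapply(cfg$drivers, function(d) {
      driver_curve(d$pulses, d$name)
    })
  }
  out
}

#' Export a fit to JSON
#'
#' A full snapshot of a `"bone_fit"` -- parameters, baseline, coefficients,
#' diagnostics, optimizer effort and seed -- sufficient to re-simulate the
#' fitted model.  (The frozen cell fit is referenced by its own seed and
#' coefficients rather than nested in full.)
#'
#' @param fit a `"bone_fit"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bone_fit"))
  extras <- fit$extras
  if (!is.null(extras$cell_fit)) {
    extras$cell_fit <- list(coefficients = as.list(coef(extras$cell_fit)),
                            seed = extras$cell_fit$seed)
  }
  if (!is.null(extras$rate_fn)) {
    fn <- extras$rate_fn
    extras$rate_fn <- list(t_breaks = fn$t_breaks, rate_0 = fn$rate_0,
                           slopes = fn$slopes, lower_bound = fn$lower_bound,
                           upper_bound = fn$upper_bound)
  }
  snap <- list(workflow = fit$workflow,
               coefficients = as.list(coef(fit)),
               params = .serialize_params(fit$params),
               baseline = unclass(fit$baseline),
               LS = fit$LS, AIC = fit$AIC,
               per_variable_SS = as.list(fit$per_variable_SS),
               r_squared = as.list(fit$r_squared),
               n_residuals_below_one = lapply(fit$n_residuals_below_one, as.list),
               converged = fit$converged, n_evals = fit$n_evals,
               seed = fit$seed, extras = extras)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
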