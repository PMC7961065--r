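#' Replicated sparse time-course dataset
#'
#' The universal fitting input: long-format replicated observations of the
#' study variables (`OB`, `OC`, `B` and the myeloid fold-change series
#' `pro_mono`, `pro_mac`, `anti_mac`, `anti_mono`) at sparse time points.
#' On construction the replicates are aggregated to per-(variable, time)
#' means and standard errors of the mean; the SEM is the experimental error
#' `sigma_i` used by the minimax objective.  Where replicates carry no spread
#' (e.g. a noiseless synthetic dataset, or a single replicate) a floor of
#' `sigma_floor_frac` times the variable's baseline level is substituted, so
#' the objective is always defined.
#'
#' @param replicates a data frame with columns `variable`, `time_day`,
#'   `replicate`, `value` (long format).  Values must be non-negative and
#'   every variable must be observed at time 0 (the baseline defines the
#'   initial condition).
#' @param sigma_floor_frac sigma floor as a fraction of the baseline mean
#'   (default 0.05).
#' @return An object of class `"bone_dataset"` with elements `replicates`
#'   (as supplied), `summary` (columns `variable`, `time_day`, `mean`, `sem`,
#'   `sigma`, `n`), `variables` and `times`.
#' @export
bone_dataset <- function(replicates, sigma_floor_frac = 0.05) {
  need <- c("variable", "time_day", "replicate", "value")
  if (!is.data.frame(replicates) || !all(need %in% names(replicates))) {
    stop("replicates must be a data frame with columns variable, time_day, replicate, value")
  }
  if (nrow(replicates) == 0L) stop("no data: the replicate table is empty")
  if (any(!is.finite(replicates$value))) stop("values must be finite")
  if (any(replicates$value < 0)) {
    bad <- which(replicates$value < 0)[1L]
    stop(sprintf("negative value at row %d (variable %s, day %g)",
                 bad, replicates$variable[bad], replicates$time_day[bad]))
  }

  agg <- aggregate(value ~ variable + time_day, data = replicates,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  s <- data.frame(variable = agg$variable, time_day = agg$time_day,
                  mean = agg$value[, "mean"],
                  sem = agg$value[, "sd"] / sqrt(agg$value[, "n"]),
                  n = agg$value[, "n"])
  s$sem[!is.finite(s$sem)] <- 0
  s <- s[order(s$variable, s$time_day), ]
  rownames(s) <- NULL

  for (v in unique(s$variable)) {
    if (!any(s$time_day[s$variable == v] == 0)) {
      stop(sprintf("variable '%s' has no observation at time 0", v))
    }
  }

  s$sigma <- s$sem
  for (v in unique(s$variable)) {
    i <- s$variable == v
    base <- s$mean[i & s$time_day == 0][1L]
    if (!is.finite(base) || base <= 0) base <- max(abs(s$mean[i]), 1)
    floor_v <- sigma_floor_frac * base
    if (floor_v <= 0) floor_v <- 1e-8
    zero <- i & s$sigma <= 0
    s$sigma[zero] <- floor_v
  }

  structure(list(replicates = replicates[, need], summary = s,
                 variables = sort(unique(as.character(s$variable))),
                 times = sort(unique(s$time_day)),
                 sigma_floor_frac = sigma_floor_frac),
            class = "bone_dataset")
}

#' @export
print.bone_dataset <- function(x, ...) {
  cat(sprintf("Bone repair time-course dataset: %d variable(s) x %d time point(s)\n",
              length(x$variables), length(x$times)))
  cat(sprintf("  variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  days: %s\n", paste(x$times, collapse = ", ")))
  reps <- range(x$summary$n)
  cat(sprintf("  replicates per point: %s\n",
              if (reps[1L] == reps[2L]) reps[1L] else paste(reps, collapse = "-")))
  invisible(x)
}

#' Baseline state of a dataset
#'
#' Reads the day-0 replicate means of `OB`, `OC` and `B` as the homeostatic
#' baseline (the experimental baseline values are the initial conditions of
#' every simulation).
#'
#' @param data a [bone_dataset()] containing `OB`, `OC` and `B`.
#' @return A [homeostatic_baseline()].
#' @export
dataset_baseline <- function(data) {
  stopifnot(inherits(data, "bone_dataset"))
  get0 <- function(v) {
    m <- data$summary$mean[data$summary$variable == v & data$summary$time_day == 0]
    if (length(m) == 0L) stop(sprintf("variable '%s' has no baseline observation", v))
    m[1L]
  }
  homeostatic_baseline(OB_0 = get0("OB"), OC_0 = get0("OC"), B_0 = get0("B"))
}
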