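#' Minimax weighted least-squares objective
#'
#' For each variable j the inner weighted sum of squared residuals
#' `SS_j = sum_i (f_j(t_i) - D_ij)^2 / sigma_i^2` is computed over its
#' observed time points, and the objective is the *worst* of them,
#' `LS = max_j SS_j`.  Minimizing the maximum (rather than the total) keeps
#' any one variable from being sacrificed to the benefit of another.
#'
#' @param predictions a data frame with columns `variable`, `time_day`,
#'   `value`: the model evaluation `f_j(t_i)` at every observed
#'   (variable, time) pair.
#' @param data a [bone_dataset()].
#' @param variables variables to include (default: all variables in `data`).
#'   Every included observation must have a prediction.
#' @return A list of class `"ls_objective"`: `LS` (the max), `per_variable`
#'   (named vector of inner sums).
#' @export
objective_ls <- function(predictions, data, variables = NULL) {
  stopifnot(inherits(data, "bone_dataset"))
  need <- c("variable", "time_day", "value")
  if (!is.data.frame(predictions) || !all(need %in% names(predictions))) {
    stop("predictions must have columns variable, time_day, value")
  }
  s <- data$summary
  if (is.null(variables)) variables <- data$variables
  s <- s[s$variable %in% variables, , drop = FALSE]
  if (nrow(s) == 0L) stop("no observations for the requested variables")
  key <- function(v, t) paste(v, format(t, digits = 15), sep = "@")
  pk <- key(predictions$variable, predictions$time_day)
  per <- vapply(variables, function(v) {
    si <- s[s$variable == v, , drop = FALSE]
    idx <- match(key(si$variable, si$time_day), pk)
    if (anyNA(idx)) {
      stop(sprintf("missing prediction for variable '%s' at day %s",
                   v, paste(si$time_day[is.na(idx)], collapse = ", ")))
    }
    f <- predictions$value[idx]
    sum((f - si$mean)^2 / si$sigma^2)
  }, numeric(1))
  structure(list(LS = max(per), per_variable = per), class = "ls_objective")
}

#' Penalize an objective outside box bounds
#'
#' Wraps an objective `f(par)` so that the returned function equals `f`
#' inside the per-parameter bounds and grows quadratically in the normalized
#' violation outside them.  The default scale (1e6) dominates any plausible
#' objective value while keeping the surface smooth for the simplex, which
#' is how fminsearch-style unconstrained search is kept in a reasonable
#' parameter range.
#'
#' @param fn objective function of a numeric parameter vector.
#' @param bounds a list with numeric vectors `lower` and `upper` (recycled to
#'   the parameter length; use `-Inf`/`Inf` for unbounded components).
#' @param scale penalty scale (default 1e6).
#' @return A function `par -> fn(par) + penalty(par)`.
#' @export
penalized_objective <- function(fn, bounds, scale = 1e6) {
  stopifnot(is.function(fn), is.list(bounds),
            !is.null(bounds$lower), !is.null(bounds$upper))
  lower <- bounds$lower; upper <- bounds$upper
  function(par) {
    lo <- rep_len(lower, length(par)); hi <- rep_len(upper, length(par))
    width <- ifelse(is.finite(hi - lo) & (hi - lo) > 0, hi - lo,
                    pmax(abs(lo), abs(hi), 1))
    width[!is.finite(width) | width <= 0] <- 1
    viol <- pmax(0, lo - par, par - hi) / width
    fn(par) + scale * sum(viol^2)
  }
}

#' Penalized derivative-free simplex minimization
#'
#' Nelder-Mead simplex search (via `stats::optim`) with seeded multi-start:
#' the first start is used as given, the remaining `restarts - 1` starts are
#' multiplicative log-normal jitters of it, and the best result is returned.
#' Deterministic given `start`, options and `seed`.
#'
#' @param fn objective function (typically already wrapped by
#'   [penalized_objective()]).
#' @param start finite numeric start vector.
#' @param restarts total number of starts (default 5).
#' @param seed RNG seed for the jitter (default 1).
#' @param max_evals maximum function evaluations per start (default
#'   `2000 * length(start)`).
#' @param reltol relative convergence tolerance (default 1e-8).
#' @param jitter standard deviation of the log-normal start jitter
#'   (default 0.3).
#' @param parscale parameter scaling passed to `optim` (default
#'   `pmax(abs(start), 1)`).
#' @param polish_rounds maximum number of simplex re-starts from the current
#'   optimum (the simplex is re-initialized around its own endpoint until the
#'   improvement falls below `reltol`; default 3).  Guards against premature
#'   simplex collapse in higher dimensions.
#' @return A list: `par`, `value`, `converged`, `n_evals`, `n_restarts`,
#'   `seed`.
#' @examples
#' # convex sanity check: a quadratic bowl
#' f <- function(p) (p[1] - 3)^2 + (p[2] + 1)^2
#' simplex_minimize(f, c(0, 0), restarts = 1)$par
#' @export
simplex_minimize <- function(fn, start, restarts = 5, seed = 1,
                             max_evals = NULL, reltol = 1e-8, jitter = 0.3,
                             parscale = NULL, polish_rounds = 3) {
  if (any(!is.finite(start))) stop("start must be finite")
  p <- length(start)
  if (is.null(max_evals)) max_evals <- 2000L * p
  if (is.null(parscale)) parscale <- pmax(abs(start), 1)
  starts <- with_seed(seed, {
    c(list(start), lapply(seq_len(max(restarts - 1L, 0L)), function(k) {
      start * exp(rnorm(p, 0, jitter))
    }))
  })
  one_run <- function(s0) {
    if (p == 1L) {
      # optim's Nelder-Mead is unreliable in 1-D; use a bracketed search
      # around the start instead
      opt <- optim(s0, fn, method = "Brent",
                   lower = s0 - 10 * max(abs(s0), 1),
                   upper = s0 + 10 * max(abs(s0), 1))
      return(list(par = opt$par, value = opt$value,
                  convergence = opt$convergence, n_evals = 0L))
    }
    res <- optim(s0, fn, method = "Nelder-Mead",
                 control = list(maxit = max_evals, reltol = reltol,
                                parscale = parscale))
    evals <- sum(res$counts, na.rm = TRUE)
    for (r in seq_len(polish_rounds)) {
      res2 <- optim(res$par, fn, method = "Nelder-Mead",
                    control = list(maxit = max_evals, reltol = reltol,
                                   parscale = parscale))
      evals <- evals + sum(res2$counts, na.rm = TRUE)
      gain <- res$value - res2$value
      res <- res2
      if (gain <= reltol * (abs(res$value) + reltol)) break
    }
    list(par = res$par, value = res$value, convergence = res$convergence,
         n_evals = evals)
  }
  best <- NULL
  n_evals <- 0L
  for (s0 in starts) {
    res <- one_run(s0)
    n_evals <- n_evals + res$n_evals
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(par = unname(best$par), value = best$value,
       converged = identical(best$convergence, 0L) || best$convergence == 0,
       n_evals = n_evals, n_restarts = length(starts), seed = seed)
}

#' Akaike information criterion for a minimax fit
#'
#' `AIC = 2p + LS`, where `p` is the number of free parameters of the fit
#' and `LS` the minimax objective value.  Between models with equal LS, the
#' one with fewer parameters scores lower.
#'
#' @param p number of free parameters (>= 0).
#' @param LS objective value.
#' @return `2 * p + LS`.
#' @examples
#' aic(3, 10)  # 16
#' @export
aic <- function(p, LS) {
  if (p < 0) stop("p must be >= 0")
  2 * p + LS
}

# evaluate `code` with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
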