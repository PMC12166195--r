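#' @title Fitting the influx rate laws
#' @description
#' The package fits the single-phase and two-stage Michaelis-Menten rate
#' laws to replicate-level influx observations by nonlinear least squares.
#' For the two-stage model the activation threshold `T` is profiled over a
#' finite candidate set (the objective is non-smooth in `T`), and for each
#' fixed `T` the problem is solved by variable projection: the maximal
#' rates `V1`, `V2` enter linearly and are solved in closed form, leaving a
#' bounded 2-D search over `(log Km1, log Km2)` initialised from a
#' Hanes-Woolf linearisation and a two-point solve of the upper phase.
#' All parameters are bounded to (1e-6, 1e4) in native units. Ties in the
#' `T` profile break toward the smallest `T`.
#' @name fitting
NULL

PARAM_LB <- 1e-6
PARAM_UB <- 1e4

# replicate-level influx table -> validated list(S, v)
check_influx_data <- function(data) {
  if (!is.data.frame(data))
    abort("data must be a data frame of influx records",
          class = "ninflux_schema_error")
  need <- c("S_mM", "v_umol_per_gDW_h")
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste0("influx data is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ninflux_schema_error")
  S <- data$S_mM
  v <- data$v_umol_per_gDW_h
  if (!is.numeric(S) || !is.numeric(v) || anyNA(S) || anyNA(v))
    abort("S_mM and v_umol_per_gDW_h must be numeric without missing values",
          class = "ninflux_schema_error")
  if (any(S <= 0))
    abort("S_mM must be strictly positive", class = "ninflux_domain_error")
  if (any(v < 0))
    abort("rates must be nonnegative", class = "ninflux_domain_error")
  list(S = as.numeric(S), v = as.numeric(v))
}

# order-invariant fingerprint used to refuse cross-dataset comparisons
dataset_fingerprint <- function(S, v) {
  paste(length(S),
        format(sum(S), digits = 15),
        format(sum(v), digits = 15),
        format(sum(S * v), digits = 15),
        format(sum(v * v), digits = 15),
        sep = "|")
}

new_influx_fit <- function(model, params, S, v, fitted, t_profile = NULL,
                           converged = TRUE, ci = NULL) {
  structure(
    list(
      model = model,
      params = params,
      sse = sum((v - fitted)^2),
      residuals = v - fitted,
      fitted = fitted,
      n_obs = length(v),
      converged = converged,
      t_profile = t_profile,
      ci = ci,
      data = tibble::tibble(S_mM = S, v_umol_per_gDW_h = v),
      fingerprint = dataset_fingerprint(S, v)
    ),
    class = "influx_fit"
  )
}

#' Fit a single-phase Michaelis-Menten model
#'
#' Estimates `(V, Km)` minimising the unweighted sum of squared residuals
#' over all replicate-level records. `Km` is profiled on the log scale with
#' `V` solved linearly at each step; the search is bracketed around a
#' Hanes-Woolf (`S/v` vs `S`) initial estimate and over the full parameter
#' bounds, keeping the better optimum.
#'
#' @param data Data frame with columns `S_mM` and `v_umol_per_gDW_h`
#'   (additional columns are ignored), at least 3 distinct concentrations.
#' @return An `influx_fit` object (`model = "mono"`); see [tidy()] and
#'   [glance()] methods.
#' @examples
#' d <- simulate_influx(kinetic_params(2, 0.3, 1e-6, 1, T = 100),
#'                      noise = noise_model("none"), seed = 1)
#' glance(fit_single_mm(d))
#' @export
fit_single_mm <- function(data) {
  d <- check_influx_data(data)
  if (length(unique(d$S)) < 3L)
    abort("need at least 3 distinct concentrations to fit a mono model",
          class = "ninflux_insufficient_data_error")
  if (all(d$v == 0))
    abort("all rates are zero: degenerate data",
          class = "ninflux_degenerate_data_error")
  sse_at <- function(logKm) {
    f <- d$S / (exp(logKm) + d$S)
    V <- max(sum(f * d$v) / sum(f * f), 0)
    sum((d$v - V * f)^2)
  }
  lb <- log(PARAM_LB); ub <- log(PARAM_UB)
  cand <- stats::optimize(sse_at, c(lb, ub), tol = 1e-12)
  hw <- hanes_woolf_km(d$S, d$v)
  if (!is.null(hw)) {
    bracket <- c(max(lb, log(hw) - log(100)), min(ub, log(hw) + log(100)))
    local <- stats::optimize(sse_at, bracket, tol = 1e-12)
    if (local$objective < cand$objective) cand <- local
  }
  Km <- exp(cand$minimum)
  f <- d$S / (Km + d$S)
  V <- max(sum(f * d$v) / sum(f * f), PARAM_LB)
  fit <- new_influx_fit("mono", mono_params(V, max(Km, PARAM_LB)),
                        d$S, d$v, V * f,
                        converged = is.finite(cand$objective))
  fit
}

hanes_woolf_km <- function(S, v) {
  ok <- v > 0
  if (sum(ok) < 2L) return(NULL)
  cf <- tryCatch(coef(lm(I(S[ok] / v[ok]) ~ S[ok])), error = function(e) NULL)
  if (is.null(cf) || any(!is.finite(cf)) || cf[2] <= 0 || cf[1] <= 0)
    return(NULL)
  unname(cf[1] / cf[2])
}

#' Default threshold candidate set
#'
#' The observed distinct concentrations plus the midpoints between
#' consecutive observed concentrations, ascending.
#'
#' @param S Observed concentrations, mM.
#' @return Sorted numeric vector of candidate activation thresholds.
#' @export
default_t_candidates <- function(S) {
  u <- sort(unique(as.numeric(S)))
  sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
}

#' Fit the two-stage Michaelis-Menten model by profiled least squares
#'
#' For each candidate activation threshold `T`, fits `(V1, Km1, V2, Km2)`
#' by bounded nonlinear least squares (variable projection over the linear
#' `V1`, `V2`; Nelder-Mead over `(log Km1, log Km2)` initialised from a
#' Hanes-Woolf linearisation of the records below `T` and an exact
#' two-point solve of the upper phase on the two largest concentrations),
#' then returns the candidate with minimal SSE. Ties break toward the
#' smallest `T`.
#'
#' @inheritParams fit_single_mm
#' @param t_candidates Candidate thresholds, mM. Default:
#'   [default_t_candidates()] of the observed concentrations.
#' @return An `influx_fit` object (`model = "two_stage"`) whose
#'   `t_profile` element is a tibble of per-candidate `(T, sse)`.
#' @examples
#' nit <- kinetic_params(2.02, 0.31, 16.0, 2.29, T = 2)
#' fit <- fit_two_stage(simulate_influx(nit, noise = noise_model("none")))
#' tidy(fit)
#' @export
fit_two_stage <- function(data, t_candidates = NULL) {
  d <- check_influx_data(data)
  uS <- sort(unique(d$S))
  if (length(uS) < 5L)
    abort("need at least 5 distinct concentrations to fit a two-stage model",
          class = "ninflux_insufficient_data_error")
  if (all(d$v == 0))
    abort("all rates are zero: degenerate data",
          class = "ninflux_degenerate_data_error")
  cand <- if (is.null(t_candidates)) default_t_candidates(d$S)
          else sort(unique(as.numeric(t_candidates)))
  if (!length(cand) || any(cand <= 0))
    abort("t_candidates must be positive", class = "ninflux_config_error")
  splits <- vapply(cand, function(T)
    sum(uS < T) >= 2L && sum(uS > T) >= 2L, logical(1))
  if (!any(splits))
    abort(paste0("no candidate threshold leaves at least 2 distinct ",
                 "concentrations on each side"),
          class = "ninflux_insufficient_data_error")
  res <- .profile_fit_cpp(d$S, d$v, cand)
  if (!is.finite(res$sse))
    abort("two-stage optimisation failed at every candidate threshold",
          class = "ninflux_fit_failure_error")
  params <- kinetic_params(max(res$V1, PARAM_LB), res$Km1,
                           max(res$V2, 0), res$Km2, res$T)
  fitted <- two_stage_rate(params, d$S)
  fit <- new_influx_fit(
    "two_stage", params, d$S, d$v, fitted,
    t_profile = tibble::tibble(T = cand, sse = res$profile_sse),
    converged = all(is.finite(res$profile_sse))
  )
  fit
}

#' Brute-force grid minimisation (test oracle)
#'
#' Exhaustive SSE minimisation of the two-stage model over the Cartesian
#' product of per-parameter value grids. Intended as an
#' optimizer-independent oracle on small instances; refuses grids above
#' 1e7 points.
#'
#' @inheritParams fit_single_mm
#' @param grids Named list of numeric vectors `V1`, `Km1`, `V2`, `Km2`, `T`.
#' @return An `influx_fit` object with the argmin grid cell as parameters.
#' @export
brute_force_fit <- function(data, grids) {
  d <- check_influx_data(data)
  need <- c("V1", "Km1", "V2", "Km2", "T")
  if (!is.list(grids) || !all(need %in% names(grids)))
    abort("grids must be a named list with V1, Km1, V2, Km2, T",
          class = "ninflux_config_error")
  total <- prod(vapply(grids[need], length, integer(1)))
  if (total > 1e7)
    abort(sprintf("grid of %.3g points exceeds the 1e7-point limit", total),
          class = "ninflux_config_error")
  g <- expand.grid(grids[need], KEEP.OUT.ATTRS = FALSE)
  sse <- vapply(seq_len(nrow(g)), function(i)
    .sse_two_stage_cpp(d$S, d$v, g$V1[i], g$Km1[i], g$V2[i], g$Km2[i],
                       g$T[i]),
    numeric(1))
  best <- which.min(sse)
  params <- kinetic_params(g$V1[best], g$Km1[best], g$V2[best], g$Km2[best],
                           g$T[best])
  new_influx_fit("two_stage", params, d$S, d$v,
                 two_stage_rate(params, d$S))
}

#' @export
print.influx_fit <- function(x, ...) {
  cat(sprintf("%s Michaelis-Menten fit: n = %d, SSE = %.6g, converged: %s\n",
              if (x$model == "mono") "Single-phase" else "Two-stage",
              x$n_obs, x$sse, x$converged))
  print(x$params)
  if (!is.null(x$ci)) {
    cat(sprintf("bootstrap %d%% percentile intervals (%d resamples):\n",
                round(100 * attr(x$ci, "level")), attr(x$ci, "n_boot")))
    print(as.data.frame(x$ci), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy and summarise influx fits
#'
#' `tidy()` returns one row per parameter with any bootstrap interval;
#' `glance()` returns a one-row model summary.
#'
#' @param x An `influx_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.influx_fit <- function(x, ...) {
  est <- unlist(x$params)
  out <- tibble::tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(out, x$ci, by = "term")
  } else {
    out$conf.low <- NA_real_
    out$conf.high <- NA_real_
  }
  out
}

#' @rdname tidy.influx_fit
#' @export
glance.influx_fit <- function(x, ...) {
  k <- if (x$model == "mono") 2L else 5L
  tibble::tibble(
    model = x$model,
    n_obs = x$n_obs,
    sse = x$sse,
    sigma = sqrt(x$sse / max(x$n_obs - k, 1)),
    aicc = if (x$n_obs - k - 1 > 0) aicc(x$sse, x$n_obs, k) else NA_real_,
    converged = x$converged
  )
}

#' Serialise a fit to JSON
#'
#' Writes `{model, params, sse, n_obs, converged, t_profile, ci,
#' provenance}` as a JSON object.
#'
#' @param fit An `influx_fit`.
#' @param path Output file path.
#' @return `fit`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "influx_fit"))
  payload <- list(
    model = fit$model,
    params = unclass(fit$params),
    sse = fit$sse,
    n_obs = fit$n_obs,
    converged = fit$converged,
    t_profile = if (!is.null(fit$t_profile)) fit$t_profile,
    ci = if (!is.null(fit$ci))
      setNames(lapply(seq_len(nrow(fit$ci)), function(i)
        c(fit$ci$conf.low[i], fit$ci$conf.high[i])), fit$ci$term),
    provenance = list(package = "ninflux", fingerprint = fit$fingerprint)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(fit)
}
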