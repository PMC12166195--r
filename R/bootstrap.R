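#' Bootstrap confidence intervals for an influx fit
#'
#' Case-resampling bootstrap stratified within concentration levels:
#' within each observed concentration, records are resampled with
#' replacement (preserving the assay design), the model is refitted, and
#' percentile intervals are formed from the successful refits. Two-stage
#' refits profile `T` over the same candidate set as the original fit and
#' warm-start the `(Km1, Km2)` search at the original estimates.
#' Deterministic under a fixed seed.
#'
#' @param data The influx data frame the fit was computed on.
#' @param fit The `influx_fit` to wrap with intervals (must have
#'   converged).
#' @param n_boot Number of bootstrap resamples, >= 100.
#' @param seed Integer seed.
#' @param level Interval coverage level, default 0.95.
#' @return `fit` with a `ci` element: a tibble of per-parameter
#'   `term`, `conf.low`, `conf.high` (attributes: `level`, `n_boot`,
#'   `n_failed`). If more than 20\% of refits fail, a warning is issued and
#'   the intervals come from the successful draws only.
#' @examples
#' \donttest{
#' nit <- kinetic_params(2.02, 0.31, 16, 2.29, T = 2)
#' d <- simulate_influx(nit, noise = noise_model(cv_or_sigma = 0.05),
#'                      seed = 2)
#' fit <- fit_two_stage(d)
#' tidy(bootstrap_ci(d, fit, n_boot = 100, seed = 3))
#' }
#' @export
bootstrap_ci <- function(data, fit, n_boot = 200L, seed = 1L,
                         level = 0.95) {
  stopifnot(inherits(fit, "influx_fit"))
  d <- check_influx_data(data)
  if (dataset_fingerprint(d$S, d$v) != fit$fingerprint)
    abort("data does not match the dataset the fit was computed on",
          class = "ninflux_comparison_error")
  if (!isTRUE(fit$converged))
    abort("refusing to bootstrap a non-converged fit",
          class = "ninflux_fit_failure_error")
  if (n_boot < 100)
    abort("n_boot must be at least 100", class = "ninflux_config_error")
  if (level <= 0 || level >= 1)
    abort("level must be in (0, 1)", class = "ninflux_config_error")

  strata <- split(seq_along(d$S), d$S)
  warm <- if (fit$model == "two_stage")
    log(c(fit$params$Km1, fit$params$Km2))
  cand <- if (fit$model == "two_stage") fit$t_profile$T

  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      refit_params(d$S[idx], d$v[idx], fit$model, warm, cand)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    warn(sprintf(
      "bootstrap refit failure rate %.0f%% exceeds 20%%: intervals use the %d successful draws only",
      100 * n_failed / n_boot, sum(ok)))
  if (!any(ok))
    abort("every bootstrap refit failed", class = "ninflux_fit_failure_error")
  mat <- do.call(rbind, draws[ok])
  alpha <- (1 - level) / 2
  # type 6 matches the classical (n+1)p percentile-bootstrap convention
  ci <- tibble::tibble(
    term = colnames(mat),
    conf.low = apply(mat, 2, quantile, probs = alpha, names = FALSE,
                     type = 6),
    conf.high = apply(mat, 2, quantile, probs = 1 - alpha, names = FALSE,
                      type = 6)
  )
  attr(ci, "level") <- level
  attr(ci, "n_boot") <- as.integer(n_boot)
  attr(ci, "n_failed") <- as.integer(n_failed)
  attr(ci, "seed") <- as.integer(seed)
  fit$ci <- ci
  fit
}

# one bootstrap refit; NULL on failure
refit_params <- function(S, v, model, warm = NULL, cand = NULL) {
  if (model == "mono") {
    f <- tryCatch(
      fit_single_mm(tibble::tibble(S_mM = S, v_umol_per_gDW_h = v)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    return(c(V = f$params$V, Km = f$params$Km))
  }
  res <- tryCatch(
    .profile_fit_cpp(S, v, cand, warm_start = warm, reltol = 1e-9,
                     maxit = 150, restarts = 0),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$sse)) return(NULL)
  c(V1 = max(res$V1, PARAM_LB), Km1 = res$Km1,
    V2 = max(res$V2, 0), Km2 = res$Km2, T = res$T)
}
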