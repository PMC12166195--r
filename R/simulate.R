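#' Influx assay design
#'
#' Describes a short-term tracer influx assay: which nitrogen source is fed,
#' the external concentration grid, and the number of replicate plants per
#' concentration. The default grid is the 13-point series 0.01-10 mM used
#' for root influx assays, with 4 replicates per concentration and a 10-min
#' incubation (rates are still expressed per hour; any normalisation from
#' the incubation time to one hour is the data producer's responsibility).
#'
#' @param n_source `"ammonium"` or `"nitrate"`.
#' @param grid Strictly positive, strictly increasing concentration grid, mM.
#' @param replicates Number of replicates per concentration, >= 1.
#' @param duration_min Incubation time in minutes (informational only).
#' @return An `assay_design` object (named list).
#' @export
assay_design <- function(n_source = c("ammonium", "nitrate"),
                         grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4,
                                  0.5, 0.75, 1, 2, 5, 10),
                         replicates = 4L,
                         duration_min = 10) {
  n_source <- match.arg(n_source)
  if (!is.numeric(grid) || !length(grid) || any(grid <= 0) ||
      is.unsorted(grid, strictly = TRUE))
    abort("grid must be strictly positive and strictly increasing",
          class = "ninflux_config_error")
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    abort("replicates must be a single count >= 1",
          class = "ninflux_config_error")
  structure(list(n_source = n_source, grid = as.numeric(grid),
                 replicates = as.integer(replicates),
                 duration_min = duration_min),
            class = "assay_design")
}

#' Measurement-noise model for simulated influx
#'
#' @param kind `"multiplicative-normal"` (default): observed rate is
#'   `max(0, rate * (1 + e))` with `e ~ Normal(0, cv)`;
#'   `"additive-normal"`: `max(0, rate + e)` with `e ~ Normal(0, sigma)` in
#'   rate units; or `"none"`.
#' @param cv_or_sigma Coefficient of variation (dimensionless) for
#'   multiplicative noise, or standard deviation (\eqn{\mu}mol/g DW/h) for
#'   additive noise. Default 0.05, a typical relative error for
#'   IRMS-derived uptake rates.
#' @return A `noise_model` object (named list).
#' @export
noise_model <- function(kind = c("multiplicative-normal", "additive-normal",
                                 "none"),
                        cv_or_sigma = 0.05) {
  if (is.character(kind) && length(kind) == 1L &&
      !kind %in% c("multiplicative-normal", "additive-normal", "none"))
    abort(paste0("unknown noise kind '", kind, "'"),
          class = "ninflux_config_error")
  kind <- match.arg(kind)
  if (!is.numeric(cv_or_sigma) || length(cv_or_sigma) != 1L ||
      cv_or_sigma < 0)
    abort("cv_or_sigma must be a single nonnegative number",
          class = "ninflux_config_error")
  structure(list(kind = kind, cv_or_sigma = as.numeric(cv_or_sigma)),
            class = "noise_model")
}

#' Simulate a tracer influx dataset
#'
#' Draws one observation per (grid concentration x replicate) from the
#' two-stage Michaelis-Menten rate law of `params`, perturbed by the chosen
#' noise model and truncated at zero. With `noise_model("none")` every
#' observation equals [two_stage_rate()] exactly. Output is bit-identical
#' for identical inputs and seed.
#'
#' @param params A [kinetic_params()] object: the generating truth.
#' @param design An [assay_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draws.
#' @return A tibble with columns `n_source`, `S_mM`, `replicate`,
#'   `v_umol_per_gDW_h`, carrying a `provenance` attribute (generating
#'   parameters, design, noise, seed).
#' @examples
#' nit <- kinetic_params(2.02, 0.31, 16.0, 2.29, T = 2)
#' sim <- simulate_influx(nit, assay_design("nitrate"),
#'                        noise_model("none"), seed = 1)
#' dplyr::filter(sim, S_mM == 2)
#' @export
simulate_influx <- function(params, design = assay_design(),
                            noise = noise_model(), seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(design, "assay_design"),
            inherits(noise, "noise_model"))
  S <- rep(design$grid, each = design$replicates)
  mu <- two_stage_rate(params, S)
  v <- withr::with_seed(as.integer(seed), {
    switch(noise$kind,
      "none" = mu,
      "multiplicative-normal" =
        pmax(0, mu * (1 + rnorm(length(mu), 0, noise$cv_or_sigma))),
      "additive-normal" =
        pmax(0, mu + rnorm(length(mu), 0, noise$cv_or_sigma))
    )
  })
  out <- tibble::tibble(
    n_source = design$n_source,
    S_mM = S,
    replicate = rep(seq_len(design$replicates), times = length(design$grid)),
    v_umol_per_gDW_h = v
  )
  attr(out, "provenance") <- list(
    generator = "simulate_influx",
    params = unclass(params),
    design = unclass(design),
    noise = unclass(noise),
    seed = as.integer(seed)
  )
  out
}

#' Convert atom percent excess to an influx rate
#'
#' Minimal isotope-dilution conversion from the IRMS-measured quantities to
#' an uptake rate: the fraction of tissue N drawn from the labelled feeding
#' solution, times the total N pool, per unit time,
#' `rate = (ape_sample / ape_source) * n_total / duration`. Natural-abundance
#' background subtraction is assumed to have produced `ape_sample` already
#' and is not performed here.
#'
#' @param ape_sample Atom percent excess of the tissue sample
#'   (0-`ape_source`).
#' @param ape_source Atom percent of the feeding solution (default 99.9,
#'   the enrichment of the labelled salts).
#' @param n_total Total N in the tissue, \eqn{\mu}mol per g DW.
#' @param duration_h Incubation time, hours.
#' @return Influx rate(s), \eqn{\mu}mol/g DW/h.
#' @examples
#' ape_to_influx(1, 99.9, n_total = 100, duration_h = 1)
#' @export
ape_to_influx <- function(ape_sample, ape_source = 99.9, n_total,
                          duration_h) {
  if (any(!is.finite(ape_sample)) || any(ape_sample < 0))
    abort("ape_sample must be nonnegative", class = "ninflux_domain_error")
  if (any(ape_source <= 0) || any(ape_source > 100))
    abort("ape_source must be in (0, 100]", class = "ninflux_domain_error")
  if (any(ape_sample > ape_source))
    abort("ape_sample exceeds ape_source: inconsistent measurement",
          class = "ninflux_measurement_error")
  if (any(n_total <= 0) || any(duration_h <= 0))
    abort("n_total and duration_h must be positive",
          class = "ninflux_domain_error")
  (ape_sample / ape_source) * n_total / duration_h
}
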