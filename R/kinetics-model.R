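#' Single-phase Michaelis-Menten parameters
#'
#' Bundle of the maximal rate `V` (\eqn{\mu}mol/g DW/h) and Michaelis
#' constant `Km` (mM) of a single saturable transport phase, used for the
#' low-concentration description of influx and for model comparison against
#' the two-stage law.
#'
#' @param V Maximal rate at saturating substrate, \eqn{\mu}mol/g DW/h.
#'   Must be positive.
#' @param Km Michaelis constant, the external concentration at which the
#'   phase runs at half `V`, mM. Must be positive.
#' @return An object of class `mono_params`: a named list with elements
#'   `V` and `Km`.
#' @examples
#' mono_params(V = 2.02, Km = 0.31)
#' @seealso [kinetic_params()] for the biphasic model, [mm_rate()].
#' @export
mono_params <- function(V, Km) {
  check_scalar_positive(V, "V")
  check_scalar_positive(Km, "Km")
  structure(list(V = as.numeric(V), Km = as.numeric(Km)),
            class = "mono_params")
}

#' Two-stage Michaelis-Menten parameters
#'
#' Parameters of the biphasic influx rate law used for root nitrogen uptake:
#' a high-affinity phase `(V1, Km1)` active at all concentrations, and a
#' low-affinity phase `(V2, Km2)` that switches on above the activation
#' threshold `T`:
#' \deqn{v(S) = \frac{V_1 S}{K_{m1} + S} \quad (S < T)}
#' \deqn{v(S) = \frac{V_1 T}{K_{m1} + T} + \frac{V_2 (S - T)}{K_{m2} + S - T}
#'   \quad (S \ge T)}
#' The curve is continuous at `S = T` by construction.
#'
#' Phase identity follows the convention `Km1 <= Km2` (phase 1 is the
#' high-affinity system). Inputs violating it are normalised by swapping the
#' two phases, with a warning.
#'
#' @param V1,V2 Maximal rates of the high- and low-affinity phases,
#'   \eqn{\mu}mol/g DW/h. `V1` must be positive; `V2` may be zero
#'   (second phase absent).
#' @param Km1,Km2 Michaelis constants of the two phases, mM; both positive.
#' @param T Activation threshold of the low-affinity phase, mM; positive.
#' @return An object of class `kinetic_params`: a named list with elements
#'   `V1`, `Km1`, `V2`, `Km2`, `T`.
#' @examples
#' # printed constants for nitrate influx into tea roots
#' kinetic_params(V1 = 2.02, Km1 = 0.31, V2 = 16.0, Km2 = 2.29, T = 2)
#' @export
kinetic_params <- function(V1, Km1, V2, Km2, T) {
  check_scalar_positive(V1, "V1")
  check_scalar_positive(Km1, "Km1")
  check_scalar_nonneg(V2, "V2")
  check_scalar_positive(Km2, "Km2")
  check_scalar_positive(T, "T")
  if (Km1 > Km2) {
    warn(paste0(
      "Km1 (", format(Km1), ") > Km2 (", format(Km2), "): swapping phases ",
      "so that phase 1 is the high-affinity system (Km1 <= Km2)."
    ))
    tmp <- c(V1, Km1)
    V1 <- V2; Km1 <- Km2
    V2 <- tmp[1]; Km2 <- tmp[2]
    if (V1 <= 0) abort("after phase normalisation V1 must be > 0")
  }
  structure(
    list(V1 = as.numeric(V1), Km1 = as.numeric(Km1), V2 = as.numeric(V2),
         Km2 = as.numeric(Km2), T = as.numeric(T)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-stage Michaelis-Menten parameters\n")
  cat(sprintf("  high-affinity: V1 = %g umol/g DW/h, Km1 = %g mM\n",
              x$V1, x$Km1))
  cat(sprintf("  low-affinity:  V2 = %g umol/g DW/h, Km2 = %g mM\n",
              x$V2, x$Km2))
  cat(sprintf("  activation threshold T = %g mM\n", x$T))
  invisible(x)
}

#' @export
print.mono_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten parameters: V = %g umol/g DW/h, Km = %g mM\n",
              x$V, x$Km))
  invisible(x)
}

#' Single-phase Michaelis-Menten rate
#'
#' Evaluates \eqn{v = V S / (K_m + S)} at external concentration(s) `S`.
#'
#' @param params A [mono_params()] object.
#' @param S External substrate concentration(s), mM; nonnegative.
#' @return Numeric vector of rates, \eqn{\mu}mol/g DW/h, same length as `S`.
#' @examples
#' mm_rate(mono_params(2.02, 0.31), S = 0.31) # half-saturation: 1.01
#' @export
mm_rate <- function(params, S) {
  stopifnot(inherits(params, "mono_params"))
  check_concentration(S)
  params$V * S / (params$Km + S)
}

#' Two-stage Michaelis-Menten rate
#'
#' Evaluates the biphasic rate law of [kinetic_params()]: the high-affinity
#' phase alone below the activation threshold `T`, and the high-affinity
#' plateau at `T` plus a shifted Michaelis-Menten term above it. The two
#' branches agree at `S = T`, so the curve is continuous; it is
#' nondecreasing in `S` and bounded above by `V1 + V2`.
#'
#' @param params A [kinetic_params()] object.
#' @param S External substrate concentration(s), mM; nonnegative.
#' @return Numeric vector of rates, \eqn{\mu}mol/g DW/h, same length as `S`.
#' @examples
#' amm <- kinetic_params(1.81, 0.02, 213.7, 81.3, T = 0.5)
#' two_stage_rate(amm, S = c(0.5, 10))
#' @export
two_stage_rate <- function(params, S) {
  stopifnot(inherits(params, "kinetic_params"))
  check_concentration(S)
  plateau <- params$V1 * params$T / (params$Km1 + params$T)
  ifelse(S < params$T,
         params$V1 * S / (params$Km1 + S),
         plateau + params$V2 * (S - params$T) / (params$Km2 + S - params$T))
}

#' Rate curve over a concentration grid
#'
#' Elementwise [two_stage_rate()] over a grid, returned as a tidy tibble.
#' Preserves grid order and length; an empty grid yields an empty tibble.
#'
#' @inheritParams two_stage_rate
#' @param grid Numeric vector of external concentrations, mM; nonnegative.
#' @return A tibble with columns `S_mM` and `v_umol_per_gDW_h`.
#' @export
rate_curve <- function(params, grid) {
  check_concentration(grid)
  tibble::tibble(
    S_mM = as.numeric(grid),
    v_umol_per_gDW_h = if (length(grid)) two_stage_rate(params, grid)
                       else numeric(0)
  )
}

#' Read and write kinetic parameters as JSON
#'
#' Parameters serialise to a flat JSON object `{V1, Km1, V2, Km2, T}` (or
#' `{V, Km}` for the single-phase model) in their native units.
#'
#' @param params A [kinetic_params()] or [mono_params()] object.
#' @param path File path for the JSON object.
#' @return `write_params_json()` returns `params` invisibly;
#'   `read_params_json()` returns the reconstructed parameter object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, c("kinetic_params", "mono_params")))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(params)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("V1", "Km1", "V2", "Km2", "T") %in% names(x))) {
    kinetic_params(x$V1, x$Km1, x$V2, x$Km2, x$T)
  } else if (all(c("V", "Km") %in% names(x))) {
    mono_params(x$V, x$Km)
  } else {
    abort(paste0(
      "JSON at '", path, "' is not a parameter object: expected fields ",
      "{V1, Km1, V2, Km2, T} or {V, Km}, found {",
      paste(names(x), collapse = ", "), "}"
    ), class = "ninflux_schema_error")
  }
}

# -- validation helpers -------------------------------------------------------

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(paste0(name, " must be a single positive finite number"),
          class = "ninflux_domain_error")
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    abort(paste0(name, " must be a single nonnegative finite number"),
          class = "ninflux_domain_error")
  invisible(x)
}

check_concentration <- function(S) {
  if (length(S) && (!is.numeric(S) || anyNA(S) || any(S < 0)))
    abort("concentrations S must be nonnegative numbers",
          class = "ninflux_domain_error")
  invisible(S)
}
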