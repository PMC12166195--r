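#' Treatment labels of the ammonium:nitrate ratio design
#'
#' The five feeding treatments, total inorganic N held at 2.86 mM and split
#' between ammonium and nitrate: 100:0 (2.86:0 mM), 75:25 (2.14:0.71),
#' 50:50 (1.43:1.43), 25:75 (0.71:2.14) and 0:100 (0:2.86).
#'
#' @return A tibble with columns `treatment`, `nh4_mM`, `no3_mM`, ordered
#'   from all-ammonium to all-nitrate.
#' @export
nitrogen_treatments <- function() {
  tibble::tibble(
    treatment = c("100:0", "75:25", "50:50", "25:75", "0:100"),
    nh4_mM = c(2.86, 2.14, 1.43, 0.71, 0),
    no3_mM = c(0, 0.71, 1.43, 2.14, 2.86)
  )
}

#' Default expected free-amino-acid means
#'
#' A synthetic mean table (treatment x organ x analyte expected
#' concentrations, \eqn{\mu}mol/g DW) emulating the qualitative behaviour of
#' free amino acids in tea organs under the five ammonium:nitrate
#' treatments: theanine and arginine rise steeply with the ammonium share,
#' glutamate stays comparatively flat, and glutamine peaks at the 25:75
#' treatment. The numbers are plausible magnitudes for tea tissues, not
#' measurements.
#'
#' @param organs Organ labels; default new leaves and new roots.
#' @return A tibble with columns `treatment`, `organ`, `analyte`, `mean`.
#' @export
default_metabolite_means <- function(organs = c("new_leaves", "new_roots")) {
  trt <- nitrogen_treatments()$treatment
  # per-treatment multipliers, ordered 100:0 ... 0:100
  profiles <- list(
    Thea = c(1.8, 1.7, 1.2, 0.8, 0.4),
    Arg  = c(2.5, 1.6, 1.0, 0.5, 0.2),
    Gln  = c(1.0, 1.1, 1.3, 1.6, 0.9),
    Glu  = c(1.0, 1.05, 1.1, 1.05, 0.95),
    Asp  = c(1.1, 1.05, 1.0, 0.95, 0.9),
    Ser  = c(1.05, 1.0, 1.0, 0.95, 0.95)
  )
  base <- c(Thea = 60, Arg = 8, Gln = 6, Glu = 10, Asp = 5, Ser = 3)
  organ_scale <- setNames(c(1, 0.6), organs)
  out <- lapply(names(profiles), function(a) {
    lapply(organs, function(o) {
      tibble::tibble(treatment = trt, organ = o, analyte = a,
                     mean = base[[a]] * profiles[[a]] * organ_scale[[o]])
    })
  })
  dplyr::bind_rows(unlist(out, recursive = FALSE))
}

#' Metabolite simulation design
#'
#' @param means Tibble with columns `treatment`, `organ`, `analyte`, `mean`
#'   (expected concentration per g DW for every cell of the design).
#'   Default [default_metabolite_means()].
#' @param cv Coefficient of variation of replicate noise; default 0.10.
#' @param replicates Replicates per treatment x organ; default 6.
#' @return A `metabolite_design` object.
#' @export
metabolite_design <- function(means = default_metabolite_means(),
                              cv = 0.10, replicates = 6L) {
  required <- c("treatment", "organ", "analyte", "mean")
  if (!is.data.frame(means) || !all(required %in% names(means)))
    abort("means must have columns treatment, organ, analyte, mean",
          class = "ninflux_config_error")
  if (anyNA(means$mean) || any(means$mean < 0))
    abort("design means must be nonnegative and complete",
          class = "ninflux_config_error")
  full <- tidyr::expand_grid(
    treatment = unique(means$treatment),
    organ = unique(means$organ),
    analyte = unique(means$analyte)
  )
  missing <- dplyr::anti_join(full, means,
                              by = c("treatment", "organ", "analyte"))
  if (nrow(missing) > 0)
    abort(paste0("missing design mean for ", nrow(missing),
                 " treatment x organ x analyte cell(s), e.g. ",
                 missing$treatment[1], "/", missing$organ[1], "/",
                 missing$analyte[1]),
          class = "ninflux_config_error")
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0)
    abort("cv must be a single nonnegative number",
          class = "ninflux_config_error")
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    abort("replicates must be a single count >= 1",
          class = "ninflux_config_error")
  structure(list(means = tibble::as_tibble(means), cv = cv,
                 replicates = as.integer(replicates)),
            class = "metabolite_design")
}

#' Simulate a metabolite concentration table
#'
#' One record per treatment x organ x replicate x analyte. Replicate values
#' are normal draws around the design mean with standard deviation
#' `cv * mean`, truncated at zero; `cv = 0` reproduces the means exactly.
#' Deterministic under a fixed seed.
#'
#' @param design A [metabolite_design()].
#' @param seed Integer seed.
#' @return A tibble with columns `treatment`, `organ`, `replicate`,
#'   `analyte`, `concentration`, carrying a `provenance` attribute.
#' @examples
#' tab <- simulate_metabolites(metabolite_design(), seed = 7)
#' dplyr::count(tab, treatment, organ)
#' @export
simulate_metabolites <- function(design = metabolite_design(), seed = 1L) {
  stopifnot(inherits(design, "metabolite_design"))
  out <- tidyr::expand_grid(
    dplyr::distinct(design$means[c("treatment", "organ")]),
    replicate = seq_len(design$replicates)
  )
  out <- dplyr::inner_join(out, design$means,
                           by = c("treatment", "organ"),
                           relationship = "many-to-many")
  out <- dplyr::arrange(out, .data$treatment, .data$organ, .data$analyte,
                        .data$replicate)
  out$concentration <- withr::with_seed(as.integer(seed), {
    pmax(0, rnorm(nrow(out), mean = out$mean, sd = design$cv * out$mean))
  })
  out <- tibble::as_tibble(
    out[c("treatment", "organ", "replicate", "analyte", "concentration")]
  )
  attr(out, "provenance") <- list(
    generator = "simulate_metabolites",
    cv = design$cv,
    replicates = design$replicates,
    noise = "normal truncated at zero, sd = cv * mean",
    seed = as.integer(seed)
  )
  out
}
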