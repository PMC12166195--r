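check_metabolite_table <- function(table) {
  need <- c("treatment", "organ", "replicate", "analyte", "concentration")
  miss <- setdiff(need, names(table))
  if (!is.data.frame(table) || length(miss))
    abort(paste0("metabolite table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ninflux_schema_error")
  invisible(table)
}

#' Per-replicate ratio of two analytes
#'
#' Computes `numerator / denominator` within each
#' (treatment, organ, replicate) — e.g. the Gln:Glu or Gln:Thea ratios that
#' index the balance of glutamine versus theanine synthesis. The ratio is
#' formed per replicate (matching per-replicate dots in figures), then may
#' be summarised by treatment downstream. Replicates with a nonpositive
#' denominator yield a flagged missing value, never a silent drop.
#'
#' @param table Metabolite data frame with columns `treatment`, `organ`,
#'   `replicate`, `analyte`, `concentration`.
#' @param numerator,denominator Analyte labels; both must be present in
#'   every (treatment, organ, replicate).
#' @return A tibble with columns `treatment`, `organ`, `replicate`,
#'   `ratio_name`, `value`, `flag` (`NA` or `"nonpositive_denominator"`).
#' @examples
#' tab <- simulate_metabolites(seed = 1)
#' pair_ratio(tab, "Gln", "Glu")
#' @export
pair_ratio <- function(table, numerator, denominator) {
  check_metabolite_table(table)
  present <- unique(table$analyte)
  miss <- setdiff(c(numerator, denominator), present)
  if (length(miss))
    abort(paste0("analyte(s) not in table: ", paste(miss, collapse = ", ")),
          class = "ninflux_config_error")
  keys <- c("treatment", "organ", "replicate")
  wide <- tidyr::pivot_wider(
    dplyr::filter(table, .data$analyte %in% c(numerator, denominator)),
    id_cols = dplyr::all_of(keys),
    names_from = "analyte", values_from = "concentration"
  )
  num <- wide[[numerator]]
  den <- wide[[denominator]]
  if (anyNA(num) || anyNA(den))
    abort(paste0("analytes '", numerator, "' and '", denominator,
                 "' must be present in every (treatment, organ, replicate)"),
          class = "ninflux_schema_error")
  bad <- den <= 0
  out <- tibble::tibble(
    wide[keys],
    ratio_name = paste0(numerator, ":", denominator),
    value = ifelse(bad, NA_real_, num / den),
    flag = ifelse(bad, "nonpositive_denominator", NA_character_)
  )
  if (any(bad))
    warn(sprintf("%d replicate(s) had nonpositive %s: ratio set to NA",
                 sum(bad), denominator))
  out
}

#' Per-sample total over an analyte set
#'
#' Sums concentrations over the stated analytes within each
#' (treatment, organ, replicate), e.g. the total free-amino-acid pool.
#'
#' @inheritParams pair_ratio
#' @param analyte_set Nonempty character vector of analyte labels, all
#'   present in the table.
#' @return A tibble with columns `treatment`, `organ`, `replicate`,
#'   `total`.
#' @examples
#' tab <- simulate_metabolites(seed = 1)
#' total_faa(tab, c("Thea", "Gln", "Glu"))
#' @export
total_faa <- function(table, analyte_set) {
  check_metabolite_table(table)
  if (!length(analyte_set))
    abort("analyte_set must be nonempty", class = "ninflux_config_error")
  miss <- setdiff(analyte_set, unique(table$analyte))
  if (length(miss))
    abort(paste0("unknown analyte(s) in set: ", paste(miss, collapse = ", ")),
          class = "ninflux_config_error")
  table |>
    dplyr::filter(.data$analyte %in% analyte_set) |>
    dplyr::summarise(total = sum(.data$concentration),
                     .by = c("treatment", "organ", "replicate")) |>
    dplyr::arrange(.data$treatment, .data$organ, .data$replicate)
}

#' Log2 fold-change matrix relative to the across-treatment mean
#'
#' The heat-map statistic: each value is divided by its row's grand mean
#' and log2-transformed. By default the grand mean of a row is the mean of
#' the treatment means (treatments weighted equally, robust to unequal
#' replicate counts), so the plain treatment-mean fold-changes of every row
#' average to exactly 1; `grand_mean = "samples"` uses the mean over all
#' samples instead. Rows are every combination of the grouping columns
#' (all columns other than `treatment`, `replicate` and the value column,
#' e.g. organ x analyte).
#'
#' @param table Long-form data frame with a `treatment` column, a
#'   `replicate` column, the measurement column, and any number of row
#'   grouping columns (e.g. `organ`, `analyte` — or `gene`).
#' @param value_field Name of the measurement column; default
#'   `"concentration"`.
#' @param grand_mean `"treatment_means"` (default) or `"samples"`.
#' @return A `fold_change_matrix` object: a list with
#'   `by_treatment` (long tibble of row keys, `treatment`, `mean`, `fc`,
#'   `log2fc`), `per_sample` (per-replicate `fc`/`log2fc`), and
#'   `grand_means`. Rows whose grand mean is zero are emitted with missing
#'   cells and a warning.
#' @examples
#' tab <- simulate_metabolites(seed = 1)
#' fcm <- log2fc_matrix(tab)
#' head(fcm$by_treatment)
#' fc_wide(fcm)
#' @export
log2fc_matrix <- function(table, value_field = "concentration",
                          grand_mean = c("treatment_means", "samples")) {
  grand_mean <- match.arg(grand_mean)
  if (!is.data.frame(table) ||
      !all(c("treatment", "replicate", value_field) %in% names(table)))
    abort(paste0("table must have columns treatment, replicate and '",
                 value_field, "'"),
          class = "ninflux_schema_error")
  rows <- setdiff(names(table), c("treatment", "replicate", value_field))
  if (!length(rows))
    abort("no row grouping columns (e.g. analyte) found",
          class = "ninflux_schema_error")
  val <- rlang::sym(value_field)
  trt_means <- table |>
    dplyr::summarise(mean = mean(!!val),
                     .by = dplyr::all_of(c(rows, "treatment")))
  grand <- if (grand_mean == "treatment_means") {
    dplyr::summarise(trt_means, grand_mean = mean(.data$mean),
                     .by = dplyr::all_of(rows))
  } else {
    dplyr::summarise(table, grand_mean = mean(!!val),
                     .by = dplyr::all_of(rows))
  }
  if (any(grand$grand_mean == 0))
    warn(sprintf("%d row(s) have a zero grand mean: cells set to NA",
                 sum(grand$grand_mean == 0)))
  by_treatment <- trt_means |>
    dplyr::left_join(grand, by = rows) |>
    dplyr::mutate(
      fc = ifelse(.data$grand_mean > 0, .data$mean / .data$grand_mean,
                  NA_real_),
      log2fc = log2(.data$fc)
    ) |>
    dplyr::select(-"grand_mean")
  per_sample <- table |>
    dplyr::left_join(grand, by = rows) |>
    dplyr::mutate(
      fc = ifelse(.data$grand_mean > 0, !!val / .data$grand_mean, NA_real_),
      log2fc = log2(.data$fc)
    ) |>
    dplyr::select(dplyr::all_of(c(rows, "treatment", "replicate")),
                  "fc", "log2fc")
  structure(
    list(by_treatment = tibble::as_tibble(by_treatment),
         per_sample = tibble::as_tibble(per_sample),
         grand_means = tibble::as_tibble(grand),
         grand_mean_basis = grand_mean,
         row_cols = rows),
    class = "fold_change_matrix"
  )
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf(
    "Fold-change matrix: %d row(s) x %d treatment(s), grand mean over %s\n",
    nrow(x$grand_means), length(unique(x$by_treatment$treatment)),
    if (x$grand_mean_basis == "treatment_means") "treatment means"
    else "all samples"))
  print(fc_wide(x))
  invisible(x)
}

#' Wide log2 fold-change table
#'
#' @param x A `fold_change_matrix`.
#' @return A tibble: one row per row key, one column of `log2fc` per
#'   treatment.
#' @export
fc_wide <- function(x) {
  stopifnot(inherits(x, "fold_change_matrix"))
  tidyr::pivot_wider(x$by_treatment[c(x$row_cols, "treatment", "log2fc")],
                     names_from = "treatment", values_from = "log2fc")
}

#' @export
tidy.fold_change_matrix <- function(x, ...) x$by_treatment

#' Convert a concentration to an organ content
#'
#' `content = concentration x organ dry mass`; the distinction between a
#' per-gram concentration and a per-organ content matters because organ
#' biomass responds to treatment.
#'
#' @param conc Concentration(s), amount per g DW; nonnegative.
#' @param mass Organ dry weight(s), g; nonnegative.
#' @return Content(s), amount per organ.
#' @examples
#' content_from_concentration(30, 2) # 60
#' @export
content_from_concentration <- function(conc, mass) {
  if (any(conc < 0, na.rm = TRUE) || any(mass < 0, na.rm = TRUE))
    abort("conc and mass must be nonnegative",
          class = "ninflux_domain_error")
  conc * mass
}
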