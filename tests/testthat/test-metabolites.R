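toy_table <- function() {
  tidyr::expand_grid(
    treatment = c("A", "B"),
    organ = "leaf",
    replicate = 1:2,
    analyte = c("Gln", "Glu")
  ) |>
    dplyr::mutate(concentration = c(2, 1, 4, 2, 2, 1, 4, 2))
}

test_that("pair ratios are computed per replicate", {
  # Gln = (2, 4), Glu = (1, 2) within each treatment -> ratios (2, 2)
  r <- pair_ratio(toy_table(), "Gln", "Glu")
  expect_equal(nrow(r), 4L)
  expect_equal(r$value, rep(2, 4))
  expect_equal(unique(r$ratio_name), "Gln:Glu")
  # equal analytes give unit ratios; doubling the numerator doubles them
  tab <- simulate_metabolites(seed = 2)
  gg <- dplyr::mutate(tab,
    concentration = ifelse(analyte == "Glu",
      concentration[match(paste(treatment, organ, replicate, "Gln"),
                          paste(treatment, organ, replicate, analyte))],
      concentration))
  expect_equal(pair_ratio(gg, "Gln", "Glu")$value,
               rep(1, 5 * 2 * 6))
  doubled <- dplyr::mutate(tab, concentration =
    ifelse(analyte == "Gln", 2 * concentration, concentration))
  expect_equal(pair_ratio(doubled, "Gln", "Glu")$value,
               2 * pair_ratio(tab, "Gln", "Glu")$value)
})

test_that("nonpositive denominators flag missing values, never drop records", {
  tab <- toy_table()
  tab$concentration[tab$analyte == "Glu" & tab$replicate == 1] <- 0
  expect_warning(r <- pair_ratio(tab, "Gln", "Glu"), "nonpositive")
  expect_equal(nrow(r), 4L)
  expect_equal(sum(is.na(r$value)), 2L)
  expect_equal(r$flag[is.na(r$value)],
               rep("nonpositive_denominator", 2))
  expect_error(pair_ratio(tab, "Gln", "Thea"),
               class = "ninflux_config_error")
})

test_that("totals sum the stated analyte set per sample and ignore order", {
  tab <- toy_table()
  one <- total_faa(tab, "Gln")
  expect_equal(one$total,
               tab$concentration[tab$analyte == "Gln"][order(
                 tab$treatment[tab$analyte == "Gln"],
                 tab$replicate[tab$analyte == "Gln"])])
  both <- total_faa(tab, c("Gln", "Glu"))
  expect_equal(both$total, c(3, 6, 3, 6))
  shuffled <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  expect_equal(total_faa(shuffled, c("Gln", "Glu")), both)
  expect_error(total_faa(tab, character(0)),
               class = "ninflux_config_error")
  expect_error(total_faa(tab, c("Gln", "Lys")),
               class = "ninflux_config_error")
})

test_that("log2 fold-changes are zero under equal treatments and centred otherwise", {
  tab <- toy_table()
  fcm <- log2fc_matrix(tab)
  # treatments identical -> every treatment-mean log2FC is 0
  expect_equal(fcm$by_treatment$log2fc, rep(0, 4))
  # treatment means 1..5: grand mean 3, middle treatment log2FC = 0
  tab5 <- tibble::tibble(
    treatment = as.character(1:5), replicate = 1L,
    analyte = "x", concentration = 1:5
  )
  f5 <- log2fc_matrix(tab5)
  expect_equal(f5$grand_means$grand_mean, 3)
  expect_equal(f5$by_treatment$log2fc[f5$by_treatment$treatment == "3"], 0)
  expect_equal(f5$by_treatment$fc, (1:5) / 3)
})

test_that("fold-change rows are normalised, scale-invariant and relabel-equivariant", {
  tab <- simulate_metabolites(seed = 3)
  fcm <- log2fc_matrix(tab)
  # mean over treatments of the plain FC is exactly 1 for every row
  norm <- dplyr::summarise(fcm$by_treatment, m = mean(fc),
                           .by = c(organ, analyte))
  expect_equal(norm$m, rep(1, nrow(norm)))
  # rescaling one row's values leaves its log2FC unchanged
  scaled <- dplyr::mutate(tab, concentration =
    ifelse(analyte == "Thea", concentration * 17, concentration))
  expect_equal(log2fc_matrix(scaled)$by_treatment$log2fc,
               fcm$by_treatment$log2fc)
  # relabeling treatments permutes, not changes, the cells
  relab <- dplyr::mutate(tab, treatment = paste0("trt_", treatment))
  f2 <- log2fc_matrix(relab)
  key <- paste(fcm$by_treatment$organ, fcm$by_treatment$analyte,
               paste0("trt_", fcm$by_treatment$treatment))
  key2 <- paste(f2$by_treatment$organ, f2$by_treatment$analyte,
                f2$by_treatment$treatment)
  expect_equal(f2$by_treatment$log2fc[match(key, key2)],
               fcm$by_treatment$log2fc)
})

test_that("per-sample and treatment-mean fold-change forms are both emitted", {
  tab <- simulate_metabolites(seed = 4)
  fcm <- log2fc_matrix(tab)
  expect_equal(nrow(fcm$per_sample), nrow(tab))
  # per-sample values average (within treatment) to the treatment-mean FC
  agg <- dplyr::summarise(fcm$per_sample, fc = mean(fc),
                          .by = c(organ, analyte, treatment))
  merged <- dplyr::inner_join(
    agg, fcm$by_treatment, by = c("organ", "analyte", "treatment"))
  expect_equal(merged$fc.x, merged$fc.y)
  # sample-mean grand basis differs in general under unequal weighting
  sub <- dplyr::filter(tab, !(treatment == "0:100" & replicate > 2))
  a <- log2fc_matrix(sub)$grand_means
  b <- log2fc_matrix(sub, grand_mean = "samples")$grand_means
  expect_false(isTRUE(all.equal(a$grand_mean, b$grand_mean)))
})

test_that("zero rows warn and propagate missing cells", {
  tab <- toy_table()
  tab$concentration[tab$analyte == "Glu"] <- 0
  expect_warning(fcm <- log2fc_matrix(tab), "zero grand mean")
  glu <- dplyr::filter(fcm$by_treatment, analyte == "Glu")
  expect_true(all(is.na(glu$log2fc)))
  expect_equal(nrow(glu), 2L)
})

test_that("content conversion is the concentration-mass product", {
  expect_equal(content_from_concentration(30, 2), 60)
  expect_equal(content_from_concentration(30, 0), 0)
  conc <- c(1.5, 20); mass <- c(0.4, 2.2)
  expect_equal(content_from_concentration(conc, mass) / mass, conc)
  expect_error(content_from_concentration(-1, 2),
               class = "ninflux_domain_error")
})
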