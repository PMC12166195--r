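test_that("mono fit recovers a noise-free Michaelis-Menten law", {
  d <- mono_data(V = 2.02, Km = 0.31)
  f <- fit_single_mm(d)
  expect_true(f$converged)
  expect_lt(rel_err(f$params$V, 2.02), 1e-6)
  expect_lt(rel_err(f$params$Km, 0.31), 1e-6)
  expect_lt(f$sse, 1e-12)
})

test_that("mono fit handles the saturated limit", {
  # rates constant at V for S >> Km: Km estimate collapses toward 0
  d <- tibble::tibble(S_mM = rep(c(50, 100, 500, 1000), each = 2),
                      v_umol_per_gDW_h = 3)
  f <- fit_single_mm(d)
  expect_lt(f$params$Km, 1e-3)
  expect_lt(rel_err(f$params$V, 3), 1e-4)
})

test_that("mono fit rejects degenerate and insufficient data", {
  expect_error(
    fit_single_mm(tibble::tibble(S_mM = c(1, 2, 3),
                                 v_umol_per_gDW_h = 0)),
    class = "ninflux_degenerate_data_error")
  expect_error(
    fit_single_mm(tibble::tibble(S_mM = c(1, 1, 2),
                                 v_umol_per_gDW_h = c(1, 1, 2))),
    class = "ninflux_insufficient_data_error")
})

test_that("two-stage fit recovers both printed parameter sets from noise-free data", {
  for (truth in list(amm_params(), nit_params())) {
    d <- simulate_influx(truth, noise = noise_model("none"))
    f <- fit_two_stage(d)
    expect_true(f$converged)
    expect_lt(rel_err(f$params$V1, truth$V1), 1e-3)
    expect_lt(rel_err(f$params$Km1, truth$Km1), 1e-3)
    expect_lt(rel_err(f$params$V2, truth$V2), 1e-3)
    expect_lt(rel_err(f$params$Km2, truth$Km2), 1e-3)
    expect_identical(f$params$T, truth$T)
    # mono fit on biphasic data is strictly worse
    m <- fit_single_mm(d)
    expect_gt(m$sse, f$sse)
  }
})

test_that("threshold profile covers the default candidate set and ties break low", {
  d <- simulate_influx(nit_params(), noise = noise_model("none"))
  f <- fit_two_stage(d)
  expect_equal(f$t_profile$T, default_t_candidates(d$S_mM))
  expect_equal(nrow(f$t_profile), 13 + 12)
  expect_true(all(is.finite(f$t_profile$sse)))
  # the reported T attains the profile minimum
  expect_lte(f$sse, min(f$t_profile$sse) * (1 + 1e-9) + 1e-10)
})

test_that("purely single-phase data drives the second phase to its floor", {
  d <- mono_data(V = 2.02, Km = 0.31)
  f <- fit_two_stage(d, t_candidates = c(default_t_candidates(d$S_mM), 11))
  m <- fit_single_mm(d)
  # two-stage emulates mono: SSE no worse, second phase negligible
  expect_lte(f$sse, m$sse + 1e-9)
  extra <- two_stage_rate(f$params, 10) - mm_rate(m$params, 10)
  expect_lt(abs(extra), 1e-3 * mm_rate(m$params, 10))
})

test_that("two-stage fit rejects unfittable datasets", {
  expect_error(
    fit_two_stage(tibble::tibble(S_mM = c(0.1, 0.2, 0.5, 1),
                                 v_umol_per_gDW_h = 1:4)),
    class = "ninflux_insufficient_data_error")
  d <- simulate_influx(nit_params(), noise = noise_model("none"))
  expect_error(fit_two_stage(d, t_candidates = 0.001),
               class = "ninflux_insufficient_data_error")
  expect_error(fit_two_stage(d, t_candidates = -2),
               class = "ninflux_config_error")
  expect_error(
    fit_two_stage(dplyr::mutate(d, v_umol_per_gDW_h = 0)),
    class = "ninflux_degenerate_data_error")
})

test_that("optimizer dominates the generating parameters on noisy data", {
  for (s in 1:5) {
    truth <- nit_params()
    d <- simulate_influx(truth, noise = noise_model(cv_or_sigma = 0.05),
                         seed = 40 + s)
    f <- fit_two_stage(d)
    sse_truth <- sum((d$v_umol_per_gDW_h -
                        two_stage_rate(truth, d$S_mM))^2)
    expect_lte(f$sse, sse_truth * (1 + 1e-9))
  }
})

test_that("profiled fit agrees with the brute-force grid oracle", {
  truth <- nit_params()
  d <- simulate_influx(truth, assay_design(replicates = 2),
                       noise = noise_model("none"))
  grids <- list(
    V1 = truth$V1 * c(0.9, 0.95, 1, 1.05, 1.1),
    Km1 = truth$Km1 * c(0.9, 0.95, 1, 1.05, 1.1),
    V2 = truth$V2 * c(0.9, 0.95, 1, 1.05, 1.1),
    Km2 = truth$Km2 * c(0.9, 0.95, 1, 1.05, 1.1),
    T = c(1, 1.5, 2, 2.5, 3)
  )
  bf <- brute_force_fit(d, grids)
  # grid contains the exact generating parameters -> SSE 0 there
  expect_lt(bf$sse, 1e-18)
  expect_equal(unlist(bf$params), unlist(truth))
  f <- fit_two_stage(d)
  expect_lte(f$sse, bf$sse + 1e-9)
  # same argmin cell: profiled estimates land on the oracle's best cell
  expect_lt(rel_err(f$params$V1, bf$params$V1), 0.025)
  expect_lt(rel_err(f$params$Km2, bf$params$Km2), 0.025)
})

test_that("brute force refuses oversized grids and beats nothing off-grid", {
  d <- simulate_influx(nit_params(), assay_design(replicates = 1),
                       noise = noise_model("none"))
  expect_error(
    brute_force_fit(d, list(V1 = 1:100, Km1 = 1:100, V2 = 1:100,
                            Km2 = 1:10, T = 1:10)),
    class = "ninflux_config_error")
  off <- brute_force_fit(d, list(V1 = c(1, 3), Km1 = c(0.1, 0.5),
                                 V2 = c(10, 20), Km2 = c(1, 3),
                                 T = c(1, 3)))
  expect_gt(off$sse, 0)
})

test_that("ammonium ridge: V2/Km2 slope is recovered even when the pair is not", {
  truth <- amm_params()
  for (s in 1:3) {
    d <- simulate_influx(truth, noise = noise_model(cv_or_sigma = 0.02),
                         seed = 60 + s)
    f <- fit_two_stage(d)
    expect_lt(rel_err(f$params$V2 / f$params$Km2, truth$V2 / truth$Km2),
              0.05)
  }
})

test_that("nesting: two-stage SSE never exceeds mono SSE when T can leave the grid", {
  for (s in 1:3) {
    d <- simulate_influx(nit_params(),
                         noise = noise_model(cv_or_sigma = 0.08),
                         seed = 70 + s)
    m <- fit_single_mm(d)
    f <- fit_two_stage(
      d, t_candidates = c(default_t_candidates(d$S_mM), max(d$S_mM) + 1))
    expect_lte(f$sse, m$sse * (1 + 1e-9))
  }
})

test_that("tidy and glance expose estimates and fit summaries", {
  d <- simulate_influx(nit_params(), noise = noise_model("none"))
  f <- fit_two_stage(d)
  td <- tidy(f)
  expect_equal(td$term, c("V1", "Km1", "V2", "Km2", "T"))
  expect_true(all(is.na(td$conf.low)))
  g <- glance(f)
  expect_equal(g$model, "two_stage")
  expect_equal(g$n_obs, 52L)
  expect_true(g$converged)
})

test_that("fit JSON serialisation carries model, params and profile", {
  d <- simulate_influx(nit_params(), noise = noise_model("none"))
  f <- fit_two_stage(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$model, "two_stage")
  expect_equal(x$params$V1, f$params$V1)
  expect_equal(nrow(x$t_profile), nrow(f$t_profile))
  expect_equal(x$n_obs, 52L)
})
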