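test_that("cohort sampling respects bounds and the seed", {
  b <- parameter_bounds()
  ch <- sample_cohort(1000, seed = 5)
  for (j in sample(nrow(b), 12)) {
    v <- ch[[b$name[j]]]
    expect_true(all(v >= b$lb[j] & v <= b$ub[j]))
  }
  expect_identical(ch, sample_cohort(1000, seed = 5))
  expect_false(identical(ch$kg_FLS_Baseline,
                         sample_cohort(1000, seed = 6)$kg_FLS_Baseline))
})

test_that("log-uniform draws fill each range", {
  b <- parameter_bounds()[c(1, 40, 100), ]
  ch <- sample_cohort(50000, seed = 9, bounds = b)
  for (j in seq_len(nrow(b))) {
    lv <- log(ch[[b$name[j]]])
    span <- log(b$ub[j]) - log(b$lb[j])
    expect_lt((lv[which.min(lv)] - log(b$lb[j])) / span, 0.01)
    expect_lt((log(b$ub[j]) - max(lv)) / span, 0.01)
    # uniformity in log space: interior quartiles near 0.25/0.5/0.75
    q <- (quantile(lv, c(.25, .5, .75)) - log(b$lb[j])) / span
    expect_equal(unname(q), c(.25, .5, .75), tolerance = 0.02)
  }
})

test_that("plausibility filtering applies cell ranges and the score gate", {
  cols <- parameter_bounds()$name
  ref_row <- tibble::as_tibble(as.list(ra_ref$params[cols]))
  # reference: plausible; Th17-starved variant: excluded on cell range
  starved <- ref_row
  starved$kg_Th17_Baseline <- 1e-6
  starved$kIn_Th17_Baseline <- 1e-6
  cohort <- dplyr::bind_cols(tibble::tibble(id = c("ok", "starved")),
                             dplyr::bind_rows(ref_row, starved))
  pop <- filter_plausible(cohort, ra_net, ra_ref)
  expect_true(pop$plausible[1])
  expect_false(pop$plausible[2])
  expect_match(pop$exclusion_reason[2], "cell density")
  # the score gate: same states, higher threshold
  pop2 <- filter_plausible(cohort[1, ], ra_net, ra_ref, min_das = 9.9)
  expect_false(pop2$plausible[1])
  expect_match(pop2$exclusion_reason[1], "DAS28")
})

test_that("zero-dose trials leave scores unchanged and filters compose", {
  cols <- parameter_bounds()$name
  cohort <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("p%d", 1:3)),
    dplyr::bind_rows(tibble::as_tibble(as.list(ra_ref$params[cols])),
                     tibble::as_tibble(as.list(ra_ref$params[cols] * 1.0)),
                     tibble::as_tibble(as.list(ra_ref$params[cols]))))
  pop <- filter_plausible(cohort, ra_net, ra_ref)
  null_prot <- mtx_protocol(dose = 0, readout_week = 2)
  pop0 <- run_trial(pop, ra_net, null_prot, ra_ref)
  expect_true(all(abs(pop0$mtx_pct_reduction[pop0$plausible]) < 1e-4))
  # a real MTX run, then TCZ restricted to its inadequate responders
  pop1 <- run_trial(pop, ra_net, mtx_protocol(readout_week = 2), ra_ref)
  n_ir <- sum(pop1$mtx_ir[pop1$plausible])
  if (n_ir > 0) {
    pop2 <- run_trial(pop1, ra_net,
                      tcz_protocol(readout_week = 2, entry = "mtx_ir"),
                      ra_ref)
    expect_equal(sum(!is.na(pop2$tcz_pct_reduction)), n_ir)
  }
  expect_error(run_trial(pop1[!pop1$plausible, ], ra_net, mtx_protocol(),
                         ra_ref), "no patients")
})

test_that("placebo correction follows the independence model", {
  expect_equal(placebo_correct(0.46, 0.26), (0.46 - 0.26) / (1 - 0.26))
  expect_equal(round(placebo_correct(0.46, 0.26), 4), 0.2703)
  expect_equal(placebo_correct(0.3, 0), 0.3)
  expect_equal(placebo_correct(0.3, 0.3), 0)
  expect_error(placebo_correct(0.5, 1), "undefined")
  expect_warning(out <- placebo_correct(0.2, 0.4), "clipping")
  expect_equal(out, 0)
  # bounds: 0 <= corrected <= observed whenever observed >= placebo
  set.seed(3)
  obs <- runif(100)
  plc <- runif(100) * obs
  cor <- placebo_correct(obs, plc)
  expect_true(all(cor >= 0 & cor <= obs + 1e-12))
})

test_that("calibration targets reproduce the published arm arithmetic", {
  tg <- calibration_targets()
  e <- tg$endpoints
  expect_equal(e$target[e$trial == "MTX" & e$endpoint == "acr20"],
               (0.46 - 0.26) / (1 - 0.26), tolerance = 1e-12)
  expect_equal(e$target[e$trial == "ADA" & e$endpoint == "acr50"],
               (0.52 - 0.34) / (1 - 0.34), tolerance = 1e-12)
  expect_equal(tg$baseline$das_baseline_mean[tg$baseline$trial == "ADA"], 6.0)
  expect_equal(tg$baseline$das_baseline_mean[tg$baseline$trial == "TCZ"],
               6.53)
  expect_true(all(e$target >= 0 & e$target <= 1))
})

test_that("the selector matches targets it can reach and recovers planted truth", {
  ph <- list(
    list(das_mean = 5.4, das_sd = 0.6, mtx_acr20 = 0.85, mtx_acr50 = 0.5),
    list(das_mean = 6.6, das_sd = 0.6, mtx_acr20 = 0.05, mtx_acr50 = 0))
  pop <- make_synthetic_selector_cohort(3000, c(0.4, 0.6), ph, seed = 2)
  # plant: 30% of a mixed population responding at ACR20
  targets <- list(
    baseline = tibble::tibble(trial = "MTX", das_baseline_mean = 6.0,
                              das_baseline_sd = 0.8, tol = 0.3),
    endpoints = tibble::tibble(trial = "MTX",
                               endpoint = c("acr20", "acr50"),
                               target = c(0.30, 0.16), tol = 0.05))
  class(targets) <- "calibration_targets"
  sel <- select_vpop(pop, targets, n_select = 300, seed = 8, n_iter = 3000)
  res <- tidy(sel)
  expect_true(attr(sel, "selection")$converged)
  expect_true(all(abs(res$residual) <= res$tol))
  # recovered mixing fraction consistent with the planted response rates:
  # w * 0.85 + (1 - w) * 0.05 = 0.30 gives w = 0.3125
  w <- mean(sel$phenotype[sel$selected] == 1)
  expect_lt(abs(w - 0.3125), 0.05)
})

test_that("enrichment shrinks to clones and respects global bounds", {
  ch <- sample_cohort(3, seed = 14)
  cols <- parameter_bounds()$name
  tiny <- enrich_cohort(ch, ch$id[2], shrink_factor = 1e-9, n_new = 4,
                        seed = 15)
  for (cl in sample(cols, 10))
    expect_equal(tiny[[cl]], rep(ch[[cl]][2], 4), tolerance = 1e-6)
  wide <- enrich_cohort(ch, ch$id, shrink_factor = 0.9, n_new = 50,
                        seed = 16)
  b <- parameter_bounds()
  for (j in sample(nrow(b), 10)) {
    v <- wide[[b$name[j]]]
    expect_true(all(v >= b$lb[j] - 1e-12 & v <= b$ub[j] + 1e-12))
  }
  expect_error(enrich_cohort(ch, "nope", 0.5, 2, 1), "unknown ids")
})

test_that("enrichment concentrates sampling near its seed", {
  # constructed landscape: 'plausible' means staying within a half-decade
  # of the seed in every coordinate; global sampling almost never does
  ch <- sample_cohort(400, seed = 17)
  b <- parameter_bounds()
  seed_row <- ch[1, ]
  inside <- function(tb) {
    ok <- rep(TRUE, nrow(tb))
    for (nm in b$name) {
      ok <- ok & abs(log10(tb[[nm]] / seed_row[[nm]])) < 0.5
    }
    mean(ok)
  }
  enr <- enrich_cohort(ch, ch$id[1], shrink_factor = 0.1, n_new = 200,
                       seed = 18)
  expect_gt(inside(enr), 0.5)
  expect_lt(inside(ch[-1, ]), 0.01)
})
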