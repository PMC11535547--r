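make_state <- function(cells) {
  synovium_state(cells, setNames(rep(1, length(rasim:::RA_MEDIATORS)),
                                 rasim:::RA_MEDIATORS))
}

zero_state <- setNames(rep(0, 9), rasim:::RA_CELLS)

test_that("the score vanishes at zero densities and saturates at 10", {
  sp <- score_parameters()
  expect_equal(das28(make_state(zero_state)), 0)
  sup <- sum(sp$coefficients[sp$coefficients > 0])
  expect_equal(sup, 10)
  hot <- setNames(rep(1e14, 9), rasim:::RA_CELLS)
  hot[["Treg"]] <- 0
  expect_equal(das28(make_state(hot)), sup, tolerance = 1e-6)
})

test_that("densities at the half-max points give 4.75 with the Treg Hill", {
  sp <- score_parameters()
  at_km <- sp$km[rasim:::RA_CELLS]
  expect_equal(das28(make_state(at_km)), 10 * 0.5 - 0.5 * 0.5)
  # the literal raw-density reading drops the Treg Hill transform
  sp_raw <- score_parameters(treg_hill = FALSE)
  raw <- das28(make_state(at_km), sp_raw)
  expect_equal(raw, 5 - 0.5 * at_km[["Treg"]])
})

test_that("the score is monotone in each cell density", {
  set.seed(7)
  sp <- score_parameters()
  base <- setNames(10^runif(9, 4, 8), rasim:::RA_CELLS)
  s0 <- das28(make_state(base), sp)
  for (cl in rasim:::RA_CELLS) {
    up <- base
    up[[cl]] <- up[[cl]] * 3
    s1 <- das28(make_state(up), sp)
    if (cl == "Treg") expect_lt(s1, s0) else expect_gt(s1, s0)
  }
})

test_that("the score is bounded in (-0.5, 10) for arbitrary states", {
  set.seed(11)
  for (k in 1:50) {
    dens <- setNames(10^runif(9, 0, 12), rasim:::RA_CELLS)
    s <- das28(make_state(dens))
    expect_gt(s, -0.5)
    expect_lt(s, 10)
  }
})

test_that("response categories follow percent reduction with nesting", {
  o <- acr_category(6.0, 4.5)
  expect_equal(o$pct_reduction, 25)
  expect_true(o$acr20)
  expect_false(o$acr50)
  o0 <- acr_category(6.0, 6.0)
  expect_equal(o0$pct_reduction, 0)
  expect_false(o0$acr20)
  o70 <- acr_category(6.0, 1.5)
  expect_equal(o70$pct_reduction, 75)
  expect_true(all(o70$acr20, o70$acr50, o70$acr70, o70$das_lt_2_6,
                  o70$das_lt_3_2, o70$delta_gt_1_2))
  expect_error(acr_category(0, 1), "positive")
  # nesting holds for arbitrary score pairs
  set.seed(5)
  pairs <- acr_category(runif(200, 0.1, 10), runif(200, 0, 10))
  expect_true(all(!pairs$acr70 | pairs$acr50))
  expect_true(all(!pairs$acr50 | pairs$acr20))
})

test_that("inadequate response requires both failed reduction and high score", {
  ir <- classify_ir(acr_category(6, 6 * (1 - 0.30))) # 30% reduction, post 4.2
  expect_true(ir)
  expect_false(classify_ir(acr_category(5, 2)))      # 60% reduction
  expect_false(classify_ir(acr_category(4.2, 3.0)))  # 29% but post < 3.2
})
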