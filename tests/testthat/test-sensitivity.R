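test_that("local sensitivity is signed, sorted, and null for severed paths", {
  pars <- c("kg_FLS_Baseline", "kg_Macrophage_Baseline",
            "MacroInflux_MaxbyMCP1")
  # sever the only edge through which MCP-1 reaches a scored cell
  pat <- virtual_patient(setNames(0, "MacroInflux_MaxbyMCP1"),
                         base = ra_ref, id = "severed")
  ls <- local_sensitivity(ra_net, pat,
                          parameter_names = c(pars, "F_MCP1"))
  expect_s3_class(ls, "local_sensitivity")
  row <- ls[ls$parameter == "F_MCP1", ]
  expect_lt(abs(row$pct_change_up), 1e-8)
  expect_lt(abs(row$pct_change_down), 1e-8)
  # a baseline proliferation rate of a scored cell moves the score the
  # expected way, and opposite perturbations have opposite signs
  fls <- ls[ls$parameter == "kg_FLS_Baseline", ]
  expect_gt(fls$pct_change_up, 0)
  expect_lt(fls$pct_change_down, 0)
  # sorted by the larger absolute effect
  worst <- pmax(abs(ls$pct_change_up), abs(ls$pct_change_down))
  expect_true(all(diff(worst) <= 1e-12))
})

test_that("raising a pro-inflammatory secretion baseline never lowers the score", {
  ls <- local_sensitivity(ra_net, ra_ref,
                          parameter_names = rasim:::ksec_name("TNFa",
                                                              "Macrophage"))
  expect_gte(ls$pct_change_up[1], 0)
})

test_that("Sobol estimates match the additive analytic decomposition", {
  a <- c(4, 2, 1)
  fn <- function(m) m %*% a
  res <- sobol_indices(fn, lower = c(x1 = 0, x2 = 0, x3 = 0),
                       upper = c(x1 = 1, x2 = 1, x3 = 1),
                       n = 4096, seed = 10)
  truth <- a^2 / sum(a^2)
  expect_lt(max(abs(res$first_order - truth)), 0.03)
  expect_lt(max(abs(res$total_order - truth)), 0.03)
  expect_lte(sum(res$first_order), 1.05)
})

test_that("Sobol estimates reproduce the Ishigami decomposition", {
  a <- 7; b <- 0.1
  fn <- function(m) sin(m[, 1]) + a * sin(m[, 2])^2 +
    b * m[, 3]^4 * sin(m[, 1])
  res <- sobol_indices(fn, lower = rep(-pi, 3), upper = rep(pi, 3),
                       n = 8192, seed = 2)
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  v <- v1 + v2 + v13
  expect_lt(max(abs(res$first_order - c(v1 / v, v2 / v, 0))), 0.05)
  expect_lt(max(abs(res$total_order -
                      c((v1 + v13) / v, v2 / v, v13 / v))), 0.05)
})

test_that("model Sobol indices are reproducible with total >= first", {
  b <- parameter_bounds()
  sub <- b[b$name %in% c("kg_FLS_Baseline", "kg_Macrophage_Baseline",
                         "F_TNFa", "F_IL6", "LeukoInflux_MaxbyCAM"), ]
  res <- sobol_analysis(ra_net, sub, n = 48, seed = 6, base = ra_ref)
  res2 <- sobol_analysis(ra_net, sub, n = 48, seed = 6, base = ra_ref)
  expect_equal(res$first_order, res2$first_order)
  expect_true(all(res$total_order >= res$first_order -
                    (res$first_ci + res$total_ci)))
  expect_lte(sum(res$first_order), 1 + sum(res$first_ci) + 0.15)
})

test_that("a frozen parameter has exactly zero Sobol indices", {
  b <- parameter_bounds()
  sub <- b[b$name %in% c("kg_FLS_Baseline", "F_TNFa", "F_IL6"), ]
  sub$ub[sub$name == "F_IL6"] <- sub$lb[sub$name == "F_IL6"]
  res <- sobol_analysis(ra_net, sub, n = 16, seed = 3, base = ra_ref)
  frozen <- res[res$parameter == "F_IL6", ]
  expect_identical(frozen$first_order, 0)
  expect_identical(frozen$total_order, 0)
})
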