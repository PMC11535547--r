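test_that("hill is half-maximal at km, zero at zero, bounded by vm", {
  for (slope in c(0.5, 1, 2.5, 4)) {
    expect_equal(hill(2, vm = 3, km = 2, slope = slope), 1.5)
  }
  expect_equal(hill(0, vm = 3, km = 2, slope = 1.7), 0)
  # near-saturation: direct evaluation of vm * c / (c + km) at c = 1e6 km
  expect_equal(hill(1e6 * 0.4, vm = 3, km = 0.4, slope = 1), 2.999997,
               tolerance = 1e-9)
  conc <- sort(runif(50, 0, 100))
  h <- hill(conc, vm = 2, km = 5, slope = 1.3)
  expect_true(all(diff(h) >= 0))
  expect_true(all(h < 2))
  expect_error(hill(-1, 1, 1, 1), "non-negative")
})

test_that("aggregated effects cap the sum, not the terms", {
  conc <- c(TNFa = 10, IL6 = 10, IL1b = 10)
  # three pro edges whose contributions sum to 50 at these concentrations
  pro <- lapply(c(20, 20, 10), function(vm)
    regulatory_edge("TNFa", "prolif:FLS", "pro", vm_effect = 2 * vm,
                    km_effect = 10, slope_effect = 1))
  agg <- aggregate_effects(pro, conc)
  expect_equal(sum(agg$contributions), 50)
  expect_equal(agg$pro_rate, 10)
  # two anti edges summing to 2.0 cap at 0.75
  anti <- lapply(c(1.2, 0.8), function(vm)
    regulatory_edge("IL6", "prolif:FLS", "anti", vm_effect = 2 * vm,
                    km_effect = 10, slope_effect = 1))
  agg2 <- aggregate_effects(anti, conc)
  expect_equal(sum(agg2$contributions), 2)
  expect_equal(agg2$anti_rate, 0.75)
  # neutral element
  agg0 <- aggregate_effects(list(), conc)
  expect_equal(agg0$pro_rate, 0)
  expect_equal(agg0$anti_rate, 0)
  expect_equal(rate_factor(agg0), 1)
})

test_that("rate factor reproduces the capped arithmetic", {
  expect_identical(rate_factor(list(pro_rate = 10, anti_rate = 0)), 11)
  expect_equal(rate_factor(list(pro_rate = 0, anti_rate = 0.9)), 0.1)
  expect_identical(rate_factor(list(pro_rate = 0, anti_rate = 0)), 1)
  # a 0.9 anti cap must be configured explicitly; the default is 0.75
  pol <- cap_policy(anti_limit = 0.9)
  agg <- aggregate_effects(
    list(regulatory_edge("IL10", "x", "anti", 100, 1, 1)),
    c(IL10 = 1e6), pol)
  expect_equal(rate_factor(agg), 0.1, tolerance = 1e-4)
  expect_error(cap_policy(anti_limit = 1.2))
})

test_that("aggregation matches a symbolic hand evaluation", {
  conc <- c(TNFa = 0.7, IL6 = 31, IL10 = 0.04)
  e1 <- regulatory_edge("TNFa", "p", "pro", 2.2, 0.63, 1)
  e2 <- regulatory_edge("IL6", "p", "pro", 1.1, 400, 2)
  e3 <- regulatory_edge("IL10", "p", "anti", 0.9, 1.0, 1)
  by_hand_pro <- 2.2 * 0.7 / (0.7 + 0.63) +
    1.1 * 31^2 / (31^2 + 400^2)
  by_hand_anti <- 0.9 * 0.04 / (0.04 + 1)
  agg <- aggregate_effects(list(e1, e2, e3), conc)
  expect_equal(agg$pro_rate, by_hand_pro, tolerance = 1e-12)
  expect_equal(agg$anti_rate, by_hand_anti, tolerance = 1e-12)
})

test_that("edge order does not change the result bit-for-bit", {
  conc <- c(TNFa = 0.7, IL6 = 31, IL1b = 2, IL17 = 0.01)
  edges <- list(
    regulatory_edge("TNFa", "p", "pro", 2.2, 0.63, 1),
    regulatory_edge("IL6", "p", "pro", 1.1, 400, 2),
    regulatory_edge("IL1b", "p", "pro", 0.33, 1.0, 1.5),
    regulatory_edge("IL17", "p", "anti", 0.4, 0.004, 1))
  ref <- aggregate_effects(edges, conc)
  for (k in 1:5) {
    perm <- aggregate_effects(sample(edges), conc)
    expect_identical(perm$pro_rate, ref$pro_rate)
    expect_identical(perm$anti_rate, ref$anti_rate)
  }
})

test_that("rate factors stay inside the cap envelope for random edge sets", {
  set.seed(42)
  for (k in 1:30) {
    n <- sample(1:6, 1)
    edges <- lapply(seq_len(n), function(i)
      regulatory_edge(sample(c("TNFa", "IL6", "IL10"), 1), "p",
                      sample(c("pro", "anti"), 1),
                      vm_effect = runif(1, 0.1, 30),
                      km_effect = runif(1, 0.01, 10),
                      slope_effect = runif(1, 0.5, 3)))
    conc <- c(TNFa = runif(1, 0, 50), IL6 = runif(1, 0, 50),
              IL10 = runif(1, 0, 50))
    f <- rate_factor(aggregate_effects(edges, conc))
    expect_gte(f, 1 - 0.75)
    expect_lte(f, 1 + 10)
  }
})

test_that("aggregate effects are monotone in each regulator concentration", {
  edges <- list(
    regulatory_edge("TNFa", "p", "pro", 2.2, 0.63, 1),
    regulatory_edge("IL6", "p", "pro", 1.1, 400, 2),
    regulatory_edge("IL10", "p", "anti", 0.9, 1.0, 1))
  grid <- seq(0, 100, length.out = 21)
  pro <- sapply(grid, function(x)
    aggregate_effects(edges, c(TNFa = x, IL6 = 3, IL10 = 1))$pro_rate)
  anti <- sapply(grid, function(x)
    aggregate_effects(edges, c(TNFa = 1, IL6 = 3, IL10 = x))$anti_rate)
  expect_true(all(diff(pro) >= 0))
  expect_true(all(diff(anti) >= 0))
})

test_that("essential gating zeroes a rate without its mediator", {
  expect_equal(essential_gate(7, 0, km_gate = 0.01), 0)
  expect_equal(essential_gate(7, 1e9, km_gate = 0.01), 7, tolerance = 1e-8)
  expect_equal(essential_gate(7, 0.01, km_gate = 0.01, slope = 1), 3.5)
})
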