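test_that("decoupled rates reduce to the linear balance equations", {
  net <- decoupled_network()
  ov <- ra_ref$params * 0
  ov[rasim:::kg_name("FLS")] <- 100
  ov[rasim:::kdeg_name(rasim:::RA_CELLS)] <- 0.1
  ov[rasim:::clr_name(rasim:::RA_MEDIATORS)] <- 1
  ov[rasim:::f_name(rasim:::RA_MEDIATORS)] <- 1
  ov[rasim:::ksec_name("IL6", "FLS")] <- 1e-6
  pat <- virtual_patient(ov, base = ra_ref, id = "toy")
  dens <- setNames(rep(0, 9), rasim:::RA_CELLS)
  dens[["FLS"]] <- 500
  conc <- setNames(rep(0, 17), rasim:::RA_MEDIATORS)
  conc[["IL6"]] <- 0.5
  rhs <- build_rhs(net, pat)
  dy <- rhs(0, synovium_state(dens, conc))
  # cell: prolif 100 - deg 0.1 * 500 = +50
  expect_equal(dy[["FLS"]], 100 - 0.1 * 500)
  # mediator: 1e6 cells/mL would secrete 1 ng/mL/day; here 500 cells
  expect_equal(dy[["IL6"]], 1e-6 * 500 - 1 * 0.5)
})

test_that("decoupled steady states match the closed forms", {
  net <- decoupled_network()
  ref <- reference_patient(net)
  ss <- solve_steady_state(net, ref, method = "fixed")
  expect_true(ss$converged)
  p <- ref$params
  for (cl in setdiff(rasim:::RA_CELLS, "PlasmaCell")) {
    expected <- (p[[rasim:::kg_name(cl)]] + p[[rasim:::kin_name(cl)]]) /
      p[[rasim:::kdeg_name(cl)]]
    if (cl == "BCell")
      expected <- (p[[rasim:::kg_name(cl)]] + p[[rasim:::kin_name(cl)]]) /
        (p[[rasim:::kdeg_name(cl)]] + p[["kdiff_BCells_PlasmaCells"]])
    expect_equal(ss$state$cell_density[[cl]], expected, tolerance = 1e-6)
  }
  # doubling a degradation rate halves the decoupled steady density
  pat2 <- virtual_patient(
    setNames(2 * p[[rasim:::kdeg_name("FLS")]], rasim:::kdeg_name("FLS")),
    base = ref, id = "double-deg")
  ss2 <- solve_steady_state(net, pat2, method = "fixed")
  expect_equal(ss2$state$cell_density[["FLS"]],
               ss$state$cell_density[["FLS"]] / 2, tolerance = 1e-6)
})

test_that("the compiled right-hand side matches the regulation-primitive oracle", {
  set.seed(31)
  rhs <- build_rhs(ra_net, ra_ref)
  for (k in 1:5) {
    dens <- setNames(10^runif(9, 4, 8.5), rasim:::RA_CELLS)
    conc <- setNames(10^runif(17, -4, 3), rasim:::RA_MEDIATORS)
    st <- synovium_state(dens, conc)
    expect_equal(rhs(0, st), oracle_rhs(ra_net, ra_ref, st),
                 tolerance = 1e-10)
  }
})

test_that("the reference patient sits at the literature midpoints", {
  ss <- solve_steady_state(ra_net, ra_ref, method = "fixed")
  expect_true(ss$converged)
  expect_lt(ss$residual_norm, 1e-6)
  rng <- cell_density_ranges()
  for (i in seq_len(nrow(rng))) {
    d <- ss$state$cell_density[[rng$cell[i]]]
    expect_gt(d, rng$lb[i])
    expect_lt(d, rng$ub[i])
  }
  mrng <- mediator_conc_ranges()
  for (i in seq_len(nrow(mrng))) {
    m <- ss$state$mediator_conc[[mrng$mediator[i]]]
    expect_gt(m, mrng$lb[i])
    expect_lt(m, mrng$ub[i])
  }
  expect_equal(unname(ss$state$cell_density),
               unname(rasim:::reference_cell_targets()), tolerance = 1e-8)
  # the integration route agrees with the fixed-point route
  ss_ode <- solve_steady_state(ra_net, ra_ref, method = "ode", t_max = 400)
  expect_equal(ss_ode$state$cell_density, ss$state$cell_density,
               tolerance = 1e-4)
})

test_that("steady states are fixed points of the therapy-free dynamics", {
  set.seed(13)
  cohort <- sample_cohort(60, seed = 13)
  pop <- filter_plausible(cohort, ra_net, ra_ref)
  idx <- which(pop$converged)
  idx <- idx[seq_len(min(20, length(idx)))]
  for (i in idx) {
    pat <- rasim:::patient_from_row(pop, i, ra_ref)
    ss <- solve_steady_state(ra_net, pat, method = "fixed")
    if (!ss$converged) next
    tc <- simulate_timecourse(ra_net, pat, ss$state, duration = 180,
                              sample_times = c(0, 180))
    drift <- abs(as.numeric(tc[tc$time == 180, -1]) /
                   rasim:::state_to_vec(ss$state) - 1)
    expect_lt(max(drift), 1e-5)
    # the unfloored trajectory never goes (materially) negative
    expect_gte(min(as.numeric(as.matrix(tc[-1]))), 0)
  }
})

test_that("zero dose reproduces the therapy-free trajectory", {
  ss <- solve_steady_state(ra_net, ra_ref, method = "fixed")
  null_dose <- mtx_protocol(dose = 0, readout_week = 4)
  tc0 <- simulate_timecourse(ra_net, ra_ref, ss$state, duration = 28,
                             sample_times = c(0, 28))
  tc1 <- simulate_timecourse(ra_net, ra_ref, ss$state, therapy = null_dose,
                             duration = 28, sample_times = c(0, 28))
  expect_equal(as.data.frame(tc1), as.data.frame(tc0), tolerance = 1e-6)
})

test_that("adalimumab lowers free synovial TNF-alpha at readout", {
  ss <- solve_steady_state(ra_net, ra_ref, method = "fixed")
  prot <- ada_protocol(readout_week = 8)
  tc <- simulate_timecourse(ra_net, ra_ref, ss$state, therapy = prot,
                            sample_times = c(0, 56))
  post <- state_at(tc, 56)
  ada_syn <- simulate_pk(pk_model("ADA"), prot, 56)$synovial * 1000
  free_post <- ada_free_tnf(post$mediator_conc[["TNFa"]], ada_syn,
                            binding_constants()$kd_ada_ng_ml)
  expect_lt(free_post, ss$state$mediator_conc[["TNFa"]])
})

test_that("IFN-gamma secretion by Th1 vanishes without IL-12", {
  # silence the other IFN-gamma secretors, zero IL-12 production
  ov <- c(setNames(0, rasim:::ksec_name("IFNg", "CTL")),
          setNames(0, rasim:::ksec_name("IFNg", "Macrophage")),
          setNames(0, rasim:::f_name("IL12")))
  pat <- virtual_patient(ov, base = ra_ref, id = "gated")
  rhs <- build_rhs(ra_net, pat)
  st <- reference_state()
  st$mediator_conc[["IL12"]] <- 0
  st$mediator_conc[["IFNg"]] <- 0
  dy <- rhs(0, st)
  expect_equal(dy[["IFNg"]], 0)
  # with IL-12 present the same state secretes IFN-gamma
  st$mediator_conc[["IL12"]] <- 1
  expect_gt(rhs(0, st)[["IFNg"]], 0)
})

test_that("unknown parameters and negative rates are rejected", {
  expect_error(virtual_patient(c(nonsense = 1), base = ra_ref), "unknown")
  expect_error(virtual_patient(setNames(-1, rasim:::kg_name("FLS")),
                               base = ra_ref), "non-negative")
  expect_error(virtual_patient(setNames(5, rasim:::kin_name("FLS")),
                               base = ra_ref), "FLS influx")
})
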