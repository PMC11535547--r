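# Assemble the ODE system for one patient and solve it: dynamic time courses
# via deSolve (lsoda) on a compiled right-hand side, steady states via damped
# fixed-point iteration with an ODE-integration fallback.

# Pack network + patient into the flat-array layout the compiled core expects.
build_model <- function(net, patient) {
  p <- patient$params
  cells <- net$cells
  meds <- net$mediators
  sec <- net$secretion
  ed <- net$regulation
  cell_idx <- function(x) match(x, cells) - 1L
  med_idx <- function(x) match(x, meds) - 1L
  sec_key <- paste(sec$mediator, sec$cell)
  e_tk <- dplyr::case_match(ed$process, "prolif" ~ 0L, "influx" ~ 1L,
                            "deg" ~ 2L, "sec" ~ 3L, "diff" ~ 4L)
  e_ti <- ifelse(ed$process == "sec",
                 match(paste(ed$mediator, ed$cell), sec_key) - 1L,
                 ifelse(ed$process == "diff", 0L, cell_idx(ed$cell)))
  list(
    nc = length(cells), nm = length(meds), ns = nrow(sec), ne = nrow(ed),
    kg = as.numeric(p[kg_name(cells)]),
    kin = as.numeric(p[kin_name(cells)]),
    kdeg = as.numeric(p[kdeg_name(cells)]),
    clr = as.numeric(p[clr_name(meds)]),
    Fm = as.numeric(p[f_name(meds)]),
    sec_cell = cell_idx(sec$cell),
    sec_med = med_idx(sec$mediator),
    sec_mtx_mode = ifelse(sec$cell == "Treg", 1L, -1L),
    ksec = as.numeric(p[ksec_name(sec$mediator, sec$cell)]),
    influx_mtx = as.integer(!cells %in% c("FLS", "Endothelial")),
    kdiff = p[["kdiff_BCells_PlasmaCells"]],
    diff_src = cell_idx(net$differentiation$source),
    diff_dst = cell_idx(net$differentiation$target),
    e_tk = e_tk, e_ti = as.integer(e_ti),
    e_reg = med_idx(ed$regulator),
    e_sign = ifelse(ed$sign == "pro", 1L, -1L),
    e_vm = as.numeric(p[ed$param]),
    e_km = ed$km, e_sl = ed$slope,
    es_sec = match(paste(net$essential$secreted, net$essential$cell),
                   sec_key) - 1L,
    es_med = med_idx(net$essential$mediator),
    es_km = net$essential$km_gate, es_sl = net$essential$slope,
    cam_med = med_idx(net$cam$mediator),
    cam_drv = cell_idx(net$cam$driver),
    cam_km = net$cam$km, cam_sl = net$cam$slope,
    cam_level = net$cam$level, cam_krelax = net$cam$k_relax,
    pro_limit = net$policy$pro_limit, anti_limit = net$policy$anti_limit,
    tnfa_idx = med_idx("TNFa"), il6_idx = med_idx("IL6")
  )
}

#' Assemble the derivative function for one patient
#'
#' Returns `f(time, state)` computing, for each cell,
#' proliferation + influx - degradation (zeroth-order baselines scaled by the
#' capped multi-cytokine regulation factors; degradation first-order in
#' density, the B-cell to plasma-cell differentiation flux moving density
#' between the two), and for each mediator the summed regulated secretion
#' minus first-order clearance. When a therapy is supplied its
#' pharmacodynamic effects (methotrexate secretion/influx factors, free
#' TNF-alpha under adalimumab binding, tocilizumab-scaled IL-6 clearance)
#' multiply the designated rates.
#'
#' @param net An [ra_network()].
#' @param patient A [virtual_patient()].
#' @param therapy A [trial_protocol()] or `NULL`.
#' @return Function of `(time, state)` returning the named derivative
#'   vector; `state` may be a `synovium_state` or a named numeric vector.
#' @export
build_rhs <- function(net, patient, therapy = NULL) {
  model <- build_model(net, patient)
  th <- if (inherits(therapy, "trial_protocol")) build_therapy(therapy)
        else therapy
  function(time, state) {
    y <- if (inherits(state, "synovium_state")) state_to_vec(state)
         else state[c(RA_CELLS, RA_MEDIATORS)]
    dy <- rasim_rhs_(time, as.numeric(y), model, th)
    stats::setNames(dy, c(RA_CELLS, RA_MEDIATORS))
  }
}

scaled_residual <- function(dy, y) {
  max(abs(dy) / pmax(abs(y), 1e-12))
}

#' Solve for the dynamic steady state of a patient
#'
#' `method = "ode"` integrates the system from `init` (stiff-capable lsoda)
#' in chunks until the scaled derivative norm `max |dy/dt| / |y|` falls below
#' `tol` or `t_max` is reached. `method = "fixed"` runs a damped fixed-point
#' iteration on the production/removal balance (much faster for cohort-scale
#' work) and verifies the result against the same residual norm, falling
#' back to integration if it fails to converge.
#'
#' @param net An [ra_network()].
#' @param patient A [virtual_patient()].
#' @param init Initial `synovium_state` (defaults to the reference state).
#' @param t_max Maximum integration time, days.
#' @param tol Convergence tolerance on the scaled derivative norm (1/day).
#' @param method `"fixed"` or `"ode"`.
#' @return A `steady_state_result`: `state`, `converged`, `residual_norm`.
#' @export
solve_steady_state <- function(net, patient, init = NULL, t_max = 2000,
                               tol = 1e-6, method = c("fixed", "ode")) {
  method <- match.arg(method)
  stopifnot(t_max > 0)
  if (is.null(init)) init <- reference_state()
  model <- build_model(net, patient)
  y <- state_to_vec(init)

  if (method == "fixed") {
    fp <- rasim_picard_(model, as.numeric(y), NULL, 0, 600L, 1e-12, 0.5)
    if (fp$converged && fp$residual < tol) {
      return(structure(list(state = vec_to_state(fp$state),
                            converged = TRUE,
                            residual_norm = fp$residual),
                       class = "steady_state_result"))
    }
    y <- pmax(as.numeric(fp$state), 0) # warm-start the integrator
  }

  rasim_set_context_(model, NULL)
  atol <- c(rep(1e-3, length(RA_CELLS)), rep(1e-9, length(RA_MEDIATORS)))
  chunk <- t_max / 8
  t0 <- 0
  converged <- FALSE
  resid <- Inf
  for (i in 1:8) {
    out <- deSolve::lsoda(y = as.numeric(y), times = c(t0, t0 + chunk),
                          func = "rasim_derivs_c", parms = NULL,
                          dllname = "rasim",
                          rtol = 1e-8, atol = atol, maxsteps = 200000)
    if (attr(out, "istate")[1] < 0)
      stop("steady-state integration failed for patient `", patient$id, "`",
           call. = FALSE)
    y <- out[nrow(out), -1]
    t0 <- t0 + chunk
    dy <- rasim_rhs_(t0, as.numeric(y), model, NULL)
    resid <- scaled_residual(dy, as.numeric(y))
    if (resid < tol) { converged <- TRUE; break }
  }
  structure(list(state = vec_to_state(pmax(y, 0), time = t0),
                 converged = converged, residual_norm = resid),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result> converged:", x$converged,
      " residual:", format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

#' Simulate a time course, optionally under therapy
#'
#' Integrates the synovium ODEs from `init` over `duration` days. With a
#' protocol supplied, drug exposure follows the closed-form PK under the
#' protocol's dosing schedule and its pharmacodynamic effects act on the
#' designated rates throughout the integration.
#'
#' @param net An [ra_network()].
#' @param patient A [virtual_patient()].
#' @param init Initial `synovium_state`.
#' @param therapy A [trial_protocol()] or `NULL`.
#' @param duration Days to simulate (must cover the protocol readout).
#' @param sample_times Times (days) at which to report the state; defaults
#'   to weekly samples.
#' @param rtol Relative integration tolerance (cohort-scale trial runs relax
#'   this to 1e-6).
#' @return A tibble (`ra_timecourse`): `time` plus one column per species.
#' @export
simulate_timecourse <- function(net, patient, init, therapy = NULL,
                                duration = NULL, sample_times = NULL,
                                rtol = 1e-8) {
  if (inherits(therapy, "trial_protocol") && is.null(duration))
    duration <- therapy$readout_week * 7
  if (is.null(duration)) duration <- 180
  if (inherits(therapy, "trial_protocol") &&
      duration < therapy$readout_week * 7)
    stop("`duration` must cover the protocol readout week", call. = FALSE)
  if (is.null(sample_times)) sample_times <- seq(0, duration, by = 7)
  if (any(sample_times > duration))
    stop("`sample_times` beyond `duration`", call. = FALSE)
  model <- build_model(net, patient)
  th <- if (inherits(therapy, "trial_protocol")) build_therapy(therapy)
        else therapy
  rasim_set_context_(model, th)
  # restart the integrator at dose times: bolus dosing makes the drug
  # forcing discontinuous there
  dose_times <- if (!is.null(th)) th$dose_times else numeric()
  breaks <- sort(unique(c(0, dose_times[dose_times > 0 & dose_times < duration],
                          duration)))
  report <- sort(unique(sample_times))
  atol <- c(rep(1e-3, length(RA_CELLS)), rep(1e-9, length(RA_MEDIATORS)))
  y <- as.numeric(state_to_vec(init))
  kept <- list()
  if (0 %in% report) kept[[1]] <- c(0, y)
  for (s in seq_len(length(breaks) - 1)) {
    tt <- sort(unique(c(breaks[s], report[report > breaks[s] &
                                            report <= breaks[s + 1]],
                        breaks[s + 1])))
    out <- deSolve::lsoda(y = y, times = tt, func = "rasim_derivs_c",
                          parms = NULL, dllname = "rasim",
                          rtol = rtol, atol = atol, maxsteps = 200000)
    if (attr(out, "istate")[1] < 0)
      stop("time-course integration failed for patient `", patient$id, "`",
           call. = FALSE)
    y <- as.numeric(out[nrow(out), -1])
    sel <- out[, 1] %in% report & out[, 1] > breaks[s]
    if (any(sel)) kept[[length(kept) + 1]] <- out[sel, , drop = FALSE]
  }
  res <- tibble::as_tibble(as.data.frame(do.call(rbind, kept)))
  names(res) <- c("time", RA_CELLS, RA_MEDIATORS)
  res <- res[!duplicated(res$time), ]
  res[-1] <- lapply(res[-1], pmax, 0)
  class(res) <- c("ra_timecourse", class(res))
  res
}

#' Extract the synovium state at one sampled time
#'
#' @param timecourse An `ra_timecourse` tibble.
#' @param time A time present in the time course (defaults to the last).
#' @return A `synovium_state`.
#' @export
state_at <- function(timecourse, time = NULL) {
  if (is.null(time)) time <- max(timecourse$time)
  row <- which(timecourse$time == time)
  if (!length(row)) stop("time not sampled in this time course",
                         call. = FALSE)
  y <- as.numeric(timecourse[row[1], c(RA_CELLS, RA_MEDIATORS)])
  vec_to_state(stats::setNames(y, c(RA_CELLS, RA_MEDIATORS)), time = time)
}
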