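# Pharmacokinetics (closed-form linear compartmental models) and
# pharmacodynamics of methotrexate, adalimumab and tocilizumab.

#' Pharmacokinetic model for one of the supported drugs
#'
#' MTX uses a two-compartment model with bolus dosing, ADA a one-compartment
#' model with first-order subcutaneous absorption, TCZ a two-compartment
#' model with intravenous dosing. Parameter values are population estimates
#' from the published PK literature for each drug, shipped as configurable
#' defaults; none of the package's quantitative claims depend on a specific
#' set, and the PK layer is exercised through closed-form invariants
#' (superposition, dose proportionality).
#'
#' @param drug `"MTX"`, `"ADA"` or `"TCZ"`.
#' @param ... Named parameter overrides (`v1`, `v2`, `cl`, `q`, `ka`,
#'   `bioavailability`, `partition`).
#' @return A `pk_model`.
#' @export
pk_model <- function(drug = c("MTX", "ADA", "TCZ"), ...) {
  drug <- match.arg(drug)
  defaults <- switch(drug,
    MTX = list(structure = "2cmt_bolus", v1 = 20, v2 = 15, cl = 132,
               q = 12, ka = NA_real_, bioavailability = 0.7,
               partition = 0.3),
    ADA = list(structure = "1cmt_sc", v1 = 7, v2 = NA_real_, cl = 0.33,
               q = NA_real_, ka = 0.28, bioavailability = 0.64,
               partition = 0.3),
    TCZ = list(structure = "2cmt_iv", v1 = 3.5, v2 = 2.9, cl = 0.3,
               q = 5.2, ka = NA_real_, bioavailability = 1,
               partition = 0.3))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown PK parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(ov)] <- ov
  num <- unlist(defaults[-1])
  if (any(!is.na(num) & num <= 0) ||
      defaults$bioavailability > 1)
    stop("PK parameters must be positive; bioavailability in (0, 1]",
         call. = FALSE)
  structure(c(list(drug = drug), defaults), class = "pk_model")
}

#' Trial protocol
#'
#' @param drug `"MTX"`, `"ADA"`, `"TCZ"` or `"none"`.
#' @param dose Dose per administration; mg, or mg/kg when
#'   `dose_per_kg = TRUE`.
#' @param interval Days between doses.
#' @param n_doses Number of doses; defaults to covering the readout.
#' @param readout_week Week at which outcomes are read.
#' @param route `"oral"`, `"sc"` or `"iv"` (consistency-checked against the
#'   drug's model structure).
#' @param dose_per_kg Interpret `dose` as mg/kg.
#' @param body_weight_kg Body weight used to resolve mg/kg doses.
#' @param entry Entry criterion: `"all"`, `"mtx_ir"` (methotrexate inadequate
#'   responders) or `"mtx_ada_ir"`.
#' @return A `trial_protocol`.
#' @export
trial_protocol <- function(drug, dose, interval, readout_week,
                           n_doses = NULL, route = NULL,
                           dose_per_kg = FALSE, body_weight_kg = 70,
                           entry = c("all", "mtx_ir", "mtx_ada_ir")) {
  entry <- match.arg(entry)
  stopifnot(dose >= 0, interval > 0, readout_week > 0)
  if (is.null(n_doses)) n_doses <- ceiling(readout_week * 7 / interval)
  if (is.null(route))
    route <- switch(drug, MTX = "oral", ADA = "sc", TCZ = "iv", "none")
  dose_mg <- if (dose_per_kg) dose * body_weight_kg else dose
  structure(list(drug = drug, dose_mg = dose_mg, interval = interval,
                 n_doses = n_doses, readout_week = readout_week,
                 route = route, entry = entry),
            class = "trial_protocol")
}

#' @rdname trial_protocol
#' @export
mtx_protocol <- function(dose = 15, readout_week = 12, entry = "all") {
  trial_protocol("MTX", dose, interval = 7, readout_week = readout_week,
                 entry = entry)
}

#' @rdname trial_protocol
#' @export
ada_protocol <- function(dose = 40, readout_week = 24, entry = "all") {
  trial_protocol("ADA", dose, interval = 14, readout_week = readout_week,
                 entry = entry)
}

#' @rdname trial_protocol
#' @export
tcz_protocol <- function(dose = 8, readout_week = 24, entry = "mtx_ir",
                         body_weight_kg = 70) {
  trial_protocol("TCZ", dose, interval = 28, readout_week = readout_week,
                 dose_per_kg = TRUE, body_weight_kg = body_weight_kg,
                 entry = entry)
}

single_dose_conc <- function(model, dose_mg, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tt <- t[pos]
  cc <- switch(model$structure,
    "1cmt_sc" = {
      ke <- model$cl / model$v1
      ka <- model$ka
      if (abs(ka - ke) < 1e-12) ka <- ke * (1 + 1e-9)
      model$bioavailability * dose_mg * ka / (model$v1 * (ka - ke)) *
        (exp(-ke * tt) - exp(-ka * tt))
    },
    {
      # two-compartment bolus/IV: biexponential disposition
      k10 <- model$cl / model$v1
      k12 <- model$q / model$v1
      k21 <- model$q / model$v2
      s <- k10 + k12 + k21
      alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
      beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
      a <- (alpha - k21) / (alpha - beta)
      b <- (k21 - beta) / (alpha - beta)
      dose_mg / model$v1 * (a * exp(-alpha * tt) + b * exp(-beta * tt))
    })
  out[pos] <- cc
  out
}

#' Simulate drug concentrations under a protocol
#'
#' Closed-form solution of the linear compartmental model with repeated
#' dosing by superposition of single-dose profiles. Returns central (mg/L)
#' and synovial (mg/L, quasi-equilibrium partition) concentrations, plus the
#' bioavailability-scaled central concentration used by the methotrexate
#' effect functions.
#'
#' @param model A [pk_model()].
#' @param protocol A [trial_protocol()] for the same drug.
#' @param times Sampling times in days.
#' @return A tibble with columns `time`, `central`, `synovial`, `available`.
#' @export
simulate_pk <- function(model, protocol, times) {
  if (!identical(model$drug, protocol$drug))
    stop("protocol drug does not match PK model", call. = FALSE)
  ok_route <- switch(model$structure, "1cmt_sc" = "sc",
                     "2cmt_bolus" = "oral", "2cmt_iv" = "iv")
  if (!identical(protocol$route, ok_route))
    stop("route `", protocol$route, "` unsupported for ", model$structure,
         call. = FALSE)
  dose_times <- (seq_len(protocol$n_doses) - 1) * protocol$interval
  central <- Reduce(`+`, lapply(dose_times, function(td) {
    single_dose_conc(model, protocol$dose_mg, times - td)
  }), accumulate = FALSE)
  if (protocol$dose_mg == 0 || protocol$n_doses == 0)
    central <- numeric(length(times)) + 0
  tibble::tibble(
    time = times,
    central = central,
    synovial = model$partition * central,
    available = model$bioavailability * central
  )
}

#' Methotrexate effect parameters
#'
#' The three MTX Hill effects (inhibition of pro-inflammatory cytokine
#' secretion, stimulation of Treg anti-inflammatory secretion, inhibition of
#' immune-cell influx) share one calibrated parameterisation:
#' `vm = 0.5`, `km = 1e-5` mg/L, `slope = 2`.
#'
#' @param vm,km,slope Hill parameters.
#' @return A list with `vm`, `km`, `slope`.
#' @export
mtx_effect_params <- function(vm = 0.5, km = 1e-5, slope = 2) {
  stopifnot(vm > 0, vm < 1, km > 0, slope > 0)
  list(vm = vm, km = km, slope = slope)
}

#' Methotrexate pharmacodynamic effects
#'
#' @param central_conc_available Bioavailability-scaled central MTX
#'   concentration (mg/L), vectorised.
#' @param params [mtx_effect_params()].
#' @return A tibble with columns `anti_cytsec`, `pro_cytsec`,
#'   `anti_cellinflux`, each in `[0, vm]`; secretion by non-Treg cells is
#'   multiplied by `1 - anti_cytsec`, Treg anti-inflammatory secretion by
#'   `1 + pro_cytsec`, immune-cell influx by `1 - anti_cellinflux`.
#' @export
mtx_effects <- function(central_conc_available, params = mtx_effect_params()) {
  e <- hill(central_conc_available, params$vm, params$km, params$slope)
  tibble::tibble(anti_cytsec = e, pro_cytsec = e, anti_cellinflux = e)
}

#' Free TNF-alpha under adalimumab equilibrium binding
#'
#' Solves the equilibrium `A + T <-> AT` with conservation of total drug and
#' total TNF for the free-TNF root of the quadratic
#' `free^2 + (ada + kd - total) free - kd total = 0`; the physical root lies
#' in `[0, total]`.
#'
#' @param total_tnf Total synovial TNF-alpha (ng/mL).
#' @param ada_syn Total synovial adalimumab (ng/mL).
#' @param kd Dissociation constant (ng/mL).
#' @return Free TNF-alpha (ng/mL), vectorised.
#' @export
ada_free_tnf <- function(total_tnf, ada_syn, kd) {
  stopifnot(kd > 0)
  if (any(total_tnf < 0) || any(ada_syn < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  b <- total_tnf - ada_syn - kd
  free <- (b + sqrt(b^2 + 4 * kd * total_tnf)) / 2
  pmin(pmax(free, 0), total_tnf)
}

#' Tocilizumab scaling of IL-6 clearance
#'
#' Returns the divisor `kd / (tcz + kd)` in `(0, 1]`; the effective IL-6
#' clearance is the baseline clearance divided by this value, so at fixed
#' secretion the steady-state IL-6 concentration falls by exactly the
#' divisor.
#'
#' @param tcz_syn Synovial tocilizumab concentration (mg/L).
#' @param kd_tcz Dissociation constant (mg/L).
#' @return Dimensionless divisor, vectorised over `tcz_syn`.
#' @export
tcz_il6_clearance_scaling <- function(tcz_syn, kd_tcz) {
  stopifnot(kd_tcz > 0)
  if (any(tcz_syn < 0)) stop("`tcz_syn` must be non-negative", call. = FALSE)
  kd_tcz / (tcz_syn + kd_tcz)
}

#' Default binding constants of the biologics
#'
#' Adalimumab-TNF and tocilizumab-IL-6R dissociation constants (sub-nanomolar
#' and low-nanomolar in-vitro affinities converted to mass units).
#'
#' @return A list with `kd_ada_ng_ml` and `kd_tcz_mg_l`.
#' @export
binding_constants <- function() {
  list(kd_ada_ng_ml = 15, kd_tcz_mg_l = 0.37)
}

# Disposition coefficients of the central concentration per mg of dose:
# C(t) = dose * (a1 exp(-l1 t) + a2 exp(-l2 t)). The compiled right-hand
# side superposes these terms over past doses, so the exposure entering the
# ODEs is the exact closed-form PK solution.
pk_exp_coefficients <- function(model) {
  if (model$structure == "1cmt_sc") {
    ke <- model$cl / model$v1
    ka <- model$ka
    if (abs(ka - ke) < 1e-12) ka <- ke * (1 + 1e-9)
    cc <- model$bioavailability * ka / (model$v1 * (ka - ke))
    list(a1 = cc, l1 = ke, a2 = -cc, l2 = ka)
  } else {
    k10 <- model$cl / model$v1
    k12 <- model$q / model$v1
    k21 <- model$q / model$v2
    s <- k10 + k12 + k21
    alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
    beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
    list(a1 = (alpha - k21) / ((alpha - beta) * model$v1), l1 = alpha,
         a2 = (k21 - beta) / ((alpha - beta) * model$v1), l2 = beta)
  }
}

# One therapy object per protocol, consumed by the compiled core.
build_therapy <- function(protocol, model = NULL,
                          pd = mtx_effect_params(),
                          kd = binding_constants()) {
  if (is.null(protocol) || protocol$drug == "none") return(NULL)
  if (is.null(model)) model <- pk_model(protocol$drug)
  co <- pk_exp_coefficients(model)
  list(drug = protocol$drug,
       dose_times = (seq_len(protocol$n_doses) - 1) * protocol$interval,
       dose_mg = protocol$dose_mg, interval = protocol$interval,
       n_doses = protocol$n_doses,
       a1 = co$a1, l1 = co$l1, a2 = co$a2, l2 = co$l2,
       mtx_scale = if (protocol$drug == "MTX") model$bioavailability else 0,
       ada_scale = if (protocol$drug == "ADA") model$partition * 1000 else 0,
       tcz_scale = if (protocol$drug == "TCZ") model$partition else 0,
       mtx_vm = pd$vm, mtx_km = pd$km, mtx_slope = pd$slope,
       kd_ada = kd$kd_ada_ng_ml, kd_tcz = kd$kd_tcz_mg_l)
}
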