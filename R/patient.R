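# Virtual patients: one named parameter vector per simulated subject.

BASELINE_TOKEN <- c(FLS = "FLS", Endothelial = "Endo", Macrophage = "Macrophage",
                    Th1 = "Th1", Th17 = "Th17", Treg = "Treg", CTL = "CTL",
                    BCell = "BCells", PlasmaCell = "Plasma")

SEC_CELL_TOKEN <- c(FLS = "FLS", Endothelial = "Endo", Macrophage = "Macro",
                    Th1 = "Th1", Th17 = "Th17", Treg = "Treg", CTL = "CTL",
                    BCell = "BCell", PlasmaCell = "Plasma")

kg_name <- function(cell) paste0("kg_", BASELINE_TOKEN[cell], "_Baseline")
kin_name <- function(cell) paste0("kIn_", BASELINE_TOKEN[cell], "_Baseline")
kdeg_name <- function(cell) paste0("kdeg_", cell)
clr_name <- function(med) paste0("clr_", med)
f_name <- function(med) paste0("F_", MEDIATOR_TOKEN[med])
ksec_name <- function(med, cell) {
  paste0("k_", MEDIATOR_TOKEN[med], "Sec", SEC_CELL_TOKEN[cell])
}

#' First-order apoptosis rate from a percent-apoptosis measurement
#'
#' Converts an in-vitro observation of `pct` percent apoptosis over
#' `duration_days` days into a first-order rate:
#' `ln(100 / (100 - pct)) / duration_days`. The Th1 activation-induced
#' cell-death datum of 15% in 6 hours gives 0.65/day.
#'
#' @param pct Percent of cells apoptotic at the end of the assay, in [0, 100).
#' @param duration_days Assay duration in days (> 0).
#' @return Rate in 1/day.
#' @export
#' @examples
#' apoptosis_rate(15, 6 / 24) # 0.65
apoptosis_rate <- function(pct, duration_days) {
  stopifnot(duration_days > 0)
  if (any(pct < 0 | pct >= 100))
    stop("`pct` must be in [0, 100)", call. = FALSE)
  log(100 / (100 - pct)) / duration_days
}

#' Construct a virtual patient
#'
#' A virtual patient is a complete named parameter vector: baseline
#' proliferation/influx rates (cells/mL/day), apoptosis rates (1/day),
#' per-(cell, mediator) secretion rates (ng/cell/day), mediator clearances
#' (1/day), global mediator scale factors `F_*`, per-edge maximal fold
#' effects, and the B-cell differentiation rate. Parameters not supplied in
#' `overrides` are taken from `base` (usually the calibrated reference
#' patient).
#'
#' @param overrides Named numeric vector of parameter values.
#' @param base A `virtual_patient` supplying the remaining parameters.
#' @param id Patient identifier.
#' @return A `virtual_patient`.
#' @export
virtual_patient <- function(overrides = numeric(), base = NULL,
                            id = "patient") {
  if (is.null(base)) stop("`base` patient is required", call. = FALSE)
  params <- base$params
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    params[names(overrides)] <- overrides
  }
  if (any(params < 0))
    stop("all patient parameters must be non-negative", call. = FALSE)
  if (params[[kin_name("FLS")]] != 0)
    stop("FLS influx must be zero (structural cells do not migrate)",
         call. = FALSE)
  structure(list(id = id, params = params), class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("<virtual_patient> ", x$id, ": ", length(x$params), " parameters\n",
      sep = "")
  invisible(x)
}

# Regulation factors for every process at a given mediator-concentration
# vector. Pure-R mirror of the compiled right-hand side; also the workhorse
# of reference-patient calibration. `tnfa_conc` lets therapy substitute free
# for total TNF-a.
process_factors <- function(net, patient, mediator_conc, tnfa_conc = NULL) {
  p <- patient$params
  conc <- mediator_conc[net$mediators]
  if (!is.null(tnfa_conc)) conc[["TNFa"]] <- tnfa_conc
  ed <- net$regulation
  c_reg <- as.numeric(conc[ed$regulator])
  cs <- c_reg^ed$slope
  h <- as.numeric(p[ed$param]) * cs / (cs + ed$km^ed$slope)
  key <- ifelse(ed$process == "sec",
                paste0("sec:", ed$mediator, ":", ed$cell),
                ifelse(ed$process == "diff", "diff",
                       paste0(ed$process, ":", ed$cell)))
  pro <- tapply(h[ed$sign == "pro"], key[ed$sign == "pro"], sum)
  anti <- tapply(h[ed$sign == "anti"], key[ed$sign == "anti"], sum)
  all_keys <- unique(c(
    paste0("prolif:", net$cells), paste0("influx:", net$cells),
    paste0("deg:", net$cells),
    paste0("sec:", net$secretion$mediator, ":", net$secretion$cell), "diff"))
  pro_v <- stats::setNames(rep(0, length(all_keys)), all_keys)
  anti_v <- pro_v
  pro_v[names(pro)] <- pmin(net$policy$pro_limit, pro)
  anti_v[names(anti)] <- pmin(net$policy$anti_limit, anti)
  factors <- (1 + pro_v) * (1 - anti_v)
  # essential gates multiply the relevant secretion factor
  for (i in seq_len(nrow(net$essential))) {
    e <- net$essential[i, ]
    k <- paste0("sec:", e$secreted, ":", e$cell)
    factors[[k]] <- essential_gate(factors[[k]], conc[[e$mediator]],
                                   e$km_gate, e$slope)
  }
  factors
}

#' Calibrate the reference virtual patient
#'
#' Solves for baseline proliferation, influx and secretion rates so that the
#' fully coupled steady state of `net` sits exactly at the geometric
#' midpoints of the literature cell-density and mediator-concentration
#' ranges. Because regulation factors depend only on the state, and the
#' target state is known, the calibration is closed-form: each baseline is
#' the required steady-state flux divided by the regulation factor evaluated
#' at the target state. With all regulation edges removed the same
#' construction reduces to the decoupled closed forms.
#'
#' @param net An [ra_network()].
#' @param influx_share Fraction of each immune cell's production assigned to
#'   influx rather than proliferation (proliferation dominates; structural
#'   FLS and terminally differentiated plasma cells receive no influx).
#' @return A `virtual_patient` whose steady state is the reference state.
#' @export
reference_patient <- function(net, influx_share = 0.2) {
  cells <- net$cells
  meds <- net$mediators
  ctar <- reference_cell_targets()
  mtar <- reference_mediator_targets()
  kdeg <- default_cell_deg()
  clr <- default_mediator_clearance()
  bounds <- parameter_bounds()
  kdiff <- geomid(bounds$lb[bounds$name == "kdiff_BCells_PlasmaCells"],
                  bounds$ub[bounds$name == "kdiff_BCells_PlasmaCells"])

  # assemble the full parameter vector with placeholder baselines
  params <- c(
    stats::setNames(rep(0, length(cells)), kg_name(cells)),
    stats::setNames(rep(0, length(cells)), kin_name(cells)),
    stats::setNames(kdeg[cells], kdeg_name(cells)),
    stats::setNames(clr[meds], clr_name(meds)),
    stats::setNames(rep(1, length(meds)), f_name(meds)),
    stats::setNames(rep(0, nrow(net$secretion)),
                    ksec_name(net$secretion$mediator, net$secretion$cell)),
    stats::setNames(net$regulation$vm[!duplicated(net$regulation$param)],
                    net$regulation$param[!duplicated(net$regulation$param)]),
    kdiff_BCells_PlasmaCells = kdiff
  )
  pat <- structure(list(id = "reference", params = params),
                   class = "virtual_patient")
  fac <- process_factors(net, pat, mtar)

  share <- stats::setNames(rep(influx_share, length(cells)), cells)
  share[c("FLS", "PlasmaCell")] <- 0
  for (cl in cells) {
    need <- kdeg[[cl]] * fac[[paste0("deg:", cl)]] * ctar[[cl]]
    diff_in <- 0
    if (cl == net$differentiation$target)
      diff_in <- kdiff * fac[["diff"]] * ctar[[net$differentiation$source]]
    diff_out <- 0
    if (cl == net$differentiation$source)
      diff_out <- kdiff * fac[["diff"]] * ctar[[cl]]
    influx <- share[[cl]] * need
    prolif <- need + diff_out - diff_in - influx
    if (prolif < 0) stop("reference calibration: negative proliferation for ",
                         cl, call. = FALSE)
    params[[kg_name(cl)]] <- prolif / fac[[paste0("prolif:", cl)]]
    if (influx > 0)
      params[[kin_name(cl)]] <- influx / fac[[paste0("influx:", cl)]]
  }
  for (i in seq_len(nrow(net$secretion))) {
    s <- net$secretion[i, ]
    if (s$mediator == net$cam$mediator) next
    total_flux <- clr[[s$mediator]] * mtar[[s$mediator]]
    f <- fac[[paste0("sec:", s$mediator, ":", s$cell)]]
    params[[ksec_name(s$mediator, s$cell)]] <-
      s$weight * total_flux / (ctar[[s$cell]] * f)
  }
  virtual_patient(base = structure(list(id = "reference", params = params),
                                   class = "virtual_patient"),
                  id = "reference")
}

#' Reference synovium state
#'
#' The steady state the reference patient is calibrated to: geometric
#' midpoints of the literature ranges.
#'
#' @return A `synovium_state`.
#' @export
reference_state <- function() {
  synovium_state(reference_cell_targets(), reference_mediator_targets(),
                 time = 0)
}

#' Construct a synovium state
#'
#' @param cell_density Named vector of cell densities (cells/mL), one per
#'   cell type.
#' @param mediator_conc Named vector of mediator concentrations (ng/mL).
#' @param time Time in days.
#' @return A `synovium_state`.
#' @export
synovium_state <- function(cell_density, mediator_conc, time = 0) {
  stopifnot(all(RA_CELLS %in% names(cell_density)),
            all(RA_MEDIATORS %in% names(mediator_conc)))
  if (any(cell_density < 0) || any(mediator_conc < 0))
    stop("state entries must be non-negative", call. = FALSE)
  structure(list(cell_density = cell_density[RA_CELLS],
                 mediator_conc = mediator_conc[RA_MEDIATORS],
                 time = time),
            class = "synovium_state")
}

#' @export
print.synovium_state <- function(x, ...) {
  cat("<synovium_state> t =", x$time, "days\n")
  print(signif(x$cell_density, 3))
  print(signif(x$mediator_conc, 3))
  invisible(x)
}

state_to_vec <- function(state) {
  c(state$cell_density[RA_CELLS], state$mediator_conc[RA_MEDIATORS])
}

vec_to_state <- function(y, time = 0) {
  synovium_state(stats::setNames(pmax(y[seq_along(RA_CELLS)], 0), RA_CELLS),
                 stats::setNames(pmax(y[length(RA_CELLS) +
                                          seq_along(RA_MEDIATORS)], 0),
                                 RA_MEDIATORS),
                 time = time)
}
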