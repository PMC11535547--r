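#' Hill effect of a mediator concentration
#'
#' Saturating effect term `vm * conc^slope / (conc^slope + km^slope)` used for
#' every cytokine-on-process and drug-on-process modulation in the model.
#' Monotone nondecreasing in `conc` and bounded above by `vm`.
#'
#' @param conc Mediator (or drug) concentration, ng/mL (or mg/L for drugs);
#'   non-negative, vectorised.
#' @param vm Maximum fold contribution (dimensionless, > 0).
#' @param km Concentration at half-maximal effect (> 0, same units as `conc`).
#' @param slope Hill coefficient (> 0).
#' @return Dimensionless effect in `[0, vm)`.
#' @export
#' @examples
#' hill(2, vm = 3, km = 2, slope = 1.7) # half-saturation: 1.5
hill <- function(conc, vm, km, slope = 1) {
  stopifnot(km > 0, slope > 0, vm > 0)
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  cs <- conc^slope
  vm * cs / (cs + km^slope)
}

#' Caps on aggregated cytokine effects
#'
#' The summed pro effect on any rate is capped at `pro_limit` (default
#' 10-fold) and the summed anti effect at `anti_limit` (default 0.75), so a
#' rate can move between `(1 - anti_limit)` and `(1 + pro_limit)` times its
#' baseline.
#'
#' @param pro_limit Cap on the summed pro effect (> 0).
#' @param anti_limit Cap on the summed anti effect, in (0, 1).
#' @return A `cap_policy` object.
#' @export
cap_policy <- function(pro_limit = 10, anti_limit = 0.75) {
  stopifnot(pro_limit > 0, anti_limit > 0, anti_limit < 1)
  structure(list(pro_limit = pro_limit, anti_limit = anti_limit),
            class = "cap_policy")
}

#' One regulatory edge: a mediator modulating a process
#'
#' @param regulator Mediator identifier.
#' @param target_process Label of the regulated process (free-form here;
#'   network construction supplies canonical labels such as
#'   `"prolif:FLS"` or `"sec:IL6:FLS"`).
#' @param sign `"pro"` or `"anti"`.
#' @param vm_effect,km_effect,slope_effect Hill parameters of the edge.
#' @return A `regulatory_edge` object.
#' @export
regulatory_edge <- function(regulator, target_process, sign,
                            vm_effect, km_effect, slope_effect = 1) {
  sign <- match.arg(sign, c("pro", "anti"))
  stopifnot(vm_effect > 0, km_effect > 0, slope_effect > 0)
  structure(list(regulator = regulator, target_process = target_process,
                 sign = sign, vm_effect = vm_effect, km_effect = km_effect,
                 slope_effect = slope_effect),
            class = "regulatory_edge")
}

#' Aggregate multi-cytokine effects on one process
#'
#' Sums the Hill contributions of all pro edges and all anti edges acting on
#' a single process and applies the caps:
#' `pro_rate = min(pro_limit, sum of pro terms)`,
#' `anti_rate = min(anti_limit, sum of anti terms)`.
#' Edges are summed in a canonical order (regulator, then target label) so
#' the floating-point result does not depend on input order.
#'
#' @param edges List of [regulatory_edge()] objects sharing one target
#'   process.
#' @param mediator_conc Named vector of mediator concentrations (ng/mL).
#' @param policy A [cap_policy()].
#' @return An `effect_aggregate` with `pro_rate`, `anti_rate` and the
#'   per-edge `contributions` before capping.
#' @export
aggregate_effects <- function(edges, mediator_conc, policy = cap_policy()) {
  if (length(edges)) {
    tp <- unique(vapply(edges, `[[`, "", "target_process"))
    if (length(tp) > 1)
      stop("edges must share a single target process", call. = FALSE)
    ord <- order(vapply(edges, `[[`, "", "regulator"),
                 vapply(edges, `[[`, "", "sign"))
    edges <- edges[ord]
  }
  contrib <- vapply(edges, function(e) {
    if (!e$regulator %in% names(mediator_conc))
      stop("no concentration supplied for regulator `", e$regulator, "`",
           call. = FALSE)
    hill(mediator_conc[[e$regulator]], e$vm_effect, e$km_effect,
         e$slope_effect)
  }, numeric(1))
  signs <- vapply(edges, `[[`, "", "sign")
  structure(list(
    pro_rate = min(policy$pro_limit, sum(contrib[signs == "pro"])),
    anti_rate = min(policy$anti_limit, sum(contrib[signs == "anti"])),
    contributions = stats::setNames(contrib,
                                    vapply(edges, `[[`, "", "regulator")),
    policy = policy
  ), class = "effect_aggregate")
}

#' Multiplicative rate factor of an aggregated effect
#'
#' `(1 + pro_rate) * (1 - anti_rate)`: the factor applied to the baseline
#' rate of the regulated process. At the default caps it lies in
#' `[0.25, 11]`.
#'
#' @param aggregate An `effect_aggregate`, or a list with `pro_rate` and
#'   `anti_rate`.
#' @return Dimensionless factor.
#' @export
rate_factor <- function(aggregate) {
  (1 + aggregate$pro_rate) * (1 - aggregate$anti_rate)
}

#' Gate a rate on an essential mediator
#'
#' Some processes require a mediator outright (IL-12 for IFN-gamma secretion
#' by Th1 cells): rather than a fold increase, the rate is multiplied by
#' `conc^s / (conc^s + km_gate^s)` so it vanishes when the essential mediator
#' is absent and recovers the ungated rate at saturating concentrations.
#'
#' @param process_rate Ungated rate (any units).
#' @param essential_mediator_conc Concentration of the essential mediator.
#' @param km_gate Half-recovery concentration (> 0).
#' @param slope Hill coefficient of the gate (default 1).
#' @return Gated rate, same units as `process_rate`.
#' @export
essential_gate <- function(process_rate, essential_mediator_conc, km_gate,
                           slope = 1) {
  stopifnot(km_gate > 0, slope > 0)
  cs <- essential_mediator_conc^slope
  process_rate * cs / (cs + km_gate^slope)
}
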