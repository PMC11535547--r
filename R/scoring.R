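# Clinical score layer: map synovial cell densities to a model DAS28-CRP,
# derive ACR response categories as percent change from baseline, classify
# inadequate responders.

#' Parameters of the model DAS28-CRP score
#'
#' Per-cell weights, half-max densities (Km, cells/mL) and a shared Hill
#' exponent gamma = 2.5. Positive weights sum to 10 so the score is well
#' distributed between 0 and 10; the Treg term enters with weight -0.5.
#' The CTL half-max density is not part of the published parameterisation
#' and defaults to the geometric midpoint of the CTL literature density
#' range.
#'
#' @param treg_hill Apply the Hill transform to the Treg density (default);
#'   `FALSE` preserves the literal raw-density reading, which is unbounded
#'   below and kept only for comparison.
#' @param ctl_km Half-max density for the CTL term.
#' @return A `score_parameters` object.
#' @export
score_parameters <- function(treg_hill = TRUE, ctl_km = geomid(8.38e2, 6.56e6)) {
  cells <- c("Macrophage", "FLS", "Th1", "BCell", "PlasmaCell", "Th17",
             "Endothelial", "CTL", "Treg")
  structure(list(
    coefficients = stats::setNames(
      c(2.5, 2.0, 1.5, 1.5, 1.0, 0.5, 0.5, 0.5, -0.5), cells),
    km = stats::setNames(
      c(2.2e7, 1.3e7, 4.0e6, 3.0e6, 1.8e6, 1.0e5, 4.2e7, ctl_km, 2.0e6),
      cells),
    gamma = stats::setNames(rep(2.5, length(cells)), cells),
    treg_hill = treg_hill
  ), class = "score_parameters")
}

#' Model DAS28-CRP score of a synovium state
#'
#' Weighted sum of saturating per-cell terms
#' `Hill(x) = x^gamma / (x^gamma + Km^gamma)`:
#' 2.5 Hill(Macrophage) + 2 Hill(FLS) + 1.5 Hill(Th1) + 1.5 Hill(BCell) +
#' 1 Hill(PlasmaCell) + 0.5 Hill(Th17) + 0.5 Hill(Endothelial) +
#' 0.5 Hill(CTL) - 0.5 Hill(Treg). The result lies in (-0.5, 10); the
#' supremum of the positive part equals the positive-coefficient sum, 10.
#'
#' @param state A `synovium_state`, or a named vector of cell densities.
#' @param params [score_parameters()].
#' @return Score (dimensionless).
#' @export
das28 <- function(state, params = score_parameters()) {
  dens <- if (inherits(state, "synovium_state")) state$cell_density else state
  cells <- names(params$coefficients)
  if (!all(cells %in% names(dens)))
    stop("missing cell densities: ",
         paste(setdiff(cells, names(dens)), collapse = ", "), call. = FALSE)
  if (any(dens[cells] < 0))
    stop("cell densities must be non-negative", call. = FALSE)
  x <- as.numeric(dens[cells])
  g <- params$gamma[cells]
  h <- x^g / (x^g + params$km[cells]^g)
  h[x == 0] <- 0 # 0^g/0^g guard
  if (!params$treg_hill) h[cells == "Treg"] <- x[cells == "Treg"]
  sum(params$coefficients * h)
}

#' Clinical outcome from baseline and post-therapy scores
#'
#' Computes the percent reduction in the model DAS28-CRP, the ACR20/50/70
#' category (percent reduction at least 20/50/70), and the DAS-based flags:
#' remission (post < 2.6), low disease activity (post < 3.2, reported as
#' `das_lt_3_2`), and a change greater than 1.2 score units.
#'
#' @param baseline_score,post_score Model DAS28-CRP scores (baseline > 0).
#' @return A one-row tibble (`clinical_outcome`).
#' @export
acr_category <- function(baseline_score, post_score) {
  if (any(baseline_score <= 0))
    stop("baseline score must be positive", call. = FALSE)
  pct <- 100 * (baseline_score - post_score) / baseline_score
  out <- tibble::tibble(
    das28_baseline = baseline_score,
    das28_post = post_score,
    delta_das = baseline_score - post_score,
    pct_reduction = pct,
    acr20 = pct >= 20,
    acr50 = pct >= 50,
    acr70 = pct >= 70,
    das_lt_3_2 = post_score < 3.2,
    das_lt_2_6 = post_score < 2.6,
    delta_gt_1_2 = (baseline_score - post_score) > 1.2
  )
  class(out) <- c("clinical_outcome", class(out))
  out
}

#' Classify inadequate responders
#'
#' A patient is an inadequate responder (IR) when the score reduction is
#' below 50 percent AND the post-therapy model DAS28-CRP remains above 3.2.
#'
#' @param outcome A `clinical_outcome` (any number of rows).
#' @return Logical vector.
#' @export
classify_ir <- function(outcome) {
  outcome$pct_reduction < 50 & outcome$das28_post > 3.2
}
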