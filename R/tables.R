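#' @useDynLib rasim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical species ordering used throughout the package (state vectors,
# compiled model layout, serialized configs).
RA_CELLS <- c("FLS", "Endothelial", "Macrophage", "Th1", "Th17",
              "Treg", "CTL", "BCell", "PlasmaCell")

RA_MEDIATORS <- c("TNFa", "IL6", "IL17", "IL12", "IL23", "IL1b", "IFNg",
                  "GMCSF", "BAFF", "IL10", "TGFb", "RANTES", "MIP3a",
                  "MCP1", "VEGF", "CAM", "AutoAb")

# Mediator token used in varied-parameter names (MIP-3a appears as "MIP3").
MEDIATOR_TOKEN <- c(TNFa = "TNFa", IL6 = "IL6", IL17 = "IL17", IL12 = "IL12",
                    IL23 = "IL23", IL1b = "IL1b", IFNg = "IFNg",
                    GMCSF = "GMCSF", BAFF = "BAFF", IL10 = "IL10",
                    TGFb = "TGFb", RANTES = "RANTES", MIP3a = "MIP3",
                    MCP1 = "MCP1", VEGF = "VEGF", CAM = "CAM",
                    AutoAb = "AutoAb")

#' Bounds of the 129 parameters varied across the virtual cohort
#'
#' One row per varied parameter: baseline proliferation (`kg_*`) and influx
#' (`kIn_*`) rates (cells/mL/day), the B-cell to plasma-cell differentiation
#' rate (1/day), global mediator scale factors (`F_*`, dimensionless) and the
#' maximal fold effects (`*_Maxby*`, dimensionless) of each regulatory edge.
#' Cohort sampling draws each parameter log-uniformly within `[lb, ub]`.
#'
#' @return A tibble with columns `id`, `name`, `lb`, `ub`.
#' @export
parameter_bounds <- function() {
  tibble::tibble(
    id = 1:129,
    name = c(
      "kg_BCells_Baseline", "kg_CTL_Baseline", "kg_Endo_Baseline",
      "kg_FLS_Baseline", "kg_Macrophage_Baseline",
      "kdiff_BCells_PlasmaCells", "kg_Th1_Baseline", "kg_Th17_Baseline",
      "kg_Treg_Baseline", "F_AutoAb", "F_BAFF", "F_CAM", "F_VEGF", "F_TNFa",
      "F_TGFb", "F_RANTES", "F_MIP3", "F_MCP1", "F_IL6", "F_IL23", "F_IL1b",
      "F_IL17", "F_IL12", "F_IL10", "F_IFNg", "F_GMCSF",
      "kIn_Treg_Baseline", "kIn_Th1_Baseline", "kIn_Macrophage_Baseline",
      "kIn_CTL_Baseline", "kIn_BCells_Baseline", "kIn_Th17_Baseline",
      "kIn_Endo_Baseline",
      "Endoinflux_MaxbyVEGF", "EndoProlif_MaxbyVEGF", "Endoinflux_MaxbyTNFa",
      "EndoApop_MaxbyTNFa", "EndoApop_MaxbyVEGF", "FLSProlif_MaxbyTNFa",
      "Endoinflux_MaxbyIL6", "IL6SecFLS_MaxbyIL1b", "MacroInflux_MaxbyIL17",
      "FLSProlif_MaxbyIL1b", "FLSProlif_MaxbyIL17", "FLSProlif_MaxbyTGFb",
      "EndoProlif_MaxbyIL1b", "Th1Prolif_MaxbyTGFb", "TCellProlif_MaxbyIL6",
      "TregProlif_MaxbyTGFb", "IL6SecMacro_MaxbyTNFa",
      "IL1bSecMacro_MaxbyIL17", "TNFaSecMacro_MaxbyIL17",
      "TCellinflux_MaxbyTNFa", "IFNgSecTh1_MaxbyIL10", "Endoinflux_MaxbyIL17",
      "Endoinflux_MaxbyTGFb", "VEGFSecFLS_MaxbyIL1b", "VEGFSecFLS_MaxbyIL6",
      "VEGFSecFLS_MaxbyTNFa", "VEGFSecFLS_MaxbyIL17", "IL6SecFLS_MaxbyIL17",
      "LymphoInflux_MaxbyMIP3", "MacroProlif_MaxbyGMCSF",
      "GMCSFSecFLS_MaxbyTNFa", "GMCSFSecMacro_MaxbyTNFa",
      "MacroInflux_MaxbyMCP1", "IL6SecFLS_MaxbyIFNg", "IL1bSecFLS_MaxbyIL10",
      "VEGFSecFLS_MaxbyTGFb", "TNFaSecFLS_MaxbyIL10", "LeukoInflux_MaxbyCAM",
      "TCellProlif_MaxbyIL10", "BCellApop_MaxbyBAFF", "TNFaSecMacro_MaxbyIL10",
      "IL6SecMacro_MaxbyIL10", "MacroInflux_MaxbyTGFb",
      "TNFaSecMacro_MaxbyAutoAb", "BCellProlif_MaxbyIL6",
      "BCellProlif_MaxbyIFNg", "BCellProlif_MaxbyIL10",
      "BCellProlif_MaxbyTGFb", "IFNgSecCTL_MaxbyIL6", "CTLProlif_MaxbyIL1b",
      "CTLProlif_MaxbyTGFb", "IFNgSecCTL_MaxbyTGFb", "VEGFSecEndo_MaxbyTGFb",
      "MIP3SecFLS_MaxbyTNFa", "MIP3SecFLS_MaxbyIL1b", "MIP3SecFLS_MaxbyIL17",
      "MCP1SecFLS_MaxbyIL1b", "MCP1SecMacro_MaxbyIL1b",
      "IL17SecTh17_MaxbyIL1b", "IL17SecTh17_MaxbyIL6", "CTLApop_MaxbyTGFb",
      "AutoAbSecBCell_MaxbyIL6", "BCellDiff_MaxbyIL6",
      "EndoProlif_MaxbyGMCSF", "Endoinflux_MaxbyGMCSF",
      "TNFaSecMacro_MaxbyGMCSF", "CTLProlif_MaxbyIL12", "Th1Apop_MaxbyIL12",
      "Th17Prolif_MaxbyIL23", "IL17SecCTL_MaxbyIL23", "IL17SecTh17_MaxbyIL23",
      "MacroProlif_MaxbyTNFa", "RANTESSecFLS_MaxbyTNFa",
      "RANTESSecFLS_MaxbyIL1b", "RANTESSecFLS_byTNFa_MaxbyIFNg",
      "RANTESSecEndo_MaxbyTNFa", "RANTESSecEndo_byTNFa_MaxbyIFNg",
      "IL6SecFLS_MaxbyRANTES", "TCellinflux_MaxbyRANTES",
      "RANTESSecEndo_MaxbyIL1b", "RANTESSecFLS_byIL1b_MaxbyIFNg",
      "MacroInflux_MaxbyRANTES", "CTLInflux_MaxbyRANTES",
      "MCP1SecFLS_MaxbyTNFa", "FLSProlif_MaxbyIL6", "IFNgSecMacro_MaxbyIL12",
      "Th1Prolif_MaxbyIL12", "Th17Prolif_MaxbyIL1b", "TregProlif_MaxbyIL6",
      "IFNgSecCTL_MaxbyIL12", "PlasmaProlif_MaxbyIL6", "TCellApop_MaxbyIL6",
      "MacroApop_MaxbyTNFa", "MacroApop_MaxbyIFNg", "MacroApop_MaxbyGMCSF",
      "PlasmaCellApop_MaxbyIL6"),
    lb = c(9.55e2, 1.26e3, 4.62e5, 1.55e4, 4.51e3, 3.80e-6, 1.32e2, 3.09e-2,
           1.38e3, 8.59e-2, 2.17e-2, 1.39e-2, 2.19e-2, 2.17e-2, 1.75e-2,
           1.39e-2, 3.45e-2, 1.10e-2, 2.20e-2, 1.73e-2, 1.36e-2, 4.33e-2,
           1.73e-2, 1.37e-2, 5.47e-2, 1.74e-2, 9.77e2, 1.55e3, 6.17e1,
           6.17e1, 9.55e1, 1.55e2, 2.45e2, 1.30e-1, 3.30e-1, 3.15e-1,
           1.96e-1, 8.77e-2, 1.95e-1, 1.96e-1, 1.43e-1, 1.96e-1, 1.95e-1,
           1.66e-1, 1.88e-1, 2.82e-2, 7.43e-2, 6.87e-1, 3.18e-1, 2.72e-1,
           1.08e-1, 1.02e-1, 3.94e-1, 7.40e-2, 1.43e-1, 7.52e-2, 1.30e-1,
           4.58e-2, 4.55e-2, 1.30e-1, 7.16e-1, 7.11e-1, 2.71e-1, 6.00e-1,
           1.08e-1, 2.30e-1, 1.41e-1, 6.30e-2, 1.35e0, 7.48e-2, 1.08e-1,
           9.04e-2, 7.36e-2, 9.08e-2, 9.06e-2, 5.14e-1, 8.32e-1, 3.16e-1,
           7.50e-2, 9.89e-1, 1.73e-2, 5.21e-2, 1.68e-1, 6.27e-2, 9.04e-2,
           3.28e-1, 1.14e0, 1.35e0, 6.04e-1, 1.19e0, 4.34e-2, 1.35e0,
           1.09e-1, 7.45e-2, 4.55e-2, 1.03e-1, 7.41e-2, 1.88e-1, 3.16e-1,
           6.01e-1, 2.99e-2, 1.08e-1, 3.18e-1, 1.09e-1, 1.09e-1, 2.28e-1,
           1.09e-1, 3.30e-1, 1.60e0, 4.58e-2, 8.79e-2, 1.20e0, 4.40e-1,
           2.31e-1, 2.40e-2, 1.06e-1, 9.86e-1, 2.28e-1, 1.09e-1, 4.35e-1,
           8.36e-1, 4.32e-2, 1.08e-1, 1.89e-1, 5.19e-2, 9.08e-2, 1.02e-1,
           9.08e-2, 1.09e-1),
    ub = c(6.61e7, 3.16e7, 2.07e7, 4.28e6, 7.35e6, 2.63e-1, 1.91e8, 2.04e5,
           7.24e8, 3.85e2, 8.79e1, 4.15e1, 6.90e1, 8.38e1, 5.22e1, 4.15e1,
           1.26e2, 3.30e1, 6.58e1, 6.04e1, 6.41e1, 1.75e2, 6.34e1, 5.28e1,
           2.00e2, 5.48e1, 4.07e7, 6.46e7, 2.57e6, 2.57e6, 6.61e6, 6.46e6,
           1.02e7, 9.66e0, 2.10e1, 2.00e1, 1.02e1, 4.34e0, 1.07e1, 1.02e1,
           6.38e0, 1.02e1, 1.07e1, 9.55e0, 1.40e1, 1.62e0, 4.06e0, 4.60e1,
           1.57e1, 2.02e1, 8.04e0, 6.81e0, 2.78e1, 4.48e0, 6.70e0, 5.30e0,
           9.66e0, 2.51e0, 2.90e0, 1.01e1, 3.20e1, 3.70e1, 1.34e1, 3.82e1,
           8.04e0, 1.20e1, 8.53e0, 3.81e0, 7.76e1, 5.83e0, 8.04e0, 6.37e0,
           4.93e0, 5.78e0, 6.07e0, 2.81e1, 4.79e1, 1.82e1, 5.56e0, 7.33e1,
           1.10e0, 3.49e0, 7.14e0, 4.20e0, 6.37e0, 2.31e1, 7.28e1, 7.76e1,
           3.30e1, 8.00e1, 2.90e0, 7.76e1, 7.29e0, 3.87e0, 2.90e0, 5.35e0,
           4.27e0, 1.47e1, 1.82e1, 3.64e0, 2.11e0, 8.04e0, 1.65e1, 7.66e0,
           7.29e0, 1.45e1, 7.29e0, 2.00e1, 7.52e1, 2.51e0, 4.13e0, 7.26e1,
           2.17e1, 1.09e1, 1.32e0, 4.30e0, 7.69e1, 1.45e1, 7.29e0, 2.77e1,
           4.35e0, 3.20e0, 8.04e0, 1.27e1, 3.85e0, 5.78e0, 6.18e0, 5.78e0,
           6.95e0)
  )
}

#' Literature ranges of baseline synovial cell densities
#'
#' Plausibility bounds (cells/mL) for each cell type; a virtual patient whose
#' steady state leaves any of these ranges is excluded from the virtual
#' cohort.
#'
#' @return A tibble with columns `cell`, `lb`, `ub`.
#' @export
cell_density_ranges <- function() {
  tibble::tibble(
    cell = c("FLS", "Endothelial", "Macrophage", "Th1", "Th17",
             "CTL", "BCell", "PlasmaCell", "Treg"),
    lb = c(1.31e6, 4.13e7, 3.73e6, 3.32e4, 1.64e3,
           8.38e2, 6.03e3, 7.08e4, 3.51e4),
    ub = c(1.53e8, 8.31e7, 1.94e8, 2.88e8, 2.02e7,
           6.56e6, 4.17e8, 1.41e8, 9.02e7)
  )
}

#' Literature ranges of baseline synovial mediator concentrations
#'
#' Advisory bounds (ng/mL); mediator excursions are logged during
#' plausibility filtering but do not exclude patients, since tissue cytokine
#' measurements are less reliable than cell counts.
#'
#' @return A tibble with columns `mediator`, `lb`, `ub`.
#' @export
mediator_conc_ranges <- function() {
  tibble::tibble(
    mediator = c("VEGF", "RANTES", "TGFb", "TNFa", "IL23", "IL6", "MCP1",
                 "MIP3a", "IL1b", "GMCSF", "IFNg", "IL10", "IL12", "IL17",
                 "BAFF", "CAM", "AutoAb"),
    lb = c(1.48e-2, 2.34e-4, 2.40e-4, 5.25e-4, 2.40e-4, 9.12e-1, 2.34e-2,
           5.25e-5, 8.32e-4, 9.12e-5, 3.31e-6, 4.90e-3, 3.72e-5, 9.33e-7,
           3.80e-3, 1.08e-3, 3.16e1),
    ub = c(1.70e3, 2.69e1, 1.66e1, 7.59e2, 1.66e1, 1.74e5, 2.69e3,
           7.59e1, 1.20e3, 1.74e1, 7.59e2, 2.04e2, 4.27e0, 1.70e1,
           2.63e2, 5.09e0, 1.26e8)
  )
}

#' Published trial statistics used as calibration targets
#'
#' Baseline DAS28-CRP (mean, sd) and response percentages per arm for the
#' three calibration trials: methotrexate monotherapy, adalimumab (40 mg Q2W,
#' on a methotrexate background) and tocilizumab (8 mg/kg Q4W, on a DMARD
#' background, in methotrexate inadequate responders). All response columns
#' are percentages of the arm; `NA` where the trial did not report the value.
#'
#' @return A tibble, one row per trial arm.
#' @export
trial_reference_stats <- function() {
  tibble::tibble(
    trial = rep(c("MTX", "ADA", "TCZ"), each = 2),
    arm = rep(c("treatment", "placebo"), times = 3),
    n = c(182, 118, 515, 517, 409, 205),
    das_baseline_mean = c(NA, NA, 6.0, 6.0, 6.53, 6.55),
    das_baseline_sd = c(NA, NA, 1.0, 1.0, 1.03, 1.01),
    acr20 = c(46, 26, 70, 57, 45, 25),
    acr50 = c(23, 8, 52, 34, 30.1, 11.2),
    acr70 = c(9, 4, 35, 17, 13.9, 1.9),
    das_lt_2_6 = c(NA, NA, 34, 17, 38.4, 2),
    das_lt_3_2 = c(NA, NA, 47, 26, 50.7, 10.4),
    ddas_gt_1_2 = c(NA, NA, NA, NA, 87.9, 53.4)
  )
}

# Geometric midpoint of a positive range; reference steady-state targets sit
# at these midpoints.
geomid <- function(lb, ub) sqrt(lb * ub)

reference_cell_targets <- function() {
  r <- cell_density_ranges()
  stats::setNames(geomid(r$lb, r$ub), r$cell)[RA_CELLS]
}

reference_mediator_targets <- function() {
  r <- mediator_conc_ranges()
  stats::setNames(geomid(r$lb, r$ub), r$mediator)[RA_MEDIATORS]
}
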