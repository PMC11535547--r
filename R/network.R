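# Default synovial network: species, secretion topology, regulatory edges.
#
# The regulatory wiring is reconstructed mechanically from the varied-parameter
# names (`<Target>_Maxby<Regulator>`), which encode one edge each; group
# targets (TCell*, Leuko*, Lympho*) expand to one edge per member cell under a
# shared maximal-effect parameter.

CELL_TOKEN <- c(FLS = "FLS", Endo = "Endothelial", Macro = "Macrophage",
                Macrophage = "Macrophage", Th1 = "Th1", Th17 = "Th17",
                Treg = "Treg", CTL = "CTL", BCell = "BCell",
                BCells = "BCell", Plasma = "PlasmaCell",
                PlasmaCell = "PlasmaCell")

CELL_GROUPS <- list(
  TCell  = c("Th1", "Th17", "CTL"),
  Leuko  = c("Macrophage", "Th1", "Th17", "Treg", "CTL", "BCell"),
  Lympho = c("Th1", "Th17", "Treg", "CTL", "BCell")
)

# Edges where the regulator damps (anti) rather than drives (pro) the target
# process. Everything not listed is pro. Apoptosis targets: "anti" means the
# regulator is a survival factor for that cell. IFN-g and GM-CSF are wired as
# macrophage survival signals so that raising their apoptosis-edge strength
# raises disease burden, consistent with the sensitivity structure of the
# calibrated model this package re-derives.
ANTI_SIGN_PARAMS <- c(
  "IL1bSecFLS_MaxbyIL10", "TNFaSecFLS_MaxbyIL10", "TCellProlif_MaxbyIL10",
  "TNFaSecMacro_MaxbyIL10", "IL6SecMacro_MaxbyIL10", "IFNgSecTh1_MaxbyIL10",
  "BCellProlif_MaxbyIL10",
  "MacroInflux_MaxbyTGFb", "BCellProlif_MaxbyTGFb", "Th1Prolif_MaxbyTGFb",
  "CTLProlif_MaxbyTGFb", "IFNgSecCTL_MaxbyTGFb", "Endoinflux_MaxbyTGFb",
  "TregProlif_MaxbyIL6",
  "BCellApop_MaxbyBAFF", "TCellApop_MaxbyIL6", "PlasmaCellApop_MaxbyIL6",
  "MacroApop_MaxbyIFNg", "MacroApop_MaxbyGMCSF", "MacroApop_MaxbyTNFa",
  "EndoApop_MaxbyVEGF"
)

# Secretion topology: which cell secretes which mediator, with the weight of
# that cell's contribution to the reference steady-state secretion flux.
secretion_table <- function() {
  tibble::tribble(
    ~mediator, ~cell,         ~weight,
    "TNFa",    "Macrophage",  0.55,
    "TNFa",    "FLS",         0.15,
    "TNFa",    "Th1",         0.10,
    "TNFa",    "CTL",         0.10,
    "TNFa",    "BCell",       0.10,
    "IL6",     "FLS",         0.60,
    "IL6",     "Macrophage",  0.40,
    "IL17",    "Th17",        0.80,
    "IL17",    "CTL",         0.20,
    "IL12",    "Macrophage",  1.00,
    "IL23",    "Macrophage",  1.00,
    "IL1b",    "Macrophage",  0.70,
    "IL1b",    "FLS",         0.30,
    "IFNg",    "Th1",         0.60,
    "IFNg",    "CTL",         0.25,
    "IFNg",    "Macrophage",  0.15,
    "GMCSF",   "Macrophage",  0.50,
    "GMCSF",   "FLS",         0.50,
    "BAFF",    "Macrophage",  1.00,
    "IL10",    "Treg",        0.70,
    "IL10",    "Macrophage",  0.30,
    "TGFb",    "Treg",        0.60,
    "TGFb",    "Macrophage",  0.40,
    "RANTES",  "FLS",         0.60,
    "RANTES",  "Endothelial", 0.40,
    "MIP3a",   "FLS",         1.00,
    "MCP1",    "FLS",         0.50,
    "MCP1",    "Macrophage",  0.50,
    "VEGF",    "FLS",         0.50,
    "VEGF",    "Endothelial", 0.50,
    "AutoAb",  "PlasmaCell",  0.90,
    "AutoAb",  "BCell",       0.10
  )
}

# Fixed (not cohort-varied) first-order rates, 1/day. Apoptosis rates derive
# from in-vitro % apoptosis data via apoptosis_rate(); Th1 uses the
# activation-induced-cell-death figure of 15% in 6 h (0.65/day).
default_cell_deg <- function() {
  c(FLS = 0.05, Endothelial = 0.069, Macrophage = 0.1, Th1 = 0.65,
    Th17 = 0.2, Treg = 0.2, CTL = 0.3, BCell = 0.1, PlasmaCell = 0.1)
}

# Mediator clearance from reported half-lives (minutes to hours for
# cytokines; weeks for circulating antibody). CAM relaxes to its
# endothelial-driven level with its own rate below.
default_mediator_clearance <- function() {
  c(TNFa = 33.3, IL6 = 16.6, IL17 = 16.6, IL12 = 8.3, IL23 = 8.3,
    IL1b = 33.3, IFNg = 16.6, GMCSF = 16.6, BAFF = 3.3, IL10 = 16.6,
    TGFb = 8.3, RANTES = 16.6, MIP3a = 16.6, MCP1 = 16.6, VEGF = 8.3,
    CAM = 24, AutoAb = 0.033)
}

parse_varied_name <- function(name) {
  if (grepl("^kg_", name) || grepl("^kIn_", name) || grepl("^F_", name) ||
      name == "kdiff_BCells_PlasmaCells") {
    return(NULL)
  }
  parts <- strsplit(name, "_Maxby", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2)
  reg <- names(MEDIATOR_TOKEN)[match(parts[2], MEDIATOR_TOKEN)]
  if (is.na(reg)) stop("unknown regulator token in `", name, "`")
  target <- sub("_by[A-Za-z0-9]+$", "", parts[1]) # conditioned-on qualifier
  if (grepl("Sec", target, fixed = TRUE)) {
    mt <- regmatches(target, regexec("^([A-Za-z0-9]+)Sec([A-Za-z0-9]+)$",
                                     target))[[1]]
    med <- names(MEDIATOR_TOKEN)[match(mt[2], MEDIATOR_TOKEN)]
    cell <- CELL_TOKEN[[mt[3]]]
    return(tibble::tibble(param = name, regulator = reg, process = "sec",
                          cell = cell, mediator = med))
  }
  m <- regmatches(target,
                  regexec("^([A-Za-z0-9]+?)(Prolif|Influx|influx|Apop|Diff)$",
                          target))[[1]]
  if (length(m) == 0) stop("cannot parse target `", target, "`")
  proc <- c(Prolif = "prolif", Influx = "influx", influx = "influx",
            Apop = "deg", Diff = "diff")[[m[3]]]
  tok <- m[2]
  cells <- if (tok %in% names(CELL_GROUPS)) CELL_GROUPS[[tok]]
           else CELL_TOKEN[[tok]]
  tibble::tibble(param = name, regulator = reg, process = proc,
                 cell = cells, mediator = NA_character_)
}

#' Default synovial network specification
#'
#' Builds the declarative wiring of the model: nine cell types, seventeen
#' mediators, the secretion topology, every regulatory edge encoded in the
#' varied-parameter table (group targets expanded per cell), the B-cell to
#' plasma-cell differentiation flux, the IL-12-essential gate on IFN-gamma
#' secretion by Th1 cells, and the endothelial-driven CAM level.
#'
#' Per-edge Hill half-max concentrations default to the regulator's
#' reference concentration (the geometric midpoint of its literature range):
#' each effect is half-engaged at typical disease concentrations, so the
#' cohort's order-of-magnitude concentration spread sweeps the full
#' saturating curve and patients differ widely in how responsive each edge
#' is. Hill slopes default to 1; maximal fold effects default to the
#' geometric midpoint of the edge's varied-parameter bounds.
#'
#' @param policy A [cap_policy()] applied to all aggregated effects.
#' @return An object of class `ra_network`.
#' @export
ra_network <- function(policy = cap_policy()) {
  bounds <- parameter_bounds()
  med_ref <- reference_mediator_targets()
  edges <- dplyr::bind_rows(lapply(bounds$name, parse_varied_name))
  edges <- dplyr::mutate(
    edges,
    sign = ifelse(.data$param %in% ANTI_SIGN_PARAMS, "anti", "pro"),
    vm = geomid(bounds$lb[match(.data$param, bounds$name)],
                bounds$ub[match(.data$param, bounds$name)]),
    km = med_ref[.data$regulator],
    slope = 1
  )
  sec <- secretion_table()
  endo_mid <- geomid(4.13e7, 8.31e7)
  net <- structure(list(
    cells = RA_CELLS,
    mediators = RA_MEDIATORS,
    secretion = sec,
    regulation = edges,
    differentiation = list(source = "BCell", target = "PlasmaCell",
                           rate_param = "kdiff_BCells_PlasmaCells"),
    essential = tibble::tibble(mediator = "IL12", cell = "Th1",
                               secreted = "IFNg",
                               km_gate = med_ref[["IL12"]], slope = 1),
    cam = list(mediator = "CAM", driver = "Endothelial", km = endo_mid,
               slope = 2, level = 2 * med_ref[["CAM"]], k_relax = 24),
    policy = policy
  ), class = "ra_network")
  validate_network(net)
  net
}

#' Validate a network specification
#'
#' Checks the declarative invariants: all referenced species are declared,
#' every regulation edge targets a declared cell process or secretion edge,
#' secretion weights are positive and sum to one per mediator, and the
#' essential gate references an existing secretion edge.
#'
#' @param net An `ra_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "ra_network"))
  if (!all(net$secretion$cell %in% net$cells) ||
      !all(net$secretion$mediator %in% net$mediators))
    stop("secretion edge references an undeclared species", call. = FALSE)
  if (!all(net$regulation$regulator %in% net$mediators))
    stop("regulation edge with undeclared regulator", call. = FALSE)
  if (!all(net$regulation$cell %in% net$cells))
    stop("regulation edge with undeclared target cell", call. = FALSE)
  secmatch <- is.na(net$regulation$mediator) |
    paste(net$regulation$mediator, net$regulation$cell) %in%
      paste(net$secretion$mediator, net$secretion$cell)
  if (!all(secmatch))
    stop("regulation edge targets a non-existent secretion edge: ",
         paste(net$regulation$param[!secmatch], collapse = ", "),
         call. = FALSE)
  wsum <- tapply(net$secretion$weight, net$secretion$mediator, sum)
  if (any(abs(wsum - 1) > 1e-9))
    stop("secretion weights must sum to 1 per mediator", call. = FALSE)
  if (any(net$regulation$vm <= 0) || any(net$regulation$km <= 0) ||
      any(net$regulation$slope <= 0))
    stop("edge Hill parameters must be positive", call. = FALSE)
  ess_ok <- paste(net$essential$secreted, net$essential$cell) %in%
    paste(net$secretion$mediator, net$secretion$cell)
  if (!all(ess_ok)) stop("essential gate references missing secretion edge",
                         call. = FALSE)
  invisible(net)
}

#' @export
print.ra_network <- function(x, ...) {
  cat("<ra_network> ", length(x$cells), " cells, ", length(x$mediators),
      " mediators, ", nrow(x$secretion), " secretion edges, ",
      nrow(x$regulation), " regulatory edges\n", sep = "")
  invisible(x)
}
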