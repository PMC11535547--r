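# Configuration loading/validation and result serialization.

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write and read a virtual patient as JSON
#'
#' Round-trip safe: all parameters are written by name at full precision.
#'
#' @param patient A [virtual_patient()].
#' @param path Output path (`.json`).
#' @return `write_patient` returns `path` invisibly; `read_patient` a
#'   `virtual_patient`.
#' @export
write_patient <- function(patient, path) {
  jsonlite::write_json(list(id = patient$id,
                            params = as.list(patient$params)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_patient
#' @export
read_patient <- function(path) {
  raw <- read_config_file(path)
  params <- unlist(raw$params)
  structure(list(id = raw$id, params = params), class = "virtual_patient")
}

#' Write a network specification as JSON
#'
#' Serializes species lists, secretion topology, regulatory edges (with the
#' varied-parameter spelling preserved), the differentiation flux, essential
#' gates, CAM coupling and cap policy.
#'
#' @param net An [ra_network()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  jsonlite::write_json(list(
    cells = net$cells, mediators = net$mediators,
    secretion = net$secretion, regulation = net$regulation,
    differentiation = net$differentiation,
    essential = net$essential, cam = net$cam,
    policy = list(pro_limit = net$policy$pro_limit,
                  anti_limit = net$policy$anti_limit)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  raw <- read_config_file(path)
  net <- structure(list(
    cells = raw$cells, mediators = raw$mediators,
    secretion = tibble::as_tibble(raw$secretion),
    regulation = tibble::as_tibble(raw$regulation),
    differentiation = raw$differentiation,
    essential = tibble::as_tibble(raw$essential),
    cam = raw$cam,
    policy = cap_policy(raw$policy$pro_limit, raw$policy$anti_limit)),
    class = "ra_network")
  validate_network(net)
  net
}

#' Write a population table as CSV
#'
#' Species columns carry explicit units in the header
#' (`<cell>__cells_per_mL`, `<mediator>__ng_per_mL`); all other columns are
#' written as-is. `read_population` restores the plain species names.
#'
#' @param population A population tibble.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  out <- population
  cn <- names(out)
  cn[cn %in% RA_CELLS] <- paste0(cn[cn %in% RA_CELLS], "__cells_per_mL")
  cn[cn %in% RA_MEDIATORS] <- paste0(cn[cn %in% RA_MEDIATORS],
                                     "__ng_per_mL")
  names(out) <- cn
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  names(out) <- sub("__(cells_per_mL|ng_per_mL)$", "", names(out))
  class(out) <- c("ra_population", class(out))
  out
}

#' Write a run manifest
#'
#' Records seed, configuration hash, package version and any extra fields so
#' a run is reproducible from config + seed alone.
#'
#' @param path Output path (`.json`).
#' @param seed Integer seed of the run.
#' @param config Configuration object to hash.
#' @param ... Extra named fields (e.g. residual reports).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config = NULL, ...) {
  jsonlite::write_json(list(
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL,
    package_version = as.character(utils::packageVersion("rasim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    ...), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML run configuration, fills defaults, and validates:
#' parameter-bound rows must name known model parameters with
#' `0 < lb < ub`, solver settings must be positive, and referenced files
#' must exist. Unknown parameter names are reported with nearest matches.
#'
#' @param path Path to a JSON or YAML configuration.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  raw <- read_config_file(path)
  defaults <- list(n_cohort = 5000, n_select = 300, seed = 1,
                   steady_state_tol = 1e-6, t_max = 2000,
                   pro_limit = 10, anti_limit = 0.75,
                   output_dir = ".")
  for (nm in names(defaults))
    if (is.null(raw[[nm]])) raw[[nm]] <- defaults[[nm]]
  if (raw$n_cohort < 1 || raw$n_select < 1 || raw$steady_state_tol <= 0 ||
      raw$t_max <= 0)
    stop("config: sizes and tolerances must be positive", call. = FALSE)
  net <- ra_network(cap_policy(raw$pro_limit, raw$anti_limit))
  known <- c(names(reference_patient(net)$params))
  if (!is.null(raw$bounds)) {
    b <- tibble::as_tibble(raw$bounds)
    if (any(b$lb <= 0) || any(b$lb >= b$ub))
      stop("config: bounds must satisfy 0 < lb < ub (offending: ",
           paste(b$name[b$lb <= 0 | b$lb >= b$ub], collapse = ", "), ")",
           call. = FALSE)
    unknown <- setdiff(b$name, known)
    if (length(unknown)) {
      hints <- vapply(unknown, function(u) {
        d <- utils::adist(u, known)
        known[which.min(d)]
      }, character(1))
      stop("config: unknown parameter(s): ",
           paste0(unknown, " (did you mean ", hints, "?)", collapse = "; "),
           call. = FALSE)
    }
    raw$bounds <- b
  }
  for (f in c("patient_file", "network_file")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      stop("config: referenced file does not exist: ", raw[[f]],
           call. = FALSE)
  }
  structure(raw, class = "run_config")
}

#' Write the default fixture set to a directory
#'
#' Emits the default network specification, the calibrated reference
#' patient, the parameter bounds, plausibility ranges, score parameters and
#' trial reference statistics as JSON files, plus a manifest. Everything is
#' regenerated from code; no external data are read.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return The directory path, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- ra_network()
  write_network(net, file.path(dir, "network.json"))
  write_patient(reference_patient(net),
                file.path(dir, "reference_patient.json"))
  jsonlite::write_json(parameter_bounds(),
                       file.path(dir, "parameter_bounds.json"),
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(list(cells = cell_density_ranges(),
                            mediators = mediator_conc_ranges(),
                            min_baseline_das = 3.2),
                       file.path(dir, "plausibility_ranges.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sp <- score_parameters()
  jsonlite::write_json(list(coefficients = as.list(sp$coefficients),
                            km = as.list(sp$km), gamma = as.list(sp$gamma),
                            treg_hill = sp$treg_hill),
                       file.path(dir, "score_parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(trial_reference_stats(),
                       file.path(dir, "trial_reference_stats.json"),
                       digits = NA, pretty = TRUE)
  write_manifest(file.path(dir, "manifest.json"), seed = seed,
                 config = list(fixtures = "default"))
  invisible(dir)
}
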