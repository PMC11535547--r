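# Local (tornado) and global (Sobol) sensitivity of the steady-state model
# DAS28-CRP with respect to patient parameters.

#' Local sensitivity of the steady-state score
#'
#' For each parameter, re-solves the patient's steady state with the
#' parameter multiplied and divided by `fold` and reports the percent change
#' in the model DAS28-CRP relative to baseline. Rows are sorted by the
#' larger absolute effect, ready for a tornado plot; perturbations whose
#' steady state fails to converge are flagged, not dropped.
#'
#' @param net An [ra_network()].
#' @param patient A [virtual_patient()].
#' @param parameter_names Parameters to perturb (default: all varied
#'   parameters).
#' @param fold Perturbation factor (default 2).
#' @param score_params [score_parameters()].
#' @return A tibble (`local_sensitivity`): `parameter`, `pct_change_up`,
#'   `pct_change_down`, `converged_up`, `converged_down`.
#' @export
local_sensitivity <- function(net, patient,
                              parameter_names = parameter_bounds()$name,
                              fold = 2, score_params = score_parameters()) {
  stopifnot(fold > 0, fold != 1)
  unknown <- setdiff(parameter_names, names(patient$params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base_ss <- solve_steady_state(net, patient, method = "fixed")
  if (!base_ss$converged)
    stop("baseline steady state did not converge", call. = FALSE)
  das_base <- das28(base_ss$state, score_params)
  one <- function(name, f) {
    pat <- virtual_patient(
      stats::setNames(patient$params[[name]] * f, name),
      base = patient, id = paste0(patient$id, "_", name))
    ss <- solve_steady_state(net, pat, init = base_ss$state,
                             method = "fixed")
    c(pct = 100 * (das28(ss$state, score_params) - das_base) / das_base,
      conv = ss$converged)
  }
  up <- vapply(parameter_names, one, numeric(2), f = fold)
  down <- vapply(parameter_names, one, numeric(2), f = 1 / fold)
  out <- tibble::tibble(
    parameter = parameter_names,
    pct_change_up = up["pct", ],
    pct_change_down = down["pct", ],
    converged_up = as.logical(up["conv", ]),
    converged_down = as.logical(down["conv", ]))
  out <- out[order(-pmax(abs(out$pct_change_up),
                         abs(out$pct_change_down))), ]
  attr(out, "das_baseline") <- das_base
  class(out) <- c("local_sensitivity", class(out))
  out
}

#' Sobol sensitivity indices of a deterministic function
#'
#' Saltelli-scheme estimation of first-order and total-order Sobol indices:
#' two independent uniform sample matrices A and B of size `n` and the k
#' hybrid matrices AB_i give `n * (k + 2)` model evaluations; first-order
#' indices use the Saltelli 2010 estimator
#' `mean(f(B) * (f(AB_i) - f(A))) / V` and total-order indices the Jansen
#' estimator `mean((f(A) - f(AB_i))^2) / (2 V)`. Confidence half-widths come
#' from a bootstrap over sample rows. Failed evaluations (NA) are dropped
#' pairwise and counted.
#'
#' @param fn Function taking a numeric matrix (rows = points, columns =
#'   parameters) and returning one numeric output per row.
#' @param lower,upper Named parameter bounds (sampling is uniform on the
#'   given scale; pass log-bounds and exponentiate inside `fn` for
#'   log-uniform designs).
#' @param n Base sample size.
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for the confidence half-widths.
#' @return A tibble (`sobol_result`): `parameter`, `first_order`,
#'   `total_order`, `first_ci`, `total_ci`; attributes `n`, `n_failed`,
#'   `variance`.
#' @export
sobol_indices <- function(fn, lower, upper, n = 1024, seed = 1,
                          n_boot = 100) {
  stopifnot(length(lower) == length(upper), all(upper >= lower), n >= 8)
  k <- length(lower)
  nms <- names(lower)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  ab <- with_seed(seed, {
    list(A = matrix(stats::runif(n * k), n, k),
         B = matrix(stats::runif(n * k), n, k))
  })
  scale_mat <- function(u)
    sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  A <- scale_mat(ab$A)
  B <- scale_mat(ab$B)
  fA <- fn(A)
  fB <- fn(B)
  fAB <- matrix(NA_real_, n, k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fAB[, i] <- fn(ABi)
  }
  n_failed <- sum(is.na(c(fA, fB, fAB)))
  est <- function(rows) {
    a <- fA[rows]; b <- fB[rows]; ab_m <- fAB[rows, , drop = FALSE]
    v <- stats::var(c(a, b), na.rm = TRUE)
    ctr <- mean(c(a, b), na.rm = TRUE) # centering cuts estimator variance
    b_c <- b - ctr
    first <- vapply(seq_len(k), function(i)
      mean(b_c * (ab_m[, i] - a), na.rm = TRUE) / v, numeric(1))
    total <- vapply(seq_len(k), function(i)
      mean((a - ab_m[, i])^2, na.rm = TRUE) / (2 * v), numeric(1))
    list(first = first, total = total, v = v)
  }
  point <- est(seq_len(n))
  boots <- with_seed(seed + 1, {
    replicate(n_boot, {
      e <- est(sample.int(n, n, replace = TRUE))
      c(e$first, e$total)
    })
  })
  ci <- 1.96 * apply(boots, 1, stats::sd)
  out <- tibble::tibble(
    parameter = nms,
    first_order = point$first,
    total_order = point$total,
    first_ci = ci[seq_len(k)],
    total_ci = ci[k + seq_len(k)])
  attr(out, "n") <- n
  attr(out, "n_failed") <- n_failed
  attr(out, "variance") <- point$v
  class(out) <- c("sobol_result", class(out))
  out
}

#' Global Sobol analysis of the steady-state score
#'
#' Saltelli sampling in log-parameter space over the varied-parameter bounds
#' (the bounds span orders of magnitude), with the steady-state model
#' DAS28-CRP as output. Non-converged steady states are returned as NA and
#' excluded pairwise by the estimators, with the count reported.
#'
#' @param net An [ra_network()].
#' @param bounds Parameter-bounds tibble; subset the rows to analyse fewer
#'   parameters.
#' @param n Base sample size (default 256 at desk scale).
#' @param seed Integer seed.
#' @param base Reference patient supplying unvaried parameters.
#' @param score_params [score_parameters()].
#' @return A `sobol_result` tibble (see [sobol_indices()]).
#' @export
sobol_analysis <- function(net, bounds = parameter_bounds(), n = 256,
                           seed = 1, base = reference_patient(net),
                           score_params = score_parameters()) {
  frozen <- bounds$lb == bounds$ub
  fn <- function(m) {
    vapply(seq_len(nrow(m)), function(r) {
      ov <- stats::setNames(exp(m[r, ]), bounds$name)
      pat <- virtual_patient(ov, base = base, id = sprintf("sobol%d", r))
      ss <- solve_steady_state(net, pat, method = "fixed")
      if (!ss$converged) return(NA_real_)
      das28(ss$state, score_params)
    }, numeric(1))
  }
  res <- sobol_indices(fn, stats::setNames(log(bounds$lb), bounds$name),
                       stats::setNames(log(bounds$ub), bounds$name),
                       n = n, seed = seed)
  # a frozen parameter (lb == ub) has exactly zero indices
  res$first_order[frozen] <- 0
  res$total_order[frozen] <- 0
  res$first_ci[frozen] <- 0
  res$total_ci[frozen] <- 0
  res
}
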