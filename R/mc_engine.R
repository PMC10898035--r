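#' Deterministic sub-seed derivation
#'
#' Counter-based Lehmer-style mix used throughout the Monte Carlo engine so
#' that every grid cell and every replicate is independently reproducible
#' from one base seed: `(base * 48271 + index) mod (2^31 - 1)`.
#'
#' @param base Integer base seed.
#' @param index Nonnegative integer counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
sub_seed <- function(base, index) {
  m <- 2147483647
  as.integer((as.numeric(base) %% m * 48271 + as.numeric(index)) %% m)
}

.generators <- list(
  baseline = generate_baseline_panel,
  se_violation = generate_se_violation_panel,
  ct_violation = generate_ct_violation_panel
)

.estimator_funs <- list(
  concurrent_cc = function(panel) concurrent_change_change(panel, 1L, 0L),
  change_score = change_score,
  lagged_cc = lagged_change_change,
  cross_sectional = function(panel) cross_sectional(panel, 0L)
)

check_cell_compatible <- function(dgp_id, estimator_id, params) {
  if (estimator_id == "lagged_cc" && dgp_id != "baseline")
    stop("run_cell: estimator 'lagged_cc' needs the 3-wave baseline process, not '",
         dgp_id, "'", call. = FALSE)
  want_waves <- if (dgp_id == "baseline") 3L else 2L
  if (params$waves != want_waves)
    stop("run_cell: process '", dgp_id, "' requires waves = ", want_waves,
         call. = FALSE)
  invisible(TRUE)
}

#' Run one Monte Carlo cell
#'
#' Generates `replicates` independent panels from one data-generating process
#' at fixed parameters, fits one estimator to each, and aggregates the
#' exposure-term (x) coefficient: its mean, its empirical standard deviation
#' across replicates, and the mean of the model-based standard errors.
#' Replicate r uses seed `sub_seed(base_seed, r)`, so the cell is
#' reproducible in isolation.
#'
#' @param dgp_id `"baseline"`, `"se_violation"` or `"ct_violation"`.
#' @param params A [dgp_params()] object (waves must match the process:
#'   3 for baseline, 2 otherwise).
#' @param estimator_id `"concurrent_cc"`, `"change_score"`, `"lagged_cc"`
#'   or `"cross_sectional"`. `lagged_cc` requires the baseline process.
#' @param replicates Number of Monte Carlo replicates (default 1000).
#' @param base_seed Integer base seed for the cell.
#' @return A one-row data frame (class `cell_summary`) with columns
#'   `dgp, estimator, mean_estimate, empirical_sd, mean_model_se, replicates`.
#' @examples
#' run_cell("baseline", dgp_params(theta = 1, n = 200), "concurrent_cc",
#'          replicates = 20, base_seed = 1)
#' @export
run_cell <- function(dgp_id, params, estimator_id, replicates = 1000L,
                     base_seed = 1L) {
  dgp_id <- match.arg(dgp_id, names(.generators))
  estimator_id <- match.arg(estimator_id, names(.estimator_funs))
  params <- as_dgp_params(params)
  replicates <- as.integer(replicates)
  if (replicates < 1L)
    stop("run_cell: replicates must be >= 1", call. = FALSE)
  check_cell_compatible(dgp_id, estimator_id, params)
  gen <- .generators[[dgp_id]]
  est <- .estimator_funs[[estimator_id]]
  b <- numeric(replicates)
  se <- numeric(replicates)
  for (r in seq_len(replicates)) {
    panel <- gen(params, seed = sub_seed(base_seed, r))
    fit <- est(panel)
    b[r] <- fit$coefficients[["x"]]
    se[r] <- fit$std_errors[["x"]]
  }
  out <- data.frame(dgp = dgp_id,
                    estimator = estimator_id,
                    mean_estimate = mean(b),
                    empirical_sd = stats::sd(b),
                    mean_model_se = mean(se),
                    replicates = replicates)
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Specify a Monte Carlo grid experiment
#'
#' Describes one simulation experiment: a data-generating process, a
#' structural parameter to sweep, the grid of values, the estimators to run,
#' and the replication budget. The three canonical experiments are the
#' confounding sweep (baseline process, `theta` from 0 to 1 by 0.1, all four
#' estimators), the strict-exogeneity sweep (`rho` from 0 to 1 by 0.1,
#' concurrent estimator, `theta = 1`) and the common-trend sweep (`omega`
#' from -1 to 1 by 0.2, concurrent estimator, `theta = 1`).
#'
#' @param dgp_id Process identifier (see [run_cell()]).
#' @param varied_parameter Name of the [dgp_params()] field swept over the
#'   grid (one of `theta`, `rho`, `omega`, or any scalar structural field).
#' @param values Numeric grid values.
#' @param estimator_ids Character vector of estimator identifiers.
#' @param params Base [dgp_params()]; the varied field is overwritten per
#'   cell.
#' @param replicates Replicates per cell (default 1000).
#' @param base_seed Base seed; each cell derives its own seed from it.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(dgp_id, varied_parameter, values, estimator_ids,
                      params = dgp_params(), replicates = 1000L,
                      base_seed = 1L) {
  dgp_id <- match.arg(dgp_id, names(.generators))
  estimator_ids <- vapply(estimator_ids,
                          function(e) match.arg(e, names(.estimator_funs)),
                          character(1), USE.NAMES = FALSE)
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values) || any(!is.finite(values)))
    stop("grid_spec: grid values must be finite", call. = FALSE)
  if (!varied_parameter %in% names(params) ||
      !is.numeric(params[[varied_parameter]]) ||
      length(params[[varied_parameter]]) != 1L)
    stop("grid_spec: '", varied_parameter,
         "' is not a scalar parameter field", call. = FALSE)
  if (as.integer(replicates) < 1L)
    stop("grid_spec: replicates must be >= 1", call. = FALSE)
  structure(list(dgp_id = dgp_id, varied_parameter = varied_parameter,
                 values = values, estimator_ids = estimator_ids,
                 params = as_dgp_params(params),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "grid_spec")
}

#' Run a Monte Carlo grid experiment
#'
#' Executes every (grid value, estimator) cell of a [grid_spec()],
#' sequentially and independently: cell j receives base seed
#' `sub_seed(spec$base_seed, j * 100000)` so any single cell can be re-run
#' in isolation and reproduced exactly.
#'
#' @param spec A [grid_spec()] object.
#' @param oracle If `TRUE`, append an `oracle_plim` column with the
#'   closed-form probability limit ([expected_probability_limit()]) for each
#'   cell.
#' @return A data frame of cell summaries ordered by (parameter value,
#'   estimator), with columns `dgp, parameter_name, parameter_value,
#'   estimator, mean_estimate, empirical_sd, mean_model_se, replicates`
#'   (plus `oracle_plim` when requested).
#' @examples
#' spec <- grid_spec("baseline", "theta", c(0, 1), "concurrent_cc",
#'                   params = dgp_params(n = 200), replicates = 20)
#' run_grid(spec)
#' @export
run_grid <- function(spec, oracle = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- vector("list", length(spec$values) * length(spec$estimator_ids))
  k <- 0L
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    params_v <- spec$params
    params_v[[spec$varied_parameter]] <- v
    validate_dgp_params(params_v)
    for (e in spec$estimator_ids) {
      k <- k + 1L
      cell_seed <- sub_seed(spec$base_seed, k * 100000)
      cell <- tryCatch(
        run_cell(spec$dgp_id, params_v, e, spec$replicates, cell_seed),
        error = function(err) stop("run_grid: cell (", spec$varied_parameter,
                                   " = ", v, ", estimator = ", e, "): ",
                                   conditionMessage(err), call. = FALSE))
      cell <- cbind(cell[, "dgp", drop = FALSE],
                    parameter_name = spec$varied_parameter,
                    parameter_value = v,
                    cell[, c("estimator", "mean_estimate", "empirical_sd",
                             "mean_model_se", "replicates")])
      if (isTRUE(oracle))
        cell$oracle_plim <-
          expected_probability_limit(e, spec$dgp_id, params_v)
      cells[[k]] <- cell
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}
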