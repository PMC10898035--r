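#' Parameters of the panel data-generating processes
#'
#' Bundles the structural coefficients and noise scales shared by the three
#' synthetic data-generating processes (DGPs): the baseline
#' heterogeneity DGP, the strict-exogeneity (SE) violation DGP with a lagged
#' outcome term, and the common-trend (CT) violation DGP with an individual
#' time-varying confounder.
#'
#' The baseline process, for individual i at wave t, is
#' \deqn{x_{it} = \delta z_{it} + \theta u_i + \nu_{it}}
#' \deqn{y_{it} = \beta x_{it} + \gamma z_{it} + u_i + \lambda_t + \epsilon_{it}}
#' with \eqn{z, u, \nu, \epsilon} independent normals. `theta` scales the
#' loading of the unobserved individual heterogeneity \eqn{u_i} on the
#' exposure and hence the strength of unobserved time-invariant confounding;
#' the loading of \eqn{u_i} on the outcome is fixed at `u_effect_on_y`
#' (1 by default).
#'
#' @param beta Effect of exposure x on outcome y (default 1).
#' @param gamma Effect of the observed covariate z on y (default 1).
#' @param delta Effect of z on x (default 0.5).
#' @param theta Loading of the unobserved heterogeneity u on x; confounding
#'   strength (default 0).
#' @param rho Effect of the lagged outcome \eqn{y_{t-1}} on \eqn{y_t}; used
#'   only by the SE-violation DGP (default 0).
#' @param omega Outcome loading of the individual time-varying confounder
#'   \eqn{\lambda_{it}}; used only by the CT-violation DGP (default 0).
#' @param lambda_t Common time effects \eqn{\lambda_t}, one per wave
#'   (default `c(0.5, 1, 1.5)`); its length must be at least `waves`.
#' @param u_effect_on_y Loading of u on y, fixed at 1 in the structural model
#'   but exposed for sensitivity checks.
#' @param sd_z,sd_u,sd_nu,sd_eps,sd_lambda_it Standard deviations of the
#'   normal draws; all default to 1 (standard normal).
#' @param n Number of individuals per generated dataset (default 1000).
#' @param waves Number of panel waves, 2 or 3 (default 3).
#'
#' @return An object of class `dgp_params` (a validated named list).
#' @seealso [generate_baseline_panel()], [generate_se_violation_panel()],
#'   [generate_ct_violation_panel()]
#' @examples
#' p <- dgp_params(theta = 0.5)
#' p$theta
#' @export
dgp_params <- function(beta = 1, gamma = 1, delta = 0.5, theta = 0,
                       rho = 0, omega = 0, lambda_t = c(0.5, 1, 1.5),
                       u_effect_on_y = 1,
                       sd_z = 1, sd_u = 1, sd_nu = 1, sd_eps = 1,
                       sd_lambda_it = 1, n = 1000L, waves = 3L) {
  p <- list(beta = beta, gamma = gamma, delta = delta, theta = theta,
            rho = rho, omega = omega, lambda_t = as.numeric(lambda_t),
            u_effect_on_y = u_effect_on_y,
            sd_z = sd_z, sd_u = sd_u, sd_nu = sd_nu, sd_eps = sd_eps,
            sd_lambda_it = sd_lambda_it,
            n = as.integer(n), waves = as.integer(waves))
  validate_dgp_params(p)
  class(p) <- "dgp_params"
  p
}

validate_dgp_params <- function(p) {
  for (f in c("beta", "gamma", "delta", "theta", "rho", "omega",
              "u_effect_on_y")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("dgp_params: field '", f, "' must be a single finite number",
           call. = FALSE)
  }
  for (f in c("sd_z", "sd_u", "sd_nu", "sd_eps", "sd_lambda_it")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dgp_params: field '", f, "' must be strictly positive",
           call. = FALSE)
  }
  if (is.na(p$n) || p$n < 2L)
    stop("dgp_params: field 'n' must be an integer >= 2", call. = FALSE)
  if (is.na(p$waves) || !p$waves %in% c(2L, 3L))
    stop("dgp_params: field 'waves' must be 2 or 3", call. = FALSE)
  if (anyNA(p$lambda_t) || length(p$lambda_t) < p$waves)
    stop("dgp_params: field 'lambda_t' must supply one finite value per wave",
         call. = FALSE)
  invisible(p)
}

#' @export
print.dgp_params <- function(x, ...) {
  cat("Panel DGP parameters\n")
  cat(sprintf("  structural: beta=%g gamma=%g delta=%g theta=%g rho=%g omega=%g\n",
              x$beta, x$gamma, x$delta, x$theta, x$rho, x$omega))
  cat(sprintf("  time effects lambda_t: %s\n",
              paste(x$lambda_t, collapse = ", ")))
  cat(sprintf("  n=%d individuals, %d waves; all sd's: z=%g u=%g nu=%g eps=%g lambda_it=%g\n",
              x$n, x$waves, x$sd_z, x$sd_u, x$sd_nu, x$sd_eps, x$sd_lambda_it))
  invisible(x)
}

# Construct the panel_data container: the observable long-format frame plus a
# quarantined latent frame (u, lambda_it, y_init) that estimators never see.
new_panel_data <- function(df, latent, params, seed, dgp_id) {
  rownames(df) <- NULL
  structure(df,
            class = c("panel_data", "data.frame"),
            latent = latent,
            params = params,
            seed = seed,
            dgp_id = dgp_id)
}

long_format <- function(id, wave_mat_cols, n, waves) {
  # wave_mat_cols: named list of n x waves matrices -> long frame sorted by
  # (id, wave), wave coded 0..waves-1
  out <- data.frame(
    id = rep(seq_len(n), each = waves),
    wave = rep(0:(waves - 1L), times = n)
  )
  for (nm in names(wave_mat_cols)) {
    out[[nm]] <- as.vector(t(wave_mat_cols[[nm]]))
  }
  out
}

#' Generate a balanced panel from the baseline heterogeneity process
#'
#' Draws a three-wave balanced panel under the baseline structural model
#' \eqn{x_{it} = \delta z_{it} + \theta u_i + \nu_{it}},
#' \eqn{y_{it} = \beta x_{it} + \gamma z_{it} + u_i + \lambda_t + \epsilon_{it}}.
#' The parameters `rho` and `omega` are ignored here.
#'
#' @param params A [dgp_params()] object with `waves = 3`.
#' @param seed Integer seed; output is bit-identical for identical
#'   `(params, seed)`.
#' @return A `panel_data` object: a long-format data frame with columns
#'   `id, wave, x, y, z`, carrying the latent heterogeneity `u` and
#'   provenance (`params`, `seed`) as attributes.
#' @examples
#' pan <- generate_baseline_panel(dgp_params(theta = 1, n = 200), seed = 1)
#' head(pan)
#' @export
generate_baseline_panel <- function(params, seed) {
  params <- as_dgp_params(params)
  if (params$waves != 3L)
    stop("generate_baseline_panel: field 'waves' must be 3 for the baseline process",
         call. = FALSE)
  n <- params$n
  set.seed(as.integer(seed))
  u   <- stats::rnorm(n, sd = params$sd_u)
  z   <- matrix(stats::rnorm(n * 3L, sd = params$sd_z), n, 3L)
  nu  <- matrix(stats::rnorm(n * 3L, sd = params$sd_nu), n, 3L)
  eps <- matrix(stats::rnorm(n * 3L, sd = params$sd_eps), n, 3L)
  x <- params$delta * z + params$theta * u + nu
  y <- params$beta * x + params$gamma * z + params$u_effect_on_y * u +
    matrix(params$lambda_t[1:3], n, 3L, byrow = TRUE) + eps
  df <- long_format(n = n, waves = 3L,
                    wave_mat_cols = list(x = x, y = y, z = z))
  latent <- data.frame(id = seq_len(n), u = u)
  new_panel_data(df, latent, params, as.integer(seed), "baseline")
}

#' Generate a panel violating strict exogeneity (lagged outcome)
#'
#' Draws a two-wave balanced panel where the outcome depends on its own lag:
#' \eqn{y_{it} = \beta x_{it} + \gamma z_{it} + \rho y_{i,t-1} + u_i +
#' \lambda_t + \epsilon_{it}}, with the pre-sample outcome
#' \eqn{y_{i,-1} = u_i + \epsilon_{i,-1}}. The lag term breaks the strict
#' exogeneity assumption of the first-difference (concurrent change-change)
#' estimator whenever `rho != 0`.
#'
#' @inheritParams generate_baseline_panel
#' @param params A [dgp_params()] object with `waves = 2`; `rho` sets the
#'   violation strength.
#' @return A `panel_data` object (two waves); the latent frame carries `u`
#'   and the initial outcome `y_init`.
#' @export
generate_se_violation_panel <- function(params, seed) {
  params <- as_dgp_params(params)
  if (params$waves != 2L)
    stop("generate_se_violation_panel: field 'waves' must be 2 for the SE-violation process",
         call. = FALSE)
  n <- params$n
  set.seed(as.integer(seed))
  u        <- stats::rnorm(n, sd = params$sd_u)
  z        <- matrix(stats::rnorm(n * 2L, sd = params$sd_z), n, 2L)
  nu       <- matrix(stats::rnorm(n * 2L, sd = params$sd_nu), n, 2L)
  eps_init <- stats::rnorm(n, sd = params$sd_eps)
  eps      <- matrix(stats::rnorm(n * 2L, sd = params$sd_eps), n, 2L)
  x <- params$delta * z + params$theta * u + nu
  y_init <- u + eps_init
  y <- matrix(0, n, 2L)
  y[, 1L] <- params$beta * x[, 1L] + params$gamma * z[, 1L] +
    params$rho * y_init + params$u_effect_on_y * u +
    params$lambda_t[1L] + eps[, 1L]
  y[, 2L] <- params$beta * x[, 2L] + params$gamma * z[, 2L] +
    params$rho * y[, 1L] + params$u_effect_on_y * u +
    params$lambda_t[2L] + eps[, 2L]
  df <- long_format(n = n, waves = 2L,
                    wave_mat_cols = list(x = x, y = y, z = z))
  latent <- data.frame(id = seq_len(n), u = u, y_init = y_init)
  new_panel_data(df, latent, params, as.integer(seed), "se_violation")
}

#' Generate a panel violating the common-trend assumption
#'
#' Draws a two-wave balanced panel with an unobserved individual time-varying
#' confounder \eqn{\lambda_{it} \sim N(0, 1)} entering both equations:
#' \eqn{x_{it} = \delta z_{it} + \theta u_i + \lambda_{it} + \nu_{it}},
#' \eqn{y_{it} = \beta x_{it} + \gamma z_{it} + u_i + \omega \lambda_{it} +
#' \epsilon_{it}}. Heterogeneous time effects break the common-trend
#' assumption whenever `omega != 0`. Following the structural equations, no
#' common time effect enters this process (the individual term replaces it).
#'
#' @inheritParams generate_baseline_panel
#' @param params A [dgp_params()] object with `waves = 2`; `omega` sets the
#'   violation strength and direction.
#' @return A `panel_data` object (two waves); the latent frame carries `u`
#'   and `lambda_it` per (id, wave).
#' @export
generate_ct_violation_panel <- function(params, seed) {
  params <- as_dgp_params(params)
  if (params$waves != 2L)
    stop("generate_ct_violation_panel: field 'waves' must be 2 for the CT-violation process",
         call. = FALSE)
  n <- params$n
  set.seed(as.integer(seed))
  u   <- stats::rnorm(n, sd = params$sd_u)
  z   <- matrix(stats::rnorm(n * 2L, sd = params$sd_z), n, 2L)
  lam <- matrix(stats::rnorm(n * 2L, sd = params$sd_lambda_it), n, 2L)
  nu  <- matrix(stats::rnorm(n * 2L, sd = params$sd_nu), n, 2L)
  eps <- matrix(stats::rnorm(n * 2L, sd = params$sd_eps), n, 2L)
  x <- params$delta * z + params$theta * u + lam + nu
  y <- params$beta * x + params$gamma * z + params$u_effect_on_y * u +
    params$omega * lam + eps
  df <- long_format(n = n, waves = 2L,
                    wave_mat_cols = list(x = x, y = y, z = z))
  latent <- data.frame(id = rep(seq_len(n), each = 2L),
                       wave = rep(0:1, times = n),
                       lambda_it = as.vector(t(lam)))
  latent_u <- data.frame(id = seq_len(n), u = u)
  pan <- new_panel_data(df, latent, params, as.integer(seed), "ct_violation")
  attr(pan, "latent_u") <- latent_u
  pan
}

as_dgp_params <- function(params) {
  if (inherits(params, "dgp_params")) {
    validate_dgp_params(params)
    return(params)
  }
  if (is.list(params)) return(do.call(dgp_params, params))
  stop("expected a dgp_params object", call. = FALSE)
}

#' Latent diagnostic columns of a generated panel
#'
#' Returns the latent variables retained by a generator (the individual
#' heterogeneity `u`, the time-varying confounder `lambda_it`, the initial
#' outcome `y_init`, whichever apply). These never appear in the observable
#' frame, so estimators cannot consume them.
#'
#' @param panel A `panel_data` object.
#' @return A data frame of latent columns keyed by `id` (and `wave` where the
#'   latent varies over waves).
#' @export
panel_latent <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  attr(panel, "latent")
}

#' @export
print.panel_data <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Balanced synthetic panel ('%s' process): %d individuals x %d waves, seed %d\n",
              attr(x, "dgp_id"), p$n, p$waves, attr(x, "seed")))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Write / read a panel as delimited text
#'
#' Serializes the observable long-format table (columns `id, wave, x, y, z`,
#' one header row, comma-separated, UTF-8). Latent diagnostic columns are
#' written only on request and are moved back into the latent attribute on
#' reading, so round-trips never leak them to estimators.
#'
#' @param panel A `panel_data` object (or a plain long-format data frame with
#'   the observable columns).
#' @param path File path.
#' @param include_latent If `TRUE`, latent columns are merged into the file.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   `panel_data` object.
#' @export
write_panel <- function(panel, path, include_latent = FALSE) {
  df <- as.data.frame(panel)[, c("id", "wave", "x", "y", "z")]
  if (isTRUE(include_latent) && inherits(panel, "panel_data")) {
    lat <- panel_latent(panel)
    if (!is.null(lat)) {
      by <- intersect(c("id", "wave"), names(lat))
      df <- merge(df, lat, by = by, sort = FALSE)
      lu <- attr(panel, "latent_u")
      if (!is.null(lu)) df <- merge(df, lu, by = "id", sort = FALSE)
      df <- df[order(df$id, df$wave), ]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("id", "wave", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_panel: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lat_cols <- intersect(c("u", "lambda_it", "y_init"), names(df))
  latent <- NULL
  if (length(lat_cols)) {
    latent <- unique(df[, c("id", "wave", lat_cols)])
    # u and y_init are wave-constant; keep one row per id for them
    df <- df[, need]
  } else {
    df <- df[, need]
  }
  df <- df[order(df$id, df$wave), ]
  counts <- table(df$id)
  if (length(unique(counts)) != 1L)
    stop("read_panel: panel is not balanced", call. = FALSE)
  waves <- as.integer(unique(counts))
  params <- dgp_params(n = length(counts), waves = waves)
  new_panel_data(df, latent, params, NA_integer_, "external")
}
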