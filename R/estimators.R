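#' Ordinary least squares with classical standard errors
#'
#' Minimal QR-based OLS core shared by the four analysis models. The design
#' matrix must carry a leading intercept column when an intercept is wanted;
#' classical (homoskedastic) standard errors use the residual variance with
#' denominator `nrow - ncol`.
#'
#' @param response Numeric response vector.
#' @param design Numeric design matrix, one row per observation.
#' @param term_names Names for the columns of `design`; defaults to its
#'   column names.
#' @return A list with `coefficients` and `std_errors` (named numeric
#'   vectors), `sigma` (residual standard deviation), `df_residual` and
#'   `n_used`.
#' @examples
#' fit_ols(c(1, 3, 5), cbind(intercept = 1, x = 0:2))$coefficients
#' @export
fit_ols <- function(response, design, term_names = colnames(design)) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  n <- nrow(design)
  p <- ncol(design)
  if (length(response) != n)
    stop("fit_ols: response length (", length(response),
         ") must equal design rows (", n, ")", call. = FALSE)
  if (is.null(term_names)) term_names <- paste0("term", seq_len(p))
  if (n < p)
    stop("fit_ols: insufficient data: ", n, " rows for ", p, " columns",
         call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < p) {
    bad <- term_names[qrd$pivot[(qrd$rank + 1L):p]]
    stop("fit_ols: singular design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrd, response)
  resid <- response - design %*% coefs
  dfres <- n - p
  sigma2 <- if (dfres > 0) sum(resid^2) / dfres else NaN
  # (X'X)^{-1} from the R factor of the pivoted QR decomposition
  Rinv <- backsolve(qr.R(qrd), diag(p))
  xtx_inv <- Rinv %*% t(Rinv)
  unpiv <- order(qrd$pivot)
  se <- sqrt(sigma2 * diag(xtx_inv))[unpiv]
  coefs <- as.numeric(coefs)
  names(coefs) <- term_names
  names(se) <- term_names
  list(coefficients = coefs, std_errors = se,
       sigma = sqrt(sigma2), df_residual = dfres, n_used = n)
}

new_fit_result <- function(model_id, ols, waves_used) {
  structure(list(model_id = model_id,
                 coefficients = ols$coefficients,
                 std_errors = ols$std_errors,
                 sigma = ols$sigma,
                 n_used = ols$n_used,
                 waves_used = sort(unique(as.integer(waves_used)))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  labels <- c(concurrent_cc = "concurrent change-change (first difference)",
              change_score = "change score",
              lagged_cc = "lagged change-change",
              cross_sectional = "cross-sectional")
  cat(sprintf("Fit: %s, n = %d individuals, waves {%s}\n",
              labels[[x$model_id]], x$n_used,
              paste(x$waves_used, collapse = ",")))
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$coefficients

# Accept a panel_data or a plain long-format table. A plain table carrying
# latent column names is rejected: those columns exist for diagnostics only
# and must never reach an estimator.
as_estimation_frame <- function(panel) {
  df <- as.data.frame(panel)
  latent_here <- intersect(c("u", "lambda_it", "y_init"), names(df))
  if (!inherits(panel, "panel_data") && length(latent_here))
    stop("latent column(s) ", paste(latent_here, collapse = ", "),
         " are diagnostics and cannot be used for estimation; remove them",
         call. = FALSE)
  need <- c("id", "wave", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel table must contain column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, need]
  class(df) <- "data.frame"
  attributes(df)[c("latent", "params", "seed", "dgp_id", "latent_u")] <- NULL
  df
}

# One row per individual for a given wave, aligned by id order.
wave_slice <- function(df, wave) {
  s <- df[df$wave == wave, ]
  if (nrow(s) == 0L)
    stop("wave ", wave, " not found in panel", call. = FALSE)
  s[order(s$id), ]
}

#' Concurrent change-change (first-difference) analysis
#'
#' Regresses the outcome change on the exposure change and covariate change
#' over the same interval:
#' \eqn{\Delta y = \alpha + \beta \Delta x + \gamma \Delta z}. This is the
#' two-wave first-difference fixed-effects estimator; differencing removes
#' any individual-constant term, so unobserved time-invariant confounding
#' cannot bias the slope. The intercept estimates the change in common time
#' effects \eqn{\lambda_{later} - \lambda_{earlier}}.
#'
#' @param panel A `panel_data` object or long-format data frame with columns
#'   `id, wave, x, y, z`.
#' @param later_wave,earlier_wave Waves to difference (later minus earlier);
#'   defaults 1 and 0.
#' @return A `fit_result` with coefficients named `intercept`, `x`
#'   (the contemporaneous-effect estimate) and `z`.
#' @examples
#' pan <- generate_baseline_panel(dgp_params(theta = 1, n = 400), seed = 7)
#' concurrent_change_change(pan)
#' @export
concurrent_change_change <- function(panel, later_wave = 1L, earlier_wave = 0L) {
  if (later_wave <= earlier_wave)
    stop("later_wave must exceed earlier_wave", call. = FALSE)
  df <- as_estimation_frame(panel)
  a <- wave_slice(df, later_wave)
  b <- wave_slice(df, earlier_wave)
  ols <- fit_ols(a$y - b$y,
                 cbind(intercept = 1, x = a$x - b$x, z = a$z - b$z))
  new_fit_result("concurrent_cc", ols, c(earlier_wave, later_wave))
}

#' Change-score analysis
#'
#' Regresses the outcome change between waves 0 and 1 on the baseline
#' exposure and baseline covariate:
#' \eqn{y_1 - y_0 = \alpha^* + \beta^* x_0 + \gamma^* z_0}. Common in
#' cohort studies, but its slope does not estimate the contemporaneous
#' effect: under the baseline process its probability limit is
#' \eqn{-\beta \sigma_\nu^2 / (\theta^2 \sigma_u^2 + \sigma_\nu^2)}.
#'
#' @inheritParams concurrent_change_change
#' @return A `fit_result` with coefficients `intercept`, `x` (baseline
#'   exposure) and `z` (baseline covariate).
#' @export
change_score <- function(panel) {
  df <- as_estimation_frame(panel)
  a <- wave_slice(df, 1L)
  b <- wave_slice(df, 0L)
  ols <- fit_ols(a$y - b$y, cbind(intercept = 1, x = b$x, z = b$z))
  new_fit_result("change_score", ols, c(0L, 1L))
}

#' Lagged change-change analysis
#'
#' Regresses the later outcome change on the previous interval's exposure
#' change:
#' \eqn{y_2 - y_1 = \alpha^{**} + \beta^{**} (x_1 - x_0) + \gamma^{**}
#' (z_1 - z_0)}. Requires three waves. Consistent when the exposure truly
#' acts with a one-period lag; under the concurrent-effect baseline process
#' its probability limit is \eqn{-\beta/2} regardless of confounding
#' strength.
#'
#' @inheritParams concurrent_change_change
#' @return A `fit_result` with coefficients `intercept`, `x` (lagged exposure
#'   change) and `z`.
#' @export
lagged_change_change <- function(panel) {
  df <- as_estimation_frame(panel)
  if (length(unique(df$wave)) < 3L)
    stop("lagged_change_change: needs 3 waves, found ",
         length(unique(df$wave)), call. = FALSE)
  w0 <- wave_slice(df, 0L)
  w1 <- wave_slice(df, 1L)
  w2 <- wave_slice(df, 2L)
  ols <- fit_ols(w2$y - w1$y,
                 cbind(intercept = 1, x = w1$x - w0$x, z = w1$z - w0$z))
  new_fit_result("lagged_cc", ols, 0:2)
}

#' Cross-sectional analysis
#'
#' Regresses the outcome on exposure and covariate at a single wave:
#' \eqn{y_0 = \alpha^{***} + \beta^{***} x_0 + \gamma^{***} z_0}. Unbiased
#' for the contemporaneous effect only without unobserved confounding; under
#' the baseline process its probability limit is
#' \eqn{\beta + \theta \sigma_u^2 / (\theta^2 \sigma_u^2 + \sigma_\nu^2)}.
#'
#' @inheritParams concurrent_change_change
#' @param wave Wave to analyse (default 0).
#' @return A `fit_result` with coefficients `intercept`, `x` and `z`.
#' @export
cross_sectional <- function(panel, wave = 0L) {
  df <- as_estimation_frame(panel)
  w <- wave_slice(df, wave)
  ols <- fit_ols(w$y, cbind(intercept = 1, x = w$x, z = w$z))
  new_fit_result("cross_sectional", ols, wave)
}
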