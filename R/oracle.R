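#' Probability limit of an estimator under a data-generating process
#'
#' Closed-form large-sample limit of the exposure-term (x) coefficient for
#' each supported estimator/process pair, obtained by covariance algebra on
#' the linear structural equations. These limits are the analytic ground
#' truth that every Monte Carlo cell mean must converge to; each formula is
#' validated in the test suite against a single fit at n = 10^6.
#'
#' With general variances the limits are:
#' \describe{
#'   \item{concurrent_cc / baseline}{\eqn{\beta} (differencing removes the
#'     individual heterogeneity entirely).}
#'   \item{cross_sectional / baseline}{\eqn{\beta + \theta \sigma_u^2 /
#'     (\theta^2 \sigma_u^2 + \sigma_\nu^2)}; classical omitted-variable
#'     bias through u. 1.5 at unit variances and \eqn{\theta = 1}.}
#'   \item{change_score / baseline}{\eqn{-\beta \sigma_\nu^2 /
#'     (\theta^2 \sigma_u^2 + \sigma_\nu^2)}: the slope picks up the
#'     subtraction of \eqn{y_0}, attenuated by the confounded part of
#'     \eqn{x_0}. Reduces to \eqn{-\beta/(\theta^2 + 1)} at unit variances.}
#'   \item{lagged_cc / baseline}{\eqn{-\beta/2} for any \eqn{\theta}: the
#'     lagged exposure change only overlaps the current outcome change
#'     through the shared middle wave, with a negative sign.}
#'   \item{concurrent_cc / se_violation}{\eqn{\beta (1 - \rho/2)}: the lag
#'     term feeds \eqn{-\rho \beta \nu_0} into the outcome difference.}
#'   \item{concurrent_cc / ct_violation}{\eqn{\beta + \omega \sigma_\lambda^2
#'     / (\sigma_\lambda^2 + \sigma_\nu^2)}: the differenced individual
#'     trend is an omitted regressor correlated with the exposure change.}
#' }
#'
#' @param estimator_id One of `"concurrent_cc"`, `"change_score"`,
#'   `"lagged_cc"`, `"cross_sectional"`.
#' @param dgp_id One of `"baseline"`, `"se_violation"`, `"ct_violation"`.
#' @param params A [dgp_params()] object supplying the structural
#'   coefficients and noise scales.
#' @return The probability limit of the x coefficient (a single number).
#' @examples
#' expected_probability_limit("cross_sectional", "baseline",
#'                            dgp_params(theta = 1))
#' @export
expected_probability_limit <- function(estimator_id, dgp_id, params) {
  params <- as_dgp_params(params)
  estimator_id <- match.arg(estimator_id,
                            c("concurrent_cc", "change_score", "lagged_cc",
                              "cross_sectional"))
  dgp_id <- match.arg(dgp_id, c("baseline", "se_violation", "ct_violation"))
  vu <- params$sd_u^2
  vnu <- params$sd_nu^2
  vlam <- params$sd_lambda_it^2
  key <- paste(estimator_id, dgp_id, sep = "/")
  switch(key,
    "concurrent_cc/baseline" = params$beta,
    "cross_sectional/baseline" =
      params$beta + params$theta * params$u_effect_on_y * vu /
        (params$theta^2 * vu + vnu),
    "change_score/baseline" =
      -params$beta * vnu / (params$theta^2 * vu + vnu),
    "lagged_cc/baseline" = -params$beta / 2,
    "concurrent_cc/se_violation" = params$beta * (1 - params$rho / 2),
    "concurrent_cc/ct_violation" =
      params$beta + params$omega * vlam / (vlam + vnu),
    stop("expected_probability_limit: combination '", key,
         "' is not implemented", call. = FALSE)
  )
}
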