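# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: OLS via explicit normal equations, the within
# (individual-demeaned) estimator as the first-difference cross-check, and a
# recursive path-sum for SEM total effects.

# Normal-equations OLS with classical SEs.
brute_ols <- function(y, X) {
  XtX <- crossprod(X)
  coefs <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% coefs
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(coefficients = drop(coefs), std_errors = se)
}

# Two-wave within estimator: demean y, x, z and the wave indicator within
# individual, regress without intercept. Its x and z slopes must equal the
# first-difference (concurrent change-change) slopes exactly.
within_two_wave <- function(panel, later_wave = 1L, earlier_wave = 0L) {
  df <- as.data.frame(panel)
  df <- df[df$wave %in% c(earlier_wave, later_wave), ]
  df <- df[order(df$id, df$wave), ]
  dm <- function(v) v - ave(v, df$id)
  tt <- as.numeric(df$wave == later_wave)
  X <- cbind(x = dm(df$x), z = dm(df$z), t = dm(tt))
  drop(solve(crossprod(X), crossprod(X, dm(df$y))))
}

# Total causal effect as an explicit sum over directed paths.
dfs_total_effect <- function(sem, cause, effect) {
  if (cause == effect) return(1)
  kids <- sem$edges[sem$edges$parent == cause, ]
  if (nrow(kids) == 0L) return(0)
  sum(vapply(seq_len(nrow(kids)), function(j) {
    kids$coefficient[j] * dfs_total_effect(sem, kids$child[j], effect)
  }, numeric(1)))
}

# Small default parameter sets reused in tests.
base3 <- function(...) dgp_params(waves = 3L, ...)
base2 <- function(...) dgp_params(waves = 2L, ...)
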