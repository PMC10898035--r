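#' Construct a linear structural equation model over a DAG
#'
#' A linear SEM is a directed acyclic graph with a real coefficient on every
#' edge, an exogenous (disturbance) variance for every variable, and an
#' optional disturbance mean per variable. Each variable equals the
#' coefficient-weighted sum of its parents plus an independent disturbance.
#' Implied first and second moments follow from the structural recursion.
#'
#' @param edges Data frame with columns `parent`, `child`, `coefficient`.
#' @param variances Named numeric vector of exogenous variances, one entry
#'   per variable (variables not appearing in `edges` may be introduced
#'   here).
#' @param means Optional named numeric vector of disturbance means; missing
#'   entries default to 0.
#' @param variables Optional character vector fixing variable order;
#'   defaults to the order of `names(variances)`.
#' @return A `linear_sem` object.
#' @examples
#' sem <- linear_sem(data.frame(parent = "X", child = "Y", coefficient = 2),
#'                   variances = c(X = 1, Y = 1))
#' implied_moments(sem)$covariance
#' @export
linear_sem <- function(edges, variances, means = NULL, variables = NULL) {
  if (nrow(edges) && !all(c("parent", "child", "coefficient") %in% names(edges)))
    stop("linear_sem: edges needs columns parent, child, coefficient",
         call. = FALSE)
  if (is.null(variables)) variables <- names(variances)
  if (is.null(variables) || anyNA(variables) || anyDuplicated(variables))
    stop("linear_sem: variables must be unique and named via variances",
         call. = FALSE)
  extra <- setdiff(unique(c(edges$parent, edges$child)), variables)
  if (length(extra))
    stop("linear_sem: variable(s) in edges lack a variance entry: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (any(variances <= 0))
    stop("linear_sem: exogenous variances must be positive", call. = FALSE)
  m <- stats::setNames(numeric(length(variables)), variables)
  if (!is.null(means)) m[names(means)] <- means
  sem <- structure(list(variables = variables,
                        edges = edges[, c("parent", "child", "coefficient")],
                        variances = variances[variables],
                        means = m),
                   class = "linear_sem")
  sem$topo <- topological_order(sem)  # errors on a cycle
  sem
}

# Kahn's algorithm; errors if the edge set has a cycle.
topological_order <- function(sem) {
  vars <- sem$variables
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (ch in sem$edges$child) indeg[ch] <- indeg[ch] + 1L
  queue <- vars[indeg == 0L]
  order <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    kids <- sem$edges$child[sem$edges$parent == v]
    for (k in kids) {
      indeg2[k] <- indeg2[k] - 1L
      if (indeg2[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != length(vars))
    stop("linear_sem: edge set contains a cycle", call. = FALSE)
  order
}

#' @export
print.linear_sem <- function(x, ...) {
  cat(sprintf("Linear SEM: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$parent, " -> ", x$edges$child,
               " (", signif(x$edges$coefficient, 4), ")", collapse = "\n"),
        "\n")
  invisible(x)
}

# Coefficient matrix B with B[child, parent] = coefficient.
sem_B <- function(sem) {
  v <- sem$variables
  B <- matrix(0, length(v), length(v), dimnames = list(v, v))
  if (nrow(sem$edges))
    B[cbind(match(sem$edges$child, v), match(sem$edges$parent, v))] <-
      sem$edges$coefficient
  B
}

#' Three-wave panel DAG bound to the simulation parameters
#'
#' Builds the linear SEM for a three-wave balanced panel with exposure X,
#' outcome Y, observed covariate Z and unobserved time-invariant
#' heterogeneity U. Per wave t the edges are Z_t -> X_t (`delta`),
#' Z_t -> Y_t (`gamma`), X_t -> Y_t (`beta`), U -> X_t (`theta`) and
#' U -> Y_t (`u_effect_on_y`); there are no cross-wave edges, so all
#' cross-wave dependence flows through U. The common time effects enter as
#' the disturbance means of Y_0, Y_1, Y_2. The implied law of this SEM is
#' exactly the baseline data-generating process at the same parameters.
#'
#' @param params A [dgp_params()] object.
#' @return A `linear_sem` over variables U, Z0, X0, Y0, ..., Z2, X2, Y2.
#' @examples
#' sem <- build_fig1_sem(dgp_params(theta = 1))
#' nrow(sem$edges)  # 15 = 3 waves x 5 edge families
#' @export
build_fig1_sem <- function(params) {
  params <- as_dgp_params(params)
  waves <- 0:2
  edges <- do.call(rbind, lapply(waves, function(t) {
    data.frame(
      parent = c(paste0("Z", t), paste0("Z", t), paste0("X", t), "U", "U"),
      child = c(paste0("X", t), paste0("Y", t), paste0("Y", t),
                paste0("X", t), paste0("Y", t)),
      coefficient = c(params$delta, params$gamma, params$beta,
                      params$theta, params$u_effect_on_y))
  }))
  vars <- c("U", as.vector(vapply(waves, function(t)
    paste0(c("Z", "X", "Y"), t), character(3))))
  variances <- stats::setNames(rep(1, length(vars)), vars)
  variances["U"] <- params$sd_u^2
  variances[paste0("Z", waves)] <- params$sd_z^2
  variances[paste0("X", waves)] <- params$sd_nu^2
  variances[paste0("Y", waves)] <- params$sd_eps^2
  means <- stats::setNames(params$lambda_t[1:3], paste0("Y", waves))
  linear_sem(edges, variances, means)
}

#' Implied moments of a linear SEM
#'
#' Exact implied covariance matrix and mean vector from the structural
#' recursion: with edge-coefficient matrix B, disturbance covariance
#' \eqn{\Psi} and disturbance means m, the implied moments are
#' \eqn{\Sigma = (I-B)^{-1} \Psi (I-B)^{-T}} and
#' \eqn{\mu = (I-B)^{-1} m}.
#'
#' @param sem A [linear_sem()] object.
#' @return A list with `covariance` (symmetric positive semi-definite
#'   matrix) and `means` (named vector), both over `sem$variables`.
#' @export
implied_moments <- function(sem) {
  stopifnot(inherits(sem, "linear_sem"))
  B <- sem_B(sem)
  A <- solve(diag(nrow(B)) - B)
  Sigma <- A %*% diag(sem$variances, nrow = nrow(B)) %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(sem$variables, sem$variables)
  mu <- drop(A %*% sem$means)
  names(mu) <- sem$variables
  list(covariance = Sigma, means = mu)
}

#' Simulate observations from a linear SEM
#'
#' Samples each variable in topological order as the coefficient-weighted
#' sum of its parents plus a normal disturbance with the variable's
#' exogenous variance and mean.
#'
#' @param sem A [linear_sem()] object.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return A numeric matrix, one column per variable.
#' @export
simulate_sem <- function(sem, n, seed) {
  stopifnot(inherits(sem, "linear_sem"))
  set.seed(as.integer(seed))
  out <- matrix(0, n, length(sem$variables),
                dimnames = list(NULL, sem$variables))
  for (v in sem$topo) {
    val <- stats::rnorm(n, mean = sem$means[[v]],
                        sd = sqrt(sem$variances[[v]]))
    pe <- sem$edges[sem$edges$child == v, ]
    for (j in seq_len(nrow(pe)))
      val <- val + pe$coefficient[j] * out[, pe$parent[j]]
    out[, v] <- val
  }
  out
}

#' Define a contrast between two SEM variables
#'
#' A contrast such as \eqn{\Delta Y_1 = Y_1 - Y_0} is handled as a linear
#' functional of SEM variables, not as a graph node: effect and path queries
#' against a contrast are run against each component with a +1/-1 weight.
#'
#' @param name Display name (e.g. `"dY1"`).
#' @param positive,negative Names of the positive and negative component
#'   variables.
#' @return A `sem_contrast` object.
#' @examples
#' sem_contrast("dY1", "Y1", "Y0")
#' @export
sem_contrast <- function(name, positive, negative) {
  stopifnot(is.character(positive), is.character(negative),
            length(positive) == 1L, length(negative) == 1L)
  structure(list(name = name, positive = positive, negative = negative),
            class = "sem_contrast")
}

#' @export
print.sem_contrast <- function(x, ...) {
  cat(sprintf("Contrast %s = %s - %s\n", x$name, x$positive, x$negative))
  invisible(x)
}

check_sem_var <- function(sem, v) {
  if (!v %in% sem$variables)
    stop("unknown SEM variable '", v, "'", call. = FALSE)
  v
}

contrast_weights <- function(sem, target) {
  # weight vector over sem$variables for a variable name or sem_contrast
  w <- stats::setNames(numeric(length(sem$variables)), sem$variables)
  if (inherits(target, "sem_contrast")) {
    check_sem_var(sem, target$positive)
    check_sem_var(sem, target$negative)
    w[target$positive] <- 1
    w[target$negative] <- -1
  } else {
    check_sem_var(sem, target)
    w[target] <- 1
  }
  w
}

target_name <- function(target) {
  if (inherits(target, "sem_contrast")) target$name else target
}

#' Total causal effect by path tracing
#'
#' Sum over all directed paths from `cause` to the effect of the products of
#' edge coefficients, computed exactly through the matrix identity
#' \eqn{(I - B)^{-1} = I + B + B^2 + \dots}. For a [sem_contrast()] the
#' total effect is the effect on the positive component minus the effect on
#' the negative component.
#'
#' @param sem A [linear_sem()] object.
#' @param cause Variable name.
#' @param effect Variable name or [sem_contrast()].
#' @return The total causal effect (a single number); 0 when no directed
#'   path exists.
#' @examples
#' sem <- build_fig1_sem(dgp_params())
#' total_effect(sem, "X0", sem_contrast("dY1", "Y1", "Y0"))  # -beta
#' @export
total_effect <- function(sem, cause, effect) {
  stopifnot(inherits(sem, "linear_sem"))
  check_sem_var(sem, cause)
  B <- sem_B(sem)
  A <- solve(diag(nrow(B)) - B)  # A[effect, cause] = total effect
  dimnames(A) <- list(sem$variables, sem$variables)
  w <- contrast_weights(sem, effect)
  eff <- drop(w %*% A[, cause])
  if (!inherits(effect, "sem_contrast") && effect == cause) eff <- eff - 1
  eff
}

#' Population regression from implied moments
#'
#' Least-squares coefficients at infinite data, computed from a SEM's
#' implied covariance matrix and means: for response w'V and regressors
#' given by weight vectors, the slope vector solves the population normal
#' equations and the intercept is the mean residual. This evaluates what
#' each analysis model estimates when handed the exact law of the DAG.
#'
#' @param moments Output of [implied_moments()] (a list with `covariance`
#'   and `means`), or a `linear_sem` (moments are then computed).
#' @param response Variable name or [sem_contrast()].
#' @param regressors List of variable names and/or [sem_contrast()] objects.
#' @return Named numeric vector: `intercept` followed by one coefficient per
#'   regressor (named by variable or contrast name).
#' @examples
#' sem <- build_fig1_sem(dgp_params(theta = 1))
#' dY1 <- sem_contrast("dY1", "Y1", "Y0")
#' dX1 <- sem_contrast("dX1", "X1", "X0")
#' dZ1 <- sem_contrast("dZ1", "Z1", "Z0")
#' regression_from_covariance(sem, dY1, list(dX1, dZ1))
#' @export
regression_from_covariance <- function(moments, response, regressors) {
  if (inherits(moments, "linear_sem")) {
    sem <- moments
    moments <- implied_moments(sem)
  } else {
    sem <- list(variables = colnames(moments$covariance))
  }
  if (!is.list(regressors) || inherits(regressors, "sem_contrast"))
    regressors <- list(regressors)
  wy <- contrast_weights(sem, response)
  W <- vapply(regressors, contrast_weights, numeric(length(sem$variables)),
              sem = sem)
  Sigma <- moments$covariance
  Sxx <- t(W) %*% Sigma %*% W
  Sxy <- t(W) %*% Sigma %*% wy
  b <- tryCatch(drop(solve(Sxx, Sxy)),
                error = function(e)
                  stop("regression_from_covariance: collinear regressors (singular moment submatrix)",
                       call. = FALSE))
  mu <- moments$means
  intercept <- drop(wy %*% mu) - sum(b * drop(t(W) %*% mu))
  out <- c(intercept, b)
  names(out) <- c("intercept", vapply(regressors, target_name, character(1)))
  out
}

# ---- backdoor path enumeration -------------------------------------------

descendants_of <- function(sem, v) {
  # v plus everything reachable by directed edges
  out <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- unique(sem$edges$child[sem$edges$parent %in% frontier])
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# All simple paths from `from` to `to` in the skeleton, tracked with edge
# directions. Returns a list of lists(nodes, dirs) where dirs[k] is "->" if
# the edge between nodes[k] and nodes[k+1] points forward along the path.
simple_paths <- function(sem, from, to) {
  nbrs <- function(v) {
    unique(c(sem$edges$child[sem$edges$parent == v],
             sem$edges$parent[sem$edges$child == v]))
  }
  has_edge <- function(a, b)
    any(sem$edges$parent == a & sem$edges$child == b)
  paths <- list()
  walk <- function(nodes, dirs) {
    v <- nodes[length(nodes)]
    if (v == to) {
      paths[[length(paths) + 1L]] <<- list(nodes = nodes, dirs = dirs)
      return(invisible(NULL))
    }
    for (w in nbrs(v)) {
      if (w %in% nodes) next
      d <- if (has_edge(v, w)) "->" else "<-"
      walk(c(nodes, w), c(dirs, d))
    }
    invisible(NULL)
  }
  walk(from, character(0))
  paths
}

path_string <- function(nodes, dirs) {
  out <- nodes[1L]
  for (k in seq_along(dirs))
    out <- paste(out, dirs[k], nodes[k + 1L])
  out
}

# d-separation status of one path under conditioning set z.
path_status <- function(sem, nodes, dirs, z) {
  if (length(nodes) < 3L) {
    return(list(status = "open", blocked_by = character(0)))
  }
  blockers <- character(0)
  desc <- lapply(stats::setNames(nodes, nodes), function(v)
    descendants_of(sem, v))
  for (k in 2:(length(nodes) - 1L)) {
    v <- nodes[k]
    collider <- dirs[k - 1L] == "->" && dirs[k] == "<-"
    if (collider) {
      opened <- any(desc[[v]] %in% z)
      if (!opened) blockers <- c(blockers, v)
    } else {
      if (v %in% z) blockers <- c(blockers, v)
    }
  }
  list(status = if (length(blockers)) "blocked" else "open",
       blocked_by = blockers)
}

#' Enumerate noncausal (backdoor) paths with d-separation status
#'
#' Lists every simple path between the cause and the effect (or each
#' component of an effect contrast) whose first edge points into the cause,
#' and labels each as open or blocked under the conditioning set by the
#' d-separation rules: a non-collider blocks when conditioned on; a collider
#' blocks unless it (or a descendant) is conditioned on.
#'
#' @param sem A [linear_sem()] object.
#' @param cause Variable name.
#' @param effect Variable name or [sem_contrast()]; for a contrast, paths to
#'   each component are returned with the component's +1/-1 weight.
#' @param conditioning Character vector of conditioned variables (may be
#'   empty); conditioning on the cause or effect is an error.
#' @return A data frame with columns `component`, `weight`, `path`
#'   (arrow-notation string, e.g. `"X0 <- U -> Y0"`), `status`
#'   (`"open"`/`"blocked"`) and `blocked_by` (comma-separated blockers).
#' @examples
#' sem <- build_fig1_sem(dgp_params(theta = 1))
#' enumerate_noncausal_paths(sem, "X0", sem_contrast("dY1", "Y1", "Y0"),
#'                           conditioning = c("Z0", "X1", "Z1"))
#' @export
enumerate_noncausal_paths <- function(sem, cause, effect,
                                      conditioning = character(0)) {
  stopifnot(inherits(sem, "linear_sem"))
  check_sem_var(sem, cause)
  comps <- if (inherits(effect, "sem_contrast")) {
    stats::setNames(c(1, -1), c(effect$positive, effect$negative))
  } else {
    stats::setNames(1, check_sem_var(sem, effect))
  }
  for (v in conditioning) check_sem_var(sem, v)
  if (cause %in% conditioning || any(names(comps) %in% conditioning))
    stop("enumerate_noncausal_paths: cannot condition on the cause or effect",
         call. = FALSE)
  rows <- list()
  for (comp in names(comps)) {
    for (p in simple_paths(sem, cause, comp)) {
      if (length(p$dirs) == 0L || p$dirs[1L] != "<-") next  # not a backdoor
      st <- path_status(sem, p$nodes, p$dirs, conditioning)
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp,
        weight = comps[[comp]],
        path = path_string(p$nodes, p$dirs),
        status = st$status,
        blocked_by = paste(st$blocked_by, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(component = character(0), weight = numeric(0),
                      path = character(0), status = character(0),
                      blocked_by = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a linear SEM as plain text
#'
#' Serializes a SEM as an edge-list section (`parent child coefficient`),
#' a variance section and a means section.
#'
#' @param sem A [linear_sem()] object.
#' @param path File path.
#' @return `write_sem` returns `path` invisibly; `read_sem` returns a
#'   `linear_sem`.
#' @export
write_sem <- function(sem, path) {
  stopifnot(inherits(sem, "linear_sem"))
  lines <- c("# edges: parent child coefficient",
             sprintf("edge %s %s %.17g",
                     sem$edges$parent, sem$edges$child, sem$edges$coefficient),
             "# exogenous variances",
             sprintf("variance %s %.17g", sem$variables,
                     sem$variances[sem$variables]),
             "# disturbance means",
             sprintf("mean %s %.17g", sem$variables,
                     sem$means[sem$variables]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sem
#' @export
read_sem <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  kind <- vapply(tok, `[`, character(1), 1L)
  edges_tok <- tok[kind == "edge"]
  edges <- if (length(edges_tok)) {
    data.frame(parent = vapply(edges_tok, `[`, character(1), 2L),
               child = vapply(edges_tok, `[`, character(1), 3L),
               coefficient = as.numeric(vapply(edges_tok, `[`,
                                               character(1), 4L)))
  } else {
    data.frame(parent = character(0), child = character(0),
               coefficient = numeric(0))
  }
  var_tok <- tok[kind == "variance"]
  variances <- stats::setNames(
    as.numeric(vapply(var_tok, `[`, character(1), 3L)),
    vapply(var_tok, `[`, character(1), 2L))
  mean_tok <- tok[kind == "mean"]
  means <- stats::setNames(
    as.numeric(vapply(mean_tok, `[`, character(1), 3L)),
    vapply(mean_tok, `[`, character(1), 2L))
  linear_sem(edges, variances, means)
}
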