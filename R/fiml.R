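#' Specify a model variant for fitting
#'
#' Defines which structural parameters are free, the values of fixed ones,
#' whether the sibling genetic correlation is bound to its intergenerational
#' equilibrium value, and optimizer options. The basic model frees
#' \code{s}, \code{h}, \code{m} and \code{r_s}, with \code{a} fixed at 1
#' (direct assortment), \code{c} at 0 and the residual sibling PGS
#' correlation \code{g0} at 0.50.
#'
#' @param free Character vector of free parameters (subset of
#'   \code{s, h, m, a, c, r_s, g0}).
#' @param fixed Named list of values for fixed parameters (defaults:
#'   \code{a = 1}, \code{c = 0}, \code{g0 = 0.5}, and starting-point values
#'   for any other parameter removed from \code{free}).
#' @param equilibrium Logical; if \code{TRUE}, \code{r_s} is bound to
#'   \code{(1 + m h^2)/2} and is not an independent free parameter.
#' @param c_target Shared-environment placement, as in
#'   \code{\link{gensi_parameters}}.
#' @param n_starts Number of multi-start points (Latin hypercube over the
#'   valid region).
#' @param seed Seed for the multi-start draw.
#' @param reltol Convergence tolerance on the deviance.
#' @return An object of class \code{"gensi_model_spec"}.
#' @export
gensi_model_spec <- function(free = c("s", "h", "m", "r_s"),
                             fixed = list(), equilibrium = FALSE,
                             c_target = c("observed", "latent"),
                             n_starts = 10, seed = 1, reltol = 1e-10) {
  c_target <- match.arg(c_target)
  all_p <- gensi_par_names()
  free <- match.arg(free, all_p, several.ok = TRUE)
  if (equilibrium) free <- setdiff(free, "r_s")
  defaults <- list(s = 0.5, h = 0.7, m = 0.2, a = 1, c = 0, r_s = 0.5,
                   g0 = 0.5)
  fx <- defaults
  fx[names(fixed)] <- fixed
  fx <- fx[setdiff(all_p, free)]
  theta0 <- defaults
  theta0[names(fx)] <- fx
  theta0$c_target <- c_target
  class(theta0) <- "gensi_parameters"
  validate_parameters(theta0, free = free)
  structure(list(free = free, fixed = fx, equilibrium = equilibrium,
                 c_target = c_target, n_starts = n_starts, seed = seed,
                 reltol = reltol),
            class = "gensi_model_spec")
}

# assemble a gensi_parameters object from free values + spec
spec_to_theta <- function(spec, values) {
  th <- c(as.list(values)[spec$free], spec$fixed)
  th$c_target <- spec$c_target
  th <- th[c(gensi_par_names(), "c_target")]
  class(th) <- "gensi_parameters"
  if (spec$equilibrium) th$r_s <- 0.5 * (1 + th$m * th$h^2)
  th
}

# --- data preparation: group families by missingness pattern ---------------

as_family_matrix <- function(data) {
  cols <- gsub(".", "_", gensi_variable_labels(), fixed = TRUE)
  if (is.matrix(data)) {
    stopifnot(ncol(data) == 8)
    X <- data
    colnames(X) <- cols
    return(X)
  }
  missing_cols <- setdiff(cols, names(data))
  X <- matrix(NA_real_, nrow(data), 8, dimnames = list(NULL, cols))
  for (cl in setdiff(cols, missing_cols)) X[, cl] <- data[[cl]]
  X
}

# Precompute per-pattern sufficient statistics: for families sharing an
# observation pattern the deviance is n_p (k log 2pi + log|S_p| + tr(S_p^-1 M_p))
# with M_p the (uncentered, mean-zero) second-moment matrix.
gensi_pattern_data <- function(data) {
  X <- as_family_matrix(data)
  obs <- !is.na(X)
  n_obs <- rowSums(obs)
  if (any(n_obs == 0))
    stop(sum(n_obs == 0), " families have no observed values; ",
         "remove them before fitting", call. = FALSE)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(X)), key)
  pats <- lapply(groups, function(idx) {
    vars <- which(obs[idx[1], ])
    Xi <- X[idx, vars, drop = FALSE]
    list(vars = vars, n = length(idx), M = crossprod(Xi) / length(idx))
  })
  structure(list(patterns = pats, n_families = nrow(X),
                 n_values = sum(obs)),
            class = "gensi_pattern_data")
}

#' Deviance contribution of one family record
#'
#' The full-information maximum-likelihood deviance (\code{-2} log
#' likelihood) of one family's observed values under the model-implied
#' covariance, with means fixed at 0: for the observed subvector \code{x}
#' of dimension \code{k} with implied submatrix \code{S},
#' \code{k log(2 pi) + log|S| + x' S^-1 x}.
#'
#' @param record Named numeric vector (names among the family variable
#'   labels, \code{.} or \code{_} separated) or a one-row data frame;
#'   \code{NA} values are treated as missing.
#' @param theta A \code{\link{gensi_parameters}} object.
#' @return The deviance contribution (scalar).
#' @export
#' @examples
#' theta <- gensi_parameters()
#' family_neg2_loglik(c(A1_PGS = 0.3), theta)  # log(2*pi) + 0.09
family_neg2_loglik <- function(record, theta) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- unlist(record[setdiff(names(record), "family")])
  }
  labs <- gsub(".", "_", gensi_variable_labels(), fixed = TRUE)
  names(record) <- gsub(".", "_", names(record), fixed = TRUE)
  bad <- setdiff(names(record), labs)
  if (length(bad)) stop("unknown variables: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  x <- record[!is.na(record)]
  if (!length(x)) stop("record has no observed values", call. = FALSE)
  Sigma <- implied_family_covariance(theta)
  idx <- match(names(x), labs)
  S <- Sigma[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(S), error = function(e)
    stop("singular implied submatrix for observed variables ",
         paste(names(x), collapse = ", "), call. = FALSE))
  k <- length(x)
  q <- backsolve(ch, x, transpose = TRUE)
  k * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2)
}

#' Total FIML deviance of a dataset
#'
#' @param data A \code{\link{sample_families}}-style data frame, 8-column
#'   matrix, or precomputed \code{gensi_pattern_data}.
#' @param theta A \code{\link{gensi_parameters}} object.
#' @return Total deviance (\code{-2} log likelihood) across families.
#' @export
gensi_deviance <- function(data, theta) {
  pd <- if (inherits(data, "gensi_pattern_data")) data else
    gensi_pattern_data(data)
  Sigma <- implied_family_covariance(theta)
  deviance_from_patterns(pd, Sigma)
}

deviance_from_patterns <- function(pd, Sigma) {
  tot <- 0
  for (p in pd$patterns) {
    S <- Sigma[p$vars, p$vars, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    k <- length(p$vars)
    Sinv <- chol2inv(ch)
    tot <- tot + p$n * (k * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(Sinv * p$M))
  }
  tot
}

# --- optimization ----------------------------------------------------------

# open-box logistic transform for free parameters
box_transform <- function(spec) {
  b <- gensi_par_bounds()[spec$free]
  lo <- vapply(b, `[`, 0, 1); hi <- vapply(b, `[`, 0, 2)
  list(
    lo = lo, hi = hi,
    to_z = function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo),
                                               1e-8), 1 - 1e-8)),
    to_x = function(z) lo + (hi - lo) * stats::plogis(z))
}

# penalized objective on the transformed scale; joint residual-variance
# constraints handled by a smooth penalty so starts outside the valid
# region are pulled back in
make_objective <- function(pd, spec) {
  tr <- box_transform(spec)
  function(z) {
    x <- tr$to_x(z)
    names(x) <- spec$free
    th <- spec_to_theta(spec, x)
    viol <- -min(residual_variances(th), 0)
    if (viol > 1e-10) return(1e8 * (1 + viol) + sum(z^2))
    Sigma <- tryCatch(implied_family_covariance(th),
                      error = function(e) NULL)
    if (is.null(Sigma)) return(1e8)
    d <- deviance_from_patterns(pd, Sigma)
    if (!is.finite(d)) return(1e8)
    d
  }
}

#' Fit a model variant by full-information maximum likelihood
#'
#' Minimizes the total FIML deviance over the free parameters on a
#' transformed (open-interval) scale with Latin-hypercube multi-start.
#' Deterministic given the spec's seed and the data.
#'
#' @param data Family dataset (see \code{\link{gensi_deviance}}).
#' @param spec A \code{\link{gensi_model_spec}}.
#' @return An object of class \code{"gensi_fit"}: \code{theta} (full
#'   parameter object at the optimum), \code{estimates} (free parameters),
#'   \code{minus2LL}, \code{n_free}, \code{n_families}, \code{n_values},
#'   \code{convergence} (TRUE when any start converged), \code{boundary}
#'   (free parameters within 1e-3 of their bounds), \code{spec}, and
#'   \code{ci} (NULL until \code{\link{profile_confidence_interval}} or
#'   \code{\link{fit_model_ladder}} fills it).
#' @export
fit_model <- function(data, spec = gensi_model_spec()) {
  pd <- if (inherits(data, "gensi_pattern_data")) data else
    gensi_pattern_data(data)
  if (pd$n_families < 1) stop("empty dataset", call. = FALSE)
  obj <- make_objective(pd, spec)
  tr <- box_transform(spec)
  k <- length(spec$free)

  set.seed(spec$seed)
  # Latin-hypercube starts inside the box, away from the edges
  U <- lhs::randomLHS(max(1L, spec$n_starts), k)
  starts <- t(apply(U, 1, function(u)
    tr$to_z(tr$lo + (tr$hi - tr$lo) * (0.05 + 0.9 * u))))
  if (k == 1) starts <- matrix(starts, ncol = 1)

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], obj,
                    control = list(rel.tol = spec$reltol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("all optimization starts failed", call. = FALSE)
  if (!any_conv) {
    # "false convergence" is common against the feasibility penalty wall;
    # accept the solution if a restart from it cannot improve the deviance
    re <- tryCatch(
      stats::nlminb(best$par, obj,
                    control = list(rel.tol = spec$reltol, iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(re) && re$objective <= best$objective + 1e-6) {
      if (re$objective < best$objective) best <- re
      any_conv <- TRUE
    }
  }
  x <- tr$to_x(best$par)
  names(x) <- spec$free
  th <- spec_to_theta(spec, x)
  boundary <- spec$free[x < tr$lo + 1e-3 * (tr$hi - tr$lo) |
                          x > tr$hi - 1e-3 * (tr$hi - tr$lo)]
  if (!any_conv)
    warning("no start converged; best deviance ",
            format(best$objective), " returned")
  structure(list(theta = th, estimates = x, minus2LL = best$objective,
                 n_free = k, n_families = pd$n_families,
                 n_values = pd$n_values, convergence = any_conv,
                 boundary = boundary, spec = spec, ci = NULL,
                 pattern_data = pd),
            class = "gensi_fit")
}

#' @export
print.gensi_fit <- function(x, digits = 3, ...) {
  cat("FIML fit:", x$n_free, "free parameters,",
      x$n_families, "families,", x$n_values, "observed values\n")
  cat("-2 log L =", format(x$minus2LL, digits = 8), "\n")
  est <- round(x$estimates, digits)
  if (!is.null(x$ci)) {
    tab <- cbind(estimate = est,
                 lower = round(x$ci[names(est), "lower"], digits),
                 upper = round(x$ci[names(est), "upper"], digits))
    print(tab)
  } else print(est)
  if (x$spec$equilibrium)
    cat("r_s bound to equilibrium value",
        round(x$theta$r_s, digits), "\n")
  if (length(x$boundary))
    cat("at boundary:", paste(x$boundary, collapse = ", "), "\n")
  if (!x$convergence) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

# profiled deviance with one free parameter pinned
profiled_deviance <- function(pd, spec, param, value, start) {
  sub <- spec
  sub$free <- setdiff(spec$free, param)
  sub$fixed <- c(spec$fixed, stats::setNames(list(value), param))
  if (!length(sub$free)) {
    th <- spec_to_theta(sub, numeric(0))
    if (min(residual_variances(th)) < 0) return(Inf)
    return(gensi_deviance(pd, th))
  }
  obj <- make_objective(pd, sub)
  tr <- box_transform(sub)
  z0 <- tr$to_z(start[sub$free])
  res <- tryCatch(stats::nlminb(z0, obj,
                                control = list(rel.tol = spec$reltol,
                                               iter.max = 500)),
                  error = function(e) NULL)
  if (is.null(res)) Inf else res$objective
}

#' Profile-likelihood confidence interval
#'
#' For a free parameter, each bound is the value at which the profiled
#' deviance (minimized over all other free parameters) exceeds the minimum
#' deviance by the chi-square(1) quantile (3.841 at 95\%), located by
#' bisection to 1e-4 in the parameter. Bounds are clipped at the parameter
#' space limits and flagged when the profile never crosses the threshold.
#'
#' @param data Family dataset or pattern data.
#' @param fit A converged \code{\link{fit_model}} result.
#' @param param Name of a free parameter of the fit.
#' @param level Confidence level (default 0.95).
#' @return Named vector \code{c(lower, upper)} with attribute
#'   \code{"clipped"} (logical of length 2).
#' @export
profile_confidence_interval <- function(data, fit, param, level = 0.95) {
  if (!param %in% fit$spec$free)
    stop("'", param, "' is not free in this model", call. = FALSE)
  pd <- if (inherits(data, "gensi_pattern_data")) data else
    if (is.null(fit$pattern_data)) gensi_pattern_data(data) else
      fit$pattern_data
  crit <- stats::qchisq(level, df = 1)
  target <- fit$minus2LL + crit
  b <- gensi_par_bounds()[[param]]
  est <- fit$estimates[[param]]
  start <- fit$estimates
  prof <- function(v) profiled_deviance(pd, fit$spec, param, v, start)
  one_side <- function(limit) {
    at_limit <- prof(limit)
    if (at_limit < target) {
      return(structure(limit, clipped = TRUE))
    }
    lo <- min(est, limit); hi <- max(est, limit)
    # bisect for the crossing between the estimate and the limit
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (hi - lo < 1e-4) break
      v <- prof(mid)
      inside <- v < target
      if (limit < est) { # searching below the estimate
        if (inside) hi <- mid else lo <- mid
      } else {
        if (inside) lo <- mid else hi <- mid
      }
    }
    structure((lo + hi) / 2, clipped = FALSE)
  }
  lower <- one_side(b[1]); upper <- one_side(b[2])
  structure(c(lower = as.numeric(lower), upper = as.numeric(upper)),
            clipped = c(attr(lower, "clipped"), attr(upper, "clipped")))
}

#' Likelihood-ratio test of nested model fits
#'
#' @param restricted,general Converged \code{\link{fit_model}} results with
#'   the restricted model nested in the general one.
#' @param tol Negative deviance differences smaller than \code{tol} in
#'   magnitude are treated as 0 (optimizer noise); larger negative values
#'   are an error.
#' @return A list of class \code{"gensi_lrt"}: \code{delta_minus2LL},
#'   \code{delta_df}, \code{p_value} (chi-square upper tail).
#' @export
#' @examples
#' # deviance difference 3.841 on 1 df is the 5% boundary
#' pchisq(3.841, 1, lower.tail = FALSE)
likelihood_ratio_test <- function(restricted, general, tol = 1e-2) {
  delta <- restricted$minus2LL - general$minus2LL
  df <- general$n_free - restricted$n_free
  if (df <= 0) stop("models are not nested (no df difference)",
                    call. = FALSE)
  if (delta < -tol)
    stop("restricted model fits better by ", format(-delta),
         "; optimization failure in the general model", call. = FALSE)
  delta <- max(delta, 0)
  structure(list(delta_minus2LL = delta, delta_df = df,
                 p_value = stats::pchisq(delta, df, lower.tail = FALSE)),
            class = "gensi_lrt")
}

#' @export
print.gensi_lrt <- function(x, ...) {
  cat(sprintf("Delta -2LL = %.3f, Delta DF = %d, p = %.3f\n",
              x$delta_minus2LL, x$delta_df, x$p_value))
  invisible(x)
}

#' Fit the ladder of model variants
#'
#' Fits the basic model (direct assortment, no shared environment), the
#' extensions freeing \code{a} (indirect assortment), \code{c} (shared
#' environment) and both, and each with the intergenerational-equilibrium
#' constraint on \code{r_s}. Extensions are compared against their nested
#' neighbor and each constrained model against its unconstrained
#' counterpart by likelihood-ratio tests. The selected model adds an
#' extension only when its test rejects at the 5\% level, preferring the
#' more restricted variant on ties (parsimony).
#'
#' @param data Family dataset.
#' @param c_target Shared-environment placement.
#' @param n_starts,seed Optimizer options passed to each variant.
#' @param profile_ci Logical; when \code{TRUE} (default), computes 95\%
#'   profile-likelihood CIs for the free parameters of the selected model.
#' @return A list of class \code{"gensi_ladder"}: \code{fits} (named list
#'   of \code{gensi_fit}), \code{tests} (data frame of LRTs),
#'   \code{selected} (name of the chosen unconstrained variant),
#'   \code{equilibrium_test} (LRT of the selected variant against its
#'   equilibrium-constrained version), and \code{derived} (genetic-signal
#'   correlations at the selected estimates).
#' @export
fit_model_ladder <- function(data, c_target = "observed", n_starts = 10,
                             seed = 1, profile_ci = TRUE) {
  pd <- gensi_pattern_data(data)
  variants <- list(
    basic  = c("s", "h", "m", "r_s"),
    a_free = c("s", "h", "m", "a", "r_s"),
    c_free = c("s", "h", "m", "c", "r_s"),
    ac_free = c("s", "h", "m", "a", "c", "r_s"))
  fits <- list()
  for (v in names(variants)) {
    fits[[v]] <- tryCatch(
      fit_model(pd, gensi_model_spec(variants[[v]], c_target = c_target,
                                     n_starts = n_starts, seed = seed)),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "gensi_fit_failure"))
    fits[[paste0(v, "_eq")]] <- tryCatch(
      fit_model(pd, gensi_model_spec(variants[[v]], equilibrium = TRUE,
                                     c_target = c_target,
                                     n_starts = n_starts, seed = seed)),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "gensi_fit_failure"))
  }
  ok <- function(f) inherits(f, "gensi_fit")
  comparisons <- list(
    c("basic", "a_free"), c("basic", "c_free"),
    c("a_free", "ac_free"), c("c_free", "ac_free"),
    c("basic_eq", "basic"), c("a_free_eq", "a_free"),
    c("c_free_eq", "c_free"), c("ac_free_eq", "ac_free"))
  tests <- do.call(rbind, lapply(comparisons, function(cp) {
    if (!ok(fits[[cp[1]]]) || !ok(fits[[cp[2]]])) return(NULL)
    lrt <- tryCatch(likelihood_ratio_test(fits[[cp[1]]], fits[[cp[2]]], tol = 0.05),
                    error = function(e) NULL)
    if (is.null(lrt)) return(NULL)
    data.frame(restricted = cp[1], general = cp[2],
               delta_minus2LL = lrt$delta_minus2LL,
               delta_df = lrt$delta_df, p_value = lrt$p_value)
  }))
  # forward selection from the basic model at the 5% level
  p_of <- function(r, g) {
    row <- tests[tests$restricted == r & tests$general == g, ]
    if (nrow(row)) row$p_value else NA_real_
  }
  sel <- "basic"
  add_a <- isTRUE(p_of("basic", "a_free") < 0.05)
  add_c <- isTRUE(p_of("basic", "c_free") < 0.05)
  if (add_a && add_c) sel <- "ac_free"
  else if (add_a) sel <- "a_free"
  else if (add_c) sel <- "c_free"
  if (sel == "a_free" && isTRUE(p_of("a_free", "ac_free") < 0.05))
    sel <- "ac_free"
  if (sel == "c_free" && isTRUE(p_of("c_free", "ac_free") < 0.05))
    sel <- "ac_free"
  eq_test <- NULL
  if (ok(fits[[sel]]) && ok(fits[[paste0(sel, "_eq")]]))
    eq_test <- tryCatch(
      likelihood_ratio_test(fits[[paste0(sel, "_eq")]], fits[[sel]], tol = 0.05),
      error = function(e) NULL)
  derived <- if (ok(fits[[sel]]))
    genetic_signal_correlations(fits[[sel]]$theta) else NULL
  if (profile_ci && ok(fits[[sel]])) {
    f <- fits[[sel]]
    ci <- t(vapply(f$spec$free, function(p)
      profile_confidence_interval(pd, f, p), c(lower = 0, upper = 0)))
    fits[[sel]]$ci <- ci
  }
  structure(list(fits = fits, tests = tests, selected = sel,
                 equilibrium_test = eq_test, derived = derived),
            class = "gensi_ladder")
}

#' @export
print.gensi_ladder <- function(x, ...) {
  cat("Model ladder; selected variant:", x$selected, "\n\n")
  print(x$fits[[x$selected]])
  if (!is.null(x$equilibrium_test)) {
    cat("\nEquilibrium constraint on selected model: ")
    print(x$equilibrium_test)
  }
  if (!is.null(x$derived)) {
    cat("\nDerived genetic-signal correlations:\n")
    print(round(x$derived, 3))
  }
  invisible(x)
}

#' Polygenic-score level test of intergenerational equilibrium
#'
#' Jointly fits bivariate-normal models (free means fixed at 0, free
#' standard deviations) to partner PGS pairs and sibling PGS pairs, and
#' compares the free model (separate correlations \code{r_p}, \code{r_sib})
#' with the constrained model imposing
#' \code{r_sib = (1 + r_p)/2} by a 1-df likelihood-ratio test. Under the
#' structural model with the residual sibling PGS correlation at 0.50, the
#' latent equilibrium constraint implies exactly this PGS-level constraint.
#'
#' @param partner_pairs Two-column matrix or data frame of partners'
#'   polygenic scores.
#' @param sibling_pairs Two-column matrix or data frame of siblings'
#'   polygenic scores.
#' @return A list of class \code{"gensi_lrt"} with the test, plus
#'   \code{r_partner}, \code{r_sibling} (free estimates) and
#'   \code{r_sibling_constrained}.
#' @export
pgs_equilibrium_test <- function(partner_pairs, sibling_pairs) {
  prep <- function(x, what) {
    x <- as.matrix(x)
    x <- x[stats::complete.cases(x), , drop = FALSE]
    if (ncol(x) != 2 || nrow(x) < 3)
      stop(what, " pairs must be a two-column matrix with >= 3 rows",
           call. = FALSE)
    if (any(apply(x, 2, stats::sd) < .Machine$double.eps))
      stop(what, " pairs are degenerate (constant column)", call. = FALSE)
    x
  }
  P <- prep(partner_pairs, "partner"); S <- prep(sibling_pairs, "sibling")
  dev_bvn <- function(x, r, s1, s2) {
    n <- nrow(x)
    Sig <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    M <- crossprod(x) / n
    n * (2 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * M))
  }
  # free model: closed-form ML (mean-zero second-moment correlation)
  mle <- function(x) {
    M <- crossprod(x) / nrow(x)
    list(r = M[1, 2] / sqrt(M[1, 1] * M[2, 2]),
         s1 = sqrt(M[1, 1]), s2 = sqrt(M[2, 2]))
  }
  mp <- mle(P); ms <- mle(S)
  dev_free <- dev_bvn(P, mp$r, mp$s1, mp$s2) + dev_bvn(S, ms$r, ms$s1, ms$s2)
  # constrained: r_sib = (1 + r_p)/2; optimize over (r_p, 4 sds)
  obj <- function(par) {
    r_p <- tanh(par[1]); sds <- exp(par[2:5])
    r_sib <- 0.5 * (1 + r_p)
    dev_bvn(P, r_p, sds[1], sds[2]) + dev_bvn(S, r_sib, sds[3], sds[4])
  }
  start <- c(atanh(max(min(mp$r, 0.99), -0.99)),
             log(c(mp$s1, mp$s2, ms$s1, ms$s2)))
  res <- stats::nlminb(start, obj, control = list(rel.tol = 1e-10))
  out <- likelihood_ratio_test(
    structure(list(minus2LL = res$objective, n_free = 5), class = "gensi_fit"),
    structure(list(minus2LL = dev_free, n_free = 6), class = "gensi_fit"))
  out$r_partner <- mp$r
  out$r_sibling <- ms$r
  out$r_sibling_constrained <- 0.5 * (1 + tanh(res$par[1]))
  out
}
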