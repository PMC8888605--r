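#' Structural parameters of the correlation-in-genetic-signals model
#'
#' Constructs the parameter set of the latent-variable model linking each
#' person's polygenic score (PGS) and observed phenotype to a latent genetic
#' factor and a latent "mated" phenotype on which partners assort.
#' All observed and latent variables are standardized (variance 1), so every
#' parameter is a correlation or standardized loading.
#'
#' @param s Loading of the latent genetic factor on the polygenic score;
#'   \code{s^2} is the genetic-signal share of PGS variance. In \code{[0, 1]}.
#' @param h Loading of the latent genetic factor on the latent phenotype;
#'   \code{h^2} is the heritability. In \code{[0, 1]}.
#' @param m Partner co-path on the latent mated phenotype: the correlation
#'   induced between partners' mated phenotypes by assortment. In
#'   \code{[-1, 1]}; negative values encode disassortative mating.
#' @param a Loading of the latent mated phenotype on the observed phenotype.
#'   \code{a = 1} is direct (primary phenotypic) assortment; \code{a < 1}
#'   indicates indirect assortment on a correlated latent trait.
#' @param c Loading of the sibling-shared environment on the phenotype.
#' @param r_s Correlation between siblings' latent genetic factors. Under
#'   random mating in the parental generation this is 0.50; assortment in
#'   previous generations pushes it above 0.50.
#' @param g0 Residual correlation between siblings' polygenic scores (the
#'   part of the PGS unrelated to the latent genetic factor). Fixed at 0.50
#'   by default; it may be freed only in model variants where \code{c} is
#'   fixed at 0 (see \code{\link{gensi_model_spec}}).
#' @param c_target Where the shared environment loads: \code{"observed"}
#'   (default; C loads the observed phenotype, so it does not transmit
#'   through the partner co-path) or \code{"latent"} (C loads the latent
#'   mated phenotype, cascade-style, so c^2 propagates through \code{m}).
#'
#' @return An object of class \code{"gensi_parameters"}: a named list of the
#'   parameter values plus the convention flag.
#' @seealso \code{\link{validate_parameters}},
#'   \code{\link{implied_family_covariance}}
#' @export
#' @examples
#' theta <- gensi_parameters(s = 0.55, h = 0.75, m = 0.6, r_s = 0.6)
#' genetic_signal_correlations(theta)
gensi_parameters <- function(s = 0.5, h = 0.7, m = 0.3, a = 1, c = 0,
                             r_s = 0.5, g0 = 0.5,
                             c_target = c("observed", "latent")) {
  c_target <- match.arg(c_target)
  theta <- structure(
    list(s = s, h = h, m = m, a = a, c = c, r_s = r_s, g0 = g0,
         c_target = c_target),
    class = "gensi_parameters")
  validate_parameters(theta)
}

#' @export
print.gensi_parameters <- function(x, digits = 3, ...) {
  vals <- unlist(x[gensi_par_names()])
  cat("Model parameters (c on", x$c_target, "phenotype):\n")
  print(round(vals, digits))
  ev <- residual_variances(x)
  cat("Residual variances: Eg =", format(ev["Eg"], digits = digits),
      " El =", format(ev["El"], digits = digits),
      " Ep =", format(ev["Ep"], digits = digits), "\n")
  invisible(x)
}

gensi_par_names <- function() c("s", "h", "m", "a", "c", "r_s", "g0")

# Lower/upper box for each parameter. Loadings s, h, a, c are standardized
# with sign fixed positive (the sign is not identified); m, r_s, g0 are
# correlations and may be negative.
gensi_par_bounds <- function() {
  list(s   = c(0, 1), h  = c(0, 1), m = c(-1, 1), a = c(0, 1),
       c   = c(0, 1), r_s = c(-1, 1), g0 = c(-1, 1))
}

#' Residual variances implied by the structural parameters
#'
#' Returns the three residual variances fixed by the unit-variance
#' convention: \code{Eg} for the polygenic score, \code{El} for the latent
#' mated phenotype and \code{Ep} for the observed phenotype. Their exact
#' form depends on where the shared environment loads.
#'
#' @param theta A \code{\link{gensi_parameters}} object.
#' @return Named numeric vector \code{c(Eg, El, Ep)}.
#' @export
residual_variances <- function(theta) {
  with(theta, {
    if (c_target == "observed") {
      c(Eg = 1 - s^2, El = 1 - h^2, Ep = 1 - a^2 - c^2)
    } else {
      c(Eg = 1 - s^2, El = 1 - h^2 - c^2, Ep = 1 - a^2)
    }
  })
}

#' Validate model parameters
#'
#' Checks parameter bounds, non-negativity of the implied residual variances
#' and the identification rule that the residual sibling PGS correlation may
#' be freed only when the shared-environment loading is fixed at 0.
#'
#' @param theta A \code{\link{gensi_parameters}} object (or bare named list
#'   with the same fields).
#' @param free Optional character vector naming the parameters treated as
#'   free; used to enforce the \code{g0}-vs-\code{c} identification rule.
#' @return \code{theta}, invisibly unchanged, if valid; otherwise an error
#'   naming the offending parameter and the violated inequality.
#' @export
validate_parameters <- function(theta, free = character()) {
  b <- gensi_par_bounds()
  for (p in gensi_par_names()) {
    v <- theta[[p]]
    if (is.null(v) || !is.finite(v))
      stop("parameter '", p, "' is missing or non-finite", call. = FALSE)
    if (v < b[[p]][1] || v > b[[p]][2])
      stop("parameter '", p, "' = ", format(v), " violates ",
           b[[p]][1], " <= ", p, " <= ", b[[p]][2], call. = FALSE)
  }
  if (!theta$c_target %in% c("observed", "latent"))
    stop("c_target must be 'observed' or 'latent'", call. = FALSE)
  # small negative slack so boundary solutions (e.g. c -> 0 with a = 1)
  # are admissible under floating-point arithmetic
  tol <- -1e-9
  ev <- residual_variances(theta)
  if (ev["Eg"] < tol)
    stop("residual variance Eg = 1 - s^2 = ", format(ev["Eg"]),
         " violates Eg >= 0", call. = FALSE)
  if (ev["El"] < tol)
    stop("residual variance El = ", format(ev["El"]),
         if (theta$c_target == "latent") " (1 - h^2 - c^2)" else " (1 - h^2)",
         " violates El >= 0", call. = FALSE)
  if (ev["Ep"] < tol)
    stop("residual variance Ep = ", format(ev["Ep"]),
         if (theta$c_target == "observed") " (1 - a^2 - c^2)" else " (1 - a^2)",
         " violates Ep >= 0", call. = FALSE)
  if ("g0" %in% free && (theta$c != 0 || "c" %in% free))
    stop("identification error: g0 can be freely estimated only when the ",
         "shared-environment loading c is fixed at 0", call. = FALSE)
  invisible(theta)
}
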