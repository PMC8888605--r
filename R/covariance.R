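#' Variable labels of the family covariance matrix
#'
#' The family unit holds up to four members: siblings A1 and A2 and their
#' respective partners Q1 and Q2, each contributing a polygenic score and a
#' phenotype. This fixed ordering is used throughout the package.
#'
#' @return Character vector of the eight variable labels.
#' @export
gensi_variable_labels <- function() {
  c("A1.PGS", "A1.PHE", "A2.PGS", "A2.PHE",
    "Q1.PGS", "Q1.PHE", "Q2.PGS", "Q2.PHE")
}

#' Model-implied covariance of a family unit
#'
#' Computes the 8x8 model-implied covariance over (PGS, phenotype) for the
#' four family roles (siblings A1, A2 and partners Q1, Q2) by path tracing
#' with co-paths. The partner co-path \code{m} connects the two latent mated
#' phenotypes of a couple; it contributes to covariance but not variance, so
#' every covariance crossing one couple bond carries one factor of \code{m}
#' and every co-in-law covariance (crossing both couple bonds) carries
#' \code{m^2}.
#'
#' Two independent computations are available and agree for all valid
#' parameters: \code{"closed"} evaluates the per-entry path-traced formulas;
#' \code{"assembly"} builds the latent-factor covariance and loading
#' matrices and closes partner bonds by the conditional-independence rule
#' \code{cov(X, Y_partner) = cov(X, LP_own) * m * cov(LP_partner, Y_partner)}
#' (chained through the sibling latent-phenotype covariance for in-law and
#' co-in-law entries).
#'
#' @param theta A \code{\link{gensi_parameters}} object.
#' @param method \code{"closed"} (default) or \code{"assembly"}.
#' @return An 8x8 symmetric matrix with unit diagonal, dimnames from
#'   \code{\link{gensi_variable_labels}}, of class
#'   \code{c("gensi_covariance", "matrix")}.
#' @export
#' @examples
#' theta <- gensi_parameters(s = 1, h = 0.7, m = 0.6, r_s = 0.5)
#' Sigma <- implied_family_covariance(theta)
#' Sigma["Q1.PGS", "A1.PGS"]  # partner PGS-PGS: s^2 h^2 m
implied_family_covariance <- function(theta,
                                      method = c("closed", "assembly")) {
  method <- match.arg(method)
  validate_parameters(theta)
  S <- switch(method,
              closed = implied_cov_closed(theta),
              assembly = implied_cov_assembly(theta))
  dimnames(S) <- list(gensi_variable_labels(), gensi_variable_labels())
  class(S) <- c("gensi_covariance", class(S))
  S
}

# Closed-form entry table. L is the latent-mated-phenotype covariance
# between siblings; under the observed-C convention the shared environment
# bypasses the latent phenotype, so L = h^2 r_s, while under the latent-C
# convention L = h^2 r_s + c^2 and c^2 propagates through the co-path.
implied_cov_closed <- function(theta) {
  w <- with(theta, {
    L <- if (c_target == "latent") h^2 * r_s + c^2 else h^2 * r_s
    sib_phe <- if (c_target == "latent") a^2 * L else a^2 * h^2 * r_s + c^2
    list(
      within   = s * h * a,
      sib_pgs  = s^2 * r_s + g0 * (1 - s^2),
      sib_phe  = sib_phe,
      sib_x    = s * h * a * r_s,              # PGS(one) x PHE(other sib)
      par_phe  = a^2 * m,
      par_pgs  = s^2 * h^2 * m,
      par_x    = s * h * a * m,
      il_pgs   = s^2 * h^2 * m * r_s,          # PGS(sib side) x PGS(partner side)
      il_phe   = a^2 * m * L,
      il_pgs_phe = s * h * a * m * r_s,        # PGS(sib side) x PHE(partner side)
      # PHE(sib side) x PGS(partner side): a * L * m * s * h — the h-vs-h^3
      # orientation asymmetry under the observed convention
      il_phe_pgs = a * L * m * s * h,
      co_pgs   = s^2 * h^2 * m^2 * L,
      co_phe   = a^2 * m^2 * L,
      co_x     = s * h * a * m^2 * L
    )
  })

  S <- diag(8)
  put <- function(i, j, v) { S[i, j] <<- v; S[j, i] <<- v }
  # role blocks: indices 1:2 A1, 3:4 A2, 5:6 Q1, 7:8 Q2; odd = PGS, even = PHE
  for (k in c(1, 3, 5, 7)) put(k, k + 1, w$within)
  # sibling A1-A2
  put(1, 3, w$sib_pgs); put(2, 4, w$sib_phe)
  put(1, 4, w$sib_x);   put(2, 3, w$sib_x)
  # partner couples (A1,Q1) and (A2,Q2)
  for (p in list(c(1, 5), c(3, 7))) {
    i <- p[1]; j <- p[2]
    put(i, j, w$par_pgs); put(i + 1, j + 1, w$par_phe)
    put(i, j + 1, w$par_x); put(i + 1, j, w$par_x)
  }
  # in-law pairs (A1,Q2) and (A2,Q1); first index is the sibling-side member
  for (p in list(c(1, 7), c(3, 5))) {
    i <- p[1]; j <- p[2]
    put(i, j, w$il_pgs); put(i + 1, j + 1, w$il_phe)
    put(i, j + 1, w$il_pgs_phe); put(i + 1, j, w$il_phe_pgs)
  }
  # co-in-law Q1-Q2
  put(5, 7, w$co_pgs); put(6, 8, w$co_phe)
  put(5, 8, w$co_x);   put(6, 7, w$co_x)
  S
}

# Generic latent assembly. Variables per person: PGS, PHE and the latent
# mated phenotype LP. Step 1 builds the 12x12 covariance over all four
# persons' (PGS, PHE, LP) from the factor model with sibling-shared factors
# but no partner bonds. Step 2 closes the two co-paths: a co-path adjoins
# the two LPs of a couple, and any traced chain may pass through at most one
# co-path per couple bond, multiplying by m each time.
implied_cov_assembly <- function(theta) {
  s <- theta$s; h <- theta$h; m <- theta$m; a <- theta$a; cc <- theta$c
  r_s <- theta$r_s; g0 <- theta$g0
  ev <- pmax(residual_variances(theta), 0)
  latentC <- theta$c_target == "latent"

  # Factors, per person: G, C, El, Eg, Ep (15 latent factors; C shared for
  # A1/A2, private for Q1/Q2). Factor covariance Phi.
  roles <- c("A1", "A2", "Q1", "Q2")
  fac <- as.vector(outer(c("G", "C", "El", "Eg", "Ep"), roles, paste,
                         sep = "."))
  Phi <- diag(length(fac))
  dimnames(Phi) <- list(fac, fac)
  Phi["G.A1", "G.A2"] <- Phi["G.A2", "G.A1"] <- r_s
  Phi["C.A1", "C.A2"] <- Phi["C.A2", "C.A1"] <- 1   # shared environment
  Phi["Eg.A1", "Eg.A2"] <- Phi["Eg.A2", "Eg.A1"] <- g0

  # Loadings of (PGS, PHE, LP) per person on that person's factors.
  obs <- as.vector(outer(c("PGS", "PHE", "LP"), roles, paste, sep = "."))
  Lam <- matrix(0, length(obs), length(fac), dimnames = list(obs, fac))
  for (r in roles) {
    Lam[paste0("PGS.", r), paste0("G.", r)]  <- s
    Lam[paste0("PGS.", r), paste0("Eg.", r)] <- sqrt(ev["Eg"])
    if (latentC) {
      Lam[paste0("LP.", r), paste0("G.", r)]  <- h
      Lam[paste0("LP.", r), paste0("C.", r)]  <- cc
      Lam[paste0("LP.", r), paste0("El.", r)] <- sqrt(ev["El"])
      Lam[paste0("PHE.", r), paste0("G.", r)]  <- a * h
      Lam[paste0("PHE.", r), paste0("C.", r)]  <- a * cc
      Lam[paste0("PHE.", r), paste0("El.", r)] <- a * sqrt(ev["El"])
      Lam[paste0("PHE.", r), paste0("Ep.", r)] <- sqrt(ev["Ep"])
    } else {
      Lam[paste0("LP.", r), paste0("G.", r)]  <- h
      Lam[paste0("LP.", r), paste0("El.", r)] <- sqrt(ev["El"])
      Lam[paste0("PHE.", r), paste0("G.", r)]  <- a * h
      Lam[paste0("PHE.", r), paste0("C.", r)]  <- cc
      Lam[paste0("PHE.", r), paste0("El.", r)] <- a * sqrt(ev["El"])
      Lam[paste0("PHE.", r), paste0("Ep.", r)] <- sqrt(ev["Ep"])
    }
  }
  S12 <- Lam %*% Phi %*% t(Lam)

  # Couple bonds (sibling-side role, partner-side role).
  couples <- list(c("A1", "Q1"), c("A2", "Q2"))
  v <- function(x, y) S12[x, y]
  full <- S12
  sibs <- c("A1", "A2")
  for (cp in couples) {
    A <- cp[1]; Q <- cp[2]
    Asib <- setdiff(sibs, A)
    for (x in c("PGS", "PHE", "LP")) for (y in c("PGS", "PHE", "LP")) {
      xi <- paste(x, A, sep = "."); yj <- paste(y, Q, sep = ".")
      # one co-path: anything on the A side (A itself or its sibling) to Q
      val <- v(xi, paste0("LP.", A)) * m * v(paste0("LP.", Q), yj)
      full[xi, yj] <- full[yj, xi] <- val
      xs <- paste(x, Asib, sep = ".")
      val2 <- v(xs, paste0("LP.", A)) * m * v(paste0("LP.", Q), yj)
      full[xs, yj] <- full[yj, xs] <- val2
    }
  }
  # two co-paths: Q1 to Q2 chains LP.Q1 -m- LP.A1 ... LP.A2 -m- LP.Q2
  for (x in c("PGS", "PHE", "LP")) for (y in c("PGS", "PHE", "LP")) {
    xi <- paste(x, "Q1", sep = "."); yj <- paste(y, "Q2", sep = ".")
    val <- v(xi, "LP.Q1") * m * v("LP.A1", "LP.A2") * m * v("LP.Q2", yj)
    full[xi, yj] <- full[yj, xi] <- val
  }
  keep <- as.vector(outer(c("PGS", "PHE"), roles, paste, sep = "."))
  ord <- c("PGS.A1", "PHE.A1", "PGS.A2", "PHE.A2",
           "PGS.Q1", "PHE.Q1", "PGS.Q2", "PHE.Q2")
  unname(full[ord, ord])
}

#' Genetic-signal correlations between relatives
#'
#' Path-traced correlations between the latent genetic factors of the four
#' relative pair types, free of polygenic-score measurement error: partners
#' correlate \code{m h^2}, siblings \code{r_s}, siblings-in-law
#' \code{r_s m h^2} and co-siblings-in-law \code{r_s (m h^2)^2} (under the
#' observed-C convention; with C on the latent mated phenotype the co-in-law
#' value becomes \code{m^2 h^2 (h^2 r_s + c^2)}).
#'
#' @param theta A \code{\link{gensi_parameters}} object.
#' @return Named numeric vector with elements \code{within}, \code{partner},
#'   \code{sibling}, \code{in_law}, \code{co_in_law}.
#' @export
#' @examples
#' # education-like: reported sibling 0.68 and partner 0.37 imply
#' # in-law 0.25 and co-in-law 0.09 (two decimals)
#' theta <- gensi_parameters(s = 1, h = 1, m = 0.37, r_s = 0.68)
#' round(genetic_signal_correlations(theta), 2)
genetic_signal_correlations <- function(theta) {
  validate_parameters(theta)
  with(theta, {
    # L = covariance of siblings' latent mated phenotypes; the co-in-law
    # chain is h -m- (sibling LP bond) -m- h
    L <- if (c_target == "latent") h^2 * r_s + c^2 else h^2 * r_s
    c(within = 1,
      partner = m * h^2,
      sibling = r_s,
      in_law = r_s * m * h^2,
      co_in_law = h * m * L * m * h)
  })
}

#' Expected sibling genetic correlation at intergenerational equilibrium
#'
#' When the level of genetic assortment has been stable long enough for the
#' additive genetic variance to reach its steady state, the additive genetic
#' correlation between siblings equals \code{(1 + r_partner) / 2}, where
#' \code{r_partner} is the additive genetic correlation between partners.
#'
#' @param r_partner Partner genetic correlation(s), in \code{[-1, 1]}.
#' @return The implied equilibrium sibling genetic correlation(s).
#' @export
#' @examples
#' equilibrium_sibling_correlation(0)     # random mating: 0.5
#' equilibrium_sibling_correlation(0.37)  # education-like: 0.685
equilibrium_sibling_correlation <- function(r_partner) {
  if (any(!is.finite(r_partner)) || any(abs(r_partner) > 1))
    stop("r_partner must lie in [-1, 1]", call. = FALSE)
  0.5 * (1 + r_partner)
}

#' Bind the sibling genetic correlation to its equilibrium value
#'
#' Returns a copy of \code{theta} with \code{r_s} replaced by
#' \code{(1 + m h^2) / 2}, the value implied by intergenerational
#' equilibrium. In fitting, this removes \code{r_s} from the free-parameter
#' set (see \code{\link{gensi_model_spec}}).
#'
#' @param theta A \code{\link{gensi_parameters}} object.
#' @return \code{theta} with \code{r_s} bound to the equilibrium value.
#' @export
constrain_to_equilibrium <- function(theta) {
  validate_parameters(theta)
  theta$r_s <- equilibrium_sibling_correlation(theta$m * theta$h^2)
  theta
}
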