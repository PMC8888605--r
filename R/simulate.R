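#' Sample family units from the generative model
#'
#' Draws each family's 8-vector (PGS and phenotype for siblings A1, A2 and
#' partners Q1, Q2) from a zero-mean Gaussian with the model-implied
#' covariance, then applies per-variable missingness masks. This emulates
#' register-linked cohort data where genotyped and phenotyped pair counts
#' differ by relationship.
#'
#' @param theta A \code{\link{gensi_parameters}} object.
#' @param n_families Number of family units to draw.
#' @param missingness Either a single probability applied to every variable
#'   or a named numeric vector over (a subset of) the eight variable labels
#'   of \code{\link{gensi_variable_labels}} giving the probability that each
#'   value is missing.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A data frame with a \code{family} id column and the eight value
#'   columns (names as \code{\link{gensi_variable_labels}} with \code{.}
#'   replaced by \code{_}), class \code{"gensi_families"}.
#' @export
#' @examples
#' theta <- gensi_parameters(s = 0.55, h = 0.75, m = 0.6, r_s = 0.6)
#' fam <- sample_families(theta, 500, seed = 1)
#' cor(fam$A1_PHE, fam$Q1_PHE)  # approx a^2 m
sample_families <- function(theta, n_families, missingness = 0, seed = NULL) {
  stopifnot(n_families >= 1)
  Sigma <- implied_family_covariance(theta)
  ee <- eigen(Sigma, symmetric = TRUE)
  if (min(ee$values) < -1e-10)
    stop("implied covariance is not positive semidefinite", call. = FALSE)
  rt <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(n_families * 8L), n_families, 8L) %*% rt
  labs <- gensi_variable_labels()
  miss <- rep(0, 8); names(miss) <- labs
  if (length(missingness) == 1 && is.null(names(missingness))) {
    miss[] <- missingness
  } else {
    bad <- setdiff(names(missingness), labs)
    if (length(bad)) stop("unknown variable in missingness: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    miss[names(missingness)] <- missingness
  }
  if (any(miss < 0 | miss > 1))
    stop("missingness probabilities must lie in [0, 1]", call. = FALSE)
  for (j in seq_len(8L)) if (miss[j] > 0)
    X[stats::runif(n_families) < miss[j], j] <- NA_real_
  out <- data.frame(family = seq_len(n_families), X)
  names(out) <- c("family", gsub(".", "_", labs, fixed = TRUE))
  class(out) <- c("gensi_families", class(out))
  out
}

#' Agent-based mate-matching oracle
#'
#' An independent generative mechanism for the family covariance that never
#' uses the closed-form cross-partner formulas: it builds sibling pairs
#' (latent genetic factors correlated \code{r_s}, shared environment,
#' correlated PGS residuals, independent other residuals), builds separate
#' pools of potential partners with the same within-person structure, and
#' couples each sibling to a partner by Gaussian-rank matching so that the
#' correlation between the two latent mated phenotypes of a couple equals
#' \code{m}. Because matching acts only on the latent mated phenotypes, all
#' cross-partner covariances arise purely from the coupling, providing a
#' mechanism-level check of the co-path path-tracing algebra.
#'
#' @param theta A \code{\link{gensi_parameters}} object with \code{|m| < 1}.
#' @param n_couples Number of couples (i.e. families; at least 1000 for a
#'   meaningful comparison).
#' @param seed Integer seed.
#' @return A list with \code{cov} (empirical 8x8 covariance), \code{se}
#'   (elementwise Monte-Carlo standard errors, \code{sd(x_i x_j)/sqrt(n)}),
#'   \code{achieved_m} (realized latent partner correlations for the two
#'   couples) and \code{data} (the simulated 8-column matrix).
#' @export
mate_matching_oracle <- function(theta, n_couples, seed = NULL) {
  validate_parameters(theta)
  if (abs(theta$m) >= 1)
    stop("|m| must be < 1 for rank matching", call. = FALSE)
  if (n_couples < 1000) stop("n_couples too small", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_couples
  ev <- pmax(residual_variances(theta), 0)
  latentC <- theta$c_target == "latent"

  # one person's variables from their factors
  person <- function(G, C, El, Eg, Ep) {
    PGS <- theta$s * G + sqrt(ev["Eg"]) * Eg
    if (latentC) {
      LP <- theta$h * G + theta$c * C + sqrt(ev["El"]) * El
      PHE <- theta$a * LP + sqrt(ev["Ep"]) * Ep
    } else {
      LP <- theta$h * G + sqrt(ev["El"]) * El
      PHE <- theta$a * LP + theta$c * C + sqrt(ev["Ep"]) * Ep
    }
    list(PGS = PGS, PHE = PHE, LP = LP)
  }
  corr_pair <- function(r) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
  }
  Gs <- corr_pair(theta$r_s)          # siblings' latent genetic factors
  Egs <- corr_pair(theta$g0)          # siblings' PGS residuals
  Csib <- stats::rnorm(n)             # shared environment
  A1 <- person(Gs[, 1], Csib, stats::rnorm(n), Egs[, 1], stats::rnorm(n))
  A2 <- person(Gs[, 2], Csib, stats::rnorm(n), Egs[, 2], stats::rnorm(n))

  # independent partner pools; partners' own sibships are unmodeled, so
  # their shared-environment factor is private
  pool <- function() person(stats::rnorm(n), stats::rnorm(n),
                            stats::rnorm(n), stats::rnorm(n),
                            stats::rnorm(n))
  match_pool <- function(sib_LP, cand) {
    # Gaussian-rank coupling: target an m-correlated companion of the
    # sibling's latent mated phenotype, then assign candidates by rank
    target <- theta$m * sib_LP +
      sqrt(1 - theta$m^2) * stats::rnorm(length(sib_LP))
    idx <- order(cand$LP)[rank(target, ties.method = "first")]
    lapply(cand, function(v) v[idx])
  }
  Q1 <- match_pool(A1$LP, pool())
  Q2 <- match_pool(A2$LP, pool())

  X <- cbind(A1$PGS, A1$PHE, A2$PGS, A2$PHE,
             Q1$PGS, Q1$PHE, Q2$PGS, Q2$PHE)
  colnames(X) <- gensi_variable_labels()
  cv <- stats::cov(X) * (n - 1) / n
  se <- matrix(0, 8, 8, dimnames = dimnames(cv))
  for (i in 1:8) for (j in i:8) {
    se[i, j] <- se[j, i] <- stats::sd(X[, i] * X[, j]) / sqrt(n)
  }
  list(cov = cv, se = se,
       achieved_m = c(stats::cor(A1$LP, Q1$LP), stats::cor(A2$LP, Q2$LP)),
       data = X)
}

#' Forward-in-time assortative-mating simulation
#'
#' Simulates the approach of additive genetic variance and sibling genetic
#' correlations to intergenerational equilibrium under stable assortment.
#' Generation 0 founders carry genetic values with variance \code{V0};
#' each generation, individuals are paired by Gaussian-rank matching to a
#' target partner correlation (on the mated phenotype, or directly on the
#' genetic value), and each couple produces offspring whose genetic value is
#' the mid-parent value plus a segregation deviate of constant variance
#' \code{V0/2} (infinitesimal model, no inbreeding adjustment).
#'
#' Under constant partner genetic correlation \code{r}, the additive
#' variance follows \code{V(t+1) = V(t)(1+r)/2 + V0/2} with limit
#' \code{V0/(1-r)}.
#'
#' @param n_couples Couples per generation (at least 100).
#' @param generations Number of offspring generations to simulate.
#' @param V0 Founder additive genetic variance.
#' @param h2_0 Baseline heritability of the mated phenotype in the founder
#'   generation; fixes the environmental variance, which stays constant.
#' @param target_r Target partner correlation applied each generation: on
#'   the mated phenotype when \code{assort_on = "phenotype"} (so the partner
#'   genetic correlation is about \code{target_r} times the current
#'   heritability), or directly on genetic values when
#'   \code{assort_on = "genetic"} (constant-r dynamics).
#' @param assort_on \code{"phenotype"} (default) or \code{"genetic"}.
#' @param offspring_per_couple At least 2, so sibling pairs exist.
#' @param start_generation First generation at which assortment operates
#'   (earlier generations mate at random); useful for causality checks.
#' @param seed Integer seed.
#' @return A data frame of class \code{"gensi_trajectory"} with one row per
#'   generation: \code{generation}, \code{V} (additive variance),
#'   \code{r_partner} (partner genetic correlation), \code{r_sibling}
#'   (sibling genetic correlation, NA for founders), \code{h2} (current
#'   heritability of the mated phenotype), \code{n} (individuals measured).
#'   Attributes record \code{V0} and the configuration.
#' @export
forward_simulate <- function(n_couples, generations, V0 = 1, h2_0 = 0.5,
                             target_r = 0.25,
                             assort_on = c("phenotype", "genetic"),
                             offspring_per_couple = 2,
                             start_generation = 0, seed = NULL) {
  assort_on <- match.arg(assort_on)
  stopifnot(n_couples >= 100, generations >= 1, V0 > 0,
            h2_0 > 0, h2_0 <= 1, offspring_per_couple >= 2,
            abs(target_r) < 1)
  if (!is.null(seed)) set.seed(seed)
  VE <- V0 * (1 - h2_0) / h2_0
  n_ind <- 2L * n_couples

  G <- stats::rnorm(n_ind, 0, sqrt(V0))
  sib_of <- NULL   # index pairing of siblings within the current generation
  rows <- vector("list", generations + 1L)
  for (t in 0:generations) {
    V <- stats::var(G)
    if (V < .Machine$double.eps)
      stop("degenerate genetic variance at generation ", t, call. = FALSE)
    P <- G + stats::rnorm(n_ind, 0, sqrt(VE))
    r_sib <- NA_real_
    if (!is.null(sib_of))
      r_sib <- stats::cor(G[sib_of[, 1]], G[sib_of[, 2]])
    # pair into couples
    half <- n_ind %/% 2L
    perm <- sample.int(n_ind)
    i1 <- perm[seq_len(half)]; i2 <- perm[half + seq_len(half)]
    r_now <- if (t >= start_generation) target_r else 0
    score1 <- if (assort_on == "phenotype") P[i1] else G[i1]
    score2 <- if (assort_on == "phenotype") P[i2] else G[i2]
    target <- r_now * scale(score1)[, 1] +
      sqrt(1 - r_now^2) * stats::rnorm(half)
    i2 <- i2[order(score2)[rank(target, ties.method = "first")]]
    r_partner <- stats::cor(G[i1], G[i2])
    rows[[t + 1L]] <- data.frame(generation = t, V = V,
                                 r_partner = r_partner, r_sibling = r_sib,
                                 h2 = V / (V + VE), n = n_ind)
    if (t == generations) break
    # offspring: mid-parent plus constant segregation variance V0/2
    k <- offspring_per_couple
    mid <- rep((G[i1] + G[i2]) / 2, each = k)
    kids <- mid + stats::rnorm(half * k, 0, sqrt(V0 / 2))
    # constant population size: keep the first two offspring per couple
    keep <- as.vector(outer(1:2, (seq_len(half) - 1L) * k, `+`))
    keep <- keep[seq_len(min(n_ind, length(keep)))]
    G <- kids[keep]
    n_ind <- length(G)
    sib_of <- cbind(seq(1, n_ind, by = 2), seq(2, n_ind, by = 2))
  }
  traj <- do.call(rbind, rows)
  attr(traj, "V0") <- V0
  attr(traj, "config") <- list(n_couples = n_couples,
                               generations = generations, V0 = V0,
                               h2_0 = h2_0, target_r = target_r,
                               assort_on = assort_on,
                               offspring_per_couple = offspring_per_couple,
                               start_generation = start_generation)
  class(traj) <- c("gensi_trajectory", class(traj))
  traj
}

#' Summarize a forward-simulation trajectory against equilibrium
#'
#' Estimates the equilibrium variance from the trajectory tail and reports,
#' per generation, the fraction of the eventual variance increase attained,
#' \code{(V(t) - V0)/(V(inf) - V0)}, and the ratio to the equilibrium
#' variance, \code{V(t)/V(inf)}. Also compares the final sibling genetic
#' correlation with the equilibrium prediction
#' \code{(1 + r_partner)/2} on the Monte-Carlo standard-error scale.
#'
#' @param trajectory A \code{\link{forward_simulate}} result with at least
#'   5 generations.
#' @param tail_frac Fraction of trailing generations averaged for
#'   \code{V(inf)} (default 0.25, at least 2 generations).
#' @return A list: \code{V0}, \code{V_inf}, \code{fractions} (per
#'   generation, of the eventual increase), \code{variance_ratio}
#'   (\code{V(t)/V_inf}), \code{first_gen_95} (first generation with
#'   fraction of increase above 0.95, NA if never),
#'   \code{first_gen_95_ratio} (first generation with variance within 5\%
#'   of equilibrium), \code{sibling_final}, \code{sibling_predicted},
#'   \code{sibling_z} (difference over MC standard error), and flags
#'   \code{random_mating} and \code{converged}.
#' @export
equilibrium_summary <- function(trajectory, tail_frac = 0.25) {
  tr <- as.data.frame(trajectory)
  Tg <- max(tr$generation)
  if (Tg < 5) stop("trajectory must span at least 5 generations",
                   call. = FALSE)
  V0 <- attr(trajectory, "V0")
  if (is.null(V0)) V0 <- tr$V[tr$generation == 0]
  k <- max(2L, ceiling(tail_frac * (Tg + 1L)))
  tail_rows <- tr[tr$generation > Tg - k, ]
  V_inf <- mean(tail_rows$V)
  # tail considered converged if its drift is small relative to its spread
  slope <- stats::coef(stats::lm(V ~ generation, data = tail_rows))[2]
  converged <- abs(slope) * (k - 1) <
    max(0.02 * V_inf, 3 * stats::sd(tail_rows$V))
  incr <- V_inf - V0
  n_pairs <- tr$n[nrow(tr)] / 2
  se_V <- V_inf * sqrt(2 / tr$n[nrow(tr)])
  random_mating <- abs(incr) < 3 * se_V * sqrt(k)
  fractions <- if (random_mating) rep(0, nrow(tr)) else (tr$V - V0) / incr
  r_part <- tr$r_partner[nrow(tr)]
  r_sib <- tr$r_sibling[nrow(tr)]
  pred <- equilibrium_sibling_correlation(r_part)
  se_r <- (1 - r_sib^2) / sqrt(n_pairs)
  above <- function(x, thr) {
    g <- tr$generation[x >= thr]
    if (length(g)) min(g) else NA_integer_
  }
  list(V0 = V0, V_inf = V_inf,
       fractions = stats::setNames(fractions, tr$generation),
       variance_ratio = stats::setNames(tr$V / V_inf, tr$generation),
       first_gen_95 = above(fractions, 0.95),
       first_gen_95_ratio = above(tr$V / V_inf, 0.95),
       sibling_final = r_sib, sibling_predicted = pred,
       sibling_z = (r_sib - pred) / se_r,
       random_mating = random_mating, converged = converged)
}
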