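test_that("family deviances equal a dense multivariate-normal oracle", {
  set.seed(11)
  th <- theta_full()
  Sigma <- implied_family_covariance(th)
  labs <- gsub(".", "_", gensi_variable_labels(), fixed = TRUE)
  dat <- sample_families(th, 200, seed = 12)
  X <- as.matrix(as.data.frame(dat)[labs])
  # complete records
  total <- sum(apply(X, 1, dense_mvn_deviance, Sigma = Sigma))
  expect_equal(gensi_deviance(dat, th), total, tolerance = 1e-8)
  # partially missing records, family by family
  dat_m <- sample_families(th, 150, missingness = 0.35, seed = 13)
  dat_m <- dat_m[rowSums(!is.na(dat_m[labs])) > 0, ]
  Xm <- as.matrix(as.data.frame(dat_m)[labs])
  for (i in c(1, 7, 50, nrow(Xm))) {
    expect_equal(family_neg2_loglik(Xm[i, ], th),
                 dense_mvn_deviance(Xm[i, ], Sigma), tolerance = 1e-8)
  }
  expect_equal(gensi_deviance(dat_m, th),
               sum(apply(Xm, 1, dense_mvn_deviance, Sigma = Sigma)),
               tolerance = 1e-8)
})

test_that("degenerate records and simple cases behave as standard normals", {
  th <- gensi_parameters()
  x <- 1.3
  expect_equal(family_neg2_loglik(c(A1_PGS = x), th), log(2 * pi) + x^2)
  expect_error(family_neg2_loglik(c(A1_PGS = NA_real_), th), "no observed")
  expect_error(family_neg2_loglik(c(bogus = 1), th), "unknown")
  # partners' PGS only under no assortment: two independent standard normals
  th0 <- gensi_parameters(m = 0)
  expect_equal(family_neg2_loglik(c(Q1_PGS = 0.4, Q2_PGS = -1.1), th0),
               2 * log(2 * pi) + 0.4^2 + 1.1^2)
})

test_that("deviance is invariant to family order and to sibling-unit relabeling", {
  th <- theta_full()
  dat <- sample_families(th, 300, missingness = 0.2, seed = 14)
  labs <- gsub(".", "_", gensi_variable_labels(), fixed = TRUE)
  dat <- dat[rowSums(!is.na(dat[labs])) > 0, ]
  d1 <- gensi_deviance(dat, th)
  expect_equal(gensi_deviance(dat[sample(nrow(dat)), ], th), d1)
  # swap the (A1, Q1) unit with the (A2, Q2) unit
  swapped <- dat
  swap_map <- c(A1_PGS = "A2_PGS", A1_PHE = "A2_PHE",
                A2_PGS = "A1_PGS", A2_PHE = "A1_PHE",
                Q1_PGS = "Q2_PGS", Q1_PHE = "Q2_PHE",
                Q2_PGS = "Q1_PGS", Q2_PHE = "Q1_PHE")
  for (cl in names(swap_map)) swapped[[cl]] <- dat[[swap_map[cl]]]
  expect_equal(gensi_deviance(swapped, th), d1)
})

test_that("the basic model recovers its generating parameters", {
  th <- theta_edu()
  dat <- sample_families(th, 3000, seed = 15)
  fit <- fit_model(dat, gensi_model_spec(n_starts = 5, seed = 2))
  expect_true(fit$convergence)
  truth <- c(s = 0.55, h = 0.75, m = 0.60, r_s = 0.60)
  expect_lt(max(abs(fit$estimates[names(truth)] - truth)), 0.05)
  # the optimum cannot beat the deviance at a denser check of the truth
  expect_lte(fit$minus2LL, gensi_deviance(dat, th) + 1e-6)
})

test_that("null assortment yields m near 0 and equilibrium refit near r_s = 0.5", {
  th0 <- gensi_parameters(s = 0.55, h = 0.75, m = 0, a = 1, c = 0,
                          r_s = 0.5)
  dat <- sample_families(th0, 3000, seed = 16)
  fit <- fit_model(dat, gensi_model_spec(n_starts = 5, seed = 2))
  expect_lt(abs(fit$estimates[["m"]]), 0.03)
  eq <- fit_model(dat, gensi_model_spec(equilibrium = TRUE, n_starts = 5,
                                        seed = 2))
  expect_lt(abs(eq$theta$r_s - 0.5), 0.03)
})

test_that("profile CI endpoints sit at the chi-square(1) deviance rise", {
  th <- theta_edu()
  dat <- sample_families(th, 1500, seed = 17)
  pd <- rgensi:::gensi_pattern_data(dat)
  fit <- fit_model(pd, gensi_model_spec(n_starts = 4, seed = 2))
  ci <- profile_confidence_interval(pd, fit, "h")
  expect_true(ci["lower"] < fit$estimates[["h"]],
              fit$estimates[["h"]] < ci["upper"])
  for (end in ci) {
    prof <- rgensi:::profiled_deviance(pd, fit$spec, "h", end,
                                       fit$estimates)
    expect_equal(prof - fit$minus2LL, qchisq(0.95, 1), tolerance = 1e-2)
  }
  expect_false(any(attr(ci, "clipped")))
  expect_error(profile_confidence_interval(pd, fit, "a"), "not free")
})

test_that("a boundary estimate clips the profile interval and is flagged", {
  # true c = 0 fitted with c free (latent placement keeps a = 1 feasible)
  th <- gensi_parameters(s = 0.55, h = 0.7, m = 0.5, a = 1, c = 0,
                         r_s = 0.6, c_target = "latent")
  dat <- sample_families(th, 1200, seed = 18)
  pd <- rgensi:::gensi_pattern_data(dat)
  fit <- fit_model(pd, gensi_model_spec(c("s", "h", "m", "c", "r_s"),
                                        c_target = "latent",
                                        n_starts = 4, seed = 2))
  ci <- profile_confidence_interval(pd, fit, "c")
  expect_equal(unname(ci["lower"]), 0)
  expect_true(attr(ci, "clipped")[1])
})

test_that("likelihood-ratio arithmetic matches chi-square tail probabilities", {
  mk <- function(dev, k) structure(list(minus2LL = dev, n_free = k),
                                   class = "gensi_fit")
  lrt <- likelihood_ratio_test(mk(100, 4), mk(96.159, 5))
  expect_equal(lrt$delta_minus2LL, 3.841)
  expect_equal(lrt$p_value, 0.05, tolerance = 1e-3)
  expect_equal(likelihood_ratio_test(mk(101.89, 4), mk(100, 5))$p_value,
               0.1692, tolerance = 1e-3)   # prints as 0.170 at 3 decimals
  expect_equal(likelihood_ratio_test(mk(100, 4), mk(100, 5))$p_value, 1)
  expect_equal(likelihood_ratio_test(mk(100, 4), mk(100, 6))$delta_df, 2)
  expect_error(likelihood_ratio_test(mk(90, 4), mk(100, 5)), "fits better")
  expect_error(likelihood_ratio_test(mk(100, 5), mk(100, 5)), "nested")
})

test_that("the PGS-level equilibrium test accepts a true constraint and rejects inputs it cannot use", {
  set.seed(19)
  rp <- 0.11; rs <- 0.5 * (1 + rp)
  draw <- function(n, r) {
    z <- matrix(rnorm(2 * n), n)
    cbind(z[, 1], r * z[, 1] + sqrt(1 - r^2) * z[, 2])
  }
  out <- pgs_equilibrium_test(draw(8000, rp), draw(2000, rs))
  expect_gt(out$p_value, 0.01)
  expect_equal(out$r_partner, rp, tolerance = 0.05)
  # random-mating partners: constrained sibling correlation pulled to 0.5
  out0 <- pgs_equilibrium_test(draw(8000, 0), draw(2000, 0.5))
  expect_equal(out0$r_sibling_constrained, 0.5, tolerance = 0.03)
  expect_error(pgs_equilibrium_test(cbind(rep(1, 10), rnorm(10)),
                                    draw(100, 0.5)), "degenerate")
  expect_error(pgs_equilibrium_test(draw(100, 0)[, 1, drop = FALSE],
                                    draw(100, 0.5)), "two-column")
})

test_that("the model ladder prefers the generating variant and orders deviances", {
  th <- gensi_parameters(s = 0.6, h = 0.8, m = 0.5, a = 0.8, c = 0,
                         r_s = 0.7)
  dat <- sample_families(th, 4000, seed = 20)
  lad <- fit_model_ladder(dat, n_starts = 4, seed = 3, profile_ci = FALSE)
  expect_equal(lad$selected, "a_free")
  f <- lad$fits
  expect_lte(f$a_free$minus2LL, f$basic$minus2LL + 0.05)
  expect_lte(f$ac_free$minus2LL, f$a_free$minus2LL + 0.05)
  # equilibrium-constrained variants can never fit better than their
  # unconstrained counterparts
  for (v in c("basic", "a_free")) {
    expect_gte(f[[paste0(v, "_eq")]]$minus2LL, f[[v]]$minus2LL - 0.05)
  }
  expect_equal(unname(lad$derived[["in_law"]]),
               unname(lad$derived[["sibling"]] * lad$derived[["partner"]]))
  # basic-model data select the basic variant
  dat0 <- sample_families(theta_edu(), 4000, seed = 21)
  lad0 <- fit_model_ladder(dat0, n_starts = 4, seed = 3, profile_ci = FALSE)
  expect_equal(lad0$selected, "basic")
})
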