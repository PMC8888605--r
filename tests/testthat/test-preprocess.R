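test_that("residualization yields grouped z-scores orthogonal to covariates", {
  set.seed(41)
  # no covariates, one group: plain z-scores
  x <- rnorm(50, mean = 3, sd = 2)
  z <- residualize_standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(cor(z, x), 1)

  # covariate signal removed, variance restored to 1, missing propagated
  pc1 <- rnorm(300); batch <- factor(sample(c("b1", "b2"), 300, TRUE))
  y <- 2 * pc1 + 0.5 * (batch == "b2") + rnorm(300)
  y[c(5, 17)] <- NA
  covs <- data.frame(pc1 = pc1, batch = batch)
  z <- residualize_standardize(y, covs)
  expect_true(all(is.na(z[c(5, 17)])))
  ok <- !is.na(z)
  expect_lt(abs(cor(z[ok], pc1[ok])), 1e-8)
  expect_equal(sd(z[ok]), 1, tolerance = 1e-12)
  # matches the lm-based oracle
  oracle <- residuals(lm(y ~ pc1 + batch, na.action = na.exclude))
  expect_equal(z[ok], as.numeric(scale(oracle[ok])), tolerance = 1e-10)

  # groupwise standardization: each sex standardized separately
  sex <- rep(c("F", "M"), each = 150)
  v <- rnorm(300) + 10 * (sex == "M")
  zs <- residualize_standardize(v, groups = sex)
  for (g in c("F", "M")) {
    expect_equal(mean(zs[sex == g]), 0, tolerance = 1e-12)
    expect_equal(sd(zs[sex == g]), 1, tolerance = 1e-12)
  }

  # rank deficiency names the offending column
  expect_error(
    residualize_standardize(y, data.frame(pc1 = pc1, dup = pc1)), "dup")
})

test_that("family units are assembled from sibling and partner links", {
  ind <- data.frame(id = letters[1:6], sex = "F",
                    phenotype = 1:6 / 10, pgs = 6:1 / 10)
  links <- data.frame(type = c("sibling", "partner", "partner"),
                      id1 = c("b", "a", "c"), id2 = c("c", "b", "d"))
  fam <- build_family_units(ind, links)
  expect_equal(nrow(fam), 1)
  expect_equal(fam$A1_id, "b"); expect_equal(fam$A2_id, "c")
  expect_equal(fam$Q1_id, "a"); expect_equal(fam$Q2_id, "d")
  expect_equal(fam$A1_PHE, 0.2); expect_equal(fam$Q2_PGS, 0.3)
  expect_equal(attr(fam, "n_excluded"), 0L)

  # partner pair with no sibling links forms a two-member family
  fam2 <- build_family_units(ind, data.frame(type = "partner", id1 = "e",
                                             id2 = "f"))
  expect_equal(nrow(fam2), 1)
  expect_true(is.na(fam2$A2_id) && is.na(fam2$Q2_id))

  # co-in-laws who are siblings: family excluded and counted
  links3 <- rbind(links, data.frame(type = "sibling", id1 = "a", id2 = "d"))
  fam3 <- build_family_units(ind, links3)
  expect_equal(attr(fam3, "n_excluded"), 1L)
  expect_false(any(!is.na(fam3$A1_id) & fam3$A1_id == "b" &
                     !is.na(fam3$A2_id) & fam3$A2_id == "c"))

  # conflicting partner links are an error
  expect_error(build_family_units(
    ind, data.frame(type = "partner", id1 = c("a", "a"), id2 = c("b", "c"))),
    "conflicting")
  expect_error(build_family_units(
    ind, data.frame(type = "sibling", id1 = "a", id2 = "z")), "unknown")
})

test_that("family construction is order-invariant and handles large sibships", {
  ind <- data.frame(id = c("s1", "s2", "s3", "p1", "p3"), sex = "F",
                    phenotype = rnorm(5), pgs = rnorm(5))
  links <- data.frame(
    type = c("sibling", "sibling", "partner", "partner"),
    id1 = c("s1", "s2", "p1", "s3"), id2 = c("s2", "s3", "s1", "p3"))
  fam <- build_family_units(ind, links)
  # sibship of three yields all three sibling pairs, flagged overlapping
  expect_equal(nrow(fam), 3)
  expect_true(all(attr(fam, "overlapping")))
  # in-law pairs cannot exceed 2 x sibling pairs; co-in-law pairs cannot
  # exceed sibling pairs
  n_sib <- sum(!is.na(fam$A1_id) & !is.na(fam$A2_id))
  expect_lte(sum(!is.na(fam$Q1_id)) + sum(!is.na(fam$Q2_id)), 2 * n_sib)
  expect_lte(sum(!is.na(fam$Q1_id) & !is.na(fam$Q2_id)), n_sib)

  perm <- c(4, 2, 5, 1, 3)
  fam_p <- build_family_units(ind[perm, ], links[c(3, 1, 4, 2), ])
  key <- function(f) apply(as.data.frame(f)[order(f$A1_id, f$A2_id),
                                            c("A1_id", "A2_id", "Q1_id",
                                              "Q2_id")], 1, paste,
                           collapse = "|")
  expect_identical(unname(key(fam)), unname(key(fam_p)))
  # idempotence: rebuilding from the same inputs gives the same families
  expect_identical(key(build_family_units(ind, links)), key(fam))
})

test_that("correlation tables converge to the implied covariance and pool orientations", {
  th <- theta_full()
  n <- 30000
  dat <- sample_families(th, n, seed = 42)
  tab <- pairwise_correlation_table(dat)
  S <- implied_family_covariance(th)
  g <- function(rel, cell) tab$r[tab$relationship == rel & tab$cell == cell]
  tol <- 4 / sqrt(n)
  expect_equal(g("partner", "phe_phe"), S["A1.PHE", "Q1.PHE"],
               tolerance = tol * 3)
  expect_equal(g("sibling", "pgs_pgs"), S["A1.PGS", "A2.PGS"],
               tolerance = tol * 3)
  expect_equal(g("within", "phe_pgs"), th$s * th$h * th$a, tolerance = tol * 3)
  # pooled in-law cross cell estimates the average of the two orientations
  expect_equal(g("in_law", "phe_pgs"),
               (S["A1.PGS", "Q2.PHE"] + S["A1.PHE", "Q2.PGS"]) / 2,
               tolerance = tol * 6)
  tab2 <- pairwise_correlation_table(dat, pool_orientations = FALSE)
  g2 <- function(cell) tab2$r[tab2$relationship == "in_law" &
                                tab2$cell == cell]
  expect_gt(g2("phe_pgs_2"), g2("phe_pgs_1"))  # h vs h^3 asymmetry
  # intervals contain the estimates; counts match the constructed pairs
  cc <- tab[!is.na(tab$r) & tab$relationship != "within", ]
  expect_true(all(cc$lower <= cc$r & cc$r <= cc$upper))
  expect_true(all(tab$n[tab$relationship == "partner"] == 2 * n))
  expect_true(all(tab$n[tab$relationship == "sibling"] == n))
})

test_that("degenerate correlation cells are reported, not silently computed", {
  fam <- data.frame(family = 1:5, A1_PGS = rnorm(5), A1_PHE = rnorm(5),
                    A2_PGS = rnorm(5), A2_PHE = rnorm(5))
  # identical values in both members force r = 1
  fam$A2_PHE <- fam$A1_PHE
  tab <- pairwise_correlation_table(fam)
  expect_equal(tab$r[tab$relationship == "sibling" & tab$cell == "phe_phe"],
               1)
  # cells without data reported absent
  expect_true(is.na(tab$r[tab$relationship == "partner" &
                            tab$cell == "phe_phe"]))
  fam$A2_PHE <- 1
  expect_error(pairwise_correlation_table(fam), "zero-variance")
})
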