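# shared fixtures built in code

# a mid-range parameter point exercising indirect assortment and shared
# environment
theta_full <- function(c_target = "observed") {
  gensi_parameters(s = 0.5, h = 0.7, m = 0.6, a = 0.8, c = 0.3, r_s = 0.6,
                   c_target = c_target)
}

# education-like generating values used across fitting tests
theta_edu <- function() {
  gensi_parameters(s = 0.55, h = 0.75, m = 0.60, a = 1, c = 0, r_s = 0.60)
}

# rejection-sample a valid random parameter point
random_theta <- function(c_target = sample(c("observed", "latent"), 1)) {
  repeat {
    th <- try(gensi_parameters(
      s = runif(1), h = runif(1), m = runif(1, -1, 1),
      a = runif(1), c = runif(1, 0, 0.7), r_s = runif(1, -1, 1),
      g0 = runif(1, -1, 1), c_target = c_target), silent = TRUE)
    if (!inherits(th, "try-error")) return(th)
  }
}

# dense multivariate-normal deviance oracle, written independently of the
# package's Cholesky/pattern path
dense_mvn_deviance <- function(x, Sigma) {
  obs <- !is.na(x)
  S <- Sigma[obs, obs, drop = FALSE]
  xi <- x[obs]
  k <- sum(obs)
  as.numeric(k * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
               t(xi) %*% solve(S) %*% xi)
}

# turn a wide simulated family table into individuals + links files for the
# preprocessing/CLI layer
families_to_tables <- function(fam) {
  fam <- as.data.frame(fam)
  rows <- list(); links <- list()
  for (i in seq_len(nrow(fam))) {
    ids <- paste0(c("a", "b", "p", "q"), i)
    roles <- c("A1", "A2", "Q1", "Q2")
    for (k in 1:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[k], sex = ifelse(k <= 2, "F", "M"),
        phenotype = fam[[paste0(roles[k], "_PHE")]][i],
        pgs = fam[[paste0(roles[k], "_PGS")]][i])
    }
    links[[length(links) + 1L]] <- data.frame(
      type = c("sibling", "partner", "partner"),
      id1 = c(ids[1], ids[1], ids[2]),
      id2 = c(ids[2], ids[3], ids[4]))
  }
  list(individuals = do.call(rbind, rows), links = do.call(rbind, links))
}
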