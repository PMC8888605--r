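#' Residualize on covariates and standardize within groups
#'
#' Regresses values on covariates by ordinary least squares within each
#' group (default: one group) and z-scores the residuals within group, so
#' the output has mean 0 and SD 1 per group and is orthogonal to every
#' covariate column. Used to remove population structure (principal
#' components) and genotyping-batch effects from polygenic scores and to
#' standardize phenotypes within sex. Missing values propagate.
#'
#' @param values Numeric vector.
#' @param covariates Optional data frame or matrix of covariates (constant
#'   columns are dropped; remaining columns must be full rank).
#' @param groups Optional grouping factor (e.g. sex) for separate
#'   residualization and standardization.
#' @return Numeric vector of standardized residuals, NA where the value or
#'   any covariate is missing.
#' @export
#' @examples
#' x <- rnorm(100); pc1 <- rnorm(100)
#' z <- residualize_standardize(x + 2 * pc1, data.frame(pc1 = pc1))
#' round(c(mean(z), sd(z), cor(z, pc1)), 10)
residualize_standardize <- function(values, covariates = NULL,
                                    groups = NULL) {
  n <- length(values)
  if (is.null(groups)) groups <- rep(1L, n)
  stopifnot(length(groups) == n)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
  }
  out <- rep(NA_real_, n)
  for (g in unique(groups[!is.na(groups)])) {
    sel <- which(!is.na(groups) & groups == g)
    v <- values[sel]
    if (is.null(covariates)) {
      cc <- !is.na(v)
      if (sum(cc) < 2) stop("fewer than 2 non-missing values in group '",
                            g, "'", call. = FALSE)
      r <- v[cc] - mean(v[cc])
    } else {
      X <- covariates[sel, , drop = FALSE]
      cc <- !is.na(v) & stats::complete.cases(X)
      if (sum(cc) < 2) stop("fewer than 2 complete cases in group '",
                            g, "'", call. = FALSE)
      M <- stats::model.matrix(~ ., data = X[cc, , drop = FALSE])
      keep <- c(TRUE, apply(M[, -1, drop = FALSE], 2,
                            function(col) stats::sd(col) > 0))
      M <- M[, keep, drop = FALSE]
      qr_M <- qr(M)
      if (qr_M$rank < ncol(M)) {
        drop_cols <- colnames(M)[qr_M$pivot[-seq_len(qr_M$rank)]]
        stop("covariate matrix is rank deficient in group '", g,
             "'; offending columns: ", paste(drop_cols, collapse = ", "),
             call. = FALSE)
      }
      r <- stats::lm.fit(M, v[cc])$residuals
    }
    s <- stats::sd(r)
    if (s < .Machine$double.eps)
      stop("zero residual variance in group '", g, "'", call. = FALSE)
    out[sel[cc]] <- (r - mean(r)) / s
  }
  out
}

#' Build family units from individuals and relationship links
#'
#' Enumerates sibling pairs and attaches each sibling's partner, producing
#' family units with roles A1, A2 (siblings, ordered by id) and Q1, Q2
#' (their respective partners). Sibships larger than two yield all sibling
#' pairs (flagged as overlapping). Partner couples in which neither member
#' has a sibling yield two-member families. Extended families in which the
#' two partners (the co-in-laws) are themselves siblings are removed and
#' counted. Sibling links are closed transitively: connected components of
#' the sibling graph form sibships.
#'
#' @param individuals Data frame with columns \code{id}, \code{phenotype},
#'   \code{pgs} (extra columns like \code{sex} are carried along but not
#'   used here); ids must be unique.
#' @param links Data frame with columns \code{type} (\code{"partner"} or
#'   \code{"sibling"}), \code{id1}, \code{id2}.
#' @return A \code{"gensi_families"} data frame (wide, one row per family)
#'   with member-id columns \code{A1_id} ... \code{Q2_id} and value columns
#'   as in \code{\link{sample_families}}. Attributes: \code{n_excluded}
#'   (families dropped because co-in-laws were siblings),
#'   \code{n_all_missing} (families dropped with no observed values),
#'   \code{overlapping} (logical per family: from a sibship larger than 2).
#' @export
build_family_units <- function(individuals, links) {
  stopifnot(all(c("id", "phenotype", "pgs") %in% names(individuals)),
            all(c("type", "id1", "id2") %in% names(links)))
  ids <- as.character(individuals$id)
  if (anyDuplicated(ids)) stop("individual ids are not unique",
                               call. = FALSE)
  links$id1 <- as.character(links$id1); links$id2 <- as.character(links$id2)
  unknown <- setdiff(c(links$id1, links$id2), ids)
  if (length(unknown))
    stop("links reference unknown ids: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  if (any(links$id1 == links$id2)) stop("self-links present", call. = FALSE)
  pl <- links[links$type == "partner", ]
  sl <- links[links$type == "sibling", ]

  partner_of <- character(0)
  for (i in seq_len(nrow(pl))) {
    for (sw in list(c(pl$id1[i], pl$id2[i]), c(pl$id2[i], pl$id1[i]))) {
      ex <- partner_of[sw[1]]
      if (!is.na(ex) && length(ex) && ex != sw[2])
        stop("conflicting partner links for id '", sw[1], "'",
             call. = FALSE)
      partner_of[sw[1]] <- sw[2]
    }
  }
  # sibships = connected components of the sibling graph (union-find)
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(sl)))
    parent[find(sl$id1[i])] <- find(sl$id2[i])
  sibship <- vapply(ids, find, "")
  same_sibship <- function(x, y)
    !is.na(x) && !is.na(y) && sibship[x] == sibship[y]

  get_partner <- function(id) {
    p <- partner_of[id]
    if (length(p) == 0 || is.na(p)) NA_character_ else unname(p)
  }
  fams <- list(); overlapping <- logical(0); excluded_sets <- character(0)
  comps <- split(ids, sibship)
  in_sib_family <- character(0)
  for (comp in comps) {
    if (length(comp) < 2) next
    comp <- sort(comp)
    big <- length(comp) > 2
    for (i in seq_len(length(comp) - 1)) for (j in (i + 1):length(comp)) {
      a1 <- comp[i]; a2 <- comp[j]
      q1 <- get_partner(a1); q2 <- get_partner(a2)
      if (!is.na(q1) && !is.na(q2) && same_sibship(q1, q2)) {
        # one extended family may surface as several sibling-pair records
        # (e.g. its mirror image); count it once by member set
        excluded_sets <- union(excluded_sets,
                               paste(sort(c(a1, a2, q1, q2)),
                                     collapse = "|"))
        next
      }
      fams[[length(fams) + 1L]] <- c(A1 = a1, A2 = a2, Q1 = q1, Q2 = q2)
      overlapping <- c(overlapping, big)
      in_sib_family <- c(in_sib_family, a1, a2, q1, q2)
    }
  }
  # partner-only couples: neither member appears in any retained family
  for (i in seq_len(nrow(pl))) {
    pair <- sort(c(pl$id1[i], pl$id2[i]))
    if (any(pair %in% in_sib_family)) next
    fams[[length(fams) + 1L]] <- c(A1 = pair[1], A2 = NA, Q1 = pair[2],
                                   Q2 = NA)
    overlapping <- c(overlapping, FALSE)
  }
  if (!length(fams))
    return(structure(empty_families(),
                     n_excluded = length(excluded_sets),
                     n_all_missing = 0L))
  idm <- do.call(rbind, fams)
  # deduplicate partner-only duplicates
  dup <- duplicated(apply(idm, 1, paste, collapse = "|"))
  idm <- idm[!dup, , drop = FALSE]; overlapping <- overlapping[!dup]

  val <- function(which_ids, col) {
    out <- individuals[[col]][match(which_ids, ids)]
    out[is.na(which_ids)] <- NA
    out
  }
  res <- data.frame(family = seq_len(nrow(idm)))
  for (r in c("A1", "A2", "Q1", "Q2")) {
    res[[paste0(r, "_id")]] <- idm[, r]
    res[[paste0(r, "_PGS")]] <- val(idm[, r], "pgs")
    res[[paste0(r, "_PHE")]] <- val(idm[, r], "phenotype")
  }
  vcols <- gsub(".", "_", gensi_variable_labels(), fixed = TRUE)
  all_missing <- rowSums(!is.na(res[vcols])) == 0
  n_all_missing <- sum(all_missing)
  res <- res[!all_missing, , drop = FALSE]
  overlapping <- overlapping[!all_missing]
  rownames(res) <- NULL
  structure(res, n_excluded = length(excluded_sets),
            n_all_missing = n_all_missing,
            overlapping = overlapping,
            class = c("gensi_families", class(res)))
}

empty_families <- function() {
  res <- data.frame(family = integer(0))
  for (r in c("A1", "A2", "Q1", "Q2")) {
    res[[paste0(r, "_id")]] <- character(0)
    res[[paste0(r, "_PGS")]] <- numeric(0)
    res[[paste0(r, "_PHE")]] <- numeric(0)
  }
  class(res) <- c("gensi_families", class(res))
  res
}

# relationship -> list of (role1, role2) pairs in a family row
relationship_roles <- function() {
  list(within   = list(c("A1", "A1"), c("A2", "A2"), c("Q1", "Q1"),
                       c("Q2", "Q2")),
       partner  = list(c("A1", "Q1"), c("A2", "Q2")),
       sibling  = list(c("A1", "A2")),
       in_law   = list(c("A1", "Q2"), c("A2", "Q1")),
       co_in_law = list(c("Q1", "Q2")))
}

#' Relative-pair correlation table
#'
#' For each relationship type (within person, partner, sibling, in-law,
#' co-in-law) computes Pearson correlations for phenotype-phenotype,
#' phenotype-PGS and PGS-PGS pairs, with pair counts and Fisher-z 95\%
#' confidence intervals. Cross phenotype-PGS cells pool both orientations
#' (each pair contributes both (phenotype1, pgs2) and (phenotype2, pgs1))
#' unless \code{pool_orientations = FALSE}, in which case the two
#' orientations are reported separately (orientation 1 has the phenotype on
#' the role listed first: the sibling side for in-law pairs). When member
#' ids are available (families built by \code{\link{build_family_units}}),
#' duplicate pairs arising from overlapping sibships are counted once.
#'
#' @param families A \code{"gensi_families"} data frame.
#' @param min_pairs Cells with fewer complete pairs are reported as NA
#'   (default 3).
#' @param pool_orientations Logical, see above.
#' @return A data frame of class \code{"gensi_cortab"} with columns
#'   \code{relationship}, \code{cell}, \code{r}, \code{n}, \code{lower},
#'   \code{upper}.
#' @export
pairwise_correlation_table <- function(families, min_pairs = 3,
                                       pool_orientations = TRUE) {
  fam <- as.data.frame(families)
  has_ids <- all(paste0(c("A1", "A2", "Q1", "Q2"), "_id") %in% names(fam))
  get <- function(role, var) {
    col <- paste0(role, "_", var)
    if (col %in% names(fam)) fam[[col]] else rep(NA_real_, nrow(fam))
  }
  pair_key <- function(r1, r2) {
    if (!has_ids) return(NULL)
    k1 <- fam[[paste0(r1, "_id")]]; k2 <- fam[[paste0(r2, "_id")]]
    paste(pmin(k1, k2), pmax(k1, k2))
  }
  fisher_ci <- function(r, n) {
    if (is.na(r) || n < 4 || abs(r) >= 1) return(c(NA_real_, NA_real_))
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  rel_roles <- relationship_roles()
  rows <- list()
  for (rel in names(rel_roles)) {
    pairs <- rel_roles[[rel]]
    # gather member-pair values with dedup keys
    gather <- function(v1, v2) {
      xs <- list(); keys <- list()
      for (p in pairs) {
        xs[[length(xs) + 1L]] <- cbind(get(p[1], v1), get(p[2], v2))
        keys[[length(keys) + 1L]] <-
          if (has_ids) pair_key(p[1], p[2]) else
            paste(seq_len(nrow(fam)), p[1], p[2])
      }
      x <- do.call(rbind, xs); k <- unlist(keys)
      ok <- stats::complete.cases(x)
      x <- x[ok, , drop = FALSE]; k <- k[ok]
      dup <- duplicated(k)
      x[!dup, , drop = FALSE]
    }
    cells <- if (rel == "within") {
      list(phe_pgs = list(c("PHE", "PGS")))
    } else if (pool_orientations) {
      list(phe_phe = list(c("PHE", "PHE")),
           phe_pgs = list(c("PHE", "PGS"), c("PGS", "PHE")),
           pgs_pgs = list(c("PGS", "PGS")))
    } else {
      list(phe_phe = list(c("PHE", "PHE")),
           phe_pgs_1 = list(c("PHE", "PGS")),
           phe_pgs_2 = list(c("PGS", "PHE")),
           pgs_pgs = list(c("PGS", "PGS")))
    }
    for (cell in names(cells)) {
      orient <- cells[[cell]]
      mats <- lapply(orient, function(o) gather(o[1], o[2]))
      x <- do.call(rbind, mats)
      n_pairs <- nrow(mats[[1]])   # distinct pairs (orientations pooled)
      if (n_pairs < min_pairs || nrow(x) < 3) {
        r <- NA_real_; ci <- c(NA_real_, NA_real_)
      } else if (stats::sd(x[, 1]) < .Machine$double.eps ||
                 stats::sd(x[, 2]) < .Machine$double.eps) {
        stop("zero-variance values in cell ", rel, "/", cell,
             call. = FALSE)
      } else {
        r <- stats::cor(x[, 1], x[, 2])
        ci <- fisher_ci(r, n_pairs)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        relationship = rel, cell = cell, r = r, n = n_pairs,
        lower = ci[1], upper = ci[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gensi_cortab", class(out))
  out
}

#' @export
print.gensi_cortab <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$r <- round(y$r, digits); y$lower <- round(y$lower, digits)
  y$upper <- round(y$upper, digits)
  print(y)
  invisible(x)
}

#' Extract partner or sibling PGS pairs from a family dataset
#'
#' Convenience accessor for \code{\link{pgs_equilibrium_test}}: returns the
#' complete two-column pair matrices for a relationship.
#'
#' @param families A \code{"gensi_families"} data frame.
#' @param relationship One of \code{"partner"}, \code{"sibling"},
#'   \code{"in_law"}, \code{"co_in_law"}.
#' @param variable \code{"PGS"} (default) or \code{"PHE"}.
#' @return Two-column numeric matrix of complete pairs.
#' @export
family_pairs <- function(families, relationship, variable = "PGS") {
  fam <- as.data.frame(families)
  pairs <- relationship_roles()[[relationship]]
  if (is.null(pairs) || relationship == "within")
    stop("relationship must be partner, sibling, in_law or co_in_law",
         call. = FALSE)
  x <- do.call(rbind, lapply(pairs, function(p) {
    c1 <- paste0(p[1], "_", variable); c2 <- paste0(p[2], "_", variable)
    if (!all(c(c1, c2) %in% names(fam))) return(NULL)
    cbind(fam[[c1]], fam[[c2]])
  }))
  x[stats::complete.cases(x), , drop = FALSE]
}
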