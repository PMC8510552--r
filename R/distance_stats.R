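#' Bray-Curtis dissimilarity matrix
#'
#' `BC(k, m) = sum |x_k - x_m| / sum (x_k + x_m)` over OTUs, on counts or
#' proportions.  Pairs of all-zero samples are undefined and returned as
#' `NA`.
#'
#' @param table an [otu_table] or numeric matrix (samples x OTUs).
#' @return symmetric sample x sample matrix in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- as_counts(table)
  if (any(m < 0)) stop_invalid("Bray-Curtis requires non-negative values")
  n <- nrow(m)
  totals <- rowSums(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(n - 1L)) for (l in (k + 1L):n) {
    denom <- totals[k] + totals[l]
    d[k, l] <- d[l, k] <-
      if (denom == 0) NA_real_ else sum(abs(m[k, ] - m[l, ])) / denom
  }
  d
}

# Pearson correlation over complete pairs; missing entries (e.g. undefined
# betaNTI pairs) are dropped pairwise.
mantel_r <- function(v1, v2) {
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(ok) < 3) stop_invalid("fewer than 3 complete pairs")
  if (stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0)
    stop_invalid("constant distance matrix: Mantel r undefined")
  stats::cor(v1[ok], v2[ok])
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the unfolded lower triangles, with significance
#' from simultaneous row/column permutations of the second matrix.  The
#' p-value is one-sided (`r >= observed`), the usual convention for
#' dissimilarity matrices.
#'
#' @param d1,d2 aligned square symmetric matrices.
#' @param n_perm number of permutations (p resolution `1/(n_perm+1)`).
#' @param seed optional seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = NULL) {
  check_square_aligned(d1, d2)
  v1 <- lower_vec(d1)
  r_obs <- mantel_r(v1, lower_vec(d2))
  n <- nrow(d1)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (mantel_r(v1, lower_vec(d2[p, p])) >= r_obs) hits <- hits + 1L
    }
    list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
  })
}

#' Partial Mantel test
#'
#' Correlates the residuals of `d1` and `d2` after linear regression of
#' their unfolded lower triangles on the control matrices; significance by
#' permuting `d1` (rows and columns simultaneously) and recomputing the
#' residual correlation.
#'
#' @param d1,d2 aligned square symmetric matrices.
#' @param controls list of control distance matrices (>= 1).
#' @param n_perm,seed as in [mantel].
#' @return list with `r`, `p`, `n_perm`.
#' @export
partial_mantel <- function(d1, d2, controls, n_perm = 999, seed = NULL) {
  if (!is.list(controls) || length(controls) < 1)
    stop_invalid("at least one control matrix is required")
  do.call(check_square_aligned, c(list(d1, d2), controls))
  # permutations move entries around, so missing pairs are handled by
  # dropping the samples that carry them
  mats <- c(list(d1, d2), controls)
  bad <- Reduce("|", lapply(mats, function(m) rowSums(!is.finite(m)) > 0))
  if (any(bad)) {
    keep <- which(!bad)
    if (length(keep) < 4) stop_invalid("too few complete samples")
    d1 <- d1[keep, keep]; d2 <- d2[keep, keep]
    controls <- lapply(controls, function(m) m[keep, keep])
  }
  X <- do.call(cbind, lapply(controls, lower_vec))
  v2 <- lower_vec(d2)
  ok <- is.finite(v2) & apply(is.finite(X), 1L, all) &
    is.finite(lower_vec(d1))
  if (sum(ok) < 3) stop_invalid("fewer than 3 complete pairs")
  qrX <- qr(cbind(1, X[ok, , drop = FALSE]))
  if (qrX$rank < ncol(X) + 1)
    warning("collinear control matrices: rank-deficient design",
            call. = FALSE)
  res2 <- qr.resid(qrX, v2[ok])
  tol <- 1e-9 * max(1, stats::sd(v2[ok]))
  part_r <- function(m1) {
    r1 <- qr.resid(qrX, lower_vec(m1)[ok])
    if (stats::sd(r1) <= tol || stats::sd(res2) <= tol) return(0)
    stats::cor(r1, res2)
  }
  r_obs <- part_r(d1)
  n <- nrow(d1)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (part_r(d1[p, p]) >= r_obs) hits <- hits + 1L
    }
    list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
  })
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the response matrix's lower triangle on the predictors' lower
#' triangles; per-coefficient and model p-values by permuting the response
#' matrix rows/columns.
#'
#' @param response square symmetric response matrix.
#' @param predictors named list of predictor matrices.
#' @param n_perm,seed as in [mantel].
#' @return list with `coefficients` (data.frame: term, estimate, p),
#'   `r_squared`, `p_model`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL) {
  if (!is.list(predictors) || length(predictors) < 1)
    stop_invalid("at least one predictor matrix is required")
  do.call(check_square_aligned, c(list(response), predictors))
  X <- cbind(1, do.call(cbind, lapply(predictors, lower_vec)))
  nms <- names(predictors)
  if (is.null(nms)) nms <- paste0("X", seq_along(predictors))
  colnames(X) <- c("(Intercept)", nms)
  if (qr(X)$rank < ncol(X)) {
    drop_check <- vapply(seq_along(predictors), function(j)
      qr(X[, -(j + 1L), drop = FALSE])$rank == ncol(X) - 1L, logical(1))
    stop_invalid("singular design; collinear predictor(s): ",
                 paste(nms[drop_check], collapse = ", "))
  }
  fit_once <- function(y) {
    fit <- stats::lm.fit(X, y)
    b <- fit$coefficients
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    list(b = b, r2 = if (sst == 0) 1 else 1 - ssr / sst)
  }
  y <- lower_vec(response)
  obs <- fit_once(y)
  n <- nrow(response)
  with_seed(seed, {
    hit_b <- numeric(length(obs$b))
    hit_r2 <- 0
    for (bi in seq_len(n_perm)) {
      p <- sample.int(n)
      perm <- fit_once(lower_vec(response[p, p]))
      hit_b <- hit_b + (abs(perm$b) >= abs(obs$b))
      hit_r2 <- hit_r2 + (perm$r2 >= obs$r2)
    }
    list(coefficients = data.frame(term = colnames(X),
                                   estimate = unname(obs$b),
                                   p = unname((hit_b + 1) / (n_perm + 1))),
         r_squared = obs$r2,
         p_model = (hit_r2 + 1) / (n_perm + 1),
         n_perm = n_perm)
  })
}

#' Regress community dissimilarity on environmental difference
#'
#' Fits first- and second-order polynomials of pairwise `|delta env|`
#' against pairwise community dissimilarity.
#'
#' @param community_dist square symmetric dissimilarity matrix.
#' @param env_values numeric vector, one value per sample.
#' @return list with `linear` and `quadratic` fits (each: coefficients,
#'   r_squared, slope p from the `lm` t-test) and the unfolded data.
#' @export
dissimilarity_env_regression <- function(community_dist, env_values) {
  if (!is.numeric(env_values) || length(env_values) != nrow(community_dist))
    stop_invalid("env_values must be numeric, one per sample")
  dd <- euclidean_distance_1d(env_values)
  y <- lower_vec(community_dist)
  x <- lower_vec(dd)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop_invalid("fewer than 3 pairs")
  if (stats::sd(x) == 0) stop_invalid("environmental differences are constant")
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + I(x^2))
  summ <- function(f) list(
    coefficients = stats::coef(f),
    r_squared = summary(f)$r.squared,
    p = stats::coef(summary(f))[2L, 4L])
  list(linear = summ(f1), quadratic = summ(f2),
       data = data.frame(env_diff = x, dissimilarity = y))
}

#' Levins' niche breadth
#'
#' `B_j = 1 / sum_i P_ij^2` with `P_ij` the proportion of OTU `j`'s total
#' abundance found in community `i`; the inverse Simpson concentration of
#' an OTU over communities.  `B_com` is the unweighted mean of `B_j` over
#' the OTUs present (count > 0) in each community.
#'
#' @param table an [otu_table]; OTUs absent everywhere are excluded.
#' @return list with `B` (named per-OTU) and `B_com` (named per-sample).
#' @export
levins_niche_breadth <- function(table) {
  m <- as_counts(table)
  totals <- colSums(m)
  keep <- totals > 0
  m <- m[, keep, drop = FALSE]
  P <- sweep(m, 2L, colSums(m), "/")
  B <- 1 / colSums(P^2)
  B_com <- vapply(seq_len(nrow(m)), function(i) {
    present <- m[i, ] > 0
    if (!any(present)) return(NA_real_)
    mean(B[present])
  }, numeric(1))
  names(B_com) <- rownames(m)
  list(B = B, B_com = B_com)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @return list with `statistic` (W), `p`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop_invalid("both groups must be non-empty")
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values tied; p = 1", call. = FALSE)
    return(list(statistic = length(values_a) * length(values_b) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
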