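#' Partition community variation into environmental and spatial fractions
#'
#' Environmental predictors are the principal components of the scaled
#' environment table retained by the Kaiser-Guttman rule (eigenvalue above
#' the mean).  Spatial predictors are distance-based Moran eigenvector maps
#' (dbMEM, via [vegan::pcnm] with truncation at the longest minimum
#' spanning tree edge of the geographic distances), restricted to vectors
#' with positive spatial autocorrelation and then forward-selected against
#' the community ([vegan::ordistep]), the standard dbMEM practice that
#' keeps unselected eigenvectors from soaking up variance.  Canonical
#' correspondence analysis of the community on `[E]`, `[S]` and `[E+S]`
#' yields the fractions by inertia differences; they are reported as
#' shares of total inertia.
#'
#' @param table an [otu_table].
#' @param env_table numeric data.frame/matrix of environmental variables
#'   (one row per sample); standardized internally.
#' @param coords data.frame with `latitude`, `longitude` per sample.
#' @return list of class `vpa_result`: `pure_env`, `pure_space`, `shared`,
#'   `residual`, `n_env_axes`, `n_mem`.
#' @export
variation_partitioning <- function(table, env_table, coords) {
  m <- as_counts(table)
  if (nrow(m) < 3) stop_invalid("need >= 3 samples")
  env <- as.matrix(env_table)
  env <- env[, apply(env, 2L, stats::sd) > 0, drop = FALSE]
  env <- scale(env)

  pc <- stats::prcomp(env)
  ev <- pc$sdev^2
  keep_axes <- which(ev > mean(ev))
  E <- pc$x[, keep_axes, drop = FALSE]

  gd <- geographic_distance(data.frame(sample_id = rownames(m), coords))
  pcnm_fit <- vegan::pcnm(stats::as.dist(gd))
  # pcnm returns eigenvectors for positive eigenvalues; keep those with
  # positive spatial autocorrelation (Moran's I above its expectation)
  # under the truncation-neighbourhood weights
  S <- as.matrix(pcnm_fit$vectors)
  W <- (gd <= pcnm_fit$threshold) * 1
  diag(W) <- 0
  n_s <- nrow(gd)
  moran <- apply(S, 2L, function(v) {
    v <- v - mean(v)
    (n_s / sum(W)) * (t(v) %*% W %*% v) / sum(v^2)
  })
  S <- S[, moran > -1 / (n_s - 1), drop = FALSE]
  # forward selection of MEMs against the community
  S_df <- as.data.frame(S)
  # ordistep re-evaluates `cca(...)` calls in the formula environment, so
  # give it one where vegan's cca and the data are visible
  env <- new.env(parent = getNamespace("vegan"))
  env$m <- m
  env$S_df <- S_df
  m0 <- eval(quote(cca(m ~ 1, data = S_df)), env)
  mf <- eval(quote(cca(m ~ ., data = S_df)), env)
  sel <- suppressMessages(vegan::ordistep(
    m0, scope = stats::formula(mf), direction = "forward", trace = FALSE,
    permutations = 199))
  kept <- labels(stats::terms(sel))
  S <- S[, kept, drop = FALSE]
  max_pred <- max(1L, nrow(m) - 2L)
  if (ncol(E) + ncol(S) > max_pred) {
    warning("more predictors than samples support; truncating", call. = FALSE)
    nS <- max(0L, max_pred - ncol(E))
    S <- S[, seq_len(min(ncol(S), nS)), drop = FALSE]
  }

  frac <- function(X) {
    if (is.null(X) || ncol(X) == 0) return(0)
    fit <- vegan::cca(m ~ ., data = as.data.frame(X))
    fit$CCA$tot.chi / fit$tot.chi
  }
  f_e <- frac(E)
  f_s <- frac(S)
  f_es <- if (ncol(S) == 0) f_e else frac(cbind(E, S))
  out <- list(pure_env = f_es - f_s, pure_space = f_es - f_e,
              shared = f_e + f_s - f_es, residual = 1 - f_es,
              total_explained = f_es,
              n_env_axes = ncol(E), n_mem = ncol(S))
  class(out) <- "vpa_result"
  out
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf(
    "Variation partitioning (CCA): pure E %.3f | shared %.3f | pure S %.3f | residual %.3f\n",
    x$pure_env, x$shared, x$pure_space, x$residual))
  invisible(x)
}
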