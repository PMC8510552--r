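# --- SparCC: correlation inference for compositional count data -------------

# Log-ratio variance matrix t_ij = Var(log x_i / x_j) from one fraction
# estimate (samples x OTUs, rows sum to 1).
log_ratio_variances <- function(frac) {
  lf <- log(frac)
  n <- ncol(lf)
  v <- stats::var(lf)
  d <- diag(v)
  outer(d, d, "+") - 2 * v
}

# Solve basis variances from t under the sparsity assumption, by least
# squares over the included pairs: minimize sum (t_ij - w_i - w_j)^2.
# `include` is a logical OTU x OTU matrix of pairs still in the system.
solve_basis_variances <- function(t_mat, include) {
  n <- nrow(t_mat)
  A <- diag(rowSums(include)) + include
  b <- rowSums(t_mat * include)
  w <- tryCatch(solve(A, b), error = function(e)
    stop_invalid("basis system unsolvable after exclusions; ",
                 "lower exclusion_rounds or raise exclusion_r"))
  w
}

basis_correlations <- function(t_mat, w) {
  w <- pmax(w, 1e-10)
  rho <- (outer(w, w, "+") - t_mat) / (2 * outer(sqrt(w), sqrt(w)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

# One SparCC estimate from one fraction matrix, with iterative exclusion
# of the most strongly correlated pair (classic sparsity refinement).
sparcc_once <- function(frac, exclusion_r, exclusion_rounds) {
  n <- ncol(frac)
  t_mat <- log_ratio_variances(frac)
  include <- matrix(TRUE, n, n)
  diag(include) <- FALSE
  excluded <- matrix(FALSE, n, n)
  for (round in seq_len(exclusion_rounds + 1L)) {
    w <- solve_basis_variances(t_mat, include)
    rho <- basis_correlations(t_mat, w)
    if (round > exclusion_rounds) break
    cand <- abs(rho)
    cand[!include] <- 0
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_r) break
    idx <- which(cand == mx, arr.ind = TRUE)[1L, ]
    include[idx[1L], idx[2L]] <- include[idx[2L], idx[1L]] <- FALSE
    excluded[idx[1L], idx[2L]] <- excluded[idx[2L], idx[1L]] <- TRUE
    if (any(rowSums(include) < 2))
      stop_invalid("too many excluded pairs for ", n, " OTUs; ",
                   "raise exclusion_r or provide more OTUs")
  }
  list(rho = rho, w = w, excluded = excluded)
}

sparcc_point <- function(counts, n_iter, exclusion_r, exclusion_rounds) {
  n_otu <- ncol(counts)
  rhos <- array(NA_real_, c(n_otu, n_otu, n_iter))
  excl <- matrix(FALSE, n_otu, n_otu)
  for (it in seq_len(n_iter)) {
    frac <- t(apply(counts, 1L, function(x) rdirichlet1(x + 1)))
    est <- sparcc_once(frac, exclusion_r, exclusion_rounds)
    rhos[, , it] <- est$rho
    excl <- excl | est$excluded
  }
  rho <- apply(rhos, c(1L, 2L), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  list(rho = rho, excluded = excl)
}

#' SparCC correlations between OTUs
#'
#' Estimates correlations of the unobserved absolute abundances from
#' compositional counts.  Fractions are drawn from a Dirichlet posterior
#' (counts + 1); log-ratio variances `t_ij = Var(log x_i/x_j)` are
#' converted to basis variances under the sparsity assumption by least
#' squares, with iterative exclusion of the most correlated pair; the
#' median over `n_iter` Dirichlet draws is the point estimate.  Two-sided
#' pseudo p-values come from `n_bootstrap` null datasets in which every
#' OTU's counts are shuffled independently across samples.
#'
#' @param counts an [otu_table] with >= 4 OTUs.
#' @param n_iter Dirichlet resampling iterations for the point estimate.
#' @param exclusion_r threshold above which the most correlated pair is
#'   excluded from the basis system.
#' @param exclusion_rounds maximum number of exclusion rounds.
#' @param n_bootstrap null datasets for p-values (0 skips them).
#' @param seed optional seed.
#' @return list of class `sparcc_result`: `rho`, `p`, `p_adjusted` (BH),
#'   `excluded`, `n_iter`, `n_bootstrap`.
#' @export
sparcc <- function(counts, n_iter = 20, exclusion_r = 0.1,
                   exclusion_rounds = 10, n_bootstrap = 100, seed = NULL) {
  m <- as_counts(counts)
  if (ncol(m) < 4) stop_invalid("SparCC needs >= 4 OTUs")
  with_seed(seed, {
    est <- sparcc_point(m, n_iter, exclusion_r, exclusion_rounds)
    rho <- est$rho
    dimnames(rho) <- list(colnames(m), colnames(m))
    p <- p_adj <- NULL
    if (n_bootstrap > 0) {
      exceed <- matrix(0, ncol(m), ncol(m))
      for (b in seq_len(n_bootstrap)) {
        null_m <- apply(m, 2L, sample)
        # fewer inner iterations suffice for the null spread
        null_rho <- sparcc_point(null_m, max(2L, n_iter %/% 4L),
                                 exclusion_r, exclusion_rounds)$rho
        exceed <- exceed + (abs(null_rho) >= abs(rho))
      }
      p <- (exceed + 1) / (n_bootstrap + 1)
      diag(p) <- 0
      pv <- lower_vec(p)
      pa <- bh_adjust(pv)
      p_adj <- matrix(0, ncol(m), ncol(m))
      p_adj[lower.tri(p_adj)] <- pa
      p_adj <- p_adj + t(p_adj)
      dimnames(p) <- dimnames(p_adj) <- dimnames(rho)
    }
    structure(list(rho = rho, p = p, p_adjusted = p_adj,
                   excluded = est$excluded, n_iter = n_iter,
                   n_bootstrap = n_bootstrap),
              class = "sparcc_result")
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control with the usual monotonicity enforcement.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p_values) {
  p <- p_values
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_invalid("p-values must be in [0, 1]")
  n <- sum(!is.na(p))
  if (n == 0) return(p)
  ord <- order(p, na.last = NA)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- p
  out[ord] <- adj
  out
}
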