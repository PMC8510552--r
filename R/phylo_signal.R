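#' Abundance-weighted niche value of every OTU
#'
#' `niche_j = sum_i rel_ij * env_i / sum_i rel_ij`: the mean of one
#' environmental variable over samples, weighted by the OTU's relative
#' abundances.  OTUs absent from every sample are excluded.
#'
#' @param table an [otu_table].
#' @param metadata metadata data.frame aligned with the table's samples.
#' @param variable name of a numeric metadata column.
#' @return named numeric vector of per-OTU niche values.
#' @export
otu_niche_values <- function(table, metadata, variable) {
  if (!variable %in% names(metadata))
    stop_invalid("variable '", variable, "' not in metadata")
  env <- metadata[[variable]]
  if (!is.numeric(env)) stop_invalid("variable '", variable, "' not numeric")
  m <- as_counts(table)
  if (!is.null(metadata$sample_id)) {
    idx <- match(rownames(m), metadata$sample_id)
    if (any(is.na(idx))) stop_invalid("metadata missing some samples")
    env <- env[idx]
  }
  rel <- relative_abundance(table)
  w <- colSums(rel)
  keep <- w > 0
  drop_n <- sum(!keep)
  if (drop_n) message(drop_n, " OTU(s) absent everywhere excluded")
  niche <- colSums(rel * env)[keep] / w[keep]
  niche
}

#' Mantel correlogram of niche distance against phylogenetic distance
#'
#' For each phylogenetic distance class, the normalized Mantel statistic
#' between the niche distance matrix and the class-membership indicator is
#' computed with the conventional sign flip, so positive values mean
#' niches are more similar than average at that phylogenetic distance.
#' Significance is by permuting the niche values (999 permutations by
#' default), with progressive Holm correction across classes.
#'
#' @param phylo_dist,niche_dist aligned square symmetric matrices over the
#'   same OTUs.
#' @param n_classes number of equal-width distance classes; default by
#'   Sturges' rule on the number of pairs.
#' @param n_perm permutations per class.
#' @param seed optional seed.
#' @param alpha significance level for the corrected flags.
#' @return data.frame of class `mantel_correlogram`: `class_index`,
#'   `midpoint`, `n_pairs`, `r`, `p`, `p_corrected`, `significant`.
#' @export
mantel_correlogram <- function(phylo_dist, niche_dist, n_classes = NULL,
                               n_perm = 999, seed = NULL, alpha = 0.05) {
  check_square_aligned(phylo_dist, niche_dist)
  n <- nrow(phylo_dist)
  pd <- lower_vec(phylo_dist)
  n_pairs <- length(pd)
  if (is.null(n_classes)) n_classes <- ceiling(log2(n_pairs) + 1)
  breaks <- seq(0, max(pd), length.out = n_classes + 1L)
  cls <- cut(pd, breaks, include.lowest = TRUE, labels = FALSE)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2

  # permutations shuffle rows/columns of the niche distance matrix, which
  # is equivalent to shuffling niche values across OTUs
  class_r_mat <- function(ndm) {
    nd <- lower_vec(ndm)
    vapply(seq_len(n_classes), function(k) {
      ind <- as.numeric(cls == k)
      if (sum(ind) < 2 || stats::sd(ind) == 0 || stats::sd(nd) == 0)
        return(NA_real_)
      -stats::cor(nd, ind)
    }, numeric(1))
  }

  r_obs <- class_r_mat(niche_dist)
  with_seed(seed, {
    hits <- matrix(0, n_perm, n_classes)
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      hits[b, ] <- class_r_mat(niche_dist[p, p])
    }
    # two-sided permutation p per class
    pvals <- vapply(seq_len(n_classes), function(k) {
      if (is.na(r_obs[k])) return(NA_real_)
      (sum(abs(hits[, k]) >= abs(r_obs[k]), na.rm = TRUE) + 1) / (n_perm + 1)
    }, numeric(1))
    keep <- !is.na(r_obs)
    pc <- rep(NA_real_, n_classes)
    kept_idx <- which(keep)
    for (j in seq_along(kept_idx)) {
      upto <- kept_idx[seq_len(j)]
      pc[kept_idx[j]] <- stats::p.adjust(pvals[upto], method = "holm")[j]
    }
    out <- data.frame(class_index = seq_len(n_classes), midpoint = mids,
                      n_pairs = as.integer(tabulate(cls, n_classes)),
                      r = r_obs, p = pvals, p_corrected = pc,
                      significant = !is.na(pc) & pc <= alpha)
    dropped <- out$n_pairs < 2
    if (any(dropped))
      message(sum(dropped), " distance class(es) with < 2 pairs dropped")
    out <- out[!dropped, , drop = FALSE]
    class(out) <- c("mantel_correlogram", "data.frame")
    out
  })
}
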