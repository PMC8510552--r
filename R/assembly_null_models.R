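# --- beta mean nearest taxon distance and its null models -------------------

# For each sample, the distance from every OTU in the pool to its nearest
# taxon present in that sample: columns of the returned matrix index
# samples, rows index OTUs.  Vectorizes betaMNTD over all sample pairs.
nearest_taxon_mins <- function(D, presence) {
  n_samp <- nrow(presence)
  out <- matrix(NA_real_, nrow = ncol(D), ncol = n_samp)
  for (s in seq_len(n_samp)) {
    idx <- which(presence[s, ])
    if (!length(idx)) next
    sub <- D[, idx, drop = FALSE]
    out[, s] <- do.call(pmin, c(asplit(sub, 2L), list(na.rm = TRUE)))
  }
  out
}

beta_mntd_from_mins <- function(rel, mins) {
  # betaMNTD(k, m) = 0.5 * (rel[k, ] %*% mins[, m] + rel[m, ] %*% mins[, k])
  B <- rel %*% mins
  bm <- 0.5 * (B + t(B))
  diag(bm) <- 0
  bm
}

#' Beta mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted mean phylogenetic distance from each OTU in one
#' community to its evolutionarily closest OTU in the other:
#' `0.5 * [ sum_j rel_jk min_j' d(j, j') + sum_j rel_jm min_j' d(j, j') ]`,
#' with the minimum taken over OTUs present in the other community (a
#' shared OTU contributes distance 0).  OTUs with zero abundance in a
#' sample are excluded from that sample's terms.
#'
#' @param table an [otu_table] or relative-abundance matrix.
#' @param phylo_dist patristic distance matrix covering all table OTUs.
#' @param weighted use relative abundances (`TRUE`, the default) or
#'   presence/absence weights.
#' @return symmetric sample x sample matrix; pairs involving an empty
#'   community are `NA`.
#' @export
beta_mntd <- function(table, phylo_dist, weighted = TRUE) {
  m <- as_counts(table)
  if (!all(colnames(m) %in% rownames(phylo_dist)))
    stop_invalid("phylo_dist must cover all table OTUs")
  D <- phylo_dist[colnames(m), colnames(m)]
  totals <- rowSums(m)
  empty <- totals == 0
  rel <- m
  rel[!empty, ] <- m[!empty, , drop = FALSE] / totals[!empty]
  if (!weighted) {
    rel <- (m > 0) * 1
    rs <- rowSums(rel)
    rel[rs > 0, ] <- rel[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  mins <- nearest_taxon_mins(D, m > 0)
  bm <- beta_mntd_from_mins(rel, mins)
  if (any(empty)) {
    bm[empty, ] <- NA_real_
    bm[, empty] <- NA_real_
    diag(bm) <- ifelse(empty, NA_real_, 0)
    warning("empty sample(s): betaMNTD undefined for their pairs",
            call. = FALSE)
  }
  dimnames(bm) <- list(rownames(m), rownames(m))
  bm
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized deviation of observed betaMNTD from a null distribution
#' generated by shuffling OTU identities across the tips of the phylogeny
#' (the "taxa.labels" null), recomputing betaMNTD per randomization, and
#' standardizing per sample pair:
#' `(obs - mean(null)) / sd(null)`.
#'
#' @param table an [otu_table].
#' @param tree `phylo` covering the table's OTUs (or a patristic distance
#'   matrix via `phylo_dist`).
#' @param n_null number of randomizations.
#' @param seed optional seed.
#' @param phylo_dist optional precomputed patristic distances.
#' @return list of class `beta_nti`: `bnti` (sample x sample), `bmntd`
#'   observed, `n_null`.
#' @export
beta_nti <- function(table, tree = NULL, n_null = 1000, seed = NULL,
                     phylo_dist = NULL) {
  if (is.null(phylo_dist)) {
    if (is.null(tree)) stop_invalid("provide tree or phylo_dist")
    phylo_dist <- patristic_distances(tree)
  }
  m <- as_counts(table)
  if (!all(colnames(m) %in% rownames(phylo_dist)))
    stop_invalid("phylogeny must cover all table OTUs")
  D <- phylo_dist[colnames(m), colnames(m)]
  n_otu <- ncol(m)
  totals <- rowSums(m)
  rel <- sweep(m, 1L, pmax(totals, 1), "/")
  presence <- m > 0
  obs <- beta_mntd_from_mins(rel, nearest_taxon_mins(D, presence))

  with_seed(seed, {
    s1 <- matrix(0, nrow(m), nrow(m))
    s2 <- matrix(0, nrow(m), nrow(m))
    for (b in seq_len(n_null)) {
      p <- sample.int(n_otu)
      Dn <- D[p, p]
      bn <- beta_mntd_from_mins(rel, nearest_taxon_mins(Dn, presence))
      s1 <- s1 + bn
      s2 <- s2 + bn^2
    }
    mu <- s1 / n_null
    sd_null <- sqrt(pmax(s2 / n_null - mu^2, 0) * n_null / (n_null - 1))
    bnti <- (obs - mu) / sd_null
    bnti[sd_null == 0] <- NA_real_
    diag(bnti) <- 0
    if (any(is.na(bnti[lower.tri(bnti)])))
      warning("null sd = 0 for some pair(s): betaNTI reported NA",
              call. = FALSE)
    if (any(totals == 0)) {
      bnti[totals == 0, ] <- NA_real_
      bnti[, totals == 0] <- NA_real_
    }
    dimnames(bnti) <- dimnames(obs) <- list(rownames(m), rownames(m))
    structure(list(bnti = bnti, bmntd = obs, n_null = n_null),
              class = "beta_nti")
  })
}

#' Abundance-based Raup-Crick metric on Bray-Curtis dissimilarities
#'
#' The null assembly preserves each sample's observed richness and total
#' reads: OTUs are drawn without replacement with probability proportional
#' to their occurrence frequency, then reads are distributed among the
#' drawn OTUs proportionally to metacommunity relative abundance.  For
#' each pair, `RC = [(#null < obs) + 0.5 (#null = obs)] / n_null`,
#' rescaled to `[-1, 1]` by `2 RC - 1`.
#'
#' @param table an [otu_table] of counts (not proportions).
#' @param n_null number of null table draws.
#' @param seed optional seed.
#' @return list of class `raup_crick`: `rc` (sample x sample in `[-1, 1]`),
#'   `n_null`.
#' @export
raup_crick_bc <- function(table, n_null = 1000, seed = NULL) {
  m <- as_counts(table)
  n_samp <- nrow(m)
  richness <- rowSums(m > 0)
  reads <- rowSums(m)
  if (any(richness == 0))
    warning("sample(s) with richness 0: their pairs are NA", call. = FALSE)
  occ <- colSums(m > 0)
  abund <- colSums(m)
  occ_p <- occ / sum(occ)
  ab_p <- abund / sum(abund)
  obs <- bray_curtis(m)
  n_otu <- ncol(m)
  with_seed(seed, {
    lt <- lower.tri(obs)
    less <- matrix(0, n_samp, n_samp)
    equal <- matrix(0, n_samp, n_samp)
    null_m <- matrix(0, n_samp, n_otu)
    for (b in seq_len(n_null)) {
      null_m[] <- 0
      for (s in seq_len(n_samp)) {
        r <- richness[s]
        if (r == 0) next
        chosen <- sample.int(n_otu, r, prob = occ_p)
        x <- rep.int(1, r)
        extra <- reads[s] - r
        if (extra > 0) {
          pr <- ab_p[chosen]
          if (sum(pr) == 0) pr <- rep(1, r)
          x <- x + stats::rmultinom(1, extra, pr)[, 1L]
        }
        null_m[s, chosen] <- x
      }
      bc_null <- bray_curtis(null_m)
      less <- less + (bc_null < obs)
      equal <- equal + (bc_null == obs)
    }
    rc <- 2 * ((less + 0.5 * equal) / n_null) - 1
    diag(rc) <- 0
    rc[is.na(obs)] <- NA_real_
    if (any(richness == 0)) {
      rc[richness == 0, ] <- NA_real_
      rc[, richness == 0] <- NA_real_
    }
    dimnames(rc) <- dimnames(obs)
    structure(list(rc = rc, n_null = n_null), class = "raup_crick")
  })
}

#' Classify community turnover into assembly processes
#'
#' Per sample pair: `betaNTI > t` heterogeneous selection; `betaNTI < -t`
#' homogeneous selection; otherwise `RC > s` dispersal limitation,
#' `RC < -s` homogenizing dispersal, `|RC| <= s` drift.  Default
#' thresholds `t = 2`, `s = 0.95` follow the standard null-model
#' framework.
#'
#' @param bnti a [beta_nti] result or betaNTI matrix.
#' @param rc a [raup_crick] result or RC matrix.
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @return list of class `process_fractions` with the per-process
#'   fractions (summing to 1 over valid pairs), pair counts, and the
#'   selection/DL and DL/HD ratios.
#' @export
classify_processes <- function(bnti, rc, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  b <- if (inherits(bnti, "beta_nti")) bnti$bnti else bnti
  r <- if (inherits(rc, "raup_crick")) rc$rc else rc
  check_square_aligned(b, r)
  bv <- lower_vec(b)
  rv <- lower_vec(r)
  ok <- is.finite(bv) & is.finite(rv)
  if (!any(ok)) stop_invalid("no valid sample pairs")
  bv <- bv[ok]; rv <- rv[ok]
  het <- bv > bnti_threshold
  hom <- bv < -bnti_threshold
  neither <- !het & !hom
  dl <- neither & rv > rc_threshold
  hd <- neither & rv < -rc_threshold
  drift <- neither & !dl & !hd
  n <- length(bv)
  fr <- c(heterogeneous_selection = sum(het), homogeneous_selection = sum(hom),
          dispersal_limitation = sum(dl), homogenizing_dispersal = sum(hd),
          drift = sum(drift)) / n
  sel <- fr[["heterogeneous_selection"]] + fr[["homogeneous_selection"]]
  out <- list(
    fraction_selection = sel,
    fraction_heterogeneous_selection = fr[["heterogeneous_selection"]],
    fraction_homogeneous_selection = fr[["homogeneous_selection"]],
    fraction_dispersal_limitation = fr[["dispersal_limitation"]],
    fraction_homogenizing_dispersal = fr[["homogenizing_dispersal"]],
    fraction_drift = fr[["drift"]],
    n_pairs = n,
    selection_to_DL_ratio =
      if (fr[["dispersal_limitation"]] > 0) sel / fr[["dispersal_limitation"]]
      else NA_real_,
    DL_to_HD_ratio =
      if (fr[["homogenizing_dispersal"]] > 0)
        fr[["dispersal_limitation"]] / fr[["homogenizing_dispersal"]]
      else NA_real_)
  class(out) <- "process_fractions"
  out
}

#' @export
print.process_fractions <- function(x, ...) {
  cat(sprintf(paste0(
    "Assembly processes over %d pairs:\n",
    "  selection              %5.1f%% (heterogeneous %.1f%%, homogeneous %.1f%%)\n",
    "  dispersal limitation   %5.1f%%\n",
    "  homogenizing dispersal %5.1f%%\n",
    "  drift                  %5.1f%%\n"),
    x$n_pairs, 100 * x$fraction_selection,
    100 * x$fraction_heterogeneous_selection,
    100 * x$fraction_homogeneous_selection,
    100 * x$fraction_dispersal_limitation,
    100 * x$fraction_homogenizing_dispersal,
    100 * x$fraction_drift))
  invisible(x)
}

#' Relate betaNTI to environmental distance matrices
#'
#' Standard and partial Mantel tests of the betaNTI matrix against an
#' environmental distance matrix, optionally controlling for further
#' matrices.
#'
#' @param bnti a [beta_nti] result or matrix.
#' @param env_dist environmental distance matrix.
#' @param controls optional list of control matrices (triggers the partial
#'   test).
#' @param n_perm,seed as in [mantel].
#' @return list with `r`, `p`, `n_perm`.
#' @export
bnti_env_tests <- function(bnti, env_dist, controls = NULL, n_perm = 999,
                           seed = NULL) {
  b <- if (inherits(bnti, "beta_nti")) bnti$bnti else bnti
  if (is.null(controls) || !length(controls))
    mantel(b, env_dist, n_perm = n_perm, seed = seed)
  else
    partial_mantel(b, env_dist, controls, n_perm = n_perm, seed = seed)
}

#' Per-stratum process fractions
#'
#' Runs betaNTI, Raup-Crick and [classify_processes] within sample strata
#' (e.g. habitat class, depth layer, and all samples), mirroring grouped
#' process-fraction bar charts.
#'
#' @param table an [otu_table].
#' @param tree `phylo` covering the OTUs.
#' @param metadata aligned metadata.
#' @param strata named list mapping stratum label to a character vector of
#'   sample ids; defaults to all samples plus each habitat class and layer.
#' @param n_null randomizations for both null models.
#' @param seed optional seed.
#' @param ... passed to [classify_processes].
#' @return named list of `process_fractions`.
#' @export
assembly_by_stratum <- function(table, tree, metadata, strata = NULL,
                                n_null = 1000, seed = NULL, ...) {
  validate_metadata(metadata)
  m <- as_counts(table)
  if (is.null(strata)) {
    strata <- list(all = metadata$sample_id)
    for (h in unique(metadata$habitat_class))
      strata[[h]] <- metadata$sample_id[metadata$habitat_class == h]
    for (l in unique(metadata$layer))
      strata[[l]] <- metadata$sample_id[metadata$layer == l]
  }
  D <- patristic_distances(tree)
  out <- list()
  k <- 0L
  for (nm in names(strata)) {
    k <- k + 1L
    ids <- intersect(strata[[nm]], rownames(m))
    if (length(ids) < 3) next
    sub <- otu_table(m[ids, , drop = FALSE])
    sub <- otu_table(as_counts(sub)[, colSums(as_counts(sub)) > 0,
                                    drop = FALSE])
    bn <- beta_nti(sub, phylo_dist = D, n_null = n_null,
                   seed = derive_seed(seed, k))
    rc <- raup_crick_bc(sub, n_null = n_null,
                        seed = derive_seed(seed, k + 1000L))
    out[[nm]] <- classify_processes(bn, rc, ...)
  }
  out
}
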