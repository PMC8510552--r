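# --- co-occurrence network construction and characterization ----------------

#' Build a co-occurrence network from SparCC correlations
#'
#' Keeps an edge between two OTUs iff `|r| >= r_min` (inclusive) and the
#' BH-adjusted p-value is `< p_max` (strict).  The edge sign and the
#' correlation are stored as attributes; isolated nodes are dropped.
#'
#' @param corr a [sparcc] result (or list with `rho` and `p_adjusted`).
#' @param r_min correlation magnitude threshold.
#' @param p_max adjusted p-value threshold.
#' @param node_groups optional named vector tagging nodes (e.g.
#'   protist/bacteria), stored as a vertex attribute.
#' @return an undirected simple `igraph` graph with edge attributes
#'   `weight` (|r|), `r`, `sign`.
#' @export
build_network <- function(corr, r_min = 0.7, p_max = 0.01,
                          node_groups = NULL) {
  rho <- corr$rho
  padj <- corr$p_adjusted
  if (is.null(rho)) stop_invalid("corr must contain a correlation matrix")
  keep <- abs(rho) >= r_min
  if (!is.null(padj)) keep <- keep & (padj < p_max)
  diag(keep) <- FALSE
  idx <- which(keep & lower.tri(keep), arr.ind = TRUE)
  ids <- rownames(rho)
  if (nrow(idx) == 0) {
    warning("no edges survive the thresholds; empty network", call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      r = rho[idx])
  edges$weight <- abs(edges$r)
  edges$sign <- ifelse(edges$r >= 0, 1L, -1L)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  if (!is.null(node_groups)) {
    igraph::V(g)$group <-
      unname(node_groups[igraph::V(g)$name])
  }
  g
}

#' Balanced random subsample of sample ids by group
#'
#' @param metadata metadata data.frame.
#' @param group_field column to balance on.
#' @param n_per_group samples drawn per group (each group must have at
#'   least that many).
#' @param seed optional seed.
#' @return character vector of sample ids, `n_per_group` per group.
#' @export
balanced_subsample <- function(metadata, group_field, n_per_group,
                               seed = NULL) {
  if (!group_field %in% names(metadata))
    stop_invalid("group_field '", group_field, "' not in metadata")
  groups <- split(metadata$sample_id, metadata[[group_field]])
  short <- names(groups)[vapply(groups, length, 1L) < n_per_group]
  if (length(short))
    stop_invalid("group(s) with fewer than ", n_per_group, " samples: ",
                 paste(short, collapse = ", "))
  with_seed(seed, {
    unlist(lapply(groups, function(ids)
      if (length(ids) == n_per_group) ids
      else sample(ids, n_per_group)), use.names = FALSE)
  })
}

#' Detect network modules (greedy modularity optimization)
#'
#' Louvain multilevel optimization on the unweighted graph with a fixed
#' seed, returning the module assignment and Newman's modularity
#' `Q = sum_c [L_c/m - (d_c/2m)^2]`.
#'
#' @param net an `igraph` graph.
#' @param seed optional seed.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(net, seed = NULL) {
  if (igraph::vcount(net) == 0) stop_invalid("empty network")
  with_seed(if (is.null(seed)) 1L else seed, {
    cl <- igraph::cluster_louvain(net, weights = NA)
    memb <- igraph::membership(cl)
    list(membership = stats::setNames(as.integer(memb),
                                      igraph::V(net)$name),
         modularity = igraph::modularity(net, memb))
  })
}

#' Topology summary of a co-occurrence network
#'
#' All metrics are computed on the unweighted, unsigned simple graph;
#' diameter and average path length refer to the largest connected
#' component; clustering is the mean local clustering coefficient
#' (isolates and degree-1 nodes contribute 0); betweenness is the mean
#' shortest-path betweenness; assortativity is the Pearson degree
#' correlation over edge endpoints.  Edge signs are used only for the
#' percentage of positive/negative edges.
#'
#' @param net an `igraph` graph (non-empty).
#' @param modules optional [detect_modules] result; computed if missing.
#' @param seed seed for module detection.
#' @return list of class `topology_summary`.
#' @export
topology_summary <- function(net, modules = NULL, seed = NULL) {
  n <- igraph::vcount(net)
  if (n == 0) stop_invalid("empty network")
  e <- igraph::ecount(net)
  avg_degree <- 2 * e / n
  density <- if (n > 1) 2 * e / (n * (n - 1)) else NA_real_
  signs <- igraph::edge_attr(net, "sign")
  ppe <- if (e > 0 && !is.null(signs)) 100 * mean(signs > 0) else NA_real_
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  path_ok <- igraph::vcount(giant) > 1
  diam <- if (path_ok) igraph::diameter(giant, weights = NA) else NA_real_
  apl <- if (path_ok) igraph::mean_distance(giant, weights = NA) else NA_real_
  clus <- igraph::transitivity(net, type = "localaverage", isolates = "zero",
                               weights = NA)
  btw <- mean(igraph::betweenness(net, weights = NA))
  assort <- if (e > 1) igraph::assortativity_degree(net) else NA_real_
  if (is.null(modules)) modules <- detect_modules(net, seed = seed)
  out <- list(nodes = n, edges = e, avg_degree = avg_degree,
              diameter = diam, density = density,
              modularity = modules$modularity,
              avg_clustering = clus, avg_path_length = apl,
              ppe = ppe, pne = if (is.na(ppe)) NA_real_ else 100 - ppe,
              mean_betweenness = btw, assortativity = assort)
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Network: %d nodes, %d edges | avg degree %.3f | density %.3f\n",
    "diameter %s | avg path %.3f | clustering %.3f | modularity %.3f\n",
    "PPE %.1f%% / PNE %.1f%% | mean betweenness %.1f | assortativity %.3f\n"),
    x$nodes, x$edges, x$avg_degree, x$density,
    format(x$diameter), x$avg_path_length, x$avg_clustering, x$modularity,
    x$ppe, x$pne, x$mean_betweenness, x$assortativity))
  invisible(x)
}

#' Node roles from within-module degree and participation coefficient
#'
#' `z_i = (k_ib - mean_b) / sd_b`, the within-module degree of node `i`
#' standardized over the nodes of its module `b` (0 when the module's
#' within-degrees have zero spread), and
#' `c_i = 1 - sum_c (k_ic / k_i)^2`, the participation coefficient over
#' modules.  Classification: z > 2.5 & c > 0.6 network hub; z > 2.5 &
#' c <= 0.6 module hub; z <= 2.5 & c > 0.6 connector; otherwise
#' peripheral.
#'
#' @param net an `igraph` graph.
#' @param modules a [detect_modules] result (or membership vector).
#' @return data.frame: `node`, `module`, `z`, `c`, `category`.
#' @export
node_roles <- function(net, modules) {
  memb <- if (is.list(modules)) modules$membership else modules
  ids <- igraph::V(net)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(net)))
  if (!all(ids %in% names(memb)))
    stop_invalid("modules must cover all network nodes")
  memb <- memb[ids]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # links from each node into each module
  k_ic <- vapply(mods, function(c0) rowSums(adj[, memb == c0, drop = FALSE]),
                 numeric(length(ids)))
  if (length(ids) == 1L) k_ic <- matrix(k_ic, nrow = 1L)
  k_ib <- k_ic[cbind(seq_along(ids), match(memb, mods))]
  z <- numeric(length(ids))
  for (c0 in mods) {
    in_mod <- memb == c0
    mu <- mean(k_ib[in_mod])
    sdv <- stats::sd(k_ib[in_mod])
    z[in_mod] <- if (is.na(sdv) || sdv == 0) 0 else (k_ib[in_mod] - mu) / sdv
  }
  cpart <- 1 - rowSums((k_ic / pmax(k, 1))^2)
  cpart[k == 0] <- 0
  category <- ifelse(z > 2.5 & cpart > 0.6, "network hub",
              ifelse(z > 2.5, "module hub",
              ifelse(cpart > 0.6, "connector", "peripheral")))
  data.frame(node = ids, module = unname(memb), z = z, c = cpart,
             category = category, row.names = NULL)
}

#' Per-sample induced subnetworks and their association with a variable
#'
#' For every sample, the subgraph induced by the OTUs detected (count > 0)
#' in that sample is summarized (nodes, edges, mean betweenness,
#' assortativity), and each metric is rank-correlated with a metadata
#' variable.
#'
#' @param net an `igraph` graph whose node names are OTU ids.
#' @param table an [otu_table] sharing those OTU ids.
#' @param metadata optional metadata with the association `variable`.
#' @param variable metadata column name (default "temperature").
#' @return list with `per_sample` (data.frame, NA rows for samples whose
#'   subgraph is empty) and `association` (Spearman rho and p per metric),
#'   the latter `NULL` without metadata.
#' @export
per_sample_subnetworks <- function(net, table, metadata = NULL,
                                   variable = "temperature") {
  m <- as_counts(table)
  ids <- igraph::V(net)$name
  rows <- lapply(seq_len(nrow(m)), function(i) {
    present <- colnames(m)[m[i, ] > 0]
    nodes <- intersect(ids, present)
    if (!length(nodes))
      return(data.frame(sample_id = rownames(m)[i], nodes = NA_integer_,
                        edges = NA_integer_, mean_betweenness = NA_real_,
                        assortativity = NA_real_))
    sg <- igraph::induced_subgraph(net, nodes)
    data.frame(sample_id = rownames(m)[i], nodes = igraph::vcount(sg),
               edges = igraph::ecount(sg),
               mean_betweenness = mean(igraph::betweenness(sg, weights = NA)),
               assortativity = if (igraph::ecount(sg) > 1)
                 igraph::assortativity_degree(sg) else NA_real_)
  })
  per_sample <- do.call(rbind, rows)
  association <- NULL
  if (!is.null(metadata)) {
    env <- metadata[[variable]][match(per_sample$sample_id,
                                      metadata$sample_id)]
    association <- do.call(rbind, lapply(
      c("nodes", "edges", "mean_betweenness", "assortativity"),
      function(met) {
        v <- per_sample[[met]]
        ok <- is.finite(v) & is.finite(env)
        if (sum(ok) < 3)
          return(data.frame(metric = met, rho = NA_real_, p = NA_real_))
        ct <- suppressWarnings(stats::cor.test(v[ok], env[ok],
                                               method = "spearman"))
        data.frame(metric = met, rho = unname(ct$estimate), p = ct$p.value)
      }))
  }
  list(per_sample = per_sample, association = association)
}

#' Write a network to GML
#'
#' @param net an `igraph` graph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_gml <- function(net, path) {
  igraph::write_graph(net, path, format = "gml")
  invisible(path)
}
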