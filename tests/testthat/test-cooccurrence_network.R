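test_that("SparCC solves the 3-component toy system exactly", {
  # t12 = 5, t13 = 10, t23 = 13 under sparsity -> basis variances (1, 4, 9)
  t_mat <- matrix(c(0, 5, 10, 5, 0, 13, 10, 13, 0), 3, 3)
  include <- !diag(3)
  w <- otuassembly:::solve_basis_variances(t_mat, include)
  expect_equal(w, c(1, 4, 9), tolerance = 1e-12)
  rho <- otuassembly:::basis_correlations(t_mat, w)
  expect_equal(rho[lower.tri(rho)], rep(0, 3), tolerance = 1e-12)
})

test_that("SparCC suppresses compositional artifacts and finds signal", {
  set.seed(31)
  n <- 80; k <- 40
  base <- matrix(stats::rlnorm(n * (k - 2), 0, 1), n, k - 2)
  x1 <- stats::rlnorm(n, 2, 1)
  abs_ab <- cbind(x1, 2 * x1, base)   # components 1-2 perfectly covary
  counts <- t(apply(abs_ab, 1, function(r)
    stats::rmultinom(1, 4000, r / sum(r))[, 1]))
  colnames(counts) <- paste0("t", seq_len(k))
  sp <- sparcc(otu_table(counts), n_iter = 10, n_bootstrap = 0, seed = 32)
  expect_gt(sp$rho[1, 2], 0.9)
  others <- abs(sp$rho[upper.tri(sp$rho)])[-1]
  expect_lt(mean(others), 0.15)
  # naive Pearson on proportions is visibly more biased on independents
  props <- counts / rowSums(counts)
  naive <- stats::cor(props[, 3:k])
  expect_gt(mean(abs(naive[upper.tri(naive)])),
            mean(abs(sp$rho[3:k, 3:k][upper.tri(diag(k - 2))])))
  expect_error(sparcc(otu_table(counts[, 1:3])), ">= 4 OTUs")
})

test_that("SparCC is invariant to per-sample scaling of the counts", {
  set.seed(35)
  n <- 50; k <- 30
  counts <- matrix(stats::rnbinom(n * k, mu = 40, size = 1) + 1, n, k,
                   dimnames = list(paste0("S", 1:n), paste0("t", 1:k)))
  sp1 <- sparcc(otu_table(counts), n_iter = 8, n_bootstrap = 0, seed = 36)
  scaled <- counts
  scaled[1:10, ] <- scaled[1:10, ] * 10
  sp2 <- sparcc(otu_table(scaled), n_iter = 8, n_bootstrap = 0, seed = 36)
  expect_lt(mean(abs(sp1$rho - sp2$rho)[upper.tri(sp1$rho)]), 0.05)
})

test_that("bootstrap p-values and BH adjustment behave", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(37)
  p <- runif(50)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  n <- 40; k <- 12
  counts <- matrix(stats::rpois(n * k, 30) + 1, n, k,
                   dimnames = list(paste0("S", 1:n), paste0("t", 1:k)))
  sp <- sparcc(otu_table(counts), n_iter = 5, n_bootstrap = 20, seed = 38)
  expect_true(all(sp$p >= 1 / 21 - 1e-12 & sp$p <= 1 | diag(k) == 1))
  expect_true(all(sp$p_adjusted[lower.tri(sp$p_adjusted)] >=
                    sp$p[lower.tri(sp$p)] - 1e-12))
})

test_that("build_network applies inclusive r and strict p thresholds", {
  ids <- paste0("o", 1:4)
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.7     # boundary: kept
  rho[1, 3] <- rho[3, 1] <- 0.9     # p too big: rejected
  rho[2, 4] <- rho[4, 2] <- -0.8    # negative edge kept
  padj <- matrix(0.005, 4, 4); diag(padj) <- 0
  padj[1, 3] <- padj[3, 1] <- 0.02
  dimnames(rho) <- dimnames(padj) <- list(ids, ids)
  net <- build_network(list(rho = rho, p_adjusted = padj))
  em <- igraph::as_edgelist(net)
  keys <- apply(em, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(keys, c("o1-o2", "o2-o4"))
  expect_setequal(igraph::E(net)$sign, c(1L, -1L))
  # complete graph when everything passes
  rho1 <- matrix(1, 5, 5, dimnames = list(paste0("x", 1:5), paste0("x", 1:5)))
  p0 <- matrix(0, 5, 5, dimnames = dimnames(rho1))
  full <- build_network(list(rho = rho1, p_adjusted = p0))
  expect_equal(igraph::ecount(full), 10)
  # monotonicity: raising r_min never adds edges
  e_low <- igraph::ecount(build_network(list(rho = rho, p_adjusted = padj),
                                        r_min = 0.5))
  e_high <- igraph::ecount(suppressWarnings(
    build_network(list(rho = rho, p_adjusted = padj), r_min = 0.95)))
  expect_lte(e_high, e_low)
})

test_that("balanced_subsample balances groups reproducibly", {
  md <- data.frame(sample_id = paste0("S", 1:54),
                   habitat_class = rep(c("nearshore", "offshore"),
                                       c(30, 24)))
  ids <- balanced_subsample(md, "habitat_class", 24, seed = 1)
  expect_equal(length(ids), 48)
  got <- table(md$habitat_class[match(ids, md$sample_id)])
  expect_equal(unname(c(got)), c(24, 24))
  # whole group taken when n equals group size
  expect_setequal(intersect(ids, md$sample_id[31:54]), md$sample_id[31:54])
  ids2 <- balanced_subsample(md, "habitat_class", 24, seed = 2)
  expect_false(identical(sort(ids), sort(ids2)))
  expect_error(balanced_subsample(md, "habitat_class", 31), "fewer than")
})

test_that("topology_summary identities and hand cases hold", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  ts <- topology_summary(tri)
  expect_equal(ts$avg_clustering, 1)
  expect_equal(ts$diameter, 1)
  expect_equal(ts$density, 1)
  # printed Table-2-style consistency on a generated graph
  g <- random_gnm(495, 3749, seed = 41)
  tg <- topology_summary(g)
  expect_equal(round(tg$avg_degree, 3), 15.147)
  expect_equal(round(tg$density, 3), 0.031)
  expect_equal(tg$avg_degree, 2 * tg$edges / tg$nodes)
  expect_equal(tg$ppe + tg$pne, 100)
  # P4 assortativity: -0.5, cross-checked by brute-force Pearson
  p4 <- path_graph(4)
  tp <- topology_summary(p4)
  deg <- igraph::degree(p4)
  ends <- igraph::as_edgelist(p4, names = FALSE)
  xs <- c(deg[ends[, 1]], deg[ends[, 2]])
  ys <- c(deg[ends[, 2]], deg[ends[, 1]])
  expect_equal(tp$assortativity, stats::cor(xs, ys), tolerance = 1e-12)
  expect_equal(tp$assortativity, -0.5, tolerance = 1e-12)
})

test_that("module detection matches modularity hand computations", {
  tt <- two_triangles()
  mod <- detect_modules(tt, seed = 1)
  expect_equal(mod$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(mod$membership[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(mod$membership[c("b1", "b2", "b3")])), 1)
  expect_false(mod$membership[["a1"]] == mod$membership[["b1"]])
  # complete graph: no module structure
  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- paste0("v", 1:6)
  expect_lt(detect_modules(full, seed = 1)$modularity, 0.05)
  # invariance under relabeling
  perm <- igraph::permute(tt, c(3, 1, 2, 6, 4, 5))
  expect_equal(detect_modules(perm, seed = 1)$modularity, 0.5,
               tolerance = 1e-12)
})

test_that("node roles reproduce the participation hand cases", {
  # all links internal -> c = 0 (two triangles)
  tt <- two_triangles()
  mod <- detect_modules(tt, seed = 1)
  roles <- node_roles(tt, mod)
  expect_equal(roles$c, rep(0, 6))
  expect_true(all(roles$category == "peripheral"))
  expect_equal(roles$z, rep(0, 6))  # zero-variance modules

  # star node split evenly across 2 modules -> c = 0.5
  g2 <- igraph::graph_from_edgelist(cbind(c("x", "x"), c("a", "b")),
                                    directed = FALSE)
  memb <- c(x = 1L, a = 1L, b = 2L)
  r2 <- node_roles(g2, memb)
  expect_equal(r2$c[r2$node == "x"], 0.5)

  # 3 links to module A, 1 to module B -> c = 0.375
  g3 <- igraph::graph_from_edgelist(cbind(rep("x", 4),
                                          c("a1", "a2", "a3", "b1")),
                                    directed = FALSE)
  memb3 <- c(x = 1L, a1 = 1L, a2 = 1L, a3 = 1L, b1 = 2L)
  r3 <- node_roles(g3, memb3)
  expect_equal(r3$c[r3$node == "x"], 0.375)
  # categories partition all nodes by the 2.5/0.6 thresholds
  expect_true(all(r3$category %in%
                    c("network hub", "module hub", "connector",
                      "peripheral")))
  expect_true(all((r3$c > 0.6) == (r3$category %in%
                                     c("network hub", "connector"))))
})

test_that("per-sample subnetworks are induced subgraphs with bounds", {
  g <- random_gnm(20, 40, seed = 51)
  otus <- igraph::V(g)$name
  m <- rbind(all = rep(1, 20), none = rep(0, 20),
             half = rep(c(1, 0), 10))
  colnames(m) <- otus
  tab <- otu_table(m)
  res <- per_sample_subnetworks(g, tab)
  ps <- res$per_sample
  expect_equal(ps$nodes[ps$sample_id == "all"], 20)
  expect_equal(ps$edges[ps$sample_id == "all"], 40)
  expect_true(is.na(ps$nodes[ps$sample_id == "none"]))
  expect_lte(ps$nodes[ps$sample_id == "half"], 20)
  md <- data.frame(sample_id = c("all", "none", "half"),
                   temperature = c(20, 25, 30))
  res2 <- per_sample_subnetworks(g, tab, md)
  expect_true(is.data.frame(res2$association))
})

test_that("GML export round-trips through igraph", {
  g <- random_gnm(10, 15, seed = 61)
  f <- withr::local_tempfile(fileext = ".gml")
  # igraph warns when coercing sample_gnm's boolean graph attribute
  suppressWarnings(write_network_gml(g, f))
  back <- igraph::read_graph(f, format = "gml")
  expect_equal(igraph::vcount(back), 10)
  expect_equal(igraph::ecount(back), 15)
})
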