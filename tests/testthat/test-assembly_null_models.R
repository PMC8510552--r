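test_that("beta_mntd matches its definition and the brute-force oracle", {
  # identical communities: nearest taxon is itself
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  same <- otu_table(matrix(c(3, 3, 1, 1), 2, 2,
                           dimnames = list(c("S1", "S2"), c("a", "b"))))
  expect_equal(unname(beta_mntd(same, D)), matrix(0, 2, 2))
  # disjoint single-taxon communities: the single cross distance
  ab <- otu_table(matrix(c(5, 0, 0, 7), 2, 2,
                         dimnames = list(c("S1", "S2"), c("a", "b"))))
  expect_equal(beta_mntd(ab, D)["S1", "S2"], 0.4)
  # brute force on random tables
  for (s in 1:5) {
    tr <- simulate_tree(30, seed = s)
    D2 <- patristic_distances(tr)
    m <- random_table(tr, 8, depth = 100, seed = 10 + s)
    got <- beta_mntd(otu_table(m), D2)
    expect_equal(unname(got), unname(brute_beta_mntd(m, D2)),
                 tolerance = 1e-12)
  }
})

test_that("beta_nti is calibrated on pool-random communities", {
  stats_per_seed <- vapply(1:5, function(sd) {
    set.seed(sd)
    pool <- simulate_metacommunity(60)
    cnt <- t(stats::rmultinom(12, 1000, pool))
    tree <- simulate_tree(60, seed = sd + 500)
    colnames(cnt) <- tree$tip.label
    rownames(cnt) <- paste0("S", 1:12)
    bn <- suppressWarnings(beta_nti(otu_table(cnt), tree, n_null = 200,
                                    seed = sd + 600))
    v <- bn$bnti[lower.tri(bn$bnti)]
    c(mean(v, na.rm = TRUE), mean(abs(v) > 2, na.rm = TRUE))
  }, numeric(2))
  expect_lt(abs(mean(stats_per_seed[1, ])), 0.6)
  expect_lte(mean(stats_per_seed[2, ]), 0.10)
})

test_that("beta_nti null resampling is stable across seeds", {
  tr <- simulate_tree(40, seed = 21)
  tab <- otu_table(random_table(tr, 8, depth = 150, seed = 22))
  b1 <- beta_nti(tab, tr, n_null = 1000, seed = 1)$bnti
  b2 <- beta_nti(tab, tr, n_null = 1000, seed = 2)$bnti
  expect_lt(max(abs(b1 - b2), na.rm = TRUE), 0.3)
  # determinism for one seed
  b3 <- beta_nti(tab, tr, n_null = 100, seed = 9)$bnti
  b4 <- beta_nti(tab, tr, n_null = 100, seed = 9)$bnti
  expect_identical(b3, b4)
})

test_that("raup_crick_bc respects its bounds and boundary cases", {
  # two identical low-richness communities among richer neighbours:
  # observed BC = 0, null assemblies essentially never coincide -> RC = -1
  m <- matrix(0, 4, 6, dimnames = list(paste0("S", 1:4), paste0("o", 1:6)))
  m[1, 1:2] <- 25
  m[2, 1:2] <- 25
  m[3, ] <- c(10, 10, 10, 10, 10, 0)
  m[4, ] <- c(0, 10, 10, 10, 10, 10)
  rc <- raup_crick_bc(otu_table(m), n_null = 200, seed = 4)
  # a rare exact tie at BC = 0 contributes half, so allow 1/n_null slack
  expect_lte(rc$rc["S1", "S2"], -1 + 2 / 200)
  expect_true(all(abs(rc$rc) <= 1, na.rm = TRUE))
  expect_equal(rc$rc, t(rc$rc))
})

test_that("raup_crick_bc centers on communities built by its own null", {
  pooled <- vapply(1:5, function(sd) {
    set.seed(sd)
    pool <- simulate_metacommunity(60)
    ref <- t(stats::rmultinom(16, 1000, pool))
    rownames(ref) <- paste0("S", 1:16)
    colnames(ref) <- paste0("t", 1:60)
    nullt <- generate_rc_null_table(ref, sd + 50)
    rc <- raup_crick_bc(otu_table(nullt), n_null = 200, seed = sd + 700)
    rv <- rc$rc[lower.tri(rc$rc)]
    c(mean(rv), mean(abs(rv) > 0.95))
  }, numeric(2))
  expect_lt(abs(mean(pooled[1, ])), 0.4)
  expect_lt(mean(pooled[2, ]), 0.15)
  expect_gt(mean(pooled[2, ]), 0.02)
})

test_that("classify_processes applies the threshold rules exactly", {
  mk <- function(v) {
    m <- matrix(0, 4, 4)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    dimnames(m) <- list(paste0("S", 1:4), paste0("S", 1:4))
    m
  }
  # 6 pairs; one invalidated by NA to leave the 5 of the worked example
  b <- mk(c(2.5, -2.5, 0, 0, 0, NA))
  r <- mk(c(0, 0, 0.99, -0.99, 0, 0))
  pf <- classify_processes(b, r)
  expect_equal(pf$fraction_selection, 0.4)
  expect_equal(pf$fraction_dispersal_limitation, 0.2)
  expect_equal(pf$fraction_homogenizing_dispersal, 0.2)
  expect_equal(pf$fraction_drift, 0.2)
  expect_equal(pf$n_pairs, 5)
  expect_equal(pf$fraction_selection + pf$fraction_dispersal_limitation +
                 pf$fraction_homogenizing_dispersal + pf$fraction_drift,
               1, tolerance = 1e-9)
  # all |bNTI| > 2: selection only
  b2 <- mk(c(3, -3, 4, -4, 5, 3))
  pf2 <- classify_processes(b2, mk(rep(0, 6)))
  expect_equal(pf2$fraction_selection, 1)
  expect_equal(pf2$fraction_drift, 0)
})

test_that("DL/HD ratio reproduces the printed 4.4 from 9.3% vs 2.1%", {
  # 1000 valid pairs: 93 DL, 21 HD, the rest drift
  n <- 46  # 1035 pairs; 35 invalidated
  v_b <- rep(0, 1035)
  v_r <- c(rep(0.99, 93), rep(-0.99, 21), rep(0, 1035 - 93 - 21))
  v_b[1001:1035] <- NA
  mkn <- function(v) {
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- v
    m + t(m)
  }
  pf <- classify_processes(mkn(v_b), mkn(v_r))
  expect_equal(pf$n_pairs, 1000)
  expect_equal(pf$fraction_dispersal_limitation, 0.093)
  expect_equal(pf$fraction_homogenizing_dispersal, 0.021)
  expect_equal(round(pf$DL_to_HD_ratio, 1), 4.4)
})

test_that("raising the betaNTI threshold never raises selection", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 8
    v_b <- rnorm(n * (n - 1) / 2, 0, 3)
    v_r <- runif(n * (n - 1) / 2, -1, 1)
    mk <- function(v) {
      m <- matrix(0, n, n); m[lower.tri(m)] <- v; m + t(m)
    }
    f1 <- classify_processes(mk(v_b), mk(v_r), bnti_threshold = 1.5)
    f2 <- classify_processes(mk(v_b), mk(v_r), bnti_threshold = 2.5)
    expect_lte(f2$fraction_selection, f1$fraction_selection)
  }
})

test_that("bnti_env_tests delegates to Mantel machinery", {
  tr <- simulate_tree(30, seed = 41)
  tab <- otu_table(random_table(tr, 10, depth = 80, seed = 42))
  bn <- suppressWarnings(beta_nti(tab, tr, n_null = 100, seed = 43))
  self <- bnti_env_tests(bn, bn$bnti, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  set.seed(44)
  rnd <- matrix(rnorm(100), 10, 10)
  rnd <- rnd + t(rnd); diag(rnd) <- 0
  out <- bnti_env_tests(bn, rnd, n_perm = 99, seed = 2)
  expect_true(out$p >= 0.01 && out$p <= 1)
  ctrl <- euclidean_distance_1d(rnorm(10))
  pm <- bnti_env_tests(bn, rnd, controls = list(ctrl), n_perm = 99, seed = 3)
  expect_true(abs(pm$r) <= 1)
})

test_that("ground truth scenarios are recovered as the modal process", {
  run_scen <- function(scen, seed) {
    design <- synthetic_design(4, 3, 1, read_depth = 2000, seed = seed)
    ds <- simulate_dataset(design, scen, n_taxa = 150, sigma2 = 1,
                           seed = seed)
    bn <- suppressWarnings(beta_nti(ds$otu_table, ds$tree, n_null = 100,
                                    seed = seed + 50))
    rc <- raup_crick_bc(ds$otu_table, n_null = 150, seed = seed + 60)
    pf <- classify_processes(bn, rc)
    which.max(c(sel = pf$fraction_selection,
                dl = pf$fraction_dispersal_limitation,
                hd = pf$fraction_homogenizing_dispersal,
                drift = pf$fraction_drift))
  }
  # one representative seed per scenario here; the 10-seed sweep is in
  # the acceptance suite
  expect_equal(names(run_scen(assembly_scenario(drift_only = TRUE,
                                                migration_rate_m = 0.1),
                              11)), "drift")
  expect_equal(names(run_scen(assembly_scenario(1, Inf, 0.3,
                                                pool_noise_sd = 0),
                              22)), "sel")
  expect_equal(names(run_scen(assembly_scenario(0, 10, 1,
                                                pool_noise_sd = 2),
                              11)), "dl")
})
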