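test_that("Mantel identity, symmetry and null calibration", {
  set.seed(71)
  X <- matrix(rnorm(30), 15, 2)
  D <- as.matrix(dist(X))
  m <- mantel_test(D, D, n_perm = 99)
  expect_equal(m$r, 1, tolerance = 1e-9)
  expect_equal(m$p, 1 / (99 + 1))
  # symmetric in its arguments
  E <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  expect_equal(mantel_test(D, E, n_perm = 0)$r,
               mantel_test(E, D, n_perm = 0)$r, tolerance = 1e-12)
  expect_error(mantel_test(matrix(0, 4, 4), D[1:4, 1:4]), "constant")

  # type-I error near 5% for independent matrices
  rej <- vapply(1:150, function(i) {
    A <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    B <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    mantel_test(A, B, n_perm = 99)$p <= 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)
})

test_that("Mantel detects planted isolation-by-distance", {
  set.seed(72)
  lat <- runif(40, 30, 45); lon <- runif(40, -100, -80)
  # genetic distance proportional to geography plus noise
  geo <- geo_distance(lat, lon)
  gen <- geo / max(geo) + matrix(abs(rnorm(1600, 0, 0.1)), 40, 40)
  gen <- (gen + t(gen)) / 2; diag(gen) <- 0
  m <- mantel_test(gen, geo, n_perm = 199)
  expect_gt(m$r, 0.3)
  expect_lte(m$p, 0.05)
})

test_that("2D-LSA flags planted clone clusters and stays calibrated on noise", {
  set.seed(73)
  n <- 40
  lat <- runif(n, 30, 45); lon <- runif(n, -100, -80)
  # plant a tight family: samples 1..6 share a location and are genetically close
  lat[1:6] <- 35 + rnorm(6, 0, 0.01); lon[1:6] <- -90 + rnorm(6, 0, 0.01)
  G <- matrix(runif(n * n, 0.5, 1), n, n)
  G[1:6, 1:6] <- runif(36, 0, 0.05)
  G <- (G + t(G)) / 2; diag(G) <- 0
  ls <- local_spatial_autocorrelation(G, lat, lon, n_neighbors = 5:6,
                                      n_perm = 199)
  planted <- ls$consistency$consistent[ls$consistency$sample_id %in%
                                        as.character(1:6)]
  expect_true(all(planted))
  # sweep bookkeeping: every individual evaluated at every sweep value
  expect_equal(nrow(ls$per_individual), n * 2)
  expect_setequal(unique(ls$per_individual$n_neighbors), 5:6)

  # null: random geography -> about 5% significant per sweep value
  set.seed(74)
  rates <- vapply(1:30, function(i) {
    Gr <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
    lr <- local_spatial_autocorrelation(Gr, runif(30, 30, 45),
                                        runif(30, -100, -80),
                                        n_neighbors = 5, n_perm = 99)
    mean(lr$per_individual$p <= 0.05)
  }, numeric(1))
  expect_lt(mean(rates), 0.15)
  expect_error(local_spatial_autocorrelation(matrix(0, 5, 5), runif(5),
                                             runif(5), n_neighbors = 7),
               "below the sample count")
})

test_that("UPGMA reproduces the worked 3-taxon example and is ultrametric", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_bootstrap(D)
  # heights 1 (A,B ancestor) and 2 (root)
  internal <- sort(tr$heights[tr$heights > 1e-9])
  expect_equal(unname(internal), c(1, 2))
  coph <- cophenetic(tr$phylo)
  expect_equal(unname(coph["A", "B"]), 2)
  expect_equal(unname(coph["A", "C"]), 4)
  # ultrametric: all tips equidistant from root
  depths <- ape::node.depth.edgelength(tr$phylo)[1:3]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(upgma_bootstrap(D[1:2, 1:2]), "at least 3")
})

test_that("planted clades get high bootstrap support", {
  set.seed(75)
  # three clades of 5 samples with strong frequency divergence
  bn <- sim_bn_panel(5, 80, 0.6, n_pops = 3)
  tr <- upgma_bootstrap(bn$dosage, n_boot = 60)
  expect_true(ape::is.ultrametric(tr$phylo, tol = 1e-8))
  # cophenetic distances within clades smaller than between
  coph <- cophenetic(tr$phylo)
  w <- mean(coph[1:5, 1:5][upper.tri(matrix(0, 5, 5))])
  b <- mean(coph[1:5, 6:10])
  expect_lt(w, b)
  expect_true(any(tr$supports >= 95, na.rm = TRUE))
  expect_match(tr$newick, "^\\(")
})

test_that("divergence dating is linear in distance and scale-invariant", {
  dt <- divergence_time(0.05, 0.10)
  expect_equal(dt$t_mya, 6.5)
  expect_equal(divergence_time(0, 0.1)$t_mya, 0)
  expect_equal(divergence_time(0.05 * 3, 0.10 * 3)$t_mya, 6.5)
  expect_error(divergence_time(0.1, 0), "positive")

  # mutation-clock simulation: true split at 0.2 x outgroup split
  set.seed(76)
  L <- 4000
  anc <- sample(c("A", "C", "G", "T"), L, TRUE)
  mut <- function(s, r) {
    hit <- runif(L) < r
    s[hit] <- vapply(which(hit), function(i)
      sample(setdiff(c("A", "C", "G", "T"), s[i]), 1), character(1))
    s
  }
  # outgroup split accumulates 0.10 substitutions/site between lineages,
  # the ingroup split 0.02 (= 0.2 x outgroup) -> expected 2.6 Mya
  og <- mut(anc, 0.09)
  a <- mut(anc, 0.01); b <- mut(anc, 0.01)
  between <- mean(a != b)
  outd <- mean(c(mean(a != og), mean(b != og)))
  est <- divergence_time(between, outd)$t_mya
  expect_equal(est, 13 * between / outd)
  expect_lt(abs(est - 2.6), 0.3)
})
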