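test_that("degenerate and invalid K are handled", {
  set.seed(61)
  d <- matrix(rbinom(60, 2, 0.4) / 2, 10, 6)
  fit1 <- fit_admixture(d, K = 1, n_burnin = 20, n_iter = 40, seed = 1)
  expect_true(all(abs(fit1$Q - 1) < 1e-12))
  expect_true(is.finite(fit1$lnPD_per_run))
  expect_error(fit_admixture(d, K = 11, n_burnin = 5, n_iter = 5),
               "cannot exceed")
  expect_error(fit_admixture(d, K = 0, n_burnin = 5, n_iter = 5), ">= 1")
})

test_that("Q rows are proper ancestry vectors and runs are seed-reproducible", {
  set.seed(62)
  bn <- sim_bn_panel(15, 40, 0.3)
  fit <- fit_admixture(bn$dosage, K = 2, n_burnin = 100, n_iter = 200,
                       seed = 7)
  expect_equal(unname(rowSums(fit$Q)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(fit$P >= 0 & fit$P <= 1))
  fit2 <- fit_admixture(bn$dosage, K = 2, n_burnin = 100, n_iter = 200,
                        seed = 7)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$lnPD_per_run, fit2$lnPD_per_run)
})

test_that("two divergent populations are recovered almost perfectly", {
  set.seed(63)
  bn <- sim_bn_panel(n_per_pop = 30, n_loci = 150, F = 0.3)
  fit <- fit_admixture(bn$dosage, K = 2, n_burnin = 300, n_iter = 600,
                       seed = 3)
  truth <- cbind(as.numeric(bn$pop == "P1"), as.numeric(bn$pop == "P2"))
  # alignment with truth after label matching
  expect_lt(q_rmse(fit$Q, truth), 0.1)
  align <- max(mean(fit$Q[cbind(seq_len(60), (bn$pop == "P2") + 1)]),
               mean(fit$Q[cbind(seq_len(60), (bn$pop == "P1") + 1)]))
  expect_gt(align, 0.9)
})

test_that("select_k finds the plateau and ignores run order", {
  lnpd <- tibble::tibble(
    K = rep(1:4, each = 3),
    lnPD = c(-1000, -1001, -999, -900, -902, -898,
             -880, -882, -884, -881, -883, -885))
  expect_equal(select_k(lnpd), 3)
  expect_equal(select_k(lnpd[sample(nrow(lnpd)), ]), 3)
  expect_warning(k1 <- select_k(tibble::tibble(K = 2, lnPD = -5)), "one K")
  expect_equal(k1, 2)
})

test_that("membership calls apply the 70% rule to samples and accessions", {
  Q <- rbind(c(0.65, 0.25, 0.10), c(0.90, 0.05, 0.05), c(0.05, 0.90, 0.05))
  rownames(Q) <- c("a", "b", "c"); colnames(Q) <- paste0("C", 1:3)
  fit <- structure(list(K = 3, Q = Q, P = NULL, lnPD_per_run = -1,
                        chosen_run = 1), class = "pvp_admixture")
  mc <- classify_membership(fit)
  expect_identical(mc$membership$assigned, c("admixed", "C1", "C2"))

  # accession with 8/10 genotypes in C1 is representative of C1
  Q2 <- matrix(0.05, 10, 3); colnames(Q2) <- paste0("C", 1:3)
  Q2[1:8, 1] <- 0.9; Q2[9:10, 3] <- 0.9
  Q2 <- Q2 / rowSums(Q2)
  rownames(Q2) <- sprintf("s%02d", 1:10)
  fit2 <- structure(list(K = 3, Q = Q2, P = NULL, lnPD_per_run = -1,
                         chosen_run = 1), class = "pvp_admixture")
  mc2 <- classify_membership(fit2, accessions = rep("accZ", 10))
  expect_equal(mc2$representatives$subpopulation, "C1")
  expect_equal(mc2$representatives$prop, 0.8)
})

test_that("PCoA geometry: collinear points, eigenvalue identity, clusters", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  pc <- pcoa(D)
  expect_equal(pc$pct_variance[1], 100, tolerance = 1e-6)

  # eigenvalue sum equals the trace of the centred Gower matrix
  set.seed(64)
  X <- matrix(rnorm(40), 10, 4)
  D2 <- as.matrix(dist(X))
  pc2 <- pcoa(D2)
  J <- diag(10) - matrix(1 / 10, 10, 10)
  G <- -0.5 * J %*% D2^2 %*% J
  expect_equal(sum(pc2$eigenvalues), sum(diag(G)), tolerance = 1e-6)

  # three planted clusters separate on the first two axes
  set.seed(65)
  bn <- sim_bn_panel(15, 120, 0.35, n_pops = 3)
  ds <- ds_from_dosage(bn$dosage)
  pc3 <- pcoa(genetic_distance(ds))
  co <- pc3$coordinates[, 1:2]
  dco <- as.matrix(dist(co))
  sil <- vapply(seq_len(nrow(co)), function(i) {
    own <- bn$pop == bn$pop[i]; own[i] <- FALSE
    a <- mean(dco[i, own])
    b <- min(vapply(setdiff(unique(bn$pop), bn$pop[i]), function(o) {
      mean(dco[i, bn$pop == o])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
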