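make_density <- function(X, genotype) {
  ont <- toy_ontology(ncol(X))
  colnames(X) <- ont$acronym
  structure(list(values = X,
                 genotype = factor(genotype, levels = unique(genotype)),
                 animal_id = paste0("a", seq_len(nrow(X))),
                 ontology = ont),
            class = "density_matrix")
}

test_that("correlation matrices are symmetric with the right pair count", {
  ont <- shipped_ontology()
  coh <- generate_cohort(cohort_spec(ont, seed = 6))
  cm <- correlation_matrix(compute_density(coh), "WT")
  expect_equal(dim(cm$rho), c(196, 196))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 196))
  ut <- cm$rho[upper.tri(cm$rho)]
  expect_equal(sum(!is.na(ut)), 19110)  # 196 * 195 / 2
  expect_true(all(abs(ut) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("duplicated region columns correlate perfectly", {
  set.seed(3)
  X <- cbind(rnorm(5), rnorm(5), rnorm(5))
  X <- cbind(X, X[, 2])
  cm <- correlation_matrix(make_density(X, rep("g", 5)), "g")
  expect_equal(cm$rho[2, 4], 1)
})

test_that("tie-free rho values sit on the n-animal lattice", {
  for (n in c(5, 6)) {
    set.seed(n)
    X <- matrix(rnorm(n * 12), n, 12)
    cm <- correlation_matrix(make_density(X, rep("g", n)), "g")
    lattice <- 1 - 6 * seq(0, n * (n^2 - 1) / 3, by = 2) / (n * (n^2 - 1))
    ut <- cm$rho[upper.tri(cm$rho)]
    expect_true(all(vapply(ut, function(r)
      any(abs(r - lattice) < 1e-9), logical(1))))
  }
})

test_that("constant regions are flagged undefined, never edges", {
  set.seed(4)
  X <- matrix(rnorm(20), 5, 4)
  X[, 2] <- 3
  cm <- correlation_matrix(make_density(X, rep("g", 5)), "g")
  expect_false(cm$defined[2])
  expect_true(all(is.na(cm$rho[2, ])))
  adj <- threshold_adjacency(cm, 0.8)
  expect_true(all(adj$adj[2, ] == 0))
})

test_that("thresholding is inclusive, idempotent and nested", {
  rho <- diag(4)
  rho[upper.tri(rho)] <- c(0.8, 0.75, -0.85, 0.5, 0.95, -0.6)
  rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
  diag(rho) <- 1
  dimnames(rho) <- list(paste0("R", 1:4), paste0("R", 1:4))
  cm <- structure(list(genotype = "g", rho = rho,
                       p = matrix(0.5, 4, 4, dimnames = dimnames(rho)),
                       n = 6, regions = rownames(rho),
                       defined = rep(TRUE, 4), ties = rep(FALSE, 4)),
                  class = "cofos_corr")
  a08 <- threshold_adjacency(cm, 0.8)
  # rho exactly 0.8 survives the |rho| >= 0.8 rule
  expect_equal(a08$adj["R1", "R2"], 1L)
  expect_equal(a08$adj["R2", "R3"], 1L)  # negative edge counts too
  expect_equal(sum(a08$adj) / 2, 3)
  a09 <- threshold_adjacency(cm, 0.9)
  expect_true(all(a09$adj <= a08$adj))
  # re-thresholding the surviving rho values changes nothing
  cm2 <- cm
  cm2$rho <- cm$rho * a08$adj; diag(cm2$rho) <- 1
  expect_equal(threshold_adjacency(cm2, 0.8)$adj, a08$adj)
  expect_error(threshold_adjacency(cm, 1.2), "\\(0, 1\\)")
})

test_that("network density is edges over possible pairs", {
  full <- matrix(1, 5, 5) - diag(5)
  expect_equal(network_density(full), 1)
  expect_equal(network_density(matrix(0, 4, 4)), 0)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[1, 4] <- A[4, 1] <- 1
  expect_equal(network_density(A), 0.5)  # 3 of 6 pairs
  expect_error(network_density(matrix(0, 1, 1)), "at least 2")
})

test_that("density sweeps are monotone and split signed edges", {
  ont <- shipped_ontology()
  coh <- generate_cohort(preset_cohort_spec(ont, seed = 8))
  cm <- correlation_matrix(compute_density(coh), "KO")
  sw <- density_sweep(cm)
  expect_equal(sw$threshold, c(0.7, 0.8, 0.9))
  expect_true(all(diff(sw$density) <= 0))
  expect_equal(sw$n_positive + sw$n_negative, sw$n_edges)
  expect_error(density_sweep(cm, c(0.9, 0.7)), "ascending")
})

test_that("subnetwork edges keep within-network pairs at |rho| >= tau", {
  set.seed(12)
  base <- rnorm(6)
  X <- cbind(base + rnorm(6, sd = 1e-3),     # CEA
             base + rnorm(6, sd = 1e-3),     # BLA
             rnorm(6), rnorm(6))             # two unrelated regions
  d <- make_density(X, rep("g", 6))
  colnames(d$values) <- c("CEA", "BLA", "AAA", "BBB")
  cm <- correlation_matrix(d, "g")
  soc <- subnetwork_edges(cm, c("CEA", "BLA", "AAA"), "social", 0.8)
  sal <- subnetwork_edges(cm, c("CEA", "BLA"), "salience", 0.8)
  expect_true(any(soc$region_1 == "CEA" & soc$region_2 == "BLA" &
                    soc$rho == 1))
  expect_true(any(sal$rho == 1))
  expect_equal(sal$network, "salience")
  # a 2-region network below threshold yields an empty list
  low <- subnetwork_edges(cm, c("AAA", "BBB"), "low", 0.99)
  expect_equal(nrow(low), 0)
  expect_error(subnetwork_edges(cm, "CEA", "tiny"), "fewer than 2")
  expect_error(subnetwork_edges(cm, c("CEA", "ZZZ"), "bad"), "ZZZ")
})

test_that("planted 3-region blocks surface as complete subnetworks", {
  ont <- toy_ontology(10)
  spec <- cohort_spec(ont, c(A = 40), seed = 21, correlation_blocks = list(
    list(genotype = "A", regions = c("R1", "R2", "R3"), rho = 0.95)))
  cm <- correlation_matrix(compute_density(generate_cohort(spec)), "A")
  ed <- subnetwork_edges(cm, c("R1", "R2", "R3"), "block", 0.8)
  expect_equal(nrow(ed), 3)
})

test_that("restriction to common regions drops constant columns in either", {
  set.seed(7)
  Xa <- matrix(rnorm(30), 6, 5); Xa[, 2] <- 1
  Xb <- matrix(rnorm(25), 5, 5); Xb[, 4] <- 2
  da <- make_density(rbind(Xa, Xb), c(rep("A", 6), rep("B", 5)))
  ca <- correlation_matrix(da, "A")
  cb <- correlation_matrix(da, "B")
  res <- restrict_to_common_regions(ca, cb)
  expect_setequal(res[[1]]$regions, c("R1", "R3", "R5"))
  expect_equal(res[[1]]$regions, res[[2]]$regions)
  expect_equal(dim(res[[2]]$rho), c(3, 3))
  # identical defined sets pass through unchanged
  res2 <- restrict_to_common_regions(ca, ca)
  expect_equal(res2[[1]]$rho, ca$rho[res2[[1]]$regions, res2[[1]]$regions])
})

test_that("results are invariant to permuting region order", {
  set.seed(15)
  X <- matrix(rnorm(6 * 8), 6, 8)
  d1 <- make_density(X, rep("g", 6))
  perm <- sample(8)
  d2 <- make_density(X[, perm], rep("g", 6))
  colnames(d2$values) <- colnames(d1$values)[perm]
  c1 <- correlation_matrix(d1, "g")
  c2 <- correlation_matrix(d2, "g")
  expect_equal(c2$rho, c1$rho[perm, perm])
  expect_equal(network_density(threshold_adjacency(c1, 0.8)),
               network_density(threshold_adjacency(c2, 0.8)))
})

test_that("FDR-mode edge selection stays near-silent under the null", {
  ont <- toy_ontology(40)
  false_rates <- vapply(1:30, function(s) {
    coh <- generate_cohort(cohort_spec(ont, c(A = 6), seed = 100 + s))
    cm <- correlation_matrix(compute_density(coh), "A")
    adj <- threshold_adjacency(cm, mode = "fdr_p", alpha = 0.05)
    sum(adj$adj) / 2 / (40 * 39 / 2)
  }, numeric(1))
  expect_lte(mean(false_rates), 0.05)
})
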