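test_that("K = 1 collapses to the single-cluster model", {
  set.seed(3)
  g <- random_geno(n_pops = 2, n_ind = 10, n_loci = 4, n_alleles = 3)
  run <- admixture_mcmc(g, k = 1, sweeps = 300, seed = 1)
  expect_true(all(run$Q == 1))
  expect_equal(length(run$trace), 300)
  expect_true(is.finite(run$ln_pk))
})

test_that("two well-separated clusters are recovered almost perfectly", {
  cfg <- sim_config(pops = c("A", "B"), n_per_pop = 50, k_true = 2, f = 0.3,
                    loci = setNames(rep(5L, 15), paste0("L", 1:15)),
                    q_true = diag(2), seed = 53)
  sim <- simulate_msat(cfg)
  run <- admixture_mcmc(sim$geno, k = 2, sweeps = 1500, seed = 2)
  pops <- geno_individuals(sim$geno)$pop
  # align cluster labels to population A's majority column
  colA <- which.max(colMeans(run$Q[pops == "A", ]))
  assign_ok <- c(run$Q[pops == "A", colA] > 0.5,
                 run$Q[pops == "B", -colA] > 0.5)
  expect_gt(mean(assign_ok), 0.95)
})

test_that("Q rows are proper ancestry proportions and runs are seed-stable", {
  set.seed(5)
  g <- random_geno(n_pops = 2, n_ind = 12, n_loci = 5, n_alleles = 4)
  r1 <- admixture_mcmc(g, k = 3, sweeps = 400, seed = 11)
  r2 <- admixture_mcmc(g, k = 3, sweeps = 400, seed = 11)
  expect_identical(r1$Q, r2$Q)
  expect_equal(rowSums(r1$Q), setNames(rep(1, 24), rownames(r1$Q)),
               tolerance = 1e-9)
  expect_error(admixture_mcmc(g, k = 0, sweeps = 400), "k must be")
  expect_error(admixture_mcmc(g, k = 2, sweeps = 50), "sweeps")
})

test_that("replicate runs agree up to label switching", {
  cfg <- sim_config(pops = c("A", "B"), n_per_pop = 40, k_true = 2, f = 0.3,
                    loci = setNames(rep(5L, 12), paste0("L", 1:12)),
                    q_true = diag(2), seed = 59)
  sim <- simulate_msat(cfg)
  ra <- admixture_mcmc(sim$geno, k = 2, sweeps = 1500, seed = 21)
  rb <- admixture_mcmc(sim$geno, k = 2, sweeps = 1500, seed = 22)
  al <- align_runs(list(ra, rb))
  expect_gt(al$similarity[2], 0.98)
  expect_equal(unname(rowSums(al$consensus)), rep(1, nrow(al$consensus)),
               tolerance = 1e-9)
})

test_that("alignment recovers a column swap exactly", {
  q <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.1, 0.2, 0.9, 0.8), 4, 2)
  al <- align_runs(list(q, q[, 2:1]))
  expect_equal(al$permutations[[2]], c(2L, 1L))
  expect_equal(al$similarity[2], 1)
  expect_equal(al$Q_aligned[[2]], q)
  # K = 2 exhaustive alignment is itself the brute force over both
  # permutations: the non-identity must lose for an identical pair
  al2 <- align_runs(list(q, q))
  expect_equal(al2$permutations[[2]], c(1L, 2L))
})

test_that("the sampler trace does not drift downward after burn-in", {
  cfg <- sim_config(pops = c("A", "B"), n_per_pop = 40, k_true = 2, f = 0.2,
                    loci = setNames(rep(5L, 10), paste0("L", 1:10)),
                    q_true = diag(2), seed = 61)
  run <- admixture_mcmc(simulate_msat(cfg)$geno, k = 2, sweeps = 3000, seed = 31)
  post <- run$trace[601:3000]
  first <- mean(post[1:1200]); second <- mean(post[1201:2400])
  expect_gt(second, first - 2 * stats::sd(post))
})

test_that("the Evanno table reproduces a hand-computed delta-K", {
  summary <- tibble::tibble(
    k = rep(1:3, each = 3),
    rep = rep(1:3, 3),
    ln_pk = c(-1000, -1000, -1000, -510, -500, -490, -490, -490, -490))
  dk <- evanno_delta_k(summary)
  # |L(1) - 2 L(2) + L(3)| / sd(L(2)) = |-1000 + 1000 - 490 + 500| / 10
  expect_equal(dk$delta_k[dk$k == 2], 49)
  expect_equal(selected_k(dk), 2L)
  expect_true(is.na(dk$delta_k[dk$k == 1]) && is.na(dk$delta_k[dk$k == 3]))
  # zero-sd interior K gives NA
  flat <- tibble::tibble(k = rep(1:3, each = 2), rep = rep(1:2, 3),
                         ln_pk = c(-10, -20, -5, -5, -2, -4))
  expect_true(is.na(evanno_delta_k(flat)$delta_k[2]))
  # a linear ln P(X|K) profile has (near) zero second differences
  lin <- tibble::tibble(k = rep(1:4, each = 2), rep = rep(1:2, 4),
                        ln_pk = rep(c(-400, -300, -200, -100), each = 2) +
                          rep(c(-0.5, 0.5), 4))
  dk_lin <- evanno_delta_k(lin)
  expect_true(all(dk_lin$delta_k[2:3] < 1e-9))
  expect_error(evanno_delta_k(summary[summary$k < 3, ]), "consecutive")
  expect_error(evanno_delta_k(summary[summary$rep == 1, ]), "replicates")
})

test_that("ancestry recovery beats 0.1 mean absolute error at F = 0.2", {
  q_true <- cbind(rev(seq(0, 1, length.out = 4)), seq(0, 1, length.out = 4))
  cfg <- sim_config(pops = paste0("P", 1:4), n_per_pop = 50, k_true = 2,
                    f = 0.2, loci = setNames(rep(10L, 20), paste0("L", 1:20)),
                    q_true = q_true, seed = 67)
  sim <- simulate_msat(cfg)
  run <- admixture_mcmc(sim$geno, k = 2, sweeps = 2500, seed = 41)
  pop_idx <- match(geno_individuals(sim$geno)$pop, cfg$pops)
  truth <- q_true[pop_idx, ]
  mae <- function(q) mean(abs(q - truth))
  expect_lt(min(mae(run$Q), mae(run$Q[, 2:1])), 0.1)
})

test_that("DAPC separates groups and respects its guards", {
  cfg <- sim_config(pops = c("A", "B"), n_per_pop = 30, k_true = 2, f = 0.5,
                    loci = setNames(rep(6L, 12), paste0("L", 1:12)),
                    q_true = diag(2), seed = 71)
  sim <- simulate_msat(cfg)
  fit <- dapc(sim$geno, n_pca = 10)
  expect_equal(fit$n_da, 1)
  post <- fit$posterior
  own <- ifelse(post$pop == "A", post$A, post$B)
  expect_gt(mean(own > 0.99), 0.95)
  expect_equal(rowSums(as.matrix(post[c("A", "B")])), rep(1, 60),
               tolerance = 1e-9)
  expect_error(dapc(sim$geno, n_pca = 60), "smaller than the number")
  one <- sim$geno[sim$geno$id != "A_001", ]
  class(one) <- class(sim$geno)
  expect_silent(dapc(one, n_pca = 5))
})

test_that("DAPC coordinates are invariant to allele relabeling", {
  set.seed(73)
  g <- random_geno(n_pops = 3, n_ind = 15, n_loci = 5, n_alleles = 3)
  f1 <- dapc(g, n_pca = 6)
  rel <- g
  rel$a1 <- 5L - g$a1
  rel$a2 <- 5L - g$a2
  f2 <- dapc(geno_tbl(rel), n_pca = 6)
  c1 <- as.matrix(f1$ind_coord[paste0("LD", seq_len(f1$n_da))])
  c2 <- as.matrix(f2$ind_coord[paste0("LD", seq_len(f2$n_da))])
  for (j in seq_len(ncol(c1))) {
    expect_true(max(abs(c1[, j] - c2[, j])) < 1e-6 ||
                  max(abs(c1[, j] + c2[, j])) < 1e-6)
  }
})

test_that("the preset transect mirrors the survey's DAPC topology", {
  sim <- simulate_msat(preset_amapa(seed = 79))
  fit <- dapc(sim$geno, n_pca = 4)
  expect_equal(fit$n_pca, 4)
  expect_equal(fit$n_da, 4)  # discriminant count capped by retained PCs
  cent <- tidy(fit) |>
    dplyr::group_by(pop) |>
    dplyr::summarise(LD1 = mean(LD1))
  # transect endpoints sit at opposite extremes of the first discriminant
  ord <- cent$LD1[match(c("MAC", "PGR", "FGO", "TTZ", "CAL", "OIA"), cent$pop)]
  expect_true(which.max(abs(ord - ord[1])) == 6)
})
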