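test_that("Weir-Cockerham theta matches the brute-force component oracle", {
  set.seed(23)
  for (rep in 1:30) {
    g <- random_geno(n_pops = sample(2:3, 1), n_ind = sample(2:5, 1),
                     n_loci = sample(1:3, 1), n_alleles = sample(2:4, 1),
                     missing_rate = 0.1)
    expect_equal(wc_theta(g), oracle_wc_theta(g), tolerance = 1e-10)
  }
})

test_that("theta is invariant to allele relabeling and population order", {
  set.seed(29)
  g <- random_geno(n_pops = 2, n_ind = 8, n_loci = 2, n_alleles = 3)
  relabeled <- g
  relabeled$a1 <- 5L - g$a1  # 1..3 -> 4..2
  relabeled$a2 <- 5L - g$a2
  expect_equal(wc_theta(g), wc_theta(geno_tbl(relabeled)), tolerance = 1e-12)
  expect_equal(wc_theta(g, pops = c("P1", "P2")),
               wc_theta(g, pops = c("P2", "P1")), tolerance = 1e-12)
})

test_that("theta hits its panmixia and fixation limits", {
  # identical genotype arrays in both pops, n = 100 each
  set.seed(31)
  gens <- lapply(1:100, function(i) sample(4, 2, replace = TRUE))
  g <- make_geno(list(P1 = gens, P2 = gens))
  expect_lt(abs(wc_theta(g)), 0.02)
  # fixed for different alleles
  gf <- make_geno(list(P1 = replicate(20, c(1, 1), simplify = FALSE),
                       P2 = replicate(20, c(2, 2), simplify = FALSE)))
  expect_equal(wc_theta(gf), 1)
})

test_that("pairwise Fst carries Nm and permutation p-values", {
  gf <- make_geno(list(P1 = replicate(10, c(1, 1), simplify = FALSE),
                       P2 = replicate(10, c(2, 2), simplify = FALSE)))
  pf <- pairwise_fst(gf, permutations = 199, seed = 5)
  expect_equal(pf$pairs$fst, 1)
  expect_equal(pf$pairs$p, 1 / 200)  # observed theta is maximal
  expect_equal(pf$pairs$nm, 0)
  m <- as.matrix(pf)
  expect_true(isSymmetric(m))
  # reproducibility under a fixed seed
  pf2 <- pairwise_fst(gf, permutations = 199, seed = 5)
  expect_identical(pf$pairs, pf2$pairs)
})

test_that("island-model Nm follows its closed form and flags Fst <= 0", {
  expect_equal(nm_from_fst(0.2), 1)
  expect_equal(nm_from_fst(0.5), 0.25)
  expect_equal(nm_from_fst(0.004), 62.25)
  expect_equal(nm_from_fst(c(-0.01, 0)), c(Inf, Inf))
  expect_true(is.na(nm_from_fst(NA)))
})

test_that("a drifted two-cluster simulation recovers F from theta", {
  cfg <- sim_config(pops = c("A", "B"), n_per_pop = 100, k_true = 2,
                    f = 0.1, loci = setNames(rep(6L, 20), paste0("L", 1:20)),
                    q_true = diag(2), seed = 37)
  th <- wc_theta(simulate_msat(cfg)$geno)
  expect_lt(abs(th - 0.1) / 0.1, 0.35)
})

test_that("AMOVA sums of squares match pair-enumeration on toy data", {
  g <- make_geno(list(P1 = list(c(1, 1), c(1, 2)), P2 = list(c(2, 2), c(2, 3))))
  oracle <- oracle_amova_ss(g, "L1")
  parts <- popkdr:::amova_locus_ss(g[g$locus == "L1", ])
  expect_equal(parts$ssa, unname(oracle["ssa"]), tolerance = 1e-12)
  expect_equal(parts$ssb, unname(oracle["ssb"]), tolerance = 1e-12)
  expect_equal(parts$ssw, unname(oracle["ssw"]), tolerance = 1e-12)
  expect_equal(parts$ssa + parts$ssb + parts$ssw, unname(oracle["sst"]),
               tolerance = 1e-12)
})

test_that("AMOVA component table is additive and degenerate cases resolve", {
  set.seed(41)
  g <- random_geno(n_pops = 3, n_ind = 10, n_loci = 4, n_alleles = 4,
                   missing_rate = 0.05)
  res <- amova(g)
  tab <- tidy(res)
  expect_equal(tab$SS[4], sum(tab$SS[1:3]), tolerance = 1e-9)
  expect_equal(tab$sigma2[4], sum(tab$sigma2[1:3]), tolerance = 1e-9)
  expect_equal(sum(tab$pct[1:3]), 100, tolerance = 1e-9)

  # all individuals identical homozygotes: zero components, NA statistics
  g0 <- make_geno(list(P1 = list(c(1, 1), c(1, 1)), P2 = list(c(1, 1), c(1, 1))))
  res0 <- amova(g0)
  expect_equal(tidy(res0)$sigma2[1:3], rep(0, 3))
  expect_true(all(is.na(res0$statistics$value)))
  # fixed difference between pops: Fst = 1, Fis undefined
  gf <- make_geno(list(P1 = replicate(5, c(1, 1), simplify = FALSE),
                       P2 = replicate(5, c(2, 2), simplify = FALSE)))
  resf <- amova(gf)
  st <- resf$statistics
  expect_equal(st$value[st$statistic == "Fst"], 1)
  expect_true(is.na(st$value[st$statistic == "Fis"]))
  expect_error(amova(make_geno(list(P1 = list(c(1, 2))))), ">= 2 populations")
})

test_that("AMOVA permutation p flags real structure and spares panmixia", {
  gf <- make_geno(list(P1 = replicate(10, c(1, 1), simplify = FALSE),
                       P2 = replicate(10, c(2, 2), simplify = FALSE)))
  res <- amova(gf, permutations = 99, seed = 7)
  st <- res$statistics
  expect_lte(st$p[st$statistic == "Fst"], 0.02)
})

test_that("haversine distances use the 6371 km sphere", {
  sites <- tibble::tibble(name = c("a", "b"), lat = c(0, 0), lon = c(0, 1))
  m <- haversine_matrix(sites)
  expect_equal(m["a", "b"], 2 * pi * 6371 / 360, tolerance = 1e-4)
  expect_equal(diag(m), c(a = 0, b = 0))
  expect_true(isSymmetric(m))
})

test_that("Mantel r is exact under affine relations and matches vegan", {
  set.seed(43)
  n <- 6
  x <- matrix(runif(n * n), n); A <- as.matrix(stats::as.dist(x))
  B <- 2 * A + 3
  diag(B) <- 0
  res <- mantel_test(A, B, permutations = 99, seed = 1)
  expect_equal(res$r, 1)
  y <- matrix(runif(n * n), n); C <- as.matrix(stats::as.dist(y))
  r_pkg <- mantel_test(A, C, permutations = 999, seed = 2)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(A, C, permutations = 999)
  expect_equal(r_pkg$r, unname(vg$statistic), tolerance = 1e-12)
  # both one-tailed permutation p-values; agree within Monte-Carlo error
  expect_lt(abs(r_pkg$p - vg$signif), 0.12)
})

test_that("Mantel permutation p is uniform under independence", {
  set.seed(47)
  ps <- vapply(1:100, function(i) {
    A <- as.matrix(stats::as.dist(matrix(runif(49), 7)))
    B <- as.matrix(stats::as.dist(matrix(runif(49), 7)))
    mantel_test(A, B, permutations = 199)$p
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # degenerate: zero variance
  Z <- matrix(0, 4, 4)
  expect_true(is.na(mantel_test(Z, Z + 0, permutations = 9)$r))
})
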