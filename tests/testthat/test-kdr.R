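test_that("decomposition is sound and complete for all 27 possible calls", {
  calls <- all_kdr_calls()
  alphabet <- kdr_alphabet()
  states <- setNames(
    lapply(seq_len(nrow(alphabet)),
           function(i) c(alphabet$s410[i], alphabet$s1016[i], alphabet$s1534[i])),
    alphabet$allele)
  for (i in seq_len(nrow(calls))) {
    dec <- kdr_decompose(calls$g410[i], calls$g1016[i], calls$g1534[i])
    # completeness: agrees with brute force over all 21 unordered pairs
    brute <- oracle_kdr_pairs(calls$g410[i], calls$g1016[i], calls$g1534[i])
    expect_equal(length(dec$pairs), length(brute))
    # soundness: site-wise recombination of each pair reproduces the call
    for (pair in dec$pairs) {
      h1 <- states[[pair[1]]]; h2 <- states[[pair[2]]]
      rebuilt <- vapply(1:3, function(s) {
        paste(sort(c(h1[s], h2[s])), collapse = "")
      }, "")
      target <- vapply(c(calls$g410[i], calls$g1016[i], calls$g1534[i]),
                       function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""), "")
      expect_equal(rebuilt, unname(target))
    }
  }
})

test_that("named genotype classes decompose as in the field literature", {
  expect_equal(kdr_decompose("VV", "VV", "FF")$class, "SS")
  expect_equal(kdr_decompose("LL", "VI", "CC")$pairs, list(c("R2", "X1")))
  expect_equal(kdr_decompose("LL", "VI", "CC")$class, "R2X1")
  y <- kdr_decompose("LL", "VI", "FC")
  expect_equal(y$class, "Y")
  expect_true(y$ambiguous)
  expect_setequal(vapply(y$pairs, paste, "", collapse = "/"),
                  c("R2/X2", "X1/X3"))
  # requires the unobserved VIC haplotype: unresolvable in the closed alphabet
  expect_equal(kdr_decompose("VV", "VI", "CC")$class, "UNRESOLVED")
  # site order in genotype strings is irrelevant
  expect_equal(kdr_decompose("LV", "IV", "CF")$class,
               kdr_decompose("VL", "VI", "FC")$class)
  expect_error(kdr_decompose("VZ", "VV", "FF"), "invalid")
})

test_that("restricted alphabet {S,R1,R2} yields exactly six genotype classes", {
  ab <- kdr_alphabet()[kdr_alphabet()$allele %in% c("S", "R1", "R2"), ]
  classes <- unique(vapply(seq_len(nrow(all_kdr_calls())), function(i) {
    cc <- all_kdr_calls()[i, ]
    kdr_decompose(cc$g410, cc$g1016, cc$g1534, alphabet = ab)$class
  }, ""))
  classes <- setdiff(classes, "UNRESOLVED")
  expect_setequal(classes, c("SS", "SR1", "SR2", "R1R1", "R1R2", "R2R2"))
})

test_that("classification handles missing sites and empty input", {
  calls <- data.frame(id = c("a", "b"), pop = "P",
                      g410 = c("VV", NA), g1016 = c("VV", "VI"),
                      g1534 = c("CC", "FC"))
  cl <- kdr_classify(calls)
  expect_equal(cl$class, c("R1R1", "MISSING"))
  empty <- kdr_classify(calls[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("frequencies sum to one and apportion ambiguity as documented", {
  calls <- data.frame(
    id = paste0("i", 1:4), pop = "P",
    g410 = c("VV", "VV", "LL", NA),
    g1016 = c("VV", "VV", "VI", "VV"),
    g1534 = c("FF", "CC", "FC", "CC"))
  fr <- kdr_frequencies(calls)
  gt <- fr$genotypes
  expect_equal(sum(gt$freq), 1)
  expect_equal(unique(gt$n), 3)  # the missing call is excluded
  al <- fr$alleles
  expect_equal(sum(al$freq), 1, tolerance = 1e-12)

  # two-individual toy: {SS, R1R1} -> S and R1 at 0.5
  two <- data.frame(id = c("x", "y"), pop = "P", g410 = "VV", g1016 = "VV",
                    g1534 = c("FF", "CC"))
  a2 <- kdr_frequencies(two)$alleles
  expect_equal(a2$freq[a2$allele %in% c("S", "R1")], c(0.5, 0.5))

  # single Y individual under equal split: four alleles at 1/4
  y1 <- data.frame(id = "y", pop = "P", g410 = "LL", g1016 = "VI", g1534 = "FC")
  ay <- kdr_frequencies(y1)$alleles
  expect_equal(ay$freq[ay$allele %in% c("R2", "X1", "X2", "X3")],
               rep(0.25, 4))

  expect_error(kdr_frequencies(
    data.frame(id = "a", pop = "P", g410 = NA, g1016 = "VV", g1534 = "FF")),
    "no fully genotyped")
})

test_that("EM apportions Y individuals toward the pair its cohort supports", {
  # many unambiguous R2 carriers: Y should be assigned mostly to (R2, X2)
  calls <- rbind(
    data.frame(id = paste0("r", 1:20), pop = "P", g410 = "LL",
               g1016 = "II", g1534 = "CC"),              # R2R2
    data.frame(id = paste0("y", 1:4), pop = "P", g410 = "LL",
               g1016 = "VI", g1534 = "FC"))              # Y
  em <- kdr_frequencies(calls, method = "em")
  al <- tidyr::pivot_wider(em$alleles, names_from = allele,
                           values_from = freq)
  # direct likelihood maximization over the 2-pair mixture: with R2 freq
  # >> everything else, P(R2,X2) >> P(X1,X3), so X2 absorbs ~1 copy per Y
  expect_gt(al$X2, 10 * al$X1)
  expect_gt(al$X2, 10 * al$X3)
  expect_equal(sum(em$alleles$freq), 1, tolerance = 1e-9)
  # equal-split, by contrast, gives X1 = X3 = X2/... all equal weights
  eq <- kdr_frequencies(calls, method = "equal_split")$alleles
  aq <- tidyr::pivot_wider(eq, names_from = allele, values_from = freq)
  expect_equal(aq$X1, aq$X2)
  expect_equal(aq$X1, aq$X3)

  # EM log-likelihood is monotonically non-decreasing
  ll <- em$em[["P"]]$loglik
  expect_true(length(ll) >= 2)
  expect_true(all(diff(ll) >= -1e-9))
})

test_that("genotype and allele frequencies sum to one under both methods", {
  sim <- simulate_kdr(preset_amapa(seed = 5))
  for (m in c("equal_split", "em")) {
    fr <- kdr_frequencies(sim$calls, method = m)
    gsum <- tapply(fr$genotypes$freq, fr$genotypes$pop, sum)
    asum <- tapply(fr$alleles$freq, fr$alleles$pop, sum)
    expect_equal(as.vector(gsum), rep(1, 6), tolerance = 1e-12)
    expect_equal(as.vector(asum), rep(1, 6), tolerance = 1e-9)
  }
})
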