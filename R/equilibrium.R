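# ---- Levene's conditional distribution ------------------------------------
# A genotype array n_jk (j <= k) with allele counts a_j and heterozygote
# count h has conditional probability, given the allele counts:
#   P = n! 2^h prod(a_j!) / (prod(n_jk!) (2n)!)

levene_log_prob <- function(counts, n, a) {
  h <- sum(counts[upper.tri(counts)])
  lfactorial(n) + h * log(2) + sum(lfactorial(a)) -
    sum(lfactorial(counts[upper.tri(counts, diag = TRUE)])) -
    lfactorial(2 * n)
}

# Enumerate all genotype arrays compatible with allele counts `a`,
# calling fn(counts_matrix, logP) for each. Arrays are built cell by cell
# (upper triangle of a J x J matrix) with pruning on remaining counts.
enumerate_levene <- function(a, fn) {
  J <- length(a)
  n <- sum(a) / 2
  cells <- which(upper.tri(diag(J), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  counts <- matrix(0L, J, J)

  recurse <- function(idx, rem) {
    if (idx > nrow(cells)) {
      if (all(rem == 0L)) fn(counts, levene_log_prob(counts, n, a))
      return(invisible())
    }
    i <- cells[idx, 1]; j <- cells[idx, 2]
    max_c <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    # last cell touching allele i? then its count is forced
    for (cnt in 0:max_c) {
      counts[i, j] <<- cnt
      use <- integer(length(rem))
      use[i] <- use[i] + if (i == j) 2L * cnt else cnt
      if (i != j) use[j] <- use[j] + cnt
      new_rem <- rem - use
      # prune: allele i is finished once we pass its last cell
      last_for_i <- j == J
      if (!last_for_i || new_rem[i] == 0L) {
        recurse(idx + 1, new_rem)
      }
    }
    counts[i, j] <<- 0L
    invisible()
  }
  recurse(1, as.integer(a))
  invisible()
}

genotype_count_matrix <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  J <- length(alleles)
  m <- matrix(0L, J, J, dimnames = list(alleles, alleles))
  i <- match(pmin(a1, a2), alleles)
  j <- match(pmax(a1, a2), alleles)
  for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1L
  m
}

# Exact/Monte-Carlo HWE test for one genotype array.
hwe_exact_single <- function(counts, cap = 4, iter = 100000) {
  J <- nrow(counts)
  n <- sum(counts)
  a <- integer(J)  # allele counts from the upper-triangle storage
  for (i in seq_len(J)) for (j in i:J) {
    cnt <- counts[i, j]
    a[i] <- a[i] + cnt * (if (i == j) 2L else 1L)
    if (j > i) a[j] <- a[j] + cnt
  }
  if (J < 2) return(list(p = NA_real_, method = "monomorphic"))
  obs_lp <- levene_log_prob(counts, n, a)
  if (J <= cap) {
    tot <- 0
    p <- 0
    enumerate_levene(a, function(cnts, lp) {
      tot <<- tot + exp(lp)
      if (lp <= obs_lp + 1e-9) p <<- p + exp(lp)
    })
    return(list(p = min(1, p / tot), method = "enumeration"))
  }
  # Monte Carlo: random re-pairings of the allele vector sample Levene's
  # conditional null directly (no Markov chain to tune)
  copies <- rep(seq_len(J), a)
  half <- length(copies) / 2
  const <- lfactorial(n) + sum(lfactorial(a)) - lfactorial(2 * n)
  hits <- 0L
  for (s in seq_len(iter)) {
    perm <- sample(copies)
    i1 <- pmin(perm[seq_len(half)], perm[half + seq_len(half)])
    i2 <- pmax(perm[seq_len(half)], perm[half + seq_len(half)])
    cnts <- tabulate((i1 - 1L) * J + i2, nbins = J * J)
    lp <- const + sum(i1 != i2) * log(2) - sum(lfactorial(cnts))
    if (lp <= obs_lp + 1e-9) hits <- hits + 1L
  }
  list(p = (1 + hits) / (iter + 1), method = "mc")
}

#' Hardy-Weinberg exact tests
#'
#' Tests every population x locus combination against Levene's conditional
#' distribution of genotype arrays given the allele counts. The p-value is
#' the total conditional probability of arrays no more probable than the
#' observed one. Complete enumeration is used when the locus has at most
#' `cap` distinct alleles in that population; otherwise the null is
#' sampled by Monte-Carlo re-pairings of the allele vector and
#' `p = (1 + hits) / (iter + 1)`.
#'
#' @param geno A [geno_tbl()].
#' @param cap Maximum allele count for complete enumeration (>= 2).
#' @param iter Monte-Carlo iterations.
#' @param seed Seed for the Monte-Carlo path.
#' @return A tibble `pop`, `locus`, `n`, `k_alleles`, `Fis`, `p`,
#'   `method`; monomorphic loci get `p = NA`.
#' @export
hwe_exact <- function(geno, cap = 4, iter = 100000, seed = NULL) {
  if (cap < 2) stop("cap must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  typed <- tibble::as_tibble(geno)[!is.na(geno$a1), ]
  grid <- dplyr::distinct(typed[c("pop", "locus")])
  res <- purrr::pmap_dfr(grid, function(pop, locus) {
    rows <- typed[typed$pop == pop & typed$locus == locus, ]
    counts <- genotype_count_matrix(rows$a1, rows$a2)
    ho <- mean(rows$a1 != rows$a2)
    p_vec <- allele_freq_vector(rows$a1, rows$a2)
    he <- 1 - sum(p_vec^2)
    fis <- if (he > 0) (he - ho) / he else NA_real_
    out <- if (nrow(rows) < 2 || nrow(counts) < 2) {
      list(p = NA_real_, method = if (nrow(counts) < 2) "monomorphic" else "too_few")
    } else {
      hwe_exact_single(counts, cap = cap, iter = iter)
    }
    tibble::tibble(pop = pop, locus = locus, n = nrow(rows),
                   k_alleles = nrow(counts), Fis = fis,
                   p = out$p, method = out$method)
  })
  res
}

allele_freq_vector <- function(a1, a2) {
  tab <- table(c(a1, a2))
  as.numeric(tab) / sum(tab)
}

# ---- genotypic linkage disequilibrium -------------------------------------

g_statistic <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sel <- tab > 0
  2 * sum(tab[sel] * log(tab[sel] / E[sel]))
}

#' Genotypic linkage-disequilibrium permutation tests
#'
#' For every population and unordered locus pair, builds the contingency
#' table of unphased genotype categories and computes the log-likelihood
#' ratio statistic `G = 2 sum O log(O/E)`. Significance comes from
#' permuting one locus's genotypes across the individuals of that
#' population; `p = (1 + exceedances) / (permutations + 1)`. A degenerate
#' table (a single genotype category at either locus) gives `G = 0`,
#' `p = 1`.
#'
#' @param geno A [geno_tbl()].
#' @param permutations Number of permutations.
#' @param seed Seed.
#' @return A tibble `pop`, `locus1`, `locus2`, `n`, `G`, `p`.
#' @export
ld_test <- function(geno, permutations = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- ld_test_grid(locus_names(geno), pop_names(geno))
  typed <- tibble::as_tibble(geno)[!is.na(geno$a1), ]
  typed$g <- paste(typed$a1, typed$a2, sep = "/")
  purrr::pmap_dfr(grid, function(pop, locus1, locus2) {
    x <- typed[typed$pop == pop & typed$locus == locus1, c("id", "g")]
    y <- typed[typed$pop == pop & typed$locus == locus2, c("id", "g")]
    m <- dplyr::inner_join(x, y, by = "id", suffix = c("1", "2"))
    n <- nrow(m)
    if (n < 2) {
      return(tibble::tibble(pop = pop, locus1 = locus1, locus2 = locus2,
                            n = n, G = 0, p = 1))
    }
    tab <- table(m$g1, m$g2)
    g_obs <- g_statistic(tab)
    if (g_obs == 0 || length(unique(m$g1)) < 2 || length(unique(m$g2)) < 2) {
      return(tibble::tibble(pop = pop, locus1 = locus1, locus2 = locus2,
                            n = n, G = g_obs, p = 1))
    }
    hits <- 0L
    for (s in seq_len(permutations)) {
      gp <- g_statistic(table(m$g1, sample(m$g2)))
      if (gp >= g_obs - 1e-12) hits <- hits + 1L
    }
    tibble::tibble(pop = pop, locus1 = locus1, locus2 = locus2, n = n,
                   G = g_obs, p = (1 + hits) / (permutations + 1))
  })
}

#' The LD test grid
#'
#' All unordered locus pairs crossed with all populations: `choose(L, 2) *
#' P` tests for `L` loci and `P` populations.
#'
#' @param loci Character vector of locus names.
#' @param pops Character vector of population names.
#' @return A tibble `pop`, `locus1`, `locus2`.
#' @examples
#' nrow(ld_test_grid(paste0("L", 1:12), paste0("P", 1:6)))  # 396
#' @export
ld_test_grid <- function(loci, pops) {
  if (length(loci) < 2) stop("need >= 2 loci", call. = FALSE)
  pairs <- utils::combn(loci, 2)
  tidyr::expand_grid(pop = pops,
                     pair = seq_len(ncol(pairs))) |>
    dplyr::mutate(locus1 = pairs[1, .data$pair],
                  locus2 = pairs[2, .data$pair]) |>
    dplyr::select("pop", "locus1", "locus2")
}

#' Bonferroni correction
#'
#' Flags results whose p-value falls below `alpha / m`, where `m` is the
#' size of the test family: all rows with a defined p-value, or the rows
#' sharing a value of `by` (e.g. per-population families).
#'
#' @param results A tibble with a `p` column (e.g. from [hwe_exact()] or
#'   [ld_test()]).
#' @param alpha Family-wise error rate in (0, 1).
#' @param by Optional column name defining sub-families.
#' @return The input with `n_tests`, `threshold` and `significant` added.
#' @export
bonferroni <- function(results, alpha = 0.05, by = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (!"p" %in% names(results)) stop("results need a 'p' column", call. = FALSE)
  grp <- if (is.null(by)) rep(1L, nrow(results)) else results[[by]]
  ok <- !is.na(results$p)
  if (!any(ok)) stop("empty test family (no defined p-values)", call. = FALSE)
  fam <- tapply(ok, grp, sum)
  results$n_tests <- as.integer(fam[as.character(grp)])
  results$threshold <- alpha / results$n_tests
  results$significant <- ok & results$p <= results$threshold
  results
}

#' Brookfield null-allele frequency estimator
#'
#' Estimator 1 of Brookfield (1996): `r = (He - Ho) / (1 + He)`, truncated
#' at zero, per population and locus. Sensitive to any cause of
#' heterozygote deficit, so treat it as a screen rather than proof of null
#' alleles.
#'
#' @param geno A [geno_tbl()].
#' @return A tibble `pop`, `locus`, `Ho`, `He`, `r`.
#' @export
null_allele_estimate <- function(geno) {
  typed <- tibble::as_tibble(geno)[!is.na(geno$a1), ]
  typed |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(
      Ho = mean(.data$a1 != .data$a2),
      He = 1 - sum((table(c(.data$a1, .data$a2)) /
                      (2 * dplyr::n()))^2),
      .groups = "drop") |>
    dplyr::mutate(r = pmax(0, (.data$He - .data$Ho) / (1 + .data$He)))
}
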