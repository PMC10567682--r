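# ---- Weir & Cockerham (1984) theta ----------------------------------------

# Per pop x locus sufficient statistics for one allele A:
#   n_i individuals typed, p_i allele frequency, h_i observed frequency of
#   heterozygotes carrying A. Components a, b, c follow the 1984 estimator;
#   theta = sum(a) / sum(a + b + c) over loci and alleles.
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  if (r < 2 || nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

theta_from_stats <- function(stats_by_locus) {
  acc <- c(a = 0, b = 0, c = 0)
  any_ok <- FALSE
  for (st in stats_by_locus) {
    if (is.null(st)) next
    for (comp in st) {
      if (is.null(comp) || any(!is.finite(comp))) next
      acc <- acc + comp
      any_ok <- TRUE
    }
  }
  den <- sum(acc)
  if (!any_ok || den == 0) return(NA_real_)
  unname(acc["a"] / den)
}

# per locus: list over alleles of c(a,b,c), for the given set of pops
locus_wc_stats <- function(rows, pops) {
  rows <- rows[!is.na(rows$a1) & rows$pop %in% pops, ]
  by_pop <- split(rows, factor(rows$pop, levels = pops))
  n <- vapply(by_pop, nrow, 1L)
  keep <- n > 0
  if (sum(keep) < 2) return(NULL)
  by_pop <- by_pop[keep]
  n <- n[keep]
  alleles <- sort(unique(c(rows$a1, rows$a2)))
  if (length(alleles) < 2) return(NULL)
  lapply(alleles, function(A) {
    p <- vapply(by_pop, function(d) mean(c(d$a1, d$a2) == A), 0)
    h <- vapply(by_pop, function(d) mean((d$a1 == A) != (d$a2 == A)), 0)
    wc_components(n, p, h)
  })
}

#' Multi-locus Weir-Cockerham theta (Fst)
#'
#' The 1984 variance-component estimator of Fst across the given
#' populations: per locus and allele, among-population (`a`), among-
#' individual (`b`) and within-individual (`c`) components are accumulated
#' and `theta = sum(a) / sum(a+b+c)`. Loci monomorphic across the chosen
#' populations, or typed in fewer than two of them, are skipped.
#'
#' @param geno A [geno_tbl()].
#' @param pops Populations to include (default all).
#' @return A single numeric theta (can be slightly negative; `NA` when no
#'   locus is informative).
#' @export
wc_theta <- function(geno, pops = NULL) {
  if (is.null(pops)) pops <- pop_names(geno)
  by_locus <- split(tibble::as_tibble(geno), geno$locus)
  theta_from_stats(lapply(by_locus, locus_wc_stats, pops = pops))
}

#' Pairwise Fst with permutation significance and Nm
#'
#' Weir-Cockerham theta for every population pair, an island-model
#' migrant-number transform `Nm = (1 - Fst) / (4 Fst)`, and (optionally)
#' a permutation p-value obtained by reallocating individuals between the
#' two populations with sizes held fixed;
#' `p = (1 + #(theta_perm >= theta_obs)) / (permutations + 1)`.
#'
#' @param geno A [geno_tbl()].
#' @param permutations Permutations per pair (0 skips the test).
#' @param seed Seed.
#' @return A `pairwise_fst` object: tibble `pop1`, `pop2`, `fst`, `nm`,
#'   `p` plus the full symmetric matrix in `as.matrix()`.
#' @export
pairwise_fst <- function(geno, permutations = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- pop_names(geno)
  prs <- utils::combn(pops, 2)
  df <- tibble::as_tibble(geno)
  res <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    pa <- prs[1, k]; pb <- prs[2, k]
    sub <- df[df$pop %in% c(pa, pb), ]
    th <- wc_theta(geno_subset(sub), pops = c(pa, pb))
    p <- NA_real_
    if (permutations > 0 && is.finite(th)) {
      roster <- dplyr::distinct(sub[c("id", "pop")])
      hits <- 0L
      for (s in seq_len(permutations)) {
        new_pop <- setNames(sample(roster$pop), roster$id)
        perm <- sub
        perm$pop <- unname(new_pop[perm$id])
        tp <- wc_theta(geno_subset(perm), pops = c(pa, pb))
        if (is.finite(tp) && tp >= th - 1e-12) hits <- hits + 1L
      }
      p <- (1 + hits) / (permutations + 1)
    }
    tibble::tibble(pop1 = pa, pop2 = pb, fst = th, nm = nm_from_fst(th), p = p)
  })
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (k in seq_len(nrow(res))) {
    m[res$pop1[k], res$pop2[k]] <- m[res$pop2[k], res$pop1[k]] <- res$fst[k]
  }
  structure(list(pairs = res, matrix = m, permutations = permutations),
            class = "pairwise_fst")
}

geno_subset <- function(df) {
  out <- tibble::as_tibble(df)
  class(out) <- c("geno_tbl", class(tibble::tibble()))
  out
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("<pairwise_fst> Weir-Cockerham theta",
      if (x$permutations > 0) sprintf("(%d permutations)", x$permutations),
      "\n")
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.pairwise_fst <- function(x, ...) x$pairs

#' @export
as.matrix.pairwise_fst <- function(x, ...) x$matrix

#' Island-model migrant number
#'
#' `Nm = (1 - Fst) / (4 Fst)` under Wright's island model. Estimates at or
#' below `Fst = 0` are flagged infinite (unbounded gene flow); `NA` stays
#' `NA`.
#'
#' @param fst Numeric vector of Fst values.
#' @return Numeric vector of Nm values.
#' @examples
#' nm_from_fst(0.2)  # 1
#' @export
nm_from_fst <- function(fst) {
  ifelse(is.na(fst), NA_real_,
         ifelse(fst <= 0, Inf, (1 - fst) / (4 * fst)))
}

# ---- AMOVA ----------------------------------------------------------------

# Per-locus sums of squares on allele-identity distances (d = 0/1 between
# allele copies), with strata: among populations / among individuals
# within populations / within individuals.
amova_locus_ss <- function(rows) {
  rows <- rows[!is.na(rows$a1), ]
  pops <- unique(rows$pop)
  if (nrow(rows) < 2 || length(pops) < 2) return(NULL)
  ss_group <- function(copies) {
    m <- length(copies)
    if (m == 0) return(0)
    (m^2 - sum(table(copies)^2)) / (2 * m)
  }
  all_copies <- c(rows$a1, rows$a2)
  sst <- ss_group(all_copies)
  ssp <- vapply(pops, function(p) {
    d <- rows[rows$pop == p, ]
    ss_group(c(d$a1, d$a2))
  }, 0)
  ssw <- sum(rows$a1 != rows$a2) / 2
  n_p <- vapply(pops, function(p) sum(rows$pop == p), 0)
  N <- sum(n_p)
  list(ssa = sst - sum(ssp), ssb = sum(ssp) - ssw, ssw = ssw,
       df_a = length(pops) - 1, df_b = N - length(pops), df_w = N,
       nc = (N - sum(n_p^2) / N) / (length(pops) - 1))
}

#' Two-level analysis of molecular variance
#'
#' Locus-by-locus AMOVA on allele-identity distances (squared distance
#' between genotypes = number of non-shared allele copies), partitioning
#' variance among populations, among individuals within populations, and
#' within individuals. Sums of squares and degrees of freedom are summed
#' across loci; variance components follow the standard mean-square
#' expectations, and F-statistics are `Fst = s2a/total`,
#' `Fis = s2b/(s2b + s2c)`, `Fit = (s2a + s2b)/total`. Negative components
#' are reported as-is with a warning, never truncated. Permutation
#' p-values: whole individuals among populations for Fst, alleles among
#' individuals within populations for Fis.
#'
#' @param geno A [geno_tbl()].
#' @param permutations Number of permutations (0 skips p-values).
#' @param seed Seed.
#' @return An `amova_result` with a component table and F-statistics.
#' @export
amova <- function(geno, permutations = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(pop_names(geno)) < 2) stop("AMOVA needs >= 2 populations", call. = FALSE)
  comp <- amova_components(geno)
  if (any(is.finite(unlist(comp$sigma2))) &&
      any(unlist(comp$sigma2) < 0, na.rm = TRUE)) {
    warning("negative variance component(s) reported as-is", call. = FALSE)
  }
  p_fst <- p_fis <- NA_real_
  if (permutations > 0) {
    df <- tibble::as_tibble(geno)
    roster <- geno_individuals(geno)
    hits_fst <- 0L
    for (s in seq_len(if (is.finite(comp$stat["Fst"])) permutations else 0)) {
      new_pop <- setNames(sample(roster$pop), roster$id)
      perm <- df
      perm$pop <- unname(new_pop[perm$id])
      cp <- amova_components(geno_subset(perm))
      if (is.finite(cp$stat["Fst"]) &&
          cp$stat["Fst"] >= comp$stat["Fst"] - 1e-12) hits_fst <- hits_fst + 1L
    }
    p_fst <- if (is.finite(comp$stat["Fst"])) {
      (1 + hits_fst) / (permutations + 1)
    } else NA_real_
    hits_fis <- 0L
    for (s in seq_len(if (is.finite(comp$stat["Fis"])) permutations else 0)) {
      perm <- df |>
        dplyr::group_by(.data$pop, .data$locus) |>
        dplyr::group_modify(function(d, key) {
          typed <- !is.na(d$a1)
          copies <- c(d$a1[typed], d$a2[typed])
          copies <- sample(copies)
          half <- length(copies) / 2
          d$a1[typed] <- pmin(copies[seq_len(half)], copies[half + seq_len(half)])
          d$a2[typed] <- pmax(copies[seq_len(half)], copies[half + seq_len(half)])
          d
        }) |>
        dplyr::ungroup()
      cp <- amova_components(geno_subset(perm))
      if (is.finite(cp$stat["Fis"]) &&
          cp$stat["Fis"] >= comp$stat["Fis"] - 1e-12) hits_fis <- hits_fis + 1L
    }
    p_fis <- if (is.finite(comp$stat["Fis"])) {
      (1 + hits_fis) / (permutations + 1)
    } else NA_real_
  }
  tab <- tibble::tibble(
    source = c("Among populations", "Among individuals within populations",
               "Within individuals", "Total"),
    df = c(comp$df, sum(comp$df)),
    SS = c(comp$ss, sum(comp$ss)),
    MS = c(comp$ss / comp$df, NA),
    sigma2 = c(comp$sigma2, sum(comp$sigma2)),
    pct = 100 * c(comp$sigma2, sum(comp$sigma2)) / sum(comp$sigma2))
  structure(list(table = tab,
                 statistics = tibble::tibble(
                   statistic = c("Fst", "Fis", "Fit"),
                   value = unname(comp$stat[c("Fst", "Fis", "Fit")]),
                   p = c(p_fst, p_fis, NA_real_)),
                 permutations = permutations),
            class = "amova_result")
}

amova_components <- function(geno) {
  by_locus <- split(tibble::as_tibble(geno), geno$locus)
  parts <- purrr::compact(lapply(by_locus, amova_locus_ss))
  if (length(parts) == 0) stop("no locus usable for AMOVA", call. = FALSE)
  ssa <- sum(vapply(parts, `[[`, 0, "ssa"))
  ssb <- sum(vapply(parts, `[[`, 0, "ssb"))
  ssw <- sum(vapply(parts, `[[`, 0, "ssw"))
  dfa <- sum(vapply(parts, `[[`, 0, "df_a"))
  dfb <- sum(vapply(parts, `[[`, 0, "df_b"))
  dfw <- sum(vapply(parts, `[[`, 0, "df_w"))
  # df-weighted average of the per-locus sample-size coefficient
  nc <- sum(vapply(parts, function(p) p$nc * p$df_a, 0)) / dfa
  msa <- ssa / dfa; msb <- ssb / dfb; msw <- ssw / dfw
  s2c <- msw
  s2b <- (msb - msw) / 2
  s2a <- (msa - msb) / (2 * nc)
  tot <- s2a + s2b + s2c
  stat <- c(Fst = if (tot != 0) s2a / tot else NA_real_,
            Fis = if ((s2b + s2c) != 0) s2b / (s2b + s2c) else NA_real_,
            Fit = if (tot != 0) (s2a + s2b) / tot else NA_real_)
  if (tot == 0) stat[] <- NA_real_
  list(ss = c(ssa, ssb, ssw), df = c(dfa, dfb, dfw),
       sigma2 = c(s2a, s2b, s2c), stat = stat)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$table)
  print(x$statistics)
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) x$table

#' @export
glance.amova_result <- function(x, ...) {
  tidyr::pivot_wider(x$statistics[c("statistic", "value")],
                     names_from = "statistic", values_from = "value")
}

# ---- geography and Mantel -------------------------------------------------

#' Great-circle distance matrix between sites
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param sites A site tibble from [read_sites()] (columns `name`, `lat`,
#'   `lon` in signed decimal degrees).
#' @return A symmetric matrix of distances in kilometres.
#' @export
haversine_matrix <- function(sites) {
  xy <- cbind(sites$lon, sites$lat)
  m <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(sites$name, sites$name)
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower-triangular entries, with a one-tailed
#' (positive association) permutation test that permutes rows and columns
#' of the second matrix simultaneously;
#' `p = (1 + exceedances) / (permutations + 1)`.
#'
#' @param mat_a,mat_b Same-shape symmetric matrices (>= 3 rows).
#' @param permutations Number of permutations.
#' @param seed Seed.
#' @return A `mantel_result` with `r`, `p`, `permutations`.
#' @export
mantel_test <- function(mat_a, mat_b, permutations = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat_a <- as.matrix(mat_a); mat_b <- as.matrix(mat_b)
  n <- nrow(mat_a)
  if (n < 3 || any(dim(mat_a) != dim(mat_b))) {
    stop("need two same-shape symmetric matrices with >= 3 rows", call. = FALSE)
  }
  lt <- lower.tri(mat_a)
  va <- mat_a[lt]; vb <- mat_b[lt]
  if (sd(va) == 0 || sd(vb) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_,
                          permutations = permutations), class = "mantel_result"))
  }
  r_obs <- cor(va, vb)
  hits <- 0L
  for (s in seq_len(permutations)) {
    ord <- sample(n)
    rp <- cor(va, mat_b[ord, ord][lt])
    if (rp >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (1 + hits) / (permutations + 1),
                 permutations = permutations), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, one-tailed p = %.4g (%d permutations)\n",
              x$r, x$p, x$permutations))
  invisible(x)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, permutations = x$permutations)
}
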