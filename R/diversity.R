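#' Per-population, per-locus allele frequencies
#'
#' @param geno A [geno_tbl()].
#' @return A tibble `pop`, `locus`, `allele`, `count`, `n_copies`, `freq`;
#'   missing calls are excluded from denominators. Population x locus
#'   combinations with no typed individual simply have no rows.
#' @export
allele_frequencies <- function(geno) {
  typed <- tibble::as_tibble(geno)[!is.na(geno$a1), ]
  long <- tidyr::pivot_longer(typed, c("a1", "a2"), values_to = "allele")
  long |>
    dplyr::count(.data$pop, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::mutate(n_copies = sum(.data$count),
                  freq = .data$count / .data$n_copies) |>
    dplyr::ungroup()
}

#' Genetic diversity indices per population
#'
#' Computes, per population and locus: the number of typed individuals
#' `n`, observed alleles `Na`, effective alleles `Ne = 1 / sum(p^2)`,
#' observed heterozygosity `Ho`, expected heterozygosity
#' `He = 1 - sum(p^2)`, unbiased `uHe = 2n/(2n-1) He`, private alleles
#' `Np` (alleles seen in that population only), rarefied allelic richness
#' `R` at `g` gene copies, and the inbreeding coefficient
#' `Fis = (He - Ho)/He` (`NA` at monomorphic loci). The population summary
#' is the unweighted mean across loci (so `Np` can be fractional and `N`
#' carries decimals when typing success varies by locus).
#'
#' @param geno A [geno_tbl()].
#' @param g Rarefaction size in gene copies; default per locus is the
#'   smallest number of typed copies across populations.
#' @return An object of class `diversity_table` with tibbles `by_locus`
#'   and `summary`.
#' @export
diversity <- function(geno, g = NULL) {
  af <- allele_frequencies(geno)
  typed <- tibble::as_tibble(geno)[!is.na(geno$a1), ]
  nn <- typed |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(n = dplyr::n(), Ho = mean(.data$a1 != .data$a2),
                     .groups = "drop")

  pops_per_allele <- af |>
    dplyr::distinct(.data$locus, .data$allele, .data$pop) |>
    dplyr::count(.data$locus, .data$allele, name = "n_pops_with")

  per <- af |>
    dplyr::left_join(pops_per_allele, by = c("locus", "allele")) |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(Na = dplyr::n(),
                     Ne = 1 / sum(.data$freq^2),
                     He = 1 - sum(.data$freq^2),
                     Np = sum(.data$n_pops_with == 1),
                     .groups = "drop") |>
    dplyr::left_join(nn, by = c("pop", "locus"))

  rar <- rarefied_richness(geno, g)
  per <- per |>
    dplyr::left_join(rar, by = c("pop", "locus")) |>
    dplyr::mutate(uHe = pmin(1, 2 * .data$n / pmax(2 * .data$n - 1, 1) * .data$He),
                  Fis = ifelse(.data$He > 0, (.data$He - .data$Ho) / .data$He,
                               NA_real_)) |>
    dplyr::select("pop", "locus", "n", "Na", "Ne", "Ho", "He", "uHe",
                  "Np", "R", "g", "Fis")

  summary <- per |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(
      N = mean(.data$n), Na = mean(.data$Na), Ne = mean(.data$Ne),
      Ho = mean(.data$Ho), He = mean(.data$He), uHe = mean(.data$uHe),
      Np = mean(.data$Np), R = mean(.data$R, na.rm = TRUE),
      Fis = mean(.data$Fis, na.rm = TRUE), .groups = "drop")

  structure(list(by_locus = per, summary = summary),
            class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, ...) {
  cat("<diversity_table> across-locus means per population:\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.diversity_table <- function(x, ...) x$by_locus

#' @export
glance.diversity_table <- function(x, ...) x$summary

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `R = sum_i [1 - C(N - N_i, g) / C(N, g)]` with `N` typed copies
#' and `N_i` copies of allele i. Binomial coefficients are evaluated in
#' log space. By default `g` is, per locus, the smallest `N` across
#' populations, so values are comparable between populations.
#'
#' @param geno A [geno_tbl()].
#' @param g Rarefaction size in gene copies (>= 2), or `NULL` for the
#'   per-locus minimum.
#' @return A tibble `pop`, `locus`, `g`, `R`.
#' @export
rarefied_richness <- function(geno, g = NULL) {
  if (!is.null(g) && g < 2) stop("g must be >= 2", call. = FALSE)
  af <- allele_frequencies(geno)
  g_locus <- af |>
    dplyr::distinct(.data$pop, .data$locus, .data$n_copies) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(g_min = min(.data$n_copies), .groups = "drop")
  af <- dplyr::left_join(af, g_locus, by = "locus")
  af$g_use <- if (is.null(g)) af$g_min else as.integer(g)
  bad <- af$g_use > af$n_copies
  if (any(bad)) {
    warning("rarefaction size g exceeds typed copies for some pop x locus; ",
            "R set to NA there", call. = FALSE)
  }
  af$term <- ifelse(bad, NA_real_,
                    1 - exp(lchoose(af$n_copies - af$count, af$g_use) -
                              lchoose(af$n_copies, af$g_use)))
  af |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(g = .data$g_use[1], R = sum(.data$term),
                     .groups = "drop")
}
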