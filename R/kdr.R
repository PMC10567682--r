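#' The kdr haplotype alphabet
#'
#' Haplotypes of the voltage-gated sodium channel (Na_V) over the three
#' pyrethroid-resistance SNP sites V410L, V1016I and F1534C. The default
#' closed alphabet is the six arrangements observed in Brazilian *Aedes
#' aegypti*: the wild type S (VVF), the classical resistance alleles R1
#' (VVC, F1534C only) and R2 (LIC, triple mutant), and the rarer X1 (LVC),
#' X2 (LVF) and X3 (LIF). `kdr_alphabet(open = TRUE)` returns all eight
#' possible state triples for novel-genotype screening.
#'
#' @param open If `TRUE`, enumerate every possible triple rather than the
#'   six named field alleles.
#' @return A tibble with columns `allele`, `s410`, `s1016`, `s1534`.
#' @export
kdr_alphabet <- function(open = FALSE) {
  closed <- tibble::tribble(
    ~allele, ~s410, ~s1016, ~s1534,
    "S",  "V", "V", "F",
    "R1", "V", "V", "C",
    "R2", "L", "I", "C",
    "X1", "L", "V", "C",
    "X2", "L", "V", "F",
    "X3", "L", "I", "F")
  if (!open) return(closed)
  grid <- expand.grid(s410 = c("V", "L"), s1016 = c("V", "I"),
                      s1534 = c("F", "C"), stringsAsFactors = FALSE)
  key <- paste0(grid$s410, grid$s1016, grid$s1534)
  closed_key <- paste0(closed$s410, closed$s1016, closed$s1534)
  nm <- ifelse(key %in% closed_key,
               closed$allele[match(key, closed_key)], key)
  tibble::tibble(allele = nm, s410 = grid$s410, s1016 = grid$s1016,
                 s1534 = grid$s1534)
}

kdr_site_states <- list(g410 = c("V", "L"), g1016 = c("V", "I"),
                        g1534 = c("F", "C"))

# normalize a per-site diploid genotype string ("VL"/"LV" -> "LV" in the
# site's canonical state order wild-type first)
normalize_site_geno <- function(g, site) {
  states <- kdr_site_states[[site]]
  ch <- strsplit(toupper(trimws(g)), "")
  vapply(ch, function(x) {
    if (length(x) != 2 || !all(x %in% states)) {
      stop("invalid ", site, " genotype: '", paste(x, collapse = ""),
           "' (expected two of ", paste(states, collapse = "/"), ")",
           call. = FALSE)
    }
    paste(x[order(match(x, states))], collapse = "")
  }, "")
}

#' Decompose one tri-locus kdr genotype into haplotype pairs
#'
#' Finds every unordered pair of alphabet haplotypes whose site-wise union
#' reproduces the observed diploid genotypes at 410, 1016 and 1534.
#' Most genotypes decompose uniquely; the genotype LL + VI + FC is the
#' ambiguous class "Y" (R2/X2 or X1/X3), and genotypes with no consistent
#' pair in the alphabet are "UNRESOLVED".
#'
#' @param g410,g1016,g1534 Two-letter genotype strings, e.g. `"VL"`,
#'   `"VI"`, `"FC"` (order of the two letters is irrelevant).
#' @param alphabet A haplotype table from [kdr_alphabet()].
#' @return A list with elements `pairs` (list of sorted 2-vectors of allele
#'   names), `class`, and `ambiguous`.
#' @examples
#' kdr_decompose("VV", "VV", "FF")$class  # "SS"
#' kdr_decompose("LL", "VI", "FC")$pairs  # R2/X2 or X1/X3
#' @export
kdr_decompose <- function(g410, g1016, g1534, alphabet = kdr_alphabet()) {
  g <- c(normalize_site_geno(g410, "g410"),
         normalize_site_geno(g1016, "g1016"),
         normalize_site_geno(g1534, "g1534"))
  states <- as.matrix(alphabet[c("s410", "s1016", "s1534")])
  n <- nrow(alphabet)
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- TRUE
      for (s in 1:3) {
        combo <- sort_site(paste0(states[i, s], states[j, s]), s)
        if (combo != g[s]) { ok <- FALSE; break }
      }
      if (ok) {
        pairs[[length(pairs) + 1]] <- sort_alleles(
          c(alphabet$allele[i], alphabet$allele[j]), alphabet$allele)
      }
    }
  }
  class_label <- if (length(pairs) == 0) {
    "UNRESOLVED"
  } else if (length(pairs) == 1) {
    paste(pairs[[1]], collapse = "")
  } else if (identical(g, c("LL", "VI", "FC"))) {
    "Y"
  } else {
    "AMBIGUOUS"
  }
  list(pairs = pairs, class = class_label, ambiguous = length(pairs) > 1)
}

sort_site <- function(two, s) {
  states <- kdr_site_states[[s]]
  ch <- strsplit(two, "")[[1]]
  paste(ch[order(match(ch, states))], collapse = "")
}

sort_alleles <- function(pair, alphabet_order) {
  pair[order(match(pair, alphabet_order))]
}

#' Classify a table of kdr calls
#'
#' Decomposes every individual's tri-locus genotype. Calls with any missing
#' site are classed `MISSING` and excluded from all frequency denominators
#' downstream.
#'
#' @param calls A data frame with columns `id`, `pop`, `g410`, `g1016`,
#'   `g1534` (missing sites as `NA` or empty strings).
#' @param alphabet A haplotype table from [kdr_alphabet()].
#' @return A tibble of class `kdr_class_tbl`: the input columns plus
#'   `class`, `pairs` (list-column), `n_pairs`, `ambiguous`.
#' @export
kdr_classify <- function(calls, alphabet = kdr_alphabet()) {
  need <- c("id", "pop", "g410", "g1016", "g1534")
  if (!all(need %in% names(calls))) {
    stop("calls need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  calls <- tibble::as_tibble(calls)[need]
  is_missing <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  miss <- is_missing(calls$g410) | is_missing(calls$g1016) |
    is_missing(calls$g1534)
  dec <- purrr::pmap(list(calls$g410, calls$g1016, calls$g1534, miss),
                     function(a, b, c, m) {
                       if (m) return(list(pairs = list(), class = "MISSING",
                                          ambiguous = FALSE))
                       kdr_decompose(a, b, c, alphabet)
                     })
  out <- calls
  out$class <- vapply(dec, `[[`, "", "class")
  out$pairs <- purrr::map(dec, "pairs")
  out$n_pairs <- vapply(out$pairs, length, 1L)
  out$ambiguous <- vapply(dec, `[[`, TRUE, "ambiguous")
  class(out) <- c("kdr_class_tbl", class(tibble::tibble()))
  out
}

#' Genotype-class and allele frequencies for kdr calls
#'
#' Genotype-class frequencies are simple class counts over fully genotyped
#' individuals. For allele frequencies, unambiguous individuals contribute
#' their two haplotypes; ambiguous (Y) individuals are apportioned either
#' by `equal_split` (weight 1/2 per consistent pair, the conservative
#' default) or by `em`, which iterates expected pair weights proportional
#' to the Hardy-Weinberg probability of each pair under the current allele
#' frequencies until the largest frequency change is below `tol`.
#'
#' @param classified Output of [kdr_classify()], or a raw call table (it is
#'   classified on the fly).
#' @param method `"equal_split"` or `"em"`.
#' @param alphabet Haplotype alphabet (used when classifying raw calls).
#' @param tol EM convergence tolerance on allele frequencies.
#' @param max_iter EM iteration cap.
#' @return An object of class `kdr_freq` with tibbles `genotypes`
#'   (`pop`, `class`, `n`, `count`, `freq`), `alleles`
#'   (`pop`, `allele`, `freq`), an `ambiguous` audit table, and for the EM
#'   method per-population iteration counts and log-likelihood traces.
#' @export
kdr_frequencies <- function(classified, method = c("equal_split", "em"),
                            alphabet = kdr_alphabet(), tol = 1e-10,
                            max_iter = 10000) {
  method <- match.arg(method)
  if (!inherits(classified, "kdr_class_tbl")) {
    classified <- kdr_classify(classified, alphabet)
  }
  typed <- classified[classified$class != "MISSING", ]
  unresolved <- typed[typed$n_pairs == 0, ]
  usable <- typed[typed$n_pairs > 0, ]

  pops <- unique(classified$pop)
  n_typed <- table(factor(typed$pop, levels = pops))
  empty <- pops[n_typed == 0]
  if (length(empty) > 0) {
    stop("population(s) with no fully genotyped individual: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }

  genotypes <- typed |>
    dplyr::count(.data$pop, .data$class, name = "count") |>
    dplyr::group_by(.data$pop) |>
    dplyr::mutate(n = sum(.data$count), freq = .data$count / .data$n) |>
    dplyr::ungroup() |>
    dplyr::select("pop", "class", "n", "count", "freq")

  allele_levels <- alphabet$allele
  em_info <- list()
  alleles <- purrr::map_dfr(pops, function(p) {
    rows <- usable[usable$pop == p, ]
    res <- apportion_alleles(rows$pairs, allele_levels, method, tol, max_iter)
    if (method == "em") em_info[[p]] <<- res$info
    tibble::tibble(pop = p, allele = allele_levels, freq = res$freq)
  })

  structure(list(genotypes = genotypes, alleles = alleles,
                 ambiguous = typed[typed$ambiguous | typed$n_pairs == 0,
                                   c("id", "pop", "class", "n_pairs", "pairs")],
                 method = method, em = em_info,
                 n_unresolved = nrow(unresolved)),
            class = "kdr_freq")
}

# pair-list -> allele frequency vector over allele_levels
apportion_alleles <- function(pair_list, allele_levels, method, tol, max_iter) {
  k <- length(allele_levels)
  counts <- numeric(k)
  names(counts) <- allele_levels
  n_copies <- 2 * length(pair_list)
  if (n_copies == 0) {
    return(list(freq = rep(NA_real_, k), info = NULL))
  }
  fixed <- numeric(k); names(fixed) <- allele_levels
  amb <- list()
  for (prs in pair_list) {
    if (length(prs) == 1) {
      pair <- prs[[1]]
      fixed[pair[1]] <- fixed[pair[1]] + 1
      fixed[pair[2]] <- fixed[pair[2]] + 1
    } else {
      amb[[length(amb) + 1]] <- prs
    }
  }
  if (method == "equal_split" || length(amb) == 0) {
    w <- fixed
    for (prs in amb) {
      for (pair in prs) {
        w[pair[1]] <- w[pair[1]] + 1 / length(prs)
        w[pair[2]] <- w[pair[2]] + 1 / length(prs)
      }
    }
    return(list(freq = unname(w / n_copies),
                info = if (method == "em") list(iterations = 0L, loglik = numeric(0))))
  }
  # EM over the ambiguous individuals' pair mixtures
  freq <- fixed + 1e-6
  for (prs in amb) for (pair in prs) {
    freq[pair[1]] <- freq[pair[1]] + 1 / length(prs)
    freq[pair[2]] <- freq[pair[2]] + 1 / length(prs)
  }
  freq <- freq / sum(freq)
  ll_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- fixed
    ll <- 0
    for (pair in pair_list[vapply(pair_list, length, 1L) == 1]) {
      ll <- ll + log(pair_prob(pair[[1]], freq))
    }
    for (prs in amb) {
      pp <- vapply(prs, pair_prob, 0, freq = freq)
      tot <- sum(pp)
      ll <- ll + log(tot)
      wt <- if (tot > 0) pp / tot else rep(1 / length(prs), length(prs))
      for (j in seq_along(prs)) {
        w[prs[[j]][1]] <- w[prs[[j]][1]] + wt[j]
        w[prs[[j]][2]] <- w[prs[[j]][2]] + wt[j]
      }
    }
    new_freq <- w / n_copies
    ll_trace <- c(ll_trace, ll)
    delta <- max(abs(new_freq - freq))
    freq <- new_freq
    if (delta < tol || iter >= max_iter) break
  }
  list(freq = unname(freq),
       info = list(iterations = iter, loglik = ll_trace))
}

pair_prob <- function(pair, freq) {
  if (pair[1] == pair[2]) freq[[pair[1]]]^2 else 2 * freq[[pair[1]]] * freq[[pair[2]]]
}

#' @export
print.kdr_freq <- function(x, ...) {
  cat("<kdr_freq> allele apportioning method:", x$method, "\n")
  cat("Genotype-class frequencies:\n")
  print(x$genotypes)
  cat("Allele frequencies:\n")
  print(tidyr::pivot_wider(x$alleles, names_from = "allele",
                           values_from = "freq"))
  invisible(x)
}

#' @export
tidy.kdr_freq <- function(x, table = c("alleles", "genotypes"), ...) {
  table <- match.arg(table)
  x[[table]]
}
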