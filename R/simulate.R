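#' Simulation configuration for transect surveys
#'
#' Bundles every parameter of the Balding-Nichols admixture generator:
#' population layout, locus allele counts, number of ancestral clusters
#' `k_true` with drift parameter `f` (the expected divergence of each
#' cluster from the ancestral allele pool), the per-population admixture
#' matrix `q_true`, per-population kdr haplotype frequency vectors over
#' the closed alphabet, and nuisance rates for missing calls and null
#' alleles.
#'
#' @param pops Character vector of population names, in transect order.
#' @param n_per_pop Individuals per population (>= 2).
#' @param loci Named integer vector: alleles per locus.
#' @param k_true Number of ancestral clusters (>= 1).
#' @param f Balding-Nichols drift parameter in (0, 1).
#' @param q_true `length(pops) x k_true` matrix of admixture proportions,
#'   rows summing to 1. Default: linear interpolation along the transect
#'   between cluster-pure endpoints (and a uniform spread for `k_true > 2`).
#' @param kdr_freqs `length(pops) x 6` matrix of haplotype frequencies over
#'   `{S, R1, R2, X1, X2, X3}`, rows summing to 1. Default: uniform over
#'   S/R1/R2.
#' @param missing_rate Per-call probability of a missing microsatellite
#'   genotype.
#' @param null_allele_rate Frequency of a non-amplifying (null) allele
#'   segregating at every locus; heterozygous carriers type as apparent
#'   homozygotes and null homozygotes as missing.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A `sim_config` list.
#' @seealso [preset_amapa()], [simulate_msat()], [simulate_kdr()]
#' @export
sim_config <- function(pops = paste0("P", 1:6), n_per_pop = 45,
                       loci = setNames(rep(5L, 12), paste0("L", 1:12)),
                       k_true = 2, f = 0.07, q_true = NULL,
                       kdr_freqs = NULL, missing_rate = 0,
                       null_allele_rate = 0, seed = 1) {
  n_pops <- length(pops)
  if (n_per_pop < 2) stop("n_per_pop must be >= 2", call. = FALSE)
  if (k_true < 1) stop("k_true must be >= 1", call. = FALSE)
  if (!(f > 0 && f < 1)) stop("f must lie in (0, 1)", call. = FALSE)
  if (is.null(names(loci))) names(loci) <- paste0("L", seq_along(loci))
  if (any(loci < 2)) stop("every locus needs >= 2 possible alleles", call. = FALSE)

  if (is.null(q_true)) {
    t <- if (n_pops == 1) 0.5 else seq(0, 1, length.out = n_pops)
    q_true <- if (k_true == 1) {
      matrix(1, n_pops, 1)
    } else if (k_true == 2) {
      cbind(1 - t, t)
    } else {
      m <- vapply(seq_len(k_true), function(k) {
        stats::dnorm(t, mean = (k - 1) / (k_true - 1), sd = 0.35)
      }, numeric(n_pops))
      m / rowSums(m)
    }
  }
  q_true <- as.matrix(q_true)
  if (!all(dim(q_true) == c(n_pops, k_true))) {
    stop("q_true must be ", n_pops, " x ", k_true, call. = FALSE)
  }
  check_simplex(q_true, "q_true")

  kdr_names <- kdr_alphabet()$allele
  if (is.null(kdr_freqs)) {
    kdr_freqs <- matrix(rep(c(1 / 3, 1 / 3, 1 / 3, 0, 0, 0), each = n_pops),
                        n_pops, 6)
  }
  kdr_freqs <- as.matrix(kdr_freqs)
  if (!all(dim(kdr_freqs) == c(n_pops, 6))) {
    stop("kdr_freqs must be ", n_pops, " x 6", call. = FALSE)
  }
  colnames(kdr_freqs) <- kdr_names
  rownames(kdr_freqs) <- pops
  check_simplex(kdr_freqs, "kdr_freqs")
  stopifnot(missing_rate >= 0, missing_rate < 1,
            null_allele_rate >= 0, null_allele_rate < 1)

  structure(list(pops = pops, n_per_pop = as.integer(n_per_pop),
                 loci = loci, k_true = as.integer(k_true), f = f,
                 q_true = q_true, kdr_freqs = kdr_freqs,
                 missing_rate = missing_rate,
                 null_allele_rate = null_allele_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_simplex <- function(m, what) {
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop(what, " rows must be non-negative and sum to 1 (within 1e-12)",
         call. = FALSE)
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d pops x %d ind, %d loci (%d-%d alleles), K=%d, F=%.3f, seed=%d\n",
    length(x$pops), x$n_per_pop, length(x$loci), min(x$loci), max(x$loci),
    x$k_true, x$f, x$seed))
  invisible(x)
}

#' Six-population Amapá transect preset
#'
#' The default study-design emulation: six populations in south-to-north
#' transect order (MAC, PGR, FGO, TTZ, CAL, OIA), 45 individuals each, two
#' ancestral clusters with drift F = 0.07 and admixture proportions
#' interpolating linearly along the transect between cluster-pure
#' endpoints, 12 microsatellite loci carrying 60 alleles in total (2 to 17
#' per locus), a 3% missing-call rate, and per-population kdr haplotype
#' frequency vectors patterned on a gradient from R1-dominated in the
#' south to R2-dominated (with X1/X2/X3 segregating) in the north.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_amapa <- function(seed = 1, ...) {
  loci <- c(AC1 = 4L, AC2 = 4L, AC4 = 2L, AC5 = 4L, AG1 = 4L, AG2 = 17L,
            AG5 = 5L, CT2 = 5L, A1 = 5L, A9 = 4L, B2 = 2L, B3 = 4L)
  kdr <- rbind(
    MAC = c(S = 0.128, R1 = 0.779, R2 = 0.093, X1 = 0.000, X2 = 0.000, X3 = 0.000),
    PGR = c(S = 0.000, R1 = 0.550, R2 = 0.450, X1 = 0.000, X2 = 0.000, X3 = 0.000),
    FGO = c(S = 0.080, R1 = 0.490, R2 = 0.430, X1 = 0.000, X2 = 0.000, X3 = 0.000),
    TTZ = c(S = 0.060, R1 = 0.470, R2 = 0.470, X1 = 0.000, X2 = 0.000, X3 = 0.000),
    CAL = c(S = 0.050, R1 = 0.547, R2 = 0.359, X1 = 0.044, X2 = 0.000, X3 = 0.000),
    OIA = c(S = 0.050, R1 = 0.152, R2 = 0.522, X1 = 0.050, X2 = 0.113, X3 = 0.113))
  args <- list(pops = rownames(kdr), n_per_pop = 45, loci = loci,
               k_true = 2, f = 0.07, kdr_freqs = kdr, missing_rate = 0.03,
               null_allele_rate = 0, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a microsatellite dataset under the Balding-Nichols model
#'
#' For each locus an ancestral frequency vector is drawn from a symmetric
#' Dirichlet(1); each of the `k_true` clusters draws its own frequencies
#' from Dirichlet(`p_anc (1-F)/F`), so clusters diverge from the ancestral
#' pool by roughly Fst = F. Each allele copy of each individual first picks
#' a cluster of origin from its population's admixture vector, then an
#' allele from that cluster. Missing calls are masked at `missing_rate`;
#' when `null_allele_rate > 0` a null allele segregates at that frequency
#' at every locus (carriers type as apparent homozygotes, null homozygotes
#' as missing).
#'
#' @param config A [sim_config()].
#' @return A list of class `msat_sim`: `geno` (a [geno_tbl()]) and `truth`
#'   (ancestral and cluster allele frequencies, per-copy cluster origins,
#'   the admixture matrix used).
#' @export
simulate_msat <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pops <- length(config$pops)
  n <- config$n_per_pop
  loci <- config$loci
  K <- config$k_true

  ids <- unlist(lapply(config$pops, function(p) sprintf("%s_%03d", p, seq_len(n))))
  pop_of <- rep(config$pops, each = n)
  pop_idx <- rep(seq_len(n_pops), each = n)
  N <- length(ids)

  p_anc <- lapply(loci, function(J) rdirichlet1(rep(1, J)))
  scale <- (1 - config$f) / config$f
  p_clust <- lapply(p_anc, function(pa) {
    t(vapply(seq_len(K), function(k) rdirichlet1(pa * scale), numeric(length(pa))))
  })

  rows <- vector("list", length(loci))
  origins <- array(NA_integer_, c(N, length(loci), 2))
  for (l in seq_along(loci)) {
    P <- p_clust[[l]]                      # K x J
    z1 <- sample_cat_rows(config$q_true[pop_idx, , drop = FALSE])
    z2 <- sample_cat_rows(config$q_true[pop_idx, , drop = FALSE])
    a1 <- sample_cat_rows(P[z1, , drop = FALSE])
    a2 <- sample_cat_rows(P[z2, , drop = FALSE])
    origins[, l, 1] <- z1
    origins[, l, 2] <- z2

    if (config$null_allele_rate > 0) {
      null1 <- runif(N) < config$null_allele_rate
      null2 <- runif(N) < config$null_allele_rate
      both <- null1 & null2
      a1[null1 & !both] <- a2[null1 & !both]   # carrier -> apparent homozygote
      a2[null2 & !both] <- a1[null2 & !both]
      a1[both] <- NA_integer_
      a2[both] <- NA_integer_
    }
    if (config$missing_rate > 0) {
      drop <- runif(N) < config$missing_rate
      a1[drop] <- NA_integer_
      a2[drop] <- NA_integer_
    }
    rows[[l]] <- tibble::tibble(id = ids, pop = pop_of,
                                locus = names(loci)[l],
                                a1 = as.integer(a1), a2 = as.integer(a2))
  }
  geno <- geno_tbl(dplyr::arrange(dplyr::bind_rows(rows),
                                  match(.data$id, ids), match(.data$locus, names(loci))))
  truth <- list(p_ancestral = p_anc, p_cluster = p_clust,
                origins = origins, q_true = config$q_true,
                pops = config$pops, ids = ids)
  structure(list(geno = geno, truth = truth, config = config),
            class = "msat_sim")
}

# one categorical draw per row of a probability matrix
sample_cat_rows <- function(prob) {
  cum <- prob %*% upper.tri(diag(ncol(prob)), diag = TRUE)
  u <- runif(nrow(prob)) * cum[, ncol(prob)]
  as.integer(rowSums(u > cum) + 1L)
}

#' Simulate tri-locus kdr calls
#'
#' Each individual draws an unordered haplotype pair under Hardy-Weinberg
#' proportions from its population's kdr frequency vector; the pair is
#' translated deterministically to diploid site genotypes through the
#' haplotype table (S=VVF, R1=VVC, R2=LIC, X1=LVC, X2=LVF, X3=LIF).
#'
#' @param config A [sim_config()].
#' @return A list of class `kdr_sim`: `calls` (tibble `id`, `pop`, `g410`,
#'   `g1016`, `g1534`) and `truth` (the drawn haplotype pair per
#'   individual).
#' @export
simulate_kdr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 500009L)
  alphabet <- kdr_alphabet()
  n <- config$n_per_pop
  rows <- lapply(seq_along(config$pops), function(pi) {
    p <- config$pops[pi]
    freqs <- config$kdr_freqs[pi, ]
    h1 <- sample(alphabet$allele, n, replace = TRUE, prob = freqs)
    h2 <- sample(alphabet$allele, n, replace = TRUE, prob = freqs)
    i1 <- match(h1, alphabet$allele)
    i2 <- match(h2, alphabet$allele)
    tibble::tibble(
      id = sprintf("%s_%03d", p, seq_len(n)), pop = p,
      g410 = paste0(alphabet$s410[i1], alphabet$s410[i2]),
      g1016 = paste0(alphabet$s1016[i1], alphabet$s1016[i2]),
      g1534 = paste0(alphabet$s1534[i1], alphabet$s1534[i2]),
      true_pair = purrr::map2(h1, h2, function(a, b)
        sort_alleles(c(a, b), alphabet$allele)))
  })
  all <- dplyr::bind_rows(rows)
  # canonical per-site genotype strings (wild-type letter first)
  all$g410 <- normalize_site_geno(all$g410, "g410")
  all$g1016 <- normalize_site_geno(all$g1016, "g1016")
  all$g1534 <- normalize_site_geno(all$g1534, "g1534")
  structure(list(calls = all[c("id", "pop", "g410", "g1016", "g1534")],
                 truth = all[c("id", "pop", "true_pair")],
                 config = config),
            class = "kdr_sim")
}
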