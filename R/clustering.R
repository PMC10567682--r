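# encode a geno_tbl as the integer matrix the Gibbs sampler consumes
encode_geno <- function(geno) {
  loci <- locus_names(geno)
  roster <- geno_individuals(geno)
  allele_sets <- lapply(loci, function(l) {
    d <- geno[geno$locus == l, ]
    sort(unique(c(d$a1, d$a2)))
  })
  names(allele_sets) <- loci
  G <- matrix(-1L, nrow(roster), 2 * length(loci))
  df <- tibble::as_tibble(geno)
  row_of <- setNames(seq_len(nrow(roster)), roster$id)
  for (l in seq_along(loci)) {
    d <- df[df$locus == loci[l], ]
    r <- row_of[d$id]
    G[r, 2 * l - 1] <- match(d$a1, allele_sets[[l]]) - 1L
    G[r, 2 * l] <- match(d$a2, allele_sets[[l]]) - 1L
  }
  G[is.na(G)] <- -1L
  list(G = G, J = vapply(allele_sets, length, 1L), roster = roster,
       allele_sets = allele_sets)
}

#' Bayesian admixture clustering by Gibbs sampling
#'
#' Fits the admixture model with independent allele frequencies: each
#' individual owns ancestry proportions `q` over `K` clusters and each
#' allele copy originates from one cluster. A Gibbs sweep (i) samples each
#' copy's cluster of origin, (ii) resamples cluster allele frequencies
#' from Dirichlet(`lambda` + counts), and (iii) resamples each `q` from
#' Dirichlet(`alpha` + origin counts). `Q` is the posterior mean over
#' post-burn-in sweeps, and the model evidence is approximated as
#' `ln P(X|K) = mean(L) - var(L)/2` over the post-burn-in trace of the
#' observed-data log-likelihood.
#'
#' @param geno A [geno_tbl()].
#' @param k Number of clusters (>= 1).
#' @param sweeps Gibbs sweeps (>= 100).
#' @param burn_in Fraction of initial sweeps discarded.
#' @param alpha Dirichlet prior on ancestry proportions.
#' @param lambda Dirichlet prior on allele frequencies.
#' @param seed Seed (required for reproducibility; defaults to a random
#'   draw from the session RNG).
#' @return An `admixture_run`: `Q` (individuals x K matrix), `p_cluster`
#'   (per-locus K x alleles matrices), `trace`, `ln_pk`, plus settings.
#' @export
admixture_mcmc <- function(geno, k, sweeps = 2000, burn_in = 0.2,
                           alpha = 1, lambda = 1, seed = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (sweeps < 100) stop("sweeps must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_geno(geno)
  burn <- as.integer(floor(sweeps * burn_in))
  fit <- admixture_gibbs_cpp(enc$G, enc$J, as.integer(k),
                             as.integer(sweeps), burn, alpha, lambda)
  rownames(fit$Q) <- enc$roster$id
  post <- fit$trace[(burn + 1):sweeps]
  ln_pk <- mean(post) - stats::var(post) / 2
  structure(list(Q = fit$Q, p_cluster = fit$P, trace = fit$trace,
                 ln_pk = ln_pk, k = k, sweeps = sweeps, burn_in = burn_in,
                 alpha = alpha, lambda = lambda, seed = seed,
                 roster = enc$roster),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("<admixture_run> K=%d, %d sweeps (%.0f%% burn-in), ln P(X|K)=%.1f\n",
              x$k, x$sweeps, 100 * x$burn_in, x$ln_pk))
  invisible(x)
}

#' @export
tidy.admixture_run <- function(x, ...) {
  q <- tibble::as_tibble(x$Q, .name_repair = ~ paste0("cluster", seq_along(.x)))
  dplyr::bind_cols(x$roster, q) |>
    tidyr::pivot_longer(dplyr::starts_with("cluster"),
                        names_to = "cluster", values_to = "q")
}

#' Replicate admixture runs over a range of K
#'
#' @param geno A [geno_tbl()].
#' @param k_range Integer vector of K values (consecutive for
#'   [evanno_delta_k()]).
#' @param n_reps Replicate runs per K.
#' @param seed Base seed; run `r` at `K` uses `seed + 1000*K + r`.
#' @param ... Passed to [admixture_mcmc()].
#' @return An `admixture_scan`: list of runs plus a summary tibble.
#' @export
admixture_replicates <- function(geno, k_range = 1:5, n_reps = 10,
                                 seed = 1, ...) {
  runs <- list()
  for (k in k_range) {
    runs[[as.character(k)]] <- lapply(seq_len(n_reps), function(r) {
      admixture_mcmc(geno, k = k, seed = seed + 1000L * k + r, ...)
    })
  }
  summary <- purrr::map_dfr(names(runs), function(kname) {
    tibble::tibble(k = as.integer(kname),
                   rep = seq_along(runs[[kname]]),
                   ln_pk = vapply(runs[[kname]], `[[`, 0, "ln_pk"))
  })
  structure(list(runs = runs, summary = summary, k_range = k_range,
                 n_reps = n_reps, seed = seed),
            class = "admixture_scan")
}

#' @export
print.admixture_scan <- function(x, ...) {
  cat("<admixture_scan>\n")
  print(x$summary |>
          dplyr::group_by(.data$k) |>
          dplyr::summarise(mean_ln_pk = mean(.data$ln_pk),
                           sd_ln_pk = sd(.data$ln_pk), .groups = "drop"))
  invisible(x)
}

#' Evanno delta-K cluster-number selection
#'
#' From replicate runs across consecutive K, computes per K the mean and
#' standard deviation of `ln P(X|K)` and, for interior K,
#' `delta_K = |mean L(K-1) - 2 mean L(K) + mean L(K+1)| / sd(L(K))`.
#' The selected K is the argmax of delta-K.
#'
#' @param scan An `admixture_scan` (or its summary tibble with columns
#'   `k`, `rep`, `ln_pk`).
#' @return A `delta_k_table` tibble `k`, `n_reps`, `mean_ln_pk`,
#'   `sd_ln_pk`, `delta_k` with attribute `selected_k`.
#' @export
evanno_delta_k <- function(scan) {
  summary <- if (inherits(scan, "admixture_scan")) scan$summary else
    tibble::as_tibble(scan)
  stats <- summary |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     mean_ln_pk = mean(.data$ln_pk),
                     sd_ln_pk = sd(.data$ln_pk), .groups = "drop") |>
    dplyr::arrange(.data$k)
  if (nrow(stats) < 3 || any(diff(stats$k) != 1)) {
    stop("evanno_delta_k needs >= 3 consecutive K values", call. = FALSE)
  }
  if (any(stats$n_reps < 2)) {
    stop("evanno_delta_k needs >= 2 replicates per K", call. = FALSE)
  }
  m <- stats$mean_ln_pk
  n <- nrow(stats)
  dk <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    s <- stats$sd_ln_pk[i]
    dk[i] <- if (is.na(s) || s == 0) NA_real_ else
      abs(m[i - 1] - 2 * m[i] + m[i + 1]) / s
  }
  stats$delta_k <- dk
  sel <- if (all(is.na(dk))) NA_integer_ else stats$k[which.max(dk)]
  structure(stats, selected_k = sel,
            class = c("delta_k_table", class(stats)))
}

#' @export
print.delta_k_table <- function(x, ...) {
  cat("<delta_k_table> selected K =", attr(x, "selected_k"), "\n")
  NextMethod()
}

#' Selected cluster number of a delta-K table
#' @param dk A `delta_k_table`.
#' @return Integer K.
#' @export
selected_k <- function(dk) attr(dk, "selected_k")

# G-similarity between two Q matrices: 1 - ||A - B||_F / sqrt(2N)
q_similarity <- function(a, b) {
  1 - sqrt(sum((a - b)^2)) / sqrt(2 * nrow(a))
}

#' Align replicate runs at the same K (label switching)
#'
#' Cluster labels are arbitrary across runs. For `K <= 8` every column
#' permutation is tried against the reference run, keeping the one that
#' maximizes the G-similarity `1 - ||A - B||_F / sqrt(2N)`; for larger K
#' a greedy column assignment is used. The consensus is the element-wise
#' mean of the aligned Q matrices.
#'
#' @param runs List of `admixture_run`s (or Q matrices) at the same K.
#' @param reference Index of the reference run.
#' @return A list: `Q_aligned` (list of matrices), `consensus`,
#'   `similarity` (each run vs the reference after alignment),
#'   `permutations` used.
#' @export
align_runs <- function(runs, reference = 1) {
  qs <- lapply(runs, function(r) if (inherits(r, "admixture_run")) r$Q else as.matrix(r))
  K <- unique(vapply(qs, ncol, 1L))
  if (length(K) != 1) stop("runs have differing K", call. = FALSE)
  ref <- qs[[reference]]
  perms <- list()
  aligned <- vector("list", length(qs))
  sim <- numeric(length(qs))
  for (i in seq_along(qs)) {
    if (K <= 8) {
      best <- NULL; best_sim <- -Inf
      for (pm in all_permutations(K)) {
        s <- q_similarity(ref, qs[[i]][, pm, drop = FALSE])
        if (s > best_sim) { best_sim <- s; best <- pm }
      }
    } else {
      # greedy: repeatedly match the closest (ref column, run column) pair
      cost <- vapply(seq_len(K), function(j)
        vapply(seq_len(K), function(l) sum((ref[, j] - qs[[i]][, l])^2), 0),
        numeric(K))  # cost[l, j]
      best <- integer(K)
      free_l <- seq_len(K); free_j <- seq_len(K)
      while (length(free_j) > 0) {
        idx <- which(cost[free_l, free_j, drop = FALSE] ==
                       min(cost[free_l, free_j]), arr.ind = TRUE)[1, ]
        l <- free_l[idx[1]]; j <- free_j[idx[2]]
        best[j] <- l
        free_l <- setdiff(free_l, l); free_j <- setdiff(free_j, j)
      }
      best_sim <- q_similarity(ref, qs[[i]][, best, drop = FALSE])
    }
    perms[[i]] <- best
    aligned[[i]] <- qs[[i]][, best, drop = FALSE]
    sim[i] <- best_sim
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  list(Q_aligned = aligned, consensus = consensus, similarity = sim,
       permutations = perms)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (sub in all_permutations(k - 1)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1]] <- c(i, rest[sub])
    }
  }
  out
}

# ---- DAPC -----------------------------------------------------------------

#' Allele dosage matrix
#'
#' Encodes genotypes as an individuals x alleles matrix of dosages (0, 0.5
#' or 1 = copies/2). Missing calls are imputed with the group mean (the
#' overall mean when a group is entirely untyped).
#'
#' @param geno A [geno_tbl()].
#' @param groups Factor of group labels per individual (default:
#'   population).
#' @return A numeric matrix with rownames = individual ids.
#' @export
dosage_matrix <- function(geno, groups = NULL) {
  enc <- encode_geno(geno)
  roster <- enc$roster
  if (is.null(groups)) groups <- roster$pop
  cols <- list()
  for (l in seq_along(enc$J)) {
    J <- enc$J[l]
    a1 <- enc$G[, 2 * l - 1]; a2 <- enc$G[, 2 * l]
    m <- matrix(NA_real_, nrow(roster), J)
    typed <- a1 >= 0
    for (j in seq_len(J)) {
      m[typed, j] <- ((a1[typed] == j - 1) + (a2[typed] == j - 1)) / 2
    }
    colnames(m) <- paste0(names(enc$J)[l], ".", enc$allele_sets[[l]])
    cols[[l]] <- m
  }
  X <- do.call(cbind, cols)
  rownames(X) <- roster$id
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (!any(miss)) next
    gm <- tapply(X[, j], groups, mean, na.rm = TRUE)
    gm[is.nan(gm)] <- mean(X[, j], na.rm = TRUE)
    X[miss, j] <- gm[as.character(groups[miss])]
  }
  X
}

#' Discriminant analysis of principal components
#'
#' Genotypes are encoded as allele dosages, column-centred (optionally
#' scaled), reduced by PCA, and the retained components are fed to a
#' linear discriminant analysis on the group labels. Group membership
#' probabilities come from Gaussian densities in discriminant space with a
#' pooled covariance (the standard LDA posterior).
#'
#' @param geno A [geno_tbl()].
#' @param groups Group labels per individual (default: population).
#' @param n_pca Retained principal components; default: smallest number
#'   explaining >= 90% of the variance. Must be < number of individuals.
#' @param n_da Retained discriminant functions (<= groups - 1).
#' @param scale Scale dosage columns to unit variance?
#' @return A `dapc_fit`: individual coordinates, eigenvalues, posterior
#'   memberships, assignments, and the variance explained by the retained
#'   PCs.
#' @export
dapc <- function(geno, groups = NULL, n_pca = NULL, n_da = NULL,
                 scale = FALSE) {
  roster <- geno_individuals(geno)
  if (is.null(groups)) groups <- roster$pop
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 members", call. = FALSE)
  X <- dosage_matrix(geno, groups)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  var_expl <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  if (is.null(n_pca)) n_pca <- which(var_expl >= 0.9)[1]
  if (n_pca >= nrow(X)) {
    stop("n_pca must be smaller than the number of individuals", call. = FALSE)
  }
  n_pca <- min(n_pca, sum(pc$sdev > 1e-8))
  scores <- pc$x[, seq_len(n_pca), drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups)
  max_da <- length(levels(groups)) - 1
  if (is.null(n_da)) n_da <- max_da
  n_da <- min(n_da, max_da, ncol(fit$scaling))
  pred <- stats::predict(fit, scores)
  coord <- pred$x[, seq_len(n_da), drop = FALSE]
  structure(list(
    ind_coord = dplyr::bind_cols(
      roster, tibble::as_tibble(coord), group = as.character(groups)),
    posterior = dplyr::bind_cols(roster, tibble::as_tibble(pred$posterior)),
    assign = as.character(pred$class),
    eig = fit$svd[seq_len(n_da)]^2,
    pca_var_explained = var_expl[n_pca],
    n_pca = n_pca, n_da = n_da, groups = groups, lda = fit),
    class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf("<dapc_fit> %d PCs (%.1f%% variance), %d discriminant functions\n",
              x$n_pca, 100 * x$pca_var_explained, x$n_da))
  tab <- table(x$groups, factor(x$assign, levels = levels(x$groups)))
  cat(sprintf("reassignment rate: %.1f%%\n", 100 * sum(diag(tab)) / sum(tab)))
  invisible(x)
}

#' @export
tidy.dapc_fit <- function(x, ...) tibble::as_tibble(x$ind_coord)

#' @export
glance.dapc_fit <- function(x, ...) {
  tab <- table(x$groups, factor(x$assign, levels = levels(x$groups)))
  tibble::tibble(n_pca = x$n_pca, n_da = x$n_da,
                 pca_var_explained = x$pca_var_explained,
                 reassignment = sum(diag(tab)) / sum(tab))
}
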