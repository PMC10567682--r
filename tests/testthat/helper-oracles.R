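# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, direct formula transcriptions,
# exhaustive enumeration.

# Build a geno_tbl from a compact per-individual list:
# list(P1 = list(c(1,1), c(1,2)), ...) for a single locus, or a data frame.
make_geno <- function(pop_genotypes, locus = "L1") {
  rows <- list()
  i <- 0
  for (p in names(pop_genotypes)) {
    for (g in pop_genotypes[[p]]) {
      i <- i + 1
      rows[[i]] <- data.frame(id = sprintf("i%03d", i), pop = p,
                              locus = locus, a1 = g[1], a2 = g[2])
    }
  }
  geno_tbl(do.call(rbind, rows))
}

# random multi-locus dataset (no structure) for property tests
random_geno <- function(n_pops = 2, n_ind = 5, n_loci = 3, n_alleles = 3,
                        missing_rate = 0) {
  rows <- expand.grid(ind = seq_len(n_ind), pop = paste0("P", seq_len(n_pops)),
                      locus = paste0("L", seq_len(n_loci)),
                      stringsAsFactors = FALSE)
  rows$id <- paste0(rows$pop, "_", rows$ind)
  rows$a1 <- sample(n_alleles, nrow(rows), replace = TRUE)
  rows$a2 <- sample(n_alleles, nrow(rows), replace = TRUE)
  if (missing_rate > 0) {
    drop <- runif(nrow(rows)) < missing_rate
    rows$a1[drop] <- NA
    rows$a2[drop] <- NA
  }
  geno_tbl(rows[c("id", "pop", "locus", "a1", "a2")])
}

# --- Weir & Cockerham (1984) components, direct transcription ------------
# theta over all loci/alleles of a geno_tbl, written as plain loops.
oracle_wc_theta <- function(geno, pops = unique(geno$pop)) {
  num <- 0
  den <- 0
  for (loc in unique(geno$locus)) {
    d <- geno[geno$locus == loc & !is.na(geno$a1) & geno$pop %in% pops, ]
    if (nrow(d) == 0) next
    present <- unique(d$pop)
    if (length(present) < 2) next
    alleles <- sort(unique(c(d$a1, d$a2)))
    if (length(alleles) < 2) next
    r <- length(present)
    n <- sapply(present, function(p) sum(d$pop == p))
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    for (A in alleles) {
      p_i <- sapply(present, function(p) {
        dd <- d[d$pop == p, ]
        (sum(dd$a1 == A) + sum(dd$a2 == A)) / (2 * nrow(dd))
      })
      h_i <- sapply(present, function(p) {
        dd <- d[d$pop == p, ]
        mean((dd$a1 == A) != (dd$a2 == A))
      })
      pbar <- sum(n * p_i) / (r * nbar)
      s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      if (all(is.finite(c(a, b, cc)))) {
        num <- num + a
        den <- den + a + b + cc
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# --- rarefaction by exhaustive subset enumeration --------------------------
oracle_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subsets <- combn(length(copies), g)
  mean(apply(subsets, 2, function(ix) length(unique(copies[ix]))))
}

# --- kdr: brute force over all unordered alphabet pairs --------------------
oracle_kdr_pairs <- function(g410, g1016, g1534, alphabet = kdr_alphabet()) {
  sort_two <- function(x, ord) paste(sort(factor(strsplit(x, "")[[1]],
                                                 levels = ord)), collapse = "")
  target <- c(sort_two(g410, c("V", "L")), sort_two(g1016, c("V", "I")),
              sort_two(g1534, c("F", "C")))
  hits <- list()
  n <- nrow(alphabet)
  for (i in seq_len(n)) for (j in i:n) {
    got <- c(sort_two(paste0(alphabet$s410[i], alphabet$s410[j]), c("V", "L")),
             sort_two(paste0(alphabet$s1016[i], alphabet$s1016[j]), c("V", "I")),
             sort_two(paste0(alphabet$s1534[i], alphabet$s1534[j]), c("F", "C")))
    if (identical(got, target)) {
      hits[[length(hits) + 1]] <- c(alphabet$allele[i], alphabet$allele[j])
    }
  }
  hits
}

# --- AMOVA sums of squares by direct pair enumeration ----------------------
# one locus; distance between allele copies = 0/1; SS_group = mean over
# copies of pairwise distances / group size, straight from the definition
oracle_amova_ss <- function(geno, locus) {
  d <- geno[geno$locus == locus & !is.na(geno$a1), ]
  ss_pairs <- function(copies) {
    m <- length(copies)
    if (m < 2) return(0)
    tot <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m) tot <- tot + (copies[i] != copies[j])
    tot / m
  }
  all_copies <- c(d$a1, d$a2)
  sst <- ss_pairs(all_copies)
  ssp <- sum(sapply(unique(d$pop), function(p) {
    dd <- d[d$pop == p, ]
    ss_pairs(c(dd$a1, dd$a2))
  }))
  ssi <- sum(sapply(seq_len(nrow(d)), function(i) ss_pairs(c(d$a1[i], d$a2[i]))))
  c(ssa = sst - ssp, ssb = ssp - ssi, ssw = ssi, sst = sst)
}

# 27 possible tri-locus kdr calls
all_kdr_calls <- function() {
  expand.grid(g410 = c("VV", "VL", "LL"), g1016 = c("VV", "VI", "II"),
              g1534 = c("FF", "FC", "CC"), stringsAsFactors = FALSE)
}
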