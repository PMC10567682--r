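#' Long-format codominant genotype table
#'
#' The substrate of all microsatellite statistics in popkdr is a tidy,
#' long-format tibble with one row per individual x locus call:
#' columns `id`, `pop`, `locus`, `a1`, `a2`. Alleles are positive integer
#' codes stored in canonical (ascending) order; a missing call has `NA` in
#' both allele columns. Every individual carries exactly one population
#' label.
#'
#' @param df A data frame with columns `id`, `pop`, `locus`, `a1`, `a2`.
#' @return A tibble of class `geno_tbl` with canonically ordered alleles.
#' @examples
#' g <- geno_tbl(data.frame(
#'   id = c("i1", "i1", "i2", "i2"), pop = "P1",
#'   locus = c("L1", "L2", "L1", "L2"),
#'   a1 = c(2L, 1L, 1L, NA), a2 = c(1L, 1L, 2L, NA)
#' ))
#' g
#' @export
geno_tbl <- function(df) {
  required <- c("id", "pop", "locus", "a1", "a2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("geno_tbl requires columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)[required]
  out$id <- as.character(out$id)
  out$pop <- as.character(out$pop)
  out$locus <- as.character(out$locus)
  out$a1 <- as.integer(out$a1)
  out$a2 <- as.integer(out$a2)

  half <- xor(is.na(out$a1), is.na(out$a2))
  if (any(half)) {
    out$a1[half] <- NA_integer_
    out$a2[half] <- NA_integer_
  }
  ok <- !is.na(out$a1)
  if (any(out$a1[ok] < 1L) || any(out$a2[ok] < 1L)) {
    stop("allele codes must be >= 1 (0 is reserved for missing)", call. = FALSE)
  }
  # canonical unordered storage: ascending
  swap <- ok & out$a1 > out$a2
  if (any(swap)) {
    tmp <- out$a1[swap]
    out$a1[swap] <- out$a2[swap]
    out$a2[swap] <- tmp
  }
  pop_per_id <- tapply(out$pop, out$id, function(p) length(unique(p)))
  if (any(pop_per_id > 1)) {
    stop("individual(s) with more than one population label: ",
         paste(names(pop_per_id)[pop_per_id > 1], collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("geno_tbl", class(tibble::tibble()))
  out
}

#' @export
print.geno_tbl <- function(x, ...) {
  n_ind <- length(unique(x$id))
  n_pop <- length(unique(x$pop))
  n_loc <- length(unique(x$locus))
  miss <- mean(is.na(x$a1))
  cat(sprintf(
    "<geno_tbl> %d individuals, %d populations, %d loci, %.1f%% missing calls\n",
    n_ind, n_pop, n_loc, 100 * miss))
  NextMethod()
}

locus_names <- function(geno) unique(geno$locus)

pop_names <- function(geno) unique(geno$pop)

#' Individual roster of a genotype table
#'
#' @param geno A [geno_tbl()].
#' @return A tibble with one row per individual (`id`, `pop`), in order of
#'   first appearance.
#' @export
geno_individuals <- function(geno) {
  dplyr::distinct(tibble::as_tibble(geno)[c("id", "pop")])
}
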