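#' Read a GENEPOP text file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per line
#' (or a single comma-separated line), population blocks delimited by lines
#' equal to `Pop` (case-insensitive), and individual records
#' `ID , g1 g2 ...` where each diploid genotype is coded with 2 or 3 digits
#' per allele (`0101` or `001001`). An allele code of `00`/`000` marks a
#' missing allele; a call with any missing allele is stored as missing.
#'
#' The allele-code width (4 or 6 characters per genotype) is auto-detected
#' and must be consistent across the whole file; mixed widths are a fatal
#' format error rather than a guess. GENEPOP has no explicit population
#' names, so each block is labelled by the ID of its last individual unless
#' `pop_names` supplies one label per block.
#'
#' @param path Path to a GENEPOP file.
#' @param pop_names Optional character vector, one label per `Pop` block.
#' @return A [geno_tbl()].
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) {
    stop("GENEPOP file too short: ", path, call. = FALSE)
  }
  is_pop <- tolower(trimws(lines)) == "pop"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' line found in ", path, call. = FALSE)
  if (first_pop < 3) stop("no locus names before first 'Pop' line", call. = FALSE)

  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicated locus names", call. = FALSE)
  n_loci <- length(loci)

  pop_starts <- which(is_pop)
  n_blocks <- length(pop_starts)
  if (!is.null(pop_names) && length(pop_names) != n_blocks) {
    stop("pop_names has length ", length(pop_names),
         " but file has ", n_blocks, " Pop blocks", call. = FALSE)
  }

  block_of <- rep(NA_integer_, length(lines))
  for (b in seq_len(n_blocks)) {
    end <- if (b < n_blocks) pop_starts[b + 1] - 1 else length(lines)
    if (pop_starts[b] + 1 > end) next
    block_of[(pop_starts[b] + 1):end] <- b
  }

  rows <- list()
  width <- NA_integer_  # characters per diploid genotype, file-wide
  block_ids <- vector("list", n_blocks)
  for (i in seq_along(lines)) {
    b <- block_of[i]
    if (is.na(b) || !nzchar(trimws(lines[i]))) next
    line <- lines[i]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) {
      stop("line ", i, ": individual record without ',' separator", call. = FALSE)
    }
    id <- trimws(substr(line, 1, comma - 1))
    codes <- strsplit(trimws(substr(line, comma + 1, nchar(line))), "[ \t]+")[[1]]
    codes <- codes[nzchar(codes)]
    if (length(codes) != n_loci) {
      stop("line ", i, ": expected ", n_loci, " genotypes, found ",
           length(codes), call. = FALSE)
    }
    w <- unique(nchar(codes))
    if (length(w) != 1 || !(w %in% c(4L, 6L)) || any(!grepl("^[0-9]+$", codes))) {
      stop("line ", i, ": genotype codes must all be 4 or 6 digits", call. = FALSE)
    }
    if (is.na(width)) {
      width <- w
    } else if (w != width) {
      stop("line ", i, ": inconsistent genotype-code width (", w,
           " vs ", width, " characters)", call. = FALSE)
    }
    aw <- width / 2L
    a1 <- as.integer(substr(codes, 1, aw))
    a2 <- as.integer(substr(codes, aw + 1, width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    block_ids[[b]] <- c(block_ids[[b]], id)
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = id, block = b, locus = loci, a1 = a1, a2 = a2)
  }

  empty <- which(vapply(block_ids, length, 1L) == 0L)
  if (length(empty) > 0) {
    stop("empty Pop block(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  labels <- if (is.null(pop_names)) {
    vapply(block_ids, function(ids) ids[length(ids)], "")
  } else {
    as.character(pop_names)
  }
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }

  out <- dplyr::bind_rows(rows)
  out$pop <- labels[out$block]
  out$block <- NULL
  # disambiguate repeated IDs (common when files label every line with the
  # population name): individuals are rows, not ID strings
  key <- out$id
  per_ind <- table(key) / n_loci
  if (any(per_ind > 1)) {
    reps <- ave(seq_along(key), key, FUN = function(ix) rep(seq_len(length(ix) / n_loci), each = n_loci))
    dup_keys <- names(per_ind)[per_ind > 1]
    fix <- key %in% dup_keys
    out$id[fix] <- paste0(out$id[fix], "_", reps[fix])
  }
  geno_tbl(out[c("id", "pop", "locus", "a1", "a2")])
}

#' Write a GENEPOP text file
#'
#' Emits a file that [read_genepop()] parses back to an identical
#' [geno_tbl()] (byte-stable for a fixed `allele_width` and row ordering).
#' Missing calls are written as zero-coded alleles.
#'
#' @param geno A [geno_tbl()].
#' @param path Output path.
#' @param allele_width Digits per allele (2 or 3).
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, allele_width = 2,
                          title = "popkdr genotypes") {
  stopifnot(inherits(geno, "geno_tbl"))
  allele_width <- as.integer(allele_width)
  if (!allele_width %in% c(2L, 3L)) {
    stop("allele_width must be 2 or 3", call. = FALSE)
  }
  loci <- locus_names(geno)
  if (length(loci) == 0) stop("GENEPOP requires at least one locus", call. = FALSE)
  max_code <- suppressWarnings(max(geno$a2, na.rm = TRUE))
  if (is.finite(max_code) && max_code >= 10^allele_width) {
    stop("allele code ", max_code, " does not fit in ", allele_width,
         " digits", call. = FALSE)
  }

  wide <- tidyr::pivot_wider(
    tibble::as_tibble(geno),
    id_cols = c("id", "pop"), names_from = "locus",
    values_from = c("a1", "a2"))
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    sprintf(paste0("%0", allele_width, "d"), a)
  }
  code <- vapply(loci, function(l) {
    paste0(fmt(wide[[paste0("a1_", l)]]), fmt(wide[[paste0("a2_", l)]]))
  }, character(nrow(wide)))
  if (is.null(dim(code))) code <- matrix(code, nrow = 1)

  out <- c(title, loci)
  for (p in unique(wide$pop)) {
    sel <- which(wide$pop == p)
    out <- c(out, "Pop",
             paste0(wide$id[sel], " , ",
                    apply(code[sel, , drop = FALSE], 1, paste, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
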