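#' Parse degree-minute-second coordinate strings
#'
#' Converts strings like `03°49′53″N` or `51°50′07'' W` to signed
#' decimal degrees (`deg + min/60 + sec/3600`, negative for S and W).
#' Tolerates the typographic variation found in published tables: straight
#' or curly primes, doubled apostrophes, stray spaces, and a seconds field
#' of 60 (carried into the minutes). Numeric input is passed through.
#'
#' @param x Character (or numeric) vector of coordinates.
#' @param kind `"lat"` or `"lon"`, used for range validation.
#' @return Numeric vector of decimal degrees.
#' @examples
#' parse_dms("00°02′04″ N")     #  0.034444
#' parse_dms("51°50′07'' W", "lon")  # -51.835278
#' @export
parse_dms <- function(x, kind = c("lat", "lon")) {
  kind <- match.arg(kind)
  limit <- if (kind == "lat") 90 else 180
  out <- vapply(x, function(tok) {
    if (is.numeric(tok)) return(as.numeric(tok))
    raw <- tok
    tok <- trimws(tok)
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    hemi <- stringr::str_match(toupper(tok), "([NSEW])\\s*$")[, 2]
    if (is.na(hemi)) {
      stop("cannot parse coordinate token: '", raw, "'", call. = FALSE)
    }
    nums <- stringr::str_match_all(tok, "([0-9]+(?:\\.[0-9]+)?)")[[1]][, 2]
    if (length(nums) < 1 || length(nums) > 3) {
      stop("cannot parse coordinate token: '", raw, "'", call. = FALSE)
    }
    nums <- as.numeric(nums)
    d <- nums[1]
    m <- if (length(nums) >= 2) nums[2] else 0
    s <- if (length(nums) >= 3) nums[3] else 0
    if (m >= 61 || s > 60) {
      stop("minutes/seconds out of range in '", raw, "'", call. = FALSE)
    }
    val <- d + m / 60 + s / 3600
    if (hemi %in% c("S", "W")) val <- -val
    val
  }, numeric(1), USE.NAMES = FALSE)
  bad <- !is.na(out) & abs(out) > limit
  if (any(bad)) {
    stop(kind, " out of range [-", limit, ", ", limit, "]: '",
         paste(x[bad], collapse = "', '"), "'", call. = FALSE)
  }
  out
}

#' Read a site/coordinate table
#'
#' Reads a CSV with columns `name`, `lat`, `lon` (decimal degrees or
#' degree-minute-second strings; west longitudes come out negative) and an
#' optional `order` column giving the transect rank. Without `order`, sites
#' are ranked south to north by latitude.
#'
#' @param path CSV path.
#' @return A tibble with `name`, `lat`, `lon`, `order`.
#' @export
read_sites <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("name", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop("sites CSV needs columns name, lat, lon", call. = FALSE)
  }
  if (anyDuplicated(df$name)) stop("duplicate site names", call. = FALSE)
  out <- tibble::tibble(
    name = df$name,
    lat = parse_dms(df$lat, "lat"),
    lon = parse_dms(df$lon, "lon"))
  out$order <- if ("order" %in% names(df)) {
    as.integer(df$order)
  } else {
    rank(out$lat, ties.method = "first")
  }
  out
}

#' Read a pairwise-Fst matrix from CSV
#'
#' Accepts either a lower-triangular layout (header of population names,
#' first column the row's population, cells above the diagonal empty) or a
#' full square matrix, which must be symmetric. The diagonal may be absent
#' or zero.
#'
#' @param path CSV path.
#' @return A symmetric numeric matrix with population dimnames.
#' @export
read_fst_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  pops <- names(df)[-1]
  if (!identical(as.character(df[[1]]), pops)) {
    stop("row names must match header population names (same order)",
         call. = FALSE)
  }
  n <- length(pops)
  m <- matrix(NA_real_, n, n, dimnames = list(pops, pops))
  for (j in seq_len(n)) {
    col <- df[[j + 1]]
    blank <- is.na(col) | !nzchar(trimws(col))
    val <- suppressWarnings(as.numeric(col))
    if (any(!blank & is.na(val))) {
      stop("non-numeric cell in column ", pops[j], call. = FALSE)
    }
    m[, j] <- val
  }
  d <- diag(m)
  d[is.na(d)] <- 0
  diag(m) <- d
  lower <- m[lower.tri(m)]
  upper <- t(m)[lower.tri(m)]
  if (all(!is.na(upper))) {
    if (any(is.na(lower)) || any(abs(lower - upper) > 1e-12)) {
      stop("full matrix input is asymmetric", call. = FALSE)
    }
  } else {
    if (any(is.na(lower))) stop("incomplete lower triangle", call. = FALSE)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
  }
  m
}

#' Printed Amapá survey inputs
#'
#' Convenience accessors for the small plain-text tables shipped with the
#' package: the six city coordinates of the Amapá transect survey and the
#' published pairwise-Fst lower triangle among the six populations.
#'
#' @return `amapa_sites()`: a site tibble; `amapa_fst_printed()`: a 6x6
#'   symmetric Fst matrix.
#' @export
amapa_sites <- function() {
  read_sites(system.file("extdata", "amapa_sites.csv", package = "popkdr",
                         mustWork = TRUE))
}

#' @rdname amapa_sites
#' @export
amapa_fst_printed <- function() {
  read_fst_matrix(system.file("extdata", "amapa_fst.csv", package = "popkdr",
                              mustWork = TRUE))
}
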