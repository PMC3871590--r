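## Min/max normalization of chemical shifts and the ten-letter alphabet.
##
## Each (amino acid, atom) combination has its own observed shift range
## on the training corpus; a fitted table over all 20 x 6 combinations
## has 120 (x_min, x_max) pairs. Query values outside the training
## range are clipped to the range before the linear transform.

#' Fit per-(amino acid, atom) shift ranges
#'
#' Learns `x_min`/`x_max` for every (amino acid, atom type) combination
#' observed in a training corpus of per-residue shift tables. Vacant
#' cells are ignored. Combinations with a single observation are
#' degenerate (`x_min == x_max`) and flagged; combinations never
#' observed are absent from the table.
#'
#' @param shifts A per-residue shift tibble (columns `aa`, `HA` ... `C`),
#'   typically several chains row-bound together.
#' @return A tibble `aa`, `atom`, `x_min`, `x_max`, `n_obs`,
#'   `degenerate`, of class `scale_table`.
#' @export
#' @examples
#' corp <- tibble::tibble(aa = c("A", "A", "A"), HA = c(4, 5, 4.5),
#'   H = NA_real_, N = NA_real_, CA = c(50, 54, 52), CB = NA_real_,
#'   C = NA_real_, chain_id = "c1", num = 1:3)
#' fit_scale_table(corp)
fit_scale_table <- function(shifts) {
  if (nrow(shifts) == 0) abort("cannot fit a scale table on an empty corpus")
  long <- shifts |>
    dplyr::select(dplyr::all_of(c("aa", shift_atoms()))) |>
    tidyr::pivot_longer(dplyr::all_of(shift_atoms()),
                        names_to = "atom", values_to = "ppm") |>
    dplyr::filter(!is.na(.data$ppm))
  if (nrow(long) == 0) abort("corpus contains no assigned shifts")
  tab <- long |>
    dplyr::group_by(.data$aa, .data$atom) |>
    dplyr::summarise(x_min = min(.data$ppm), x_max = max(.data$ppm),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(degenerate = .data$x_min == .data$x_max) |>
    dplyr::arrange(.data$aa, factor(.data$atom, levels = shift_atoms()))
  class(tab) <- c("scale_table", class(tab))
  tab
}

#' Normalize chemical shifts to [0, 1]
#'
#' Applies the linear transform `(x - x_min) / (x_max - x_min)` using
#' the (amino acid, atom) entry of a fitted [fit_scale_table()] table.
#' Values outside the training range are clipped to the boundary first,
#' so the output always lies in [0, 1]. Vacant values pass through as
#' `NA`.
#'
#' @param x Numeric vector of shift values in ppm (`NA` = vacant).
#' @param aa,atom Character vectors (recycled) naming the amino acid
#'   and atom type of each value.
#' @param scale A `scale_table`.
#' @param strict If `TRUE` (default), a non-vacant value whose
#'   (aa, atom) entry is absent or degenerate is an error; if `FALSE`
#'   such values become `NA` with a warning (useful on sparse corpora).
#' @return Numeric vector in [0, 1] with `NA` for vacancies.
#' @export
normalize_shift <- function(x, aa, atom, scale, strict = TRUE) {
  n <- length(x)
  aa <- rep_len(aa, n)
  atom <- rep_len(atom, n)
  key <- paste(aa, atom)
  idx <- match(key, paste(scale$aa, scale$atom))
  lo <- scale$x_min[idx]
  hi <- scale$x_max[idx]
  live <- !is.na(x)
  bad <- live & (is.na(idx) | (hi - lo) <= 0)
  if (any(bad)) {
    msg <- sprintf("absent or degenerate scale entry for (%s, %s)",
                   aa[bad][1], atom[bad][1])
    if (strict) abort(msg)
    warn(paste0(msg, "; emitting vacancy"))
    x[bad] <- NA_real_
    live <- !is.na(x)
  }
  out <- rep(NA_real_, n)
  xi <- pmin(pmax(x[live], lo[live]), hi[live])
  out[live] <- (xi - lo[live]) / (hi[live] - lo[live])
  out
}

#' Alphabetize normalized shift values
#'
#' Maps a value in [0, 1] to one of ten bin letters (L, A, D, C, Q, M,
#' V, W, P, G in ascending-bin order): bins are half-open
#' `[k/10, (k+1)/10)` with the last bin closed at 1. `NA` (vacancy)
#' maps to the letter `N`.
#'
#' @param v Numeric vector in [0, 1], `NA` for vacancies.
#' @return Character vector of single letters.
#' @export
#' @examples
#' alphabetize(c(0.05, 0.5, 1, NA))
alphabetize <- function(v) {
  live <- !is.na(v)
  if (any(v[live] < 0 | v[live] > 1)) {
    abort("alphabetize() requires values in [0, 1]; normalize first")
  }
  out <- rep("N", length(v))
  out[live] <- shift_letters()[pmin(floor(10 * v[live]), 9) + 1]
  out
}

#' Alphabetize a per-residue shift table
#'
#' Composes [normalize_shift()] and [alphabetize()] over all six atom
#' columns of a shift tibble, yielding the six shift letter features
#' per residue.
#'
#' @inheritParams normalize_shift
#' @param shifts A per-residue shift tibble (one or more chains).
#' @return A tibble `chain_id`, `num`, `aa` plus the six atom columns
#'   holding single letters from the 11-letter alphabet.
#' @export
alphabetize_shifts <- function(shifts, scale, strict = FALSE) {
  check_shift_tbl(shifts)
  out <- shifts[, c("chain_id", "num", "aa")]
  for (a in shift_atoms()) {
    out[[a]] <- alphabetize(
      normalize_shift(shifts[[a]], shifts$aa, a, scale, strict = strict))
  }
  out
}

#' Read and write scale tables as TSV
#'
#' The on-disk form is a versioned TSV with columns
#' `aa`, `atom`, `x_min`, `x_max`, `n_obs`.
#'
#' @param scale A `scale_table`.
#' @param path File path.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
write_scale_table <- function(scale, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#scale_table v1", con)
  write.table(scale[, c("aa", "atom", "x_min", "x_max", "n_obs")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scale_table
#' @export
read_scale_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#scale_table", first)) abort("not a scale-table file")
  tab <- as_tibble(read.delim(path, skip = 1)) |>
    dplyr::mutate(degenerate = .data$x_min == .data$x_max)
  class(tab) <- c("scale_table", class(tab))
  tab
}
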