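## SHIFTY-dialect chemical-shift tables and prediction output.
##
## Dialect (strict, no sniffing):
##   * header/comment lines begin '#'
##   * '#CHAIN <id>' (optional) names the chain
##   * '#SEQUENCE <letters>' carries the one-letter sequence; long
##     sequences wrap over several '#SEQUENCE' lines (concatenated)
##   * the data table starts with the column row 'NUM AA HA H N CA CB C'
##     and is whitespace-delimited; the missing-value marker is the
##     literal token 'N'
##   * residues present in '#SEQUENCE' but absent from the table are
##     all-vacant rows

#' Read a SHIFTY-dialect chemical-shift file
#'
#' Parses a per-residue chemical-shift table into a tibble with one row
#' per residue and one column per atom type (`HA`, `H`, `N`, `CA`,
#' `CB`, `C`), in ppm. Vacant cells (the literal marker `N`) become
#' `NA`. Residues listed in the `#SEQUENCE` header but missing from the
#' table are returned as all-vacant rows, so the row count always
#' equals the chain length.
#'
#' @param path Path to a SHIFTY file.
#' @return A tibble with columns `chain_id`, `num` (1-based residue
#'   index), `aa` (one-letter code) and the six shift columns.
#' @seealso [write_shifty()], [write_prediction()]
#' @export
read_shifty <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty SHIFTY file")

  hdr <- grepl("^#", lines)
  chain_id <- NA_character_
  seq_parts <- character()
  for (ln in lines[hdr]) {
    body <- trimws(sub("^#", "", ln))
    if (grepl("^SEQUENCE\\b", body)) {
      part <- gsub("\\s", "", sub("^SEQUENCE", "", body))
      if (!nzchar(part)) abort("malformed #SEQUENCE header (no letters)")
      seq_parts <- c(seq_parts, part)
    } else if (grepl("^CHAIN\\b", body)) {
      chain_id <- trimws(sub("^CHAIN", "", body))
      if (!nzchar(chain_id)) abort("malformed #CHAIN header (no id)")
    }
  }
  seq <- paste(seq_parts, collapse = "")
  if (is.na(chain_id)) {
    chain_id <- sub("\\.[^.]*$", "", basename(path))
  }

  data_lines <- lines[!hdr]
  if (length(data_lines) == 0) {
    if (!nzchar(seq)) abort("SHIFTY file has neither sequence nor data table")
    return(all_vacant_tbl(chain_id, seq))
  }

  cols <- strsplit(trimws(data_lines[1]), "\\s+")[[1]]
  expected <- c("NUM", "AA", shift_atoms())
  if (!identical(toupper(cols), expected)) {
    abort(sprintf("malformed SHIFTY column row: '%s'", data_lines[1]))
  }
  rows <- strsplit(trimws(data_lines[-1]), "\\s+")
  bad_len <- lengths(rows) != 8L
  if (any(bad_len)) {
    abort(sprintf("SHIFTY data row with %d fields (need 8): '%s'",
                  lengths(rows)[bad_len][1], data_lines[-1][bad_len][1]))
  }

  num <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 1L)))
  if (anyNA(num)) abort("non-integer residue index in SHIFTY table")
  if (anyDuplicated(num)) {
    abort(sprintf("duplicate residue index %d in SHIFTY table",
                  num[duplicated(num)][1]))
  }
  if (is.unsorted(num, strictly = TRUE)) {
    abort("residue indices must be strictly increasing")
  }
  aa_raw <- toupper(vapply(rows, `[[`, "", 2L))
  aa <- ifelse(nchar(aa_raw) == 3L, unname(AA3TO1[aa_raw]), aa_raw)
  bad_aa <- is.na(aa) | !(aa %in% AA20)
  if (any(bad_aa)) {
    abort(sprintf("unknown amino-acid code '%s' at residue %d",
                  aa_raw[bad_aa][1], num[bad_aa][1]))
  }

  shifts <- matrix(NA_real_, nrow = length(rows), ncol = 6,
                   dimnames = list(NULL, shift_atoms()))
  for (j in 1:6) {
    cell <- vapply(rows, `[[`, "", j + 2L)
    vac <- cell == "N"
    val <- suppressWarnings(as.numeric(cell))
    bad <- !vac & is.na(val)
    if (any(bad)) {
      abort(sprintf("unparseable %s value '%s' at residue %d",
                    shift_atoms()[j], cell[bad][1], num[bad][1]))
    }
    shifts[, j] <- ifelse(vac, NA_real_, val)
  }

  out <- tibble(chain_id = chain_id, num = num, aa = aa) |>
    dplyr::bind_cols(as_tibble(shifts))

  if (nzchar(seq)) {
    sv <- chars(toupper(seq))
    if (!all(sv %in% AA20)) {
      abort("unknown amino-acid code in #SEQUENCE header")
    }
    if (any(num < 1L | num > length(sv))) {
      abort("residue index outside the #SEQUENCE range")
    }
    mism <- aa != sv[num]
    if (any(mism)) {
      abort(sprintf("AA mismatch at residue %d: table '%s' vs sequence '%s'",
                    num[mism][1], aa[mism][1], sv[num][mism][1]))
    }
    full <- all_vacant_tbl(chain_id, seq)
    full[match(num, full$num), c("aa", shift_atoms())] <-
      out[, c("aa", shift_atoms())]
    out <- full
  }
  out
}

all_vacant_tbl <- function(chain_id, seq) {
  sv <- chars(toupper(seq))
  if (!all(sv %in% AA20)) abort("unknown amino-acid code in #SEQUENCE header")
  m <- matrix(NA_real_, nrow = length(sv), ncol = 6,
              dimnames = list(NULL, shift_atoms()))
  tibble(chain_id = chain_id, num = seq_along(sv), aa = sv) |>
    dplyr::bind_cols(as_tibble(m))
}

#' Write a SHIFTY-dialect chemical-shift file
#'
#' Inverse of [read_shifty()]: writes one chain's shift tibble in the
#' documented dialect. Values are written with four decimal places and
#' vacancies as the marker `N`, so a read/write cycle is bit-stable.
#'
#' @param shifts A tibble as returned by [read_shifty()] (one chain).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shifty <- function(shifts, path) {
  check_shift_tbl(shifts)
  if (length(unique(shifts$chain_id)) > 1) {
    abort("write_shifty() writes one chain per file")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#CHAIN %s", shifts$chain_id[1] %||% "chain1"), con)
  seq <- paste(shifts$aa, collapse = "")
  if (nzchar(seq)) {
    for (piece in substring(seq, seq(1, nchar(seq), 60),
                            pmin(seq(1, nchar(seq), 60) + 59, nchar(seq)))) {
      writeLines(sprintf("#SEQUENCE %s", piece), con)
    }
  }
  writeLines(paste(c("NUM", "AA", shift_atoms()), collapse = "\t"), con)
  if (nrow(shifts) > 0) {
    cells <- vapply(shift_atoms(), function(a) {
      v <- shifts[[a]]
      ifelse(is.na(v), "N", formatC(v, format = "f", digits = 4))
    }, character(nrow(shifts)))
    cells <- matrix(cells, nrow = nrow(shifts))
    writeLines(paste(shifts$num, shifts$aa,
                     apply(cells, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# internal: validate the per-residue shift tibble contract
check_shift_tbl <- function(x) {
  need <- c("chain_id", "num", "aa", shift_atoms())
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("shift table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    for (cid in unique(x$chain_id)) {
      nums <- x$num[x$chain_id == cid]
      if (is.unsorted(nums, strictly = TRUE)) {
        abort(sprintf("residue indices not strictly increasing in chain '%s'", cid))
      }
    }
    if (!all(x$aa %in% AA20)) abort("unknown amino-acid code in shift table")
  }
  invisible(x)
}

#' Write and read a shape-string prediction table
#'
#' The prediction file is a TSV with one row per residue: position,
#' amino acid, predicted shape letter, and the eight per-state marginal
#' probabilities (columns `P_S` ... `P_G` in box order).
#'
#' @param seq One-letter amino-acid sequence (single string).
#' @param pred Predicted shape string (same length as `seq`).
#' @param marginals Numeric matrix, one row per residue, eight columns
#'   in box order S,R,U,V,K,A,T,G; each row must sum to 1 within 1e-6.
#' @param path Output path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_prediction <- function(seq, pred, marginals, path) {
  sv <- chars(seq)
  pv <- shape_chars(pred, "prediction")
  marginals <- as.matrix(marginals)
  if (length(sv) != length(pv) || nrow(marginals) != length(sv)) {
    abort("sequence, prediction and marginals must have equal lengths")
  }
  if (ncol(marginals) != 8) abort("marginals must have 8 columns")
  if (nrow(marginals) > 0 && any(abs(rowSums(marginals) - 1) > 1e-6)) {
    abort("marginal rows must sum to 1 (tolerance 1e-6)")
  }
  out <- data.frame(num = seq_along(sv), aa = sv, shape = pv,
                    formatC(marginals, format = "f", digits = 6))
  names(out)[4:11] <- paste0("P_", shape_states())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction
#' @export
read_prediction <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE))
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a
#' tibble of `chain_id`, `seq`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record.
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble(chain_id = sub("\\s.*$", "", names(ss)),
         seq = as.character(ss))
}

#' Read and write shape strings as FASTA-like records
#'
#' Shape strings (alphabet S,R,U,V,K,A,T,G plus X) are stored as
#' FASTA-like records whose sequence lines hold the shape letters.
#'
#' @param path File path.
#' @param x A tibble with columns `chain_id`, `shape`.
#' @return A tibble `chain_id`, `shape` for the reader; `path`
#'   invisibly for the writer.
#' @export
read_shape_strings <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- tibble(chain_id = unname(sub("\\s.*$", "", names(ss))),
                shape = unname(as.character(ss)))
  purrr::walk(out$shape, shape_chars)
  out
}

#' @rdname read_shape_strings
#' @export
write_shape_strings <- function(x, path) {
  purrr::walk(x$shape, shape_chars)
  writeLines(rbind(paste0(">", x$chain_id), x$shape), path)
  invisible(path)
}
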