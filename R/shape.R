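## Shape strings: assignment from backbone torsions, the 8->3 state
## collapse, and alignment of shift records to observed shape strings.

#' Default torsion-region table
#'
#' Loads the torsion-region table that maps backbone (phi, psi) pairs
#' to the eight shape letters. Each row is an axis-aligned rectangle in
#' the Ramachandran plane; rows are matched first-to-last with
#' lower-inclusive, upper-exclusive bounds, the final row being a
#' catch-all, so every angle pair maps to exactly one letter. Rows with
#' `glycine_only = TRUE` apply only to glycine and take precedence
#' (shape G is reserved for glycine). The shipped default is the
#' package's own documented approximation of the classical shape-string
#' regions (helix A, extended S, polyproline-II R, bridges U/V,
#' helix-cap K, turn T, positive-phi glycine G); the exact published
#' boundaries are not public, so the table is data, not code.
#'
#' @param path Optional path to a custom table (TSV with columns
#'   `letter`, `phi_lo`, `phi_hi`, `psi_lo`, `psi_hi`, `glycine_only`).
#' @return A tibble of region rows.
#' @export
torsion_regions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "torsion_regions.tsv", package = "shapecrf")
  }
  tab <- as_tibble(read.delim(path, comment.char = "#"))
  need <- c("letter", "phi_lo", "phi_hi", "psi_lo", "psi_hi", "glycine_only")
  if (!all(need %in% names(tab))) abort("malformed torsion-region table")
  if (!all(tab$letter %in% shape_states())) {
    abort("torsion-region letters must be shape letters")
  }
  last <- tab[nrow(tab), ]
  if (last$glycine_only ||
      last$phi_lo > -180 || last$phi_hi < 180 ||
      last$psi_lo > -180 || last$psi_hi < 180) {
    abort("final torsion-region row must be a catch-all rectangle")
  }
  tab
}

#' Assign shape letters from backbone torsions
#'
#' Maps (phi, psi) pairs to shape letters using a region table
#' ([torsion_regions()]). Glycine-only rows are consulted first for
#' glycine residues; all other residues use the base rows, so a
#' non-glycine residue falling in the G region receives the underlying
#' base letter.
#'
#' @param phi,psi Numeric vectors of backbone torsions in degrees,
#'   within [-180, 180] (180 is treated as -180).
#' @param aa Character vector of one-letter amino-acid codes (recycled).
#' @param regions A region table; default [torsion_regions()].
#' @return Character vector of shape letters.
#' @export
assign_shape <- function(phi, psi, aa, regions = torsion_regions()) {
  if (any(abs(phi) > 180, na.rm = TRUE) || any(abs(psi) > 180, na.rm = TRUE)) {
    abort("phi/psi must lie in [-180, 180]")
  }
  if (length(phi) != length(psi)) abort("phi and psi lengths differ")
  aa <- rep_len(aa, length(phi))
  phi <- ifelse(phi == 180, -180, phi)
  psi <- ifelse(psi == 180, -180, psi)
  out <- rep(NA_character_, length(phi))
  gly_rows <- which(regions$glycine_only)
  base_rows <- which(!regions$glycine_only)
  for (i in seq_along(phi)) {
    rows <- if (aa[i] == "G") c(gly_rows, base_rows) else base_rows
    for (r in rows) {
      if (phi[i] >= regions$phi_lo[r] && phi[i] < regions$phi_hi[r] &&
          psi[i] >= regions$psi_lo[r] && psi[i] < regions$psi_hi[r]) {
        out[i] <- regions$letter[r]
        break
      }
    }
  }
  out
}

#' Collapse eight shape states to three
#'
#' Maps the eight shape letters to three coarse states:
#' S, R, U, V to S (extended); A, K to H (helical); T, G to T (turn).
#' X (no data) is preserved. Any other letter is an error.
#'
#' @param s A shape string (or character vector of them).
#' @return String(s) over the alphabet S, H, T, X.
#' @export
#' @examples
#' map8to3("SRUVAKTG")
map8to3 <- function(s) {
  map <- c(S = "S", R = "S", U = "S", V = "S",
           A = "H", K = "H", T = "T", G = "T", X = "X")
  vapply(s, function(one) {
    v <- chars(one)
    bad <- setdiff(unique(v), names(map))
    if (length(bad) > 0) {
      abort(sprintf("not an 8-state shape string (letter '%s')", bad[1]))
    }
    paste(map[v], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Align a shift record to an observed shape string
#'
#' Chemical-shift records and structure-derived shape strings for the
#' same chain often disagree in coverage (disordered tails, sequence
#' breaks). This aligns the record's amino-acid sequence to the
#' observed structure's sequence globally (identity scoring, affine
#' gaps, mismatch-hostile: match +1, mismatch -10, gap open 5, gap
#' extend 1) and transfers each aligned residue's shape letter; record
#' residues aligned to a gap receive X. If any aligned pair is a
#' substitution the record is flagged unalignable (such entries should
#' be dropped rather than trusted).
#'
#' @param shifts A one-chain shift tibble ([read_shifty()]).
#' @param observed_seq Amino-acid sequence of the structure.
#' @param observed_shape Shape string of the structure (same length).
#' @return A list of class `shape_alignment`: `chain_id`, `shape`
#'   (string, one letter per record residue), `unalignable` (logical),
#'   `n_matched`, `n_x`.
#' @export
align_records <- function(shifts, observed_seq, observed_shape) {
  check_shift_tbl(shifts)
  if (nrow(shifts) == 0 || !nzchar(observed_seq)) {
    abort("both sequences must be non-empty")
  }
  obs_shape <- shape_chars(observed_shape)
  if (nchar(observed_seq) != length(obs_shape)) {
    abort("observed sequence and shape string lengths differ")
  }
  rec_seq <- paste(shifts$aa, collapse = "")

  sm <- matrix(-10, 20, 20, dimnames = list(AA20, AA20))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rec_seq), Biostrings::AAString(observed_seq),
    type = "global", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 1)
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  s <- chars(as.character(Biostrings::alignedSubject(aln)))

  labels <- character(0)
  j <- 0L                      # position in observed sequence
  unalignable <- FALSE
  for (k in seq_along(p)) {
    if (s[k] != "-") j <- j + 1L
    if (p[k] == "-") next
    if (s[k] == "-") {
      labels <- c(labels, "X")
    } else {
      if (p[k] != s[k]) unalignable <- TRUE
      labels <- c(labels, obs_shape[j])
    }
  }
  structure(list(chain_id = shifts$chain_id[1],
                 shape = paste(labels, collapse = ""),
                 unalignable = unalignable,
                 n_matched = sum(labels != "X"),
                 n_x = sum(labels == "X")),
            class = "shape_alignment")
}

#' @export
#' @method print shape_alignment
print.shape_alignment <- function(x, ...) {
  cat(sprintf("<shape_alignment> chain %s: %d labeled, %d X%s\n",
              x$chain_id, x$n_matched, x$n_x,
              if (x$unalignable) " [UNALIGNABLE]" else ""))
  invisible(x)
}
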