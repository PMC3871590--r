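## Shape-string profiles: hallmark-pattern mining with binomial
## conservation tests, exact k-mer hit gathering (the desk-scale hit
## source standing behind a pluggable interface), and per-residue
## eight-box profile construction.

#' Mine hallmark patterns from an annotated corpus
#'
#' A hallmark pattern is a short amino-acid substring (length 2-4)
#' whose occurrences across a structure-annotated corpus show a
#' statistically conserved shape letter at one or more positions.
#' All substrings of the requested lengths are enumerated (overlapping
#' occurrences counted); patterns with corpus-wide support below
#' `min_support` are dropped. For each pattern position the most
#' frequent shape letter is tested with a one-sided upper-tail binomial
#' test: with `n` occurrences carrying a defined (non-X) letter at that
#' position, `k` of them the modal letter, and `p0` the corpus
#' background frequency of that letter, the p-value is
#' `P(K >= k | n, p0)`. Patterns with at least one position at
#' `p_value <= max_p` are retained.
#'
#' @param corpus A tibble with columns `chain_id`, `seq`, `shape`
#'   (equal-length strings per row).
#' @param min_support Minimum corpus-wide occurrence count
#'   (default 100, the standard frequency criterion).
#' @param max_p Conservation p-value cutoff per position (default 0.01).
#' @param lengths Pattern lengths to enumerate (default 2:4).
#' @return A tibble with one row per (pattern, position):
#'   `pattern`, `length`, `support`, `position`, `letter` (modal),
#'   `n`, `k`, `p_value`, `conserved`.
#' @export
mine_hallmarks <- function(corpus, min_support = 100, max_p = 0.01,
                           lengths = 2:4) {
  if (nrow(corpus) == 0) abort("corpus is empty")
  if (min_support < 1) abort("min_support must be >= 1")
  purrr::walk2(corpus$seq, corpus$shape, function(s, h) {
    if (nchar(s) != nchar(h)) abort("seq and shape lengths differ in corpus")
  })

  shapes_flat <- chars(paste(corpus$shape, collapse = ""))
  bg <- table(factor(shapes_flat[shapes_flat != "X"], levels = shape_states()))
  if (sum(bg) == 0) abort("corpus has no defined shape letters")
  p0 <- as.numeric(bg) / sum(bg)
  names(p0) <- shape_states()

  occ <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    L <- nchar(corpus$seq[i])
    purrr::map_dfr(lengths[lengths <= L], function(len) {
      starts <- seq_len(L - len + 1)
      tibble(pattern = substring(corpus$seq[i], starts, starts + len - 1),
             length = len, chain = i, start = starts)
    })
  })
  supp <- occ |>
    dplyr::count(.data$pattern, .data$length, name = "support") |>
    dplyr::filter(.data$support >= min_support)
  if (nrow(supp) == 0) {
    return(tibble(pattern = character(), length = integer(),
                  support = integer(), position = integer(),
                  letter = character(), n = integer(), k = integer(),
                  p_value = numeric(), conserved = logical()))
  }
  occ <- dplyr::semi_join(occ, supp, by = c("pattern", "length"))

  # one row per (occurrence, within-pattern position), with shape letter
  pos_tbl <- occ |>
    dplyr::mutate(position = purrr::map(.data$length, seq_len)) |>
    tidyr::unnest("position") |>
    dplyr::mutate(letter = substring(corpus$shape[.data$chain],
                                     .data$start + .data$position - 1,
                                     .data$start + .data$position - 1))

  res <- pos_tbl |>
    dplyr::filter(.data$letter != "X") |>
    dplyr::count(.data$pattern, .data$length, .data$position, .data$letter) |>
    # modal-letter ties break in box order S,R,U,V,K,A,T,G
    dplyr::arrange(.data$pattern, .data$length, .data$position,
                   factor(.data$letter, levels = shape_states())) |>
    dplyr::group_by(.data$pattern, .data$length, .data$position) |>
    dplyr::summarise(k = max(.data$n),
                     letter = .data$letter[which.max(.data$n)],
                     n = sum(.data$n),
                     .groups = "drop") |>
    dplyr::mutate(
      p_value = pbinom(.data$k - 1, .data$n, p0[.data$letter],
                       lower.tail = FALSE),
      conserved = .data$p_value <= max_p) |>
    dplyr::inner_join(supp, by = c("pattern", "length"))

  keep <- res |>
    dplyr::group_by(.data$pattern) |>
    dplyr::filter(any(.data$conserved)) |>
    dplyr::ungroup()
  keep |>
    dplyr::select("pattern", "length", "support", "position",
                  "letter", "n", "k", "p_value", "conserved") |>
    dplyr::arrange(.data$pattern, .data$position)
}

#' Gather exact k-mer hits for a query sequence
#'
#' The reference hit source: every exact k-mer shared between the query
#' and a corpus sequence yields one hit per covered query position,
#' carrying the matched corpus residue's shape letter. This plays the
#' role a similarity search against a structure database plays at full
#' scale; externally produced hits can be supplied instead via
#' [read_external_hits()].
#'
#' @param query Amino-acid sequence (single string).
#' @param corpus A tibble `chain_id`, `seq`, `shape`.
#' @param k k-mer length (default 6; must be >= 2).
#' @return A tibble `query_pos`, `chain_id`, `subject_pos`, `letter`.
#' @export
kmer_hits <- function(query, corpus, k = 6) {
  if (k < 2) abort("k must be >= 2")
  Lq <- nchar(query)
  if (Lq < k || nrow(corpus) == 0) {
    return(tibble(query_pos = integer(), chain_id = character(),
                  subject_pos = integer(), letter = character()))
  }
  qs <- seq_len(Lq - k + 1)
  qtab <- tibble(kmer = substring(query, qs, qs + k - 1), q_start = qs)
  stab <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    L <- nchar(corpus$seq[i])
    if (L < k) return(NULL)
    ss <- seq_len(L - k + 1)
    tibble(kmer = substring(corpus$seq[i], ss, ss + k - 1),
           chain_id = corpus$chain_id[i], chain = i, s_start = ss)
  })
  if (nrow(stab) == 0) {
    return(tibble(query_pos = integer(), chain_id = character(),
                  subject_pos = integer(), letter = character()))
  }
  hits <- dplyr::inner_join(qtab, stab, by = "kmer",
                            relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(query_pos = integer(), chain_id = character(),
                  subject_pos = integer(), letter = character()))
  }
  hits |>
    dplyr::mutate(offset = purrr::map(.data$kmer, ~ seq_len(nchar(.x)) - 1L)) |>
    tidyr::unnest("offset") |>
    dplyr::transmute(
      query_pos = .data$q_start + .data$offset,
      chain_id = .data$chain_id,
      subject_pos = .data$s_start + .data$offset,
      letter = substring(corpus$shape[.data$chain], .data$subject_pos,
                         .data$subject_pos)) |>
    dplyr::arrange(.data$query_pos, .data$chain_id, .data$subject_pos)
}

#' Read externally produced profile hits
#'
#' Adapter for hit lists produced outside the package (e.g. a BLAST
#' post-process): a TSV with columns `query_pos` and `letter`
#' (subject shape letter), optionally `chain_id` and `subject_pos`.
#'
#' @param path TSV path.
#' @return A hit tibble compatible with [build_profile()].
#' @export
read_external_hits <- function(path) {
  tab <- as_tibble(read.delim(path))
  if (!all(c("query_pos", "letter") %in% names(tab))) {
    abort("external hits need columns query_pos, letter")
  }
  if (!"chain_id" %in% names(tab)) tab$chain_id <- "external"
  if (!"subject_pos" %in% names(tab)) tab$subject_pos <- NA_integer_
  tab[, c("query_pos", "chain_id", "subject_pos", "letter")]
}

#' Build a per-residue eight-box shape profile
#'
#' Tallies shape-letter evidence for each query position into eight
#' boxes (order S,R,U,V,K,A,T,G). Primary evidence comes from the hit
#' list restricted to the `top_n` subjects with the most matched
#' positions. Query segments left uncovered by primary hits are then
#' scanned against the hallmark-pattern library: for each pattern
#' occurrence in an uncovered segment, corpus occurrences of that
#' pattern are ranked by sequence identity of their +/-`flank` residue
#' context to the query context, and each of the `top_n` best
#' occurrences contributes one count of the pattern's conserved
#' letter(s) at the corresponding uncovered positions. Positions with
#' no evidence at all have all-zero boxes. X letters never enter boxes.
#'
#' @param query Amino-acid sequence (single string).
#' @param hits Hit tibble from [kmer_hits()] or [read_external_hits()].
#' @param patterns Hallmark tibble from [mine_hallmarks()] (optional).
#' @param corpus The annotated corpus used to locate secondary hits
#'   (required when `patterns` is given).
#' @param top_n Number of subjects / secondary occurrences to keep
#'   (default 10).
#' @param flank Context half-width for ranking secondary occurrences
#'   (default 5).
#' @return A tibble with columns `num`, `aa` and the eight box counts
#'   `S` ... `G`.
#' @export
build_profile <- function(query, hits, patterns = NULL, corpus = NULL,
                          top_n = 10, flank = 5) {
  if (top_n < 1) abort("top_n must be >= 1")
  L <- nchar(query)
  boxes <- matrix(0L, nrow = L, ncol = 8,
                  dimnames = list(NULL, shape_states()))

  if (!is.null(hits) && nrow(hits) > 0) {
    top_chains <- hits |>
      dplyr::count(.data$chain_id, sort = TRUE) |>
      dplyr::slice_head(n = top_n) |>
      dplyr::pull("chain_id")
    prim <- hits |>
      dplyr::filter(.data$chain_id %in% top_chains,
                    .data$letter %in% shape_states())
    if (nrow(prim) > 0) {
      tab <- prim |> dplyr::count(.data$query_pos, .data$letter)
      boxes[cbind(tab$query_pos, match(tab$letter, shape_states()))] <-
        boxes[cbind(tab$query_pos, match(tab$letter, shape_states()))] + tab$n
    }
  }

  if (!is.null(patterns) && nrow(patterns) > 0) {
    if (is.null(corpus)) abort("corpus required to use hallmark patterns")
    uncovered <- rowSums(boxes) == 0
    pat_tbl <- patterns |>
      dplyr::filter(.data$conserved) |>
      dplyr::group_by(.data$pattern, .data$length) |>
      dplyr::summarise(cons_pos = list(.data$position),
                       cons_letter = list(.data$letter), .groups = "drop")
    for (p in seq_len(nrow(pat_tbl))) {
      pat <- pat_tbl$pattern[p]
      len <- pat_tbl$length[p]
      q_starts <- find_occurrences(query, pat)
      # keep matches lying inside uncovered territory
      q_starts <- q_starts[vapply(q_starts, function(s)
        any(uncovered[s:(s + len - 1)]), TRUE)]
      if (length(q_starts) == 0) next
      occs <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
        st <- find_occurrences(corpus$seq[i], pat)
        if (length(st) == 0) return(NULL)
        tibble(chain = i, start = st)
      })
      if (nrow(occs) == 0) next
      for (q0 in q_starts) {
        q_ctx <- context_chars(query, q0, len, flank)
        score <- vapply(seq_len(nrow(occs)), function(j) {
          s_ctx <- context_chars(corpus$seq[occs$chain[j]], occs$start[j],
                                 len, flank)
          sum(q_ctx == s_ctx & q_ctx != ".")
        }, 0L)
        keep <- head(order(score, decreasing = TRUE), top_n)
        for (m in seq_along(pat_tbl$cons_pos[[p]])) {
          jp <- pat_tbl$cons_pos[[p]][m]
          qp <- q0 + jp - 1
          if (!uncovered[qp]) next
          col <- match(pat_tbl$cons_letter[[p]][m], shape_states())
          boxes[qp, col] <- boxes[qp, col] + length(keep)
        }
      }
    }
  }

  tibble(num = seq_len(L), aa = chars(query)) |>
    dplyr::bind_cols(as_tibble(boxes))
}

# all start positions of exact occurrences of pat in s (overlapping)
find_occurrences <- function(s, pat) {
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (i < 0) break
    out <- c(out, from + i - 1L)
    from <- from + i
  }
  out
}

# fixed-width context around a match; "." pads beyond the ends
context_chars <- function(s, start, len, flank) {
  idx <- (start - flank):(start + len - 1 + flank)
  out <- rep(".", length(idx))
  ok <- idx >= 1 & idx <= nchar(s)
  out[ok] <- chars(s)[idx[ok]]
  out
}

#' Alphabetize a shape profile
#'
#' Converts each box count to its fraction of the position's total
#' evidence and bins the fractions with the ten-letter shift alphabet
#' ([alphabetize()]), yielding the eight profile letter features per
#' residue. Positions with no evidence emit "N" for all eight boxes.
#'
#' @param profile A tibble from [build_profile()].
#' @return A tibble `num`, `aa` plus eight letter columns `S` ... `G`.
#' @export
alphabetize_profile <- function(profile) {
  counts <- as.matrix(profile[, shape_states()])
  tot <- rowSums(counts)
  frac <- counts / ifelse(tot == 0, 1, tot)
  frac[tot == 0, ] <- NA_real_
  letters <- apply(frac, 2, alphabetize)
  letters <- matrix(letters, nrow = nrow(profile),
                    dimnames = list(NULL, shape_states()))
  dplyr::bind_cols(profile[, c("num", "aa")], as_tibble(letters))
}

#' Read and write hallmark-pattern libraries as TSV
#'
#' @param patterns A tibble from [mine_hallmarks()].
#' @param path File path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_hallmarks <- function(patterns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#hallmarks v1", con)
  write.table(patterns, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hallmarks
#' @export
read_hallmarks <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#hallmarks", first)) abort("not a hallmark library file")
  as_tibble(read.delim(path, skip = 1))
}
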