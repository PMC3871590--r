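## Residue accuracy (S8/S3), segment overlap (SOV, '99 delta
## convention) and bootstrap means/standard errors. X positions in the
## reference carry no structural information: they are excluded from
## accuracy counts, split segments for SOV, and never enter N(i).

# per-class correct/total counts; ref X excluded
acc_counts <- function(pred, ref, states) {
  p <- chars(pred)
  r <- chars(ref)
  if (length(p) != length(r)) abort("pred and ref lengths differ")
  keep <- r != "X"
  p <- p[keep]
  r <- r[keep]
  m <- vapply(states, function(s) sum(r == s), 0)
  n <- vapply(states, function(s) sum(r == s & p == s), 0)
  list(m = m, n = n)
}

#' Residue-level shape-string accuracy
#'
#' Per-class accuracy `100 * n_i / m_i` (correctly predicted residues
#' of state i over reference residues of state i) and the
#' residue-weighted total `100 * sum(n_i) / sum(m_i)`. Reference
#' positions labeled X are excluded. Classes absent from the reference
#' have undefined (NA) accuracy and contribute nothing to the total's
#' denominator.
#'
#' @param pred,ref Equal-length shape strings (or 3-state strings).
#' @param states The class alphabet (default the eight shape letters;
#'   pass `c("S","H","T")` for collapsed strings).
#' @return A tibble `state`, `m`, `n_correct`, `accuracy`, with a final
#'   `total` row.
#' @export
#' @examples
#' shape_accuracy("AAAT", "AAAS")
shape_accuracy <- function(pred, ref, states = shape_states()) {
  cc <- acc_counts(pred, ref, states)
  tibble(state = c(states, "total"),
         m = unname(c(cc$m, sum(cc$m))),
         n_correct = unname(c(cc$n, sum(cc$n))),
         accuracy = 100 * unname(c(ifelse(cc$m == 0, NA_real_, cc$n / cc$m),
                                   sum(cc$n) / sum(cc$m))))
}

# state-i segments of a string as (start, end); X splits and is dropped
segments_of <- function(v, state) {
  is_s <- v == state
  if (!any(is_s)) return(matrix(integer(0), ncol = 2))
  r <- rle(is_s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(starts[r$values], ends[r$values])
}

# per-state SOV numerator/denominator pieces
sov_parts <- function(pred, ref, states) {
  p <- chars(pred)
  r <- chars(ref)
  if (length(p) != length(r)) abort("pred and ref lengths differ")
  # X in the reference: exclude those positions from both strings'
  # segment structure by marking them X in the prediction too
  p[r == "X"] <- "X"
  num <- den <- setNames(numeric(length(states)), states)
  for (s in states) {
    s1 <- segments_of(r, s)
    s2 <- segments_of(p, s)
    for (i in seq_len(nrow(s1))) {
      b1 <- s1[i, 1]; e1 <- s1[i, 2]; len1 <- e1 - b1 + 1
      paired <- FALSE
      for (j in seq_len(nrow(s2))) {
        b2 <- s2[j, 1]; e2 <- s2[j, 2]
        minov <- min(e1, e2) - max(b1, b2) + 1
        if (minov <= 0) next
        paired <- TRUE
        len2 <- e2 - b2 + 1
        maxov <- max(e1, e2) - min(b1, b2) + 1
        delta <- min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
        num[s] <- num[s] + len1 * (minov + delta) / maxov
        den[s] <- den[s] + len1
      }
      if (!paired) den[s] <- den[s] + len1
    }
  }
  list(num = num, den = den)
}

#' Segment overlap measure (SOV)
#'
#' Segment-based agreement between a predicted and a reference shape
#' string, tolerating small boundary shifts through the delta
#' allowance: for each overlapping (reference, predicted) segment pair
#' in state i the contribution is
#' `len(s1) * (minov + delta) / maxov`, with
#' `delta = min(maxov - minov, minov, floor(len(s1)/2),
#' floor(len(s2)/2))`; reference segments with no overlapping partner
#' contribute only to the normalizer N(i).
#'
#' @inheritParams shape_accuracy
#' @return A tibble `state`, `n_ref` (N(i)), `sov`, with a final
#'   `total` row.
#' @export
#' @examples
#' shape_sov("AAASSSSS", "AAAASSSS")
shape_sov <- function(pred, ref, states = shape_states()) {
  sp <- sov_parts(pred, ref, states)
  tibble(state = c(states, "total"),
         n_ref = unname(c(sp$den, sum(sp$den))),
         sov = 100 * unname(c(ifelse(sp$den == 0, NA_real_, sp$num / sp$den),
                              if (sum(sp$den) == 0) NA_real_ else
                                sum(sp$num) / sum(sp$den))))
}

#' Evaluate a prediction against a reference
#'
#' Computes the four standard scores: eight-state accuracy and SOV on
#' the shape strings themselves, and three-state accuracy and SOV
#' after the [map8to3()] collapse. Accepts vectors of strings (one per
#' chain); residues are pooled across chains for accuracy and segment
#' structure is kept per-chain for SOV.
#'
#' @param pred,ref Character vectors of equal-length shape strings.
#' @return An object of class `shape_eval`; use [tidy()] for the
#'   per-class table and [glance()] for the four totals.
#' @export
evaluate_prediction <- function(pred, ref) {
  if (length(pred) != length(ref)) abort("pred and ref chain counts differ")
  st8 <- shape_states()
  st3 <- c("S", "H", "T")
  pred3 <- map8to3(pred)
  ref3 <- map8to3(ref)
  pool <- function(preds, refs, states, fun) {
    parts <- purrr::map2(preds, refs, fun, states = states)
    parts
  }
  a8 <- pool(pred, ref, st8, acc_counts)
  a3 <- pool(pred3, ref3, st3, acc_counts)
  v8 <- pool(pred, ref, st8, sov_parts)
  v3 <- pool(pred3, ref3, st3, sov_parts)
  sum_field <- function(parts, f) Reduce(`+`, lapply(parts, `[[`, f))
  acc_tbl <- function(parts, states) {
    m <- sum_field(parts, "m"); n <- sum_field(parts, "n")
    acc <- 100 * unname(c(ifelse(m == 0, NA_real_, n / m), sum(n) / sum(m)))
    tibble(state = c(states, "total"), m = unname(c(m, sum(m))),
           n_correct = unname(c(n, sum(n))), accuracy = acc)
  }
  sov_tbl <- function(parts, states) {
    num <- sum_field(parts, "num"); den <- sum_field(parts, "den")
    tibble(state = c(states, "total"), n_ref = unname(c(den, sum(den))),
           sov = 100 * unname(c(ifelse(den == 0, NA_real_, num / den),
                                if (sum(den) == 0) NA_real_ else
                                  sum(num) / sum(den))))
  }
  structure(list(accuracy8 = acc_tbl(a8, st8), sov8 = sov_tbl(v8, st8),
                 accuracy3 = acc_tbl(a3, st3), sov3 = sov_tbl(v3, st3),
                 n_chains = length(pred)),
            class = "shape_eval")
}

#' @export
#' @method print shape_eval
print.shape_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<shape_eval> %d chain(s)\n", x$n_chains))
  cat(sprintf("  S8 %.2f  SOV8 %.2f  S3 %.2f  SOV3 %.2f\n",
              g$s8, g$sov8, g$s3, g$sov3))
  invisible(x)
}

#' @export
tidy.shape_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$accuracy8, value = "accuracy"),
                  metric = "accuracy", states = 8, n = .data$m,
                  .keep = "unused"),
    dplyr::mutate(dplyr::rename(x$sov8, value = "sov"),
                  metric = "sov", states = 8, n = .data$n_ref,
                  .keep = "unused"),
    dplyr::mutate(dplyr::rename(x$accuracy3, value = "accuracy"),
                  metric = "accuracy", states = 3, n = .data$m,
                  .keep = "unused"),
    dplyr::mutate(dplyr::rename(x$sov3, value = "sov"),
                  metric = "sov", states = 3, n = .data$n_ref,
                  .keep = "unused")
  )[, c("metric", "states", "state", "n", "value")]
}

#' @export
glance.shape_eval <- function(x, ...) {
  tot <- function(tb, col) tb[[col]][tb$state == "total"]
  tibble(s8 = tot(x$accuracy8, "accuracy"), sov8 = tot(x$sov8, "sov"),
         s3 = tot(x$accuracy3, "accuracy"), sov3 = tot(x$sov3, "sov"),
         n_chains = x$n_chains)
}

#' Bootstrap means and standard errors of prediction scores
#'
#' Resamples targets (chains): each replicate draws `ceiling(frac * n)`
#' targets without replacement, recomputes the requested total scores
#' over the resampled set (residues pooled for accuracy, per-chain
#' segments for SOV), and reports the mean and the standard deviation
#' of the replicate distribution (the quoted "standard error").
#' Deterministic given `seed`.
#'
#' @param pred,ref Character vectors of shape strings (>= 2 chains).
#' @param metrics Which totals to bootstrap (subset of
#'   `c("s8", "sov8", "s3", "sov3")`).
#' @param frac Fraction of targets per replicate (default 0.8).
#' @param reps Number of replicates (default 1000).
#' @param seed RNG seed.
#' @return A tibble `metric`, `mean`, `se`, `reps`, `frac`.
#' @export
bootstrap_metric <- function(pred, ref, metrics = c("s8", "sov8", "s3", "sov3"),
                             frac = 0.8, reps = 1000, seed = 1) {
  n <- length(pred)
  if (n < 2) abort("bootstrap needs at least 2 targets")
  if (length(ref) != n) abort("pred and ref chain counts differ")
  metrics <- match.arg(metrics, several.ok = TRUE)
  pred3 <- map8to3(pred)
  ref3 <- map8to3(ref)
  st8 <- shape_states(); st3 <- c("S", "H", "T")

  # per-chain sufficient pieces, computed once
  a8 <- purrr::map2(pred, ref, acc_counts, states = st8)
  a3 <- purrr::map2(pred3, ref3, acc_counts, states = st3)
  v8 <- purrr::map2(pred, ref, sov_parts, states = st8)
  v3 <- purrr::map2(pred3, ref3, sov_parts, states = st3)

  total_of <- function(idx, metric) {
    switch(metric,
      s8 = {x <- Reduce(`+`, lapply(a8[idx], function(p) c(sum(p$n), sum(p$m))))
            100 * x[1] / x[2]},
      s3 = {x <- Reduce(`+`, lapply(a3[idx], function(p) c(sum(p$n), sum(p$m))))
            100 * x[1] / x[2]},
      sov8 = {x <- Reduce(`+`, lapply(v8[idx], function(p) c(sum(p$num), sum(p$den))))
              100 * x[1] / x[2]},
      sov3 = {x <- Reduce(`+`, lapply(v3[idx], function(p) c(sum(p$num), sum(p$den))))
              100 * x[1] / x[2]})
  }

  m <- ceiling(frac * n)
  set.seed(seed)
  draws <- matrix(0, nrow = reps, ncol = length(metrics),
                  dimnames = list(NULL, metrics))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, m)
    for (mt in metrics) draws[r, mt] <- total_of(idx, mt)
  }
  tibble(metric = metrics,
         mean = unname(colMeans(draws)),
         se = unname(apply(draws, 2, stats::sd)),
         reps = reps, frac = frac)
}
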