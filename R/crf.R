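## Linear-chain CRF over the 14 categorical per-residue features
## (6 shift letters + 8 profile letters). Observation features are the
## base features at every offset in a +/-window context, one indicator
## per (slot, letter); one label-bigram (transition) feature family.
## Training maximizes the L2-penalized conditional log-likelihood with
## L-BFGS; inner recursions are compiled (src/crf.cpp).

# 11 alphabet letters + boundary token for out-of-range offsets
CRF_LETTERS <- function() c(shift_letters(), "^")

#' Expand base features into windowed CRF observations
#'
#' Combines the six shift letters and eight profile letters of a chain
#' into the 14 base features, then emits each base feature at every
#' offset in `[-window, window]` (boundary token `^` beyond the chain
#' ends). The result is an integer matrix of feature indicator ids,
#' one row per residue, `14 * (2*window + 1)` columns.
#'
#' @param shift_letters A tibble from [alphabetize_shifts()] (or any
#'   table with the six atom letter columns), one chain.
#' @param profile_letters A tibble from [alphabetize_profile()] with
#'   the eight letter columns, or `NULL` to use all-"N" profile
#'   features (shift-only models).
#' @param window Context half-width (default 3).
#' @param features Which base features to keep: a character vector
#'   drawn from `c(shift_atoms(), shape_states())`; dropped features
#'   still occupy their slots but always emit the vacancy letter, so
#'   models with different feature subsets share one id space.
#' @return Integer matrix of class `crf_features` with attributes
#'   `window` and `n_feature_ids`.
#' @export
crf_featurize <- function(shift_letters, profile_letters = NULL, window = 3,
                          features = c(shift_atoms(), shape_states())) {
  if (is.null(shift_letters) && is.null(profile_letters)) {
    abort("at least one feature table is required")
  }
  L <- if (!is.null(shift_letters)) nrow(shift_letters) else nrow(profile_letters)
  base <- matrix("N", nrow = L, ncol = 14,
                 dimnames = list(NULL, c(shift_atoms(), shape_states())))
  if (!is.null(shift_letters)) {
    base[, shift_atoms()] <- as.matrix(shift_letters[, shift_atoms()])
  }
  if (!is.null(profile_letters)) {
    if (nrow(profile_letters) != L) abort("feature table lengths differ")
    base[, shape_states()] <- as.matrix(profile_letters[, shape_states()])
  }
  drop <- setdiff(colnames(base), features)
  if (length(drop) > 0) base[, drop] <- "N"
  bad <- setdiff(unique(as.vector(base)), shift_letters())
  if (length(bad) > 0) {
    abort(sprintf("invalid feature letter '%s'", bad[1]))
  }
  crf_expand(base, window)
}

# base: L x 14 character matrix -> L x (14*(2w+1)) integer id matrix
crf_expand <- function(base, window) {
  L <- nrow(base)
  nl <- length(CRF_LETTERS())
  offsets <- -window:window
  n_slot <- 14L * length(offsets)
  ids <- matrix(0L, nrow = L, ncol = n_slot)
  code <- matrix(match(base, CRF_LETTERS()), nrow = L)
  bcode <- match("^", CRF_LETTERS())
  slot <- 0L
  for (f in 1:14) {
    for (o in offsets) {
      slot <- slot + 1L
      src <- seq_len(L) + o
      v <- rep(bcode, L)
      ok <- src >= 1 & src <= L
      v[ok] <- code[src[ok], f]
      ids[, slot] <- (slot - 1L) * nl + v
    }
  }
  structure(ids, class = c("crf_features", "matrix", "array"),
            window = as.integer(window),
            n_feature_ids = as.integer(n_slot * nl))
}

#' Forward-backward and Viterbi for a linear-chain CRF
#'
#' Low-level decoders operating on log-score matrices, exposed for
#' inspection and testing. `crf_forward_backward()` returns the log
#' partition function, per-position posterior marginals (rows sum
#' to 1), and the matrix of summed pairwise transition expectations.
#' `crf_viterbi()` returns the maximum-score label path (1-based label
#' indices) and its log score.
#'
#' @param emis Numeric L x K matrix of log emission scores.
#' @param trans Numeric K x K matrix of log transition scores.
#' @return A list; see description.
#' @export
crf_forward_backward <- function(emis, trans) {
  crf_fb_cpp(as.matrix(emis), as.matrix(trans))
}

#' @rdname crf_forward_backward
#' @export
crf_viterbi <- function(emis, trans) {
  crf_viterbi_cpp(as.matrix(emis), as.matrix(trans))
}

# split a labeled chain at X runs into trainable subsequences
split_at_x <- function(ids, label_chars) {
  keep <- label_chars != "X"
  if (!any(keep)) return(list())
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    rows <- starts[r]:ends[r]
    out[[length(out) + 1]] <- list(ids = ids[rows, , drop = FALSE],
                                   y = match(label_chars[rows], shape_states()))
  }
  out
}

#' Train a shape-string CRF
#'
#' Fits a linear-chain CRF over the eight shape states from windowed
#' categorical features. The objective is the L2-penalized conditional
#' log-likelihood, maximized with L-BFGS; the fit is deterministic
#' (zero initialization), `seed` is recorded for provenance of any
#' surrounding pipeline randomness. Positions labeled X carry no
#' structural information and are handled by splitting chains at X
#' runs; X is never a predicted class.
#'
#' @param features A list of `crf_features` matrices ([crf_featurize()]),
#'   one per chain, all with the same window.
#' @param labels Character vector of shape strings, one per chain.
#' @param l2 L2 penalty weight (default 1.0).
#' @param max_iter Maximum L-BFGS iterations (default 200).
#' @param seed Integer recorded in the model metadata.
#' @param verbose Print objective trace.
#' @return An object of class `shape_crf`.
#' @export
shape_crf <- function(features, labels, l2 = 1.0, max_iter = 200,
                      seed = 1L, verbose = FALSE) {
  if (length(features) == 0 || length(features) != length(labels)) {
    abort("features and labels must be non-empty and of equal length")
  }
  window <- attr(features[[1]], "window")
  nfeat <- attr(features[[1]], "n_feature_ids")
  K <- 8L

  seqs <- list()
  for (i in seq_along(features)) {
    lab <- shape_chars(labels[i])
    if (nrow(features[[i]]) != length(lab)) {
      abort(sprintf("chain %d: feature rows != label length", i))
    }
    sub <- split_at_x(features[[i]], lab)
    if (length(sub) == 0) {
      warn(sprintf("chain %d is all-X; skipped", i))
      next
    }
    seqs <- c(seqs, sub)
  }
  if (length(seqs) == 0) abort("no trainable (non-X) positions in corpus")

  # stack all positions; X is the global sparse indicator design
  Ns <- vapply(seqs, function(s) nrow(s$ids), 0L)
  N <- sum(Ns)
  id_all <- do.call(rbind, lapply(seqs, `[[`, "ids"))
  y_all <- unlist(lapply(seqs, `[[`, "y"))
  n_active <- ncol(id_all)
  X <- Matrix::sparseMatrix(i = rep(seq_len(N), n_active),
                            j = as.vector(id_all), x = 1,
                            dims = c(N, nfeat))
  Y <- Matrix::sparseMatrix(i = seq_len(N), j = y_all, x = 1, dims = c(N, K))
  bounds <- cumsum(Ns)
  starts <- bounds - Ns + 1

  # empirical transition counts
  Tobs <- matrix(0, K, K)
  for (s in seqs) {
    y <- s$y
    if (length(y) > 1) {
      for (t in 2:length(y)) Tobs[y[t - 1], y[t]] <- Tobs[y[t - 1], y[t]] + 1
    }
  }

  n_par <- nfeat * K + K * K
  cache <- new.env(parent = emptyenv())
  cache$trace <- numeric(0)

  eval_fg <- function(par) {
    W <- matrix(par[seq_len(nfeat * K)], nfeat, K)
    tr <- matrix(par[nfeat * K + seq_len(K * K)], K, K)
    E <- as.matrix(X %*% W)
    total_logZ <- 0
    obs_score <- sum(E[cbind(seq_len(N), y_all)])
    P <- matrix(0, N, K)
    Texp <- matrix(0, K, K)
    for (q in seq_along(starts)) {
      rows <- starts[q]:bounds[q]
      fb <- crf_fb_cpp(E[rows, , drop = FALSE], tr)
      total_logZ <- total_logZ + fb$logZ
      P[rows, ] <- fb$marginals
      Texp <- Texp + fb$pair_expect
      y <- y_all[rows]
      if (length(y) > 1) {
        obs_score <- obs_score + sum(tr[cbind(y[-length(y)], y[-1])])
      }
    }
    obj <- -(obs_score - total_logZ) + 0.5 * l2 * sum(par^2)
    gW <- as.matrix(Matrix::crossprod(X, P - Y)) + l2 * W
    gT <- (Texp - Tobs) + l2 * tr
    cache$last_par <- par
    cache$last_grad <- c(as.vector(gW), as.vector(gT))
    cache$trace <- c(cache$trace, obj)
    if (verbose) message(sprintf("obj = %.6f", obj))
    obj
  }
  grad_fg <- function(par) {
    if (is.null(cache$last_par) || !identical(par, cache$last_par)) eval_fg(par)
    cache$last_grad
  }

  fit <- optim(rep(0, n_par), eval_fg, grad_fg, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1e7))

  structure(list(
    weights = matrix(fit$par[seq_len(nfeat * K)], nfeat, K,
                     dimnames = list(NULL, shape_states())),
    trans = matrix(fit$par[nfeat * K + seq_len(K * K)], K, K,
                   dimnames = list(shape_states(), shape_states())),
    window = window, n_feature_ids = nfeat, l2 = l2,
    max_iter = max_iter, seed = seed,
    objective = fit$value, convergence = fit$convergence,
    n_chains = length(labels), n_sequences = length(seqs),
    n_positions = N, trace = cache$trace
  ), class = "shape_crf")
}

#' @export
#' @method print shape_crf
print.shape_crf <- function(x, ...) {
  cat(sprintf(paste0("<shape_crf> 8 states, window +/-%d, %d feature ids\n",
                     "  trained on %d chains (%d positions); ",
                     "penalized NLL %.3f\n"),
              x$window, x$n_feature_ids, x$n_chains, x$n_positions,
              x$objective))
  invisible(x)
}

#' Decode a chain with a trained CRF
#'
#' Runs Viterbi decoding (the predicted shape string) and
#' forward-backward (per-residue posterior marginals over the eight
#' states) on one chain's features.
#'
#' @param object A `shape_crf` model.
#' @param features A `crf_features` matrix for one chain, built with
#'   the model's window.
#' @param ... Unused.
#' @return A tibble with columns `num`, `shape` and the eight marginal
#'   columns `P_S` ... `P_G`; the predicted string is also available as
#'   `attr(, "shape")`.
#' @export
predict.shape_crf <- function(object, features, ...) {
  if (!inherits(features, "crf_features")) {
    abort("features must come from crf_featurize()")
  }
  if (!identical(attr(features, "window"), object$window) ||
      !identical(attr(features, "n_feature_ids"), object$n_feature_ids)) {
    abort("feature template does not match the model (window/id space)")
  }
  L <- nrow(features)
  emis <- crf_emissions(object, features)
  vit <- crf_viterbi_cpp(emis, object$trans)
  fb <- crf_fb_cpp(emis, object$trans)
  marg <- fb$marginals
  colnames(marg) <- paste0("P_", shape_states())
  shape <- paste(shape_states()[vit$path], collapse = "")
  out <- dplyr::bind_cols(tibble(num = seq_len(L),
                                 shape = shape_states()[vit$path]),
                          as_tibble(marg))
  attr(out, "shape") <- shape
  attr(out, "viterbi_score") <- vit$score
  attr(out, "logZ") <- fb$logZ
  out
}

# log emission scores (L x 8) for an id matrix under a model
crf_emissions <- function(object, features) {
  L <- nrow(features)
  E <- matrix(0, L, 8)
  for (t in seq_len(L)) {
    E[t, ] <- colSums(object$weights[features[t, ], , drop = FALSE])
  }
  E
}

#' @export
tidy.shape_crf <- function(x, ...) {
  nl <- length(CRF_LETTERS())
  n_off <- 2 * x$window + 1
  slot <- (seq_len(x$n_feature_ids) - 1) %/% nl
  letter <- CRF_LETTERS()[(seq_len(x$n_feature_ids) - 1) %% nl + 1]
  feat <- c(shift_atoms(), shape_states())[slot %/% n_off + 1]
  offset <- (slot %% n_off) - x$window
  em <- tibble(type = "emission",
               feature = rep(feat, 8),
               offset = rep(offset, 8),
               letter = rep(letter, 8),
               state = rep(shape_states(), each = x$n_feature_ids),
               estimate = as.vector(x$weights))
  tr <- tibble(type = "transition",
               feature = NA_character_, offset = NA_integer_,
               letter = rep(shape_states(), 8),
               state = rep(shape_states(), each = 8),
               estimate = as.vector(x$trans))
  dplyr::bind_rows(em, tr)
}

#' @export
glance.shape_crf <- function(x, ...) {
  tibble(n_chains = x$n_chains, n_sequences = x$n_sequences,
         n_positions = x$n_positions, window = x$window, l2 = x$l2,
         objective = x$objective, n_iter = length(x$trace),
         converged = x$convergence == 0)
}

#' Serialize and restore a CRF model
#'
#' The on-disk form is a self-describing JSON archive (format version,
#' window, id-space size, regularization, label set, weights,
#' transitions, training metadata); reading it back reproduces the
#' model bit-for-bit.
#'
#' @param model A `shape_crf`.
#' @param path File path.
#' @return The model (reader) or `path` invisibly (writer).
#' @export
write_crf_model <- function(model, path) {
  payload <- list(
    format = "shapecrf/crf-model", version = 1L,
    labels = shape_states(), window = model$window,
    n_feature_ids = model$n_feature_ids, l2 = model$l2,
    max_iter = model$max_iter, seed = model$seed,
    objective = model$objective, convergence = model$convergence,
    n_chains = model$n_chains, n_sequences = model$n_sequences,
    n_positions = model$n_positions, trace = model$trace,
    weights = as.vector(model$weights), trans = as.vector(model$trans))
  # digits = I(17): full significant digits so doubles reload bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_crf_model
#' @export
read_crf_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "shapecrf/crf-model")) {
    abort("not a shapecrf CRF model file")
  }
  structure(list(
    weights = matrix(p$weights, p$n_feature_ids, 8,
                     dimnames = list(NULL, shape_states())),
    trans = matrix(p$trans, 8, 8,
                   dimnames = list(shape_states(), shape_states())),
    window = as.integer(p$window), n_feature_ids = as.integer(p$n_feature_ids),
    l2 = p$l2, max_iter = p$max_iter, seed = p$seed,
    objective = p$objective, convergence = p$convergence,
    n_chains = p$n_chains, n_sequences = p$n_sequences,
    n_positions = p$n_positions, trace = p$trace
  ), class = "shape_crf")
}
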