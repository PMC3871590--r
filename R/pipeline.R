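## End-to-end predictor: scale table + hallmark library + profile
## database + CRF, with chain-level cross-validation and the
## feature-ablation harness.

#' Train a shape-string predictor on an annotated corpus
#'
#' Runs the full training pipeline: fits the per-(amino acid, atom)
#' scale table, mines the hallmark-pattern library, builds per-chain
#' profile features from exact k-mer hits against the corpus (the
#' chain itself is excluded from its own hit search, so training
#' profiles behave like test-time profiles), alphabetizes everything,
#' and trains the linear-chain CRF on the 14 windowed features.
#'
#' @param corpus Nested corpus tibble (`chain_id`, `seq`, `shape`,
#'   `shifts`), e.g. from [generate_corpus()] or [read_corpus()].
#' @param features Base features to use: a subset of
#'   `c(shift_atoms(), shape_states())`. Defaults to all 14.
#' @param window CRF context half-width (default 3).
#' @param l2 CRF L2 penalty (default 1.0).
#' @param max_iter CRF optimizer iteration cap (default 200).
#' @param k Exact-match k-mer length for profile hits (default 6).
#' @param top_n Subjects kept per query (default 10).
#' @param flank Secondary-hit context half-width (default 5).
#' @param min_support Hallmark frequency criterion (default 100).
#' @param max_p Hallmark conservation p-value cutoff (default 0.01).
#' @param seed Seed recorded in the model.
#' @param verbose Print optimizer trace.
#' @return An object of class `shape_predictor`.
#' @export
train_shape_predictor <- function(corpus,
                                  features = c(shift_atoms(), shape_states()),
                                  window = 3, l2 = 1.0, max_iter = 200,
                                  k = 6, top_n = 10, flank = 5,
                                  min_support = 100, max_p = 0.01,
                                  seed = 1L, verbose = FALSE) {
  if (nrow(corpus) == 0) abort("training corpus is empty")
  use_shifts <- any(features %in% shift_atoms())
  use_profile <- any(features %in% shape_states())
  if (!use_shifts && !use_profile) abort("no features selected")

  scale <- fit_scale_table(corpus_shifts(corpus))
  db <- corpus[, c("chain_id", "seq", "shape")]
  hallmarks <- NULL
  if (use_profile) {
    hallmarks <- mine_hallmarks(db, min_support = min_support, max_p = max_p)
  }

  feats <- purrr::map(seq_len(nrow(corpus)), function(i) {
    sl <- if (use_shifts) {
      alphabetize_shifts(corpus$shifts[[i]], scale, strict = FALSE)
    }
    pl <- if (use_profile) {
      chain_profile_letters(corpus$seq[i], db[db$chain_id != corpus$chain_id[i], ],
                            hallmarks, k, top_n, flank)
    }
    crf_featurize(sl, pl, window = window, features = features)
  })
  crf <- shape_crf(feats, corpus$shape, l2 = l2, max_iter = max_iter,
                   seed = seed, verbose = verbose)

  structure(list(scale = scale, hallmarks = hallmarks, db = db, crf = crf,
                 config = list(features = features, window = window, l2 = l2,
                               max_iter = max_iter, k = k, top_n = top_n,
                               flank = flank, min_support = min_support,
                               max_p = max_p, seed = seed)),
            class = "shape_predictor")
}

# profile letter table for one chain against a database
chain_profile_letters <- function(seq, db, hallmarks, k, top_n, flank) {
  hits <- kmer_hits(seq, db, k = k)
  prof <- build_profile(seq, hits, patterns = hallmarks, corpus = db,
                        top_n = top_n, flank = flank)
  alphabetize_profile(prof)
}

#' @export
#' @method print shape_predictor
print.shape_predictor <- function(x, ...) {
  cat(sprintf(paste0("<shape_predictor> %d-chain database, %s\n",
                     "  features: %s\n"),
              nrow(x$db),
              if (is.null(x$hallmarks)) "no hallmark library" else
                sprintf("%d hallmark pattern rows",
                        length(unique(x$hallmarks$pattern))),
              paste(x$config$features, collapse = ",")))
  print(x$crf)
  invisible(x)
}

#' Predict shape strings for new chains
#'
#' Applies a trained [train_shape_predictor()] model. `newdata` may be
#' a single chain's per-residue shift tibble (as from [read_shifty()])
#' or a nested corpus tibble with a `shifts` list-column; profile
#' features are computed against the predictor's stored database.
#'
#' @param object A `shape_predictor`.
#' @param newdata Shift tibble or nested corpus.
#' @param ... Unused.
#' @return For a single chain, a per-residue tibble (`num`, `aa`,
#'   `shape`, `P_S` ... `P_G`) with the predicted string in
#'   `attr(, "shape")`; for a corpus, the corpus with added `pred`
#'   (string) and `prediction` (per-residue tibble) columns.
#' @export
predict.shape_predictor <- function(object, newdata, ...) {
  if (!is.null(newdata[["shifts"]]) && is.list(newdata[["shifts"]])) {
    preds <- purrr::map(newdata$shifts, function(sh)
      predict_chain(object, sh))
    newdata$pred <- vapply(preds, attr, "", "shape")
    newdata$prediction <- preds
    return(newdata)
  }
  predict_chain(object, newdata)
}

predict_chain <- function(object, shifts) {
  check_shift_tbl(shifts)
  cfg <- object$config
  use_shifts <- any(cfg$features %in% shift_atoms())
  use_profile <- any(cfg$features %in% shape_states())
  seq <- paste(shifts$aa, collapse = "")
  sl <- if (use_shifts) alphabetize_shifts(shifts, object$scale, strict = FALSE)
  pl <- if (use_profile) {
    db <- object$db[object$db$chain_id != shifts$chain_id[1], ]
    chain_profile_letters(seq, db, object$hallmarks,
                          cfg$k, cfg$top_n, cfg$flank)
  }
  fx <- crf_featurize(sl, pl, window = cfg$window, features = cfg$features)
  out <- predict(object$crf, fx)
  out$aa <- shifts$aa
  out[, c("num", "aa", "shape", paste0("P_", shape_states()))]
}

#' Chain-level k-fold cross-validation
#'
#' Splits the corpus into `folds` chain-level folds (residue-level
#' splits would leak sequence context), trains a predictor on each
#' training portion, predicts the held-out chains, and evaluates the
#' pooled out-of-fold predictions.
#'
#' @inheritParams train_shape_predictor
#' @param folds Number of folds (default 5; must be >= 2).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [train_shape_predictor()].
#' @return A one-row tibble `s8`, `sov8`, `s3`, `sov3`, `n_chains`,
#'   with the pooled predictions in `attr(, "predictions")` (tibble
#'   `chain_id`, `fold`, `pred`, `ref`).
#' @export
cross_validate <- function(corpus, folds = 5, seed = 1L, ...) {
  n <- nrow(corpus)
  if (folds < 2) abort("need at least 2 folds")
  if (folds > n) abort("more folds than chains")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  preds <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- corpus[fold_id != f, ]
    te <- corpus[fold_id == f, ]
    mod <- train_shape_predictor(tr, seed = seed, ...)
    out <- predict(mod, te)
    tibble(chain_id = te$chain_id, fold = f, pred = out$pred,
           ref = te$shape)
  })
  ev <- glance(evaluate_prediction(preds$pred, preds$ref))
  out <- dplyr::mutate(ev, folds = folds)
  attr(out, "predictions") <- preds
  out
}

#' Leave-one-feature-out and feature-combination ablation
#'
#' Reproduces the standard feature-importance design with chain-level
#' k-fold cross-validation: six conditions each dropping one
#' chemical-shift feature (shift features only), the all-six-shifts
#' condition, and optionally the combination conditions (shift-only,
#' profile-only, combined 14 features).
#'
#' @inheritParams cross_validate
#' @param combinations Also run the shift/profile/combined conditions.
#' @param ... Passed to [train_shape_predictor()].
#' @return A tibble with one row per condition: `condition`,
#'   `features`, `s8`, `sov8`, `s3`, `sov3`.
#' @export
ablate_features <- function(corpus, folds = 5, seed = 1L,
                            combinations = FALSE, ...) {
  conds <- list()
  for (a in shift_atoms()) {
    conds[[paste0("minus_", a)]] <- setdiff(shift_atoms(), a)
  }
  conds[["all_shifts"]] <- shift_atoms()
  if (combinations) {
    conds[["profile_only"]] <- shape_states()
    conds[["combined"]] <- c(shift_atoms(), shape_states())
  }
  purrr::imap_dfr(conds, function(feat, name) {
    cv <- cross_validate(corpus, folds = folds, seed = seed,
                         features = feat, ...)
    tibble(condition = name, features = paste(feat, collapse = ","),
           s8 = cv$s8, sov8 = cv$sov8, s3 = cv$s3, sov3 = cv$sov3)
  })
}

#' Save and load a trained predictor
#'
#' Writes the predictor as a directory of plain-text artifacts:
#' `scale_table.tsv`, `hallmarks.tsv` (if mined), `crf_model.json`,
#' `database.tsv` (the profile database), and `config.json`.
#'
#' @param object A `shape_predictor`.
#' @param dir Directory path.
#' @return `dir` invisibly (writer); a `shape_predictor` (reader).
#' @export
write_predictor <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scale_table(object$scale, file.path(dir, "scale_table.tsv"))
  if (!is.null(object$hallmarks)) {
    write_hallmarks(object$hallmarks, file.path(dir, "hallmarks.tsv"))
  }
  write_crf_model(object$crf, file.path(dir, "crf_model.json"))
  write.table(object$db, file.path(dir, "database.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(object$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  hp <- file.path(dir, "hallmarks.tsv")
  structure(list(
    scale = read_scale_table(file.path(dir, "scale_table.tsv")),
    hallmarks = if (file.exists(hp)) read_hallmarks(hp),
    db = as_tibble(read.delim(file.path(dir, "database.tsv"))),
    crf = read_crf_model(file.path(dir, "crf_model.json")),
    config = cfg), class = "shape_predictor")
}

#' Read a corpus directory
#'
#' Inverse of [write_corpus()]: reads every `*.shifty` file plus
#' `shapes.txt` (and `torsions.tsv` when present) into a nested corpus
#' tibble.
#'
#' @param dir Directory written by [write_corpus()] (or assembled by
#'   hand in the same layout).
#' @return A nested corpus tibble.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.shifty$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no .shifty files under %s", dir))
  shifts <- purrr::map(files, read_shifty)
  shapes <- read_shape_strings(file.path(dir, "shapes.txt"))
  out <- tibble(chain_id = vapply(shifts, function(s) s$chain_id[1], ""),
                seq = vapply(shifts, function(s) paste(s$aa, collapse = ""), ""),
                shifts = shifts) |>
    dplyr::left_join(shapes, by = "chain_id") |>
    dplyr::relocate("shape", .after = "seq")
  if (anyNA(out$shape)) {
    abort("shapes.txt lacks a record for some chains")
  }
  bad <- nchar(out$seq) != nchar(out$shape)
  if (any(bad)) {
    abort(sprintf("chain %s: shape string length differs from sequence",
                  out$chain_id[bad][1]))
  }
  tp <- file.path(dir, "torsions.tsv")
  if (file.exists(tp)) {
    tors <- as_tibble(read.delim(tp))
    out$torsions <- purrr::map(out$chain_id, function(cid) {
      tors[tors$chain_id == cid, c("num", "phi", "psi")]
    })
  }
  out
}
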