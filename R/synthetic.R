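## Synthetic (sequence, shape string, chemical shift, torsion) corpora
## with the statistical structure the predictor assumes: shape states
## follow a first-order Markov chain with an imbalanced stationary
## distribution (helix-dominant, as real shape-string corpora are);
## shifts are Gaussian around a per-(amino acid, atom) base mean plus a
## shape-state offset whose size is the separation parameter; torsions
## are drawn inside the region of the sampled letter so torsion-based
## assignment reproduces the labels exactly.

# shape-state offset codes: 8 sign patterns over the 6 atoms with
# minimum pairwise Hamming distance 3 (extended parity code), so any
# two states differ in at least half the atoms
shape_codes <- function() {
  b <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1)
  m <- cbind(b$b1, b$b2, b$b3,
             (b$b1 + b$b2) %% 2, (b$b1 + b$b3) %% 2, (b$b2 + b$b3) %% 2)
  m <- 2 * m - 1
  dimnames(m) <- list(shape_states(), shift_atoms())
  m
}

# realistic base positions/widths per atom (ppm)
ATOM_BASE <- data.frame(
  atom = c("HA", "H", "N", "CA", "CB", "C"),
  mean = c(4.3, 8.3, 119.0, 57.0, 35.0, 176.0),
  sd   = c(0.4, 0.5, 3.5, 2.0, 3.0, 1.5)
)

#' Configuration for the synthetic corpus generator
#'
#' Collects and validates the generator's knobs. Defaults encode the
#' study conditions the rest of the package is exercised under:
#' chains of 50-150 residues; an eight-state Markov chain with
#' self-transition bias 0.82 (mean run length about 5-6 residues, the
#' scale of secondary-structure segments) and a helix-dominant
#' stationary distribution (A 40%, S 20%, R 12%, the rest spread
#' thinly); shift emissions separated between shape states by
#' `separation` standard deviations along fixed sign codes; 10% of
#' cells vacant.
#'
#' @param n_chains Number of chains (default 200).
#' @param len_range Integer min/max chain length (default c(50, 150)).
#' @param self_bias Markov self-transition probability mass
#'   (default 0.82).
#' @param stationary Named stationary frequencies over the eight
#'   states; default A-dominant imbalance.
#' @param separation Shape-state shift separation `s`, in units of
#'   each atom's SD (default 2; 0 gives a null corpus whose shifts
#'   carry no shape information).
#' @param missingness Per-cell vacancy probability in [0, 1)
#'   (default 0.1).
#' @param emission Emission family, `"gaussian"` (default) or
#'   `"student_t"` (df 3; heavy tails to stress range clipping).
#' @param seed RNG seed used by [generate_corpus()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chains = 200, len_range = c(50, 150),
                         self_bias = 0.82,
                         stationary = c(S = 0.20, R = 0.12, U = 0.056,
                                        V = 0.056, K = 0.056, A = 0.40,
                                        T = 0.056, G = 0.056),
                         separation = 2, missingness = 0.1,
                         emission = c("gaussian", "student_t"),
                         seed = 1L) {
  emission <- match.arg(emission)
  stationary <- stationary[shape_states()]
  if (anyNA(stationary) || any(stationary <= 0)) {
    abort("stationary must give positive mass to all eight states")
  }
  stationary <- stationary / sum(stationary)
  if (self_bias < 0 || self_bias >= 1) abort("self_bias must be in [0, 1)")
  if (missingness < 0 || missingness >= 1) {
    abort("missingness must be in [0, 1)")
  }
  if (length(len_range) != 2 || len_range[1] < 2 ||
      len_range[2] < len_range[1]) {
    abort("len_range must be c(min, max) with 2 <= min <= max")
  }
  trans <- self_bias * diag(8) +
    (1 - self_bias) * matrix(stationary, 8, 8, byrow = TRUE)
  dimnames(trans) <- list(shape_states(), shape_states())
  if (any(abs(rowSums(trans) - 1) > 1e-12)) {
    abort("transition rows must sum to 1")
  }
  structure(list(n_chains = n_chains, len_range = as.integer(len_range),
                 self_bias = self_bias, stationary = stationary,
                 trans = trans, separation = separation,
                 missingness = missingness, emission = emission,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# sample torsions uniformly inside a letter's region; rejection keeps
# the first-match/glycine-override semantics exact
sample_torsion <- function(letter, aa, regions) {
  rows <- which(regions$letter == letter &
                  (regions$glycine_only == (letter == "G")))
  area <- (regions$phi_hi[rows] - regions$phi_lo[rows]) *
    (regions$psi_hi[rows] - regions$psi_lo[rows])
  repeat {
    r <- rows[sample.int(length(rows), 1, prob = area)]
    phi <- runif(1, regions$phi_lo[r], regions$phi_hi[r])
    psi <- runif(1, regions$psi_lo[r], regions$psi_hi[r])
    if (assign_shape(phi, psi, aa, regions) == letter) {
      return(c(phi, psi))
    }
  }
}

#' Generate a synthetic annotated corpus
#'
#' Draws chains under a [synth_config()]: shape strings from the
#' Markov chain, amino acids uniformly over the 20 standard residues
#' (glycine forced wherever the state is G, since shape G is reserved
#' for glycine), torsions uniformly within each label's region of the
#' torsion table, and shifts from the emission model with vacancies
#' dropped at the missingness rate. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param regions Torsion-region table (default [torsion_regions()]).
#' @return A nested tibble with one row per chain: `chain_id`, `seq`,
#'   `shape`, `shifts` (list of per-residue shift tibbles) and
#'   `torsions` (list of tibbles `num`, `phi`, `psi`).
#' @export
generate_corpus <- function(cfg, regions = torsion_regions()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  codes <- shape_codes()
  states <- shape_states()
  aa_pool <- AA20

  one_chain <- function(i) {
    L <- cfg$len_range[1] +
      sample.int(cfg$len_range[2] - cfg$len_range[1] + 1L, 1) - 1L
    y <- integer(L)
    y[1] <- sample.int(8, 1, prob = cfg$stationary)
    for (t in 2:L) y[t] <- sample.int(8, 1, prob = cfg$trans[y[t - 1], ])
    lab <- states[y]
    aa <- ifelse(lab == "G", "G", sample(aa_pool, L, replace = TRUE))
    tor <- t(vapply(seq_len(L),
                    function(t) sample_torsion(lab[t], aa[t], regions),
                    c(0, 0)))
    shifts <- matrix(NA_real_, L, 6, dimnames = list(NULL, shift_atoms()))
    for (j in 1:6) {
      base <- ATOM_BASE$mean[j] + aa_offset(aa, j)
      mu <- base + cfg$separation * codes[y, j] * ATOM_BASE$sd[j]
      noise <- if (cfg$emission == "gaussian") {
        rnorm(L, 0, ATOM_BASE$sd[j])
      } else {
        stats::rt(L, df = 3) * ATOM_BASE$sd[j]
      }
      shifts[, j] <- round(mu + noise, 4)
    }
    if (cfg$missingness > 0) {
      shifts[matrix(runif(L * 6) < cfg$missingness, L, 6)] <- NA_real_
    }
    cid <- sprintf("syn%04d", i)
    tibble(chain_id = cid,
           seq = paste(aa, collapse = ""),
           shape = paste(lab, collapse = ""),
           shifts = list(dplyr::bind_cols(
             tibble(chain_id = cid, num = seq_len(L), aa = aa),
             as_tibble(shifts))),
           torsions = list(tibble(num = seq_len(L),
                                  phi = tor[, 1], psi = tor[, 2])))
  }
  purrr::map_dfr(seq_len(cfg$n_chains), one_chain)
}

# deterministic per-amino-acid spread so all 120 (aa, atom) ranges differ
aa_offset <- function(aa, atom_idx) {
  i <- match(aa, AA20)
  ((i - 1) / 19 - 0.5) * ATOM_BASE$sd[atom_idx]
}

#' Split a synthetic corpus into train and test sets
#'
#' Disjoint chain-level split: generates the corpus under `cfg` and
#' assigns `ceiling(train_frac * n)` chains to the training set.
#' Deterministic given `seed` (default `cfg$seed`).
#'
#' @param cfg A [synth_config()].
#' @param train_frac Fraction of chains in the training set, in (0, 1).
#' @param seed Split seed.
#' @param regions Torsion-region table.
#' @return A list with elements `train` and `test` (nested tibbles).
#' @export
generate_split <- function(cfg, train_frac = 0.8, seed = cfg$seed,
                           regions = torsion_regions()) {
  if (train_frac <= 0 || train_frac >= 1) {
    abort("train_frac must be in (0, 1)")
  }
  corpus <- generate_corpus(cfg, regions)
  set.seed(seed + 1e6)
  n <- nrow(corpus)
  idx <- sample.int(n, ceiling(train_frac * n))
  list(train = corpus[sort(idx), ], test = corpus[-sort(idx), ])
}

#' Flatten a corpus's shift tables
#'
#' Row-binds the per-chain shift tibbles of a nested corpus into one
#' long per-residue table (the form [fit_scale_table()] consumes).
#'
#' @param corpus A nested corpus tibble.
#' @return A per-residue shift tibble.
#' @export
corpus_shifts <- function(corpus) {
  dplyr::bind_rows(corpus$shifts)
}

#' Write a corpus to disk in the toolkit's exchange formats
#'
#' One SHIFTY file per chain plus FASTA-like shape strings and a
#' torsion TSV, under `dir`.
#'
#' @param corpus A nested corpus tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus))) {
    write_shifty(corpus$shifts[[i]],
                 file.path(dir, paste0(corpus$chain_id[i], ".shifty")))
  }
  write_shape_strings(corpus[, c("chain_id", "shape")],
                      file.path(dir, "shapes.txt"))
  tors <- purrr::map2_dfr(corpus$chain_id, corpus$torsions,
                          ~ dplyr::mutate(.y, chain_id = .x, .before = 1))
  write.table(tors, file.path(dir, "torsions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
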