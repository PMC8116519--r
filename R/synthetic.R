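# Self-contained fixtures: toy structures, analytic scoring oracles,
# discrete ensembles and exhaustive enumeration. Everything is seeded and
# leaves the caller's RNG stream untouched.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.SIDECHAIN_ATOMS <- list(
  c("CB", "C"), c("CG", "C"), c("OG", "O"), c("ND1", "N"),
  c("SD", "S"), c("CD", "C"), c("OE1", "O"), c("NE2", "N")
)

#' Generate a toy protein-like structure
#'
#' A self-avoiding chain of pseudo-residues, each carrying 1-8 heavy atoms
#' drawn from \{C, N, O, S\} (the first up to four atoms of a residue are the
#' backbone N/CA/C/O), with residue names drawn from the 20 standard codes.
#' Residue centers follow a random walk with 0.5 nm steps; atoms are placed
#' around their center with a guaranteed minimum inter-atom separation of
#' 0.05 nm. Deterministic under `seed`; the caller's RNG state is preserved.
#'
#' This is a statistical stand-in for a reference protein conformation: it
#' satisfies every contact-graph invariant but makes no attempt at realistic
#' stereochemistry.
#'
#' @param n_residues Number of pseudo-residues (>= 1).
#' @param seed Integer seed.
#' @return An [atom_table()].
#' @export
make_toy_structure <- function(n_residues, seed = 1L) {
  stopifnot(n_residues >= 1)
  with_local_seed(seed, {
    centers <- matrix(0, n_residues, 3)
    for (r in seq_len(n_residues)[-1]) {
      repeat {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- centers[r - 1, ] + 0.5 * dir
        prev <- centers[seq_len(r - 1), , drop = FALSE]
        if (min(sqrt(rowSums((prev - matrix(cand, r - 1, 3, byrow = TRUE))^2))) > 0.45) {
          centers[r, ] <- cand
          break
        }
      }
    }
    element <- character(0); aname <- character(0)
    rname <- character(0); ridx <- integer(0)
    xyz <- matrix(numeric(0), ncol = 3)
    backbone <- list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))
    for (r in seq_len(n_residues)) {
      k <- sample.int(8L, 1L)
      res <- sample(names(RESIDUE_CLASS), 1L)
      spots <- c(backbone[seq_len(min(k, 4L))],
                 if (k > 4L) .SIDECHAIN_ATOMS[seq_len(k - 4L)])
      for (s in spots) {
        placed <- FALSE
        for (try in seq_len(500)) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          pos <- centers[r, ] + stats::runif(1, 0.08, 0.28) * dir
          ok <- nrow(xyz) == 0 ||
            min(sqrt(rowSums((xyz - matrix(pos, nrow(xyz), 3, byrow = TRUE))^2))) >= 0.06
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place atom with 0.05 nm separation")
        xyz <- rbind(xyz, pos)
        element <- c(element, s[2]); aname <- c(aname, s[1])
        rname <- c(rname, res); ridx <- c(ridx, r)
      }
    }
    atom_table(element, aname, rname, ridx, xyz)
  })
}

#' Analytic scoring oracle over CG mappings of a toy structure
#'
#' `make_toy_oracle` returns a deterministic function
#' `cg_mapping -> score` with
#' `score = a * sum of inverse distances over retained pairs within cutoff
#'        + b * number of retained backbone atoms
#'        + c * roughness(mapping, seed)`,
#' where the roughness term is a seeded hash of the retained set mapped to
#' `[-1, 1]`. With `c = 0` the landscape is smooth and shares the contact
#' graph's inverse-distance structure (so a graph network can represent it);
#' large `c` makes it unlearnable. The score does not depend on the listing
#' order of the retained indices.
#'
#' @param structure An [atom_table()].
#' @param a,b,c Term coefficients (defaults 1, 0.5, 0).
#' @param seed Seed of the roughness hash.
#' @param cutoff Pair-interaction cutoff in nm (default 1.0, matching the
#'   default contact graph).
#' @return A function `cg_mapping -> numeric`, with the precomputed pair
#'   matrix attached as attribute `"pair_matrix"`.
#' @export
make_toy_oracle <- function(structure, a = 1, b = 0.5, c = 0,
                            seed = 0L, cutoff = 1.0) {
  stopifnot(inherits(structure, "atom_table"))
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  W <- ifelse(d > 0 & d < cutoff, 1 / d, 0)
  diag(W) <- 0
  bkb <- as.numeric(structure$is_backbone)
  n <- nrow(xyz)
  score_retained <- function(retained) {
    idx <- retained + 1L
    base <- a * sum(W[idx, idx]) / 2 + b * sum(bkb[idx])
    if (c != 0) base <- base + c * roughness_hash(retained, seed)
    base
  }
  f <- function(mapping) {
    stopifnot(inherits(mapping, "cg_mapping"), mapping$n == n)
    score_retained(mapping$retained)
  }
  attr(f, "pair_matrix") <- W
  # fast path used by the samplers: score a raw 0-based index vector
  attr(f, "score_retained") <- score_retained
  f
}

#' @rdname make_toy_oracle
#' @param mapping A [cg_mapping()] to score directly.
#' @export
toy_oracle_score <- function(structure, mapping, a = 1, b = 0.5, c = 0,
                             seed = 0L, cutoff = 1.0) {
  make_toy_oracle(structure, a, b, c, seed, cutoff)(mapping)
}

# deterministic hash of a sorted index set -> [-1, 1]
roughness_hash <- function(retained, seed) {
  P <- 2147483647
  h <- (as.numeric(seed) %% P)
  for (i in sort(as.integer(retained))) {
    h <- (h * 31 + i + 1) %% P
  }
  2 * (h / P) - 1
}

#' Generate a labeled data set of CG mappings
#'
#' Mirrors the composition used to train the surrogate: `n_random` mappings
#' drawn uniformly from the fixed-`N` space plus `n_optimized` mappings
#' produced by independent simulated-annealing minimizations of the oracle,
#' the SA runs divided into four equal groups by run length (`sa_steps`
#' presets). Every mapping is labeled with its oracle score and tagged with
#' its origin.
#'
#' @param structure An [atom_table()].
#' @param oracle A scoring function from [make_toy_oracle()] (or any
#'   `cg_mapping -> numeric`).
#' @param n_random Number of uniformly random samples.
#' @param n_optimized Number of SA-optimized samples (split over the four
#'   run-length groups round-robin).
#' @param N Retained atoms per mapping.
#' @param seed Master seed; each SA run gets a derived seed.
#' @param sa_steps Four SA run lengths (defaults 20000, 10000, 5000, 2500).
#' @return List of samples, each `list(mapping, smap, origin)` with origin
#'   `"random"` or `"optimized"`.
#' @export
make_mapping_dataset <- function(structure, oracle, n_random, n_optimized, N,
                                 seed = 1L,
                                 sa_steps = c(20000L, 10000L, 5000L, 2500L)) {
  stopifnot(n_random >= 0, n_optimized >= 0, length(sa_steps) == 4L)
  n <- nrow(structure)
  stopifnot(N <= n)
  samples <- vector("list", n_random + n_optimized)
  with_local_seed(seed, {
    for (i in seq_len(n_random)) {
      m <- random_mapping(n, N)
      samples[[i]] <- list(mapping = m, smap = oracle(m), origin = "random")
    }
    sa_seeds <- sample.int(2^30, max(n_optimized, 1L))
    for (j in seq_len(n_optimized)) {
      steps <- sa_steps[((j - 1L) %% 4L) + 1L]
      res <- simulated_annealing(oracle, n, N,
                                 sa_config(steps = steps, seed = sa_seeds[j]))
      samples[[n_random + j]] <- list(mapping = res$best_mapping,
                                      smap = res$best_score,
                                      origin = "optimized")
    }
  })
  samples
}

#' Write / read a mapping data set as JSON Lines
#'
#' One object per line: `{"retained": [sorted 0-based indices],
#' "smap": float, "origin": "random"|"optimized"}`.
#'
#' @param samples List of samples as from [make_mapping_dataset()].
#' @param path File path.
#' @param n Total atom count (needed to rebuild `cg_mapping`s on read).
#' @return `read_mapping_dataset` returns the sample list.
#' @export
write_mapping_dataset <- function(samples, path) {
  lines <- vapply(samples, function(s) {
    jsonlite::toJSON(list(retained = s$mapping$retained, smap = s$smap,
                          origin = s$origin),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mapping_dataset
#' @export
read_mapping_dataset <- function(path, n) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    list(mapping = cg_mapping(n, x$retained), smap = x$smap, origin = x$origin)
  })
}

#' Generate a discrete ensemble realizing a discrete system
#'
#' Draws `n_frames` microstates i.i.d. from the system's probabilities and
#' equips each frame with two synthetic atoms whose coordinates encode,
#' respectively, the macrostate label (atom 0) and the microstate identity
#' (atom 1). Retaining atom 0 therefore makes [assign_macrostates()] with
#' tolerance 0 recover the generating partition exactly, while the identity
#' mapping resolves individual microstates. Energies are assigned per
#' microstate via `energy_map`.
#'
#' @param system A [discrete_system()].
#' @param n_frames Number of frames (>= 2).
#' @param energy_map Numeric vector, one energy (kJ/mol) per microstate.
#' @param seed Integer seed.
#' @param beta Inverse temperature passed to [cg_ensemble()].
#' @return List: `ensemble` (a [cg_ensemble()]), `microstate` (1-based
#'   per-frame microstate index), `labels` (0-based per-frame macrostate
#'   labels, dense by first appearance).
#' @export
make_discrete_ensemble <- function(system, n_frames, energy_map, seed = 1L,
                                   beta = 1 / (KB_KJ_MOL_K * 300)) {
  stopifnot(inherits(system, "discrete_system"), n_frames >= 2,
            length(energy_map) == length(system$p))
  micro <- with_local_seed(seed, {
    sample.int(length(system$p), n_frames, replace = TRUE, prob = system$p)
  })
  frames <- array(0, dim = c(n_frames, 2, 3))
  frames[, 1, 1] <- system$partition[micro]
  frames[, 2, 1] <- micro
  frames[, 2, 2] <- 1
  ens <- cg_ensemble(frames, energy_map[micro], beta)
  lab <- system$partition[micro]
  list(ensemble = ens,
       microstate = micro,
       labels = as.integer(factor(lab, levels = unique(lab))) - 1L)
}

#' Enumerate all fixed-size mappings of a small space
#'
#' @param n,N Space dimensions with `choose(n, N) <= 1e6`.
#' @return Integer matrix, one row per mapping, of 0-based retained indices.
#' @export
enumerate_mappings <- function(n, N) {
  cnt <- as.numeric(count_mappings(n, N))
  if (!is.finite(cnt) || cnt > 1e6) {
    stop("mapping space too large to enumerate: ", count_mappings(n, N),
         " subsets")
  }
  t(utils::combn(n, N)) - 1L
}

#' Exact density of states by exhaustive enumeration
#'
#' Enumerates every mapping of the space, scores each with the oracle, and
#' histograms the scores. When `bins` is a [wl_config()], the Wang-Landau
#' bin edges (half-open, top edge closed) are used so that the counts are
#' directly comparable with a WL reconstruction.
#'
#' @param oracle Function `cg_mapping -> numeric`.
#' @param n,N Space dimensions with `choose(n, N) <= 1e6`.
#' @param bins Either an integer number of equal-width bins spanning the
#'   score range, or a [wl_config()].
#' @return List: `counts` per bin, `mids` (bin centers), `breaks`, `scores`
#'   (all enumerated scores, in enumeration order).
#' @export
exhaustive_dos <- function(oracle, n, N, bins = 25L) {
  maps <- enumerate_mappings(n, N)
  scores <- vapply(seq_len(nrow(maps)), function(i) {
    oracle(cg_mapping(n, maps[i, ]))
  }, numeric(1))
  if (inherits(bins, "wl_config")) {
    nb <- bins$n_bins
    idx <- vapply(scores, function(s) bin_index(s, bins), numeric(1))
    if (anyNA(idx)) {
      counts <- tabulate(idx[!is.na(idx)] + 1L, nbins = nb)
    } else {
      counts <- tabulate(idx + 1L, nbins = nb)
    }
    breaks <- bins$s_min + bins$delta_s * (0:nb)
  } else {
    nb <- as.integer(bins)
    rng <- range(scores)
    breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
    idx <- pmin(findInterval(scores, breaks, rightmost.closed = TRUE), nb)
    counts <- tabulate(idx, nbins = nb)
  }
  list(counts = counts, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       breaks = breaks, scores = scores)
}
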