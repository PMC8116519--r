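#' Boltzmann constant in kJ/mol/K
#'
#' Fixed so that all mapping-entropy outputs carry kJ/mol/K.
#' @export
KB_KJ_MOL_K <- 0.0083145

#' Discrete system: microstate probabilities plus a coarse-graining partition
#'
#' The discrete analogue of observing a molecular system through a CG
#' mapping: `m` microstates with probabilities `p`, partitioned into
#' macrostates by `partition` (one label per microstate; the label plays the
#' role of the CG configuration all its microstates map onto).
#'
#' @param p Non-negative probability vector summing to 1 (within 1e-12).
#' @param partition Vector of macrostate labels, one per microstate.
#' @return A `discrete_system`.
#' @export
discrete_system <- function(p, partition) {
  p <- as.numeric(p)
  stopifnot(length(p) >= 1L, length(partition) == length(p))
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1 (got ", sum(p), ")")
  structure(list(p = p, partition = as.integer(factor(partition))),
            class = "discrete_system")
}

#' Exact mapping entropy of a discrete system
#'
#' The mapping entropy is the Kullback-Leibler divergence between the
#' microstate distribution `p_r` and the distribution `pbar_r` obtained by
#' spreading each macrostate's probability uniformly over its members:
#' `pbar_r = p_R(macro(r)) / Omega1(macro(r))`, where `p_R` is the macrostate
#' probability and `Omega1` the number of microstates mapping onto it.
#' Terms with `p_r = 0` contribute zero.
#'
#' @param system A [discrete_system()].
#' @return `S_map` in units of `k_B` (dimensionless KL divergence; multiply
#'   by [KB_KJ_MOL_K] for kJ/mol/K). Always `>= 0`.
#' @examples
#' sys <- discrete_system(c(0.5, 0.3, 0.2), c("A", "B", "B"))
#' exact_smap_discrete(sys) # ~0.01007
#' @export
exact_smap_discrete <- function(system) {
  stopifnot(inherits(system, "discrete_system"))
  p <- system$p
  lab <- system$partition
  p_macro <- tapply(p, lab, sum)
  omega <- tapply(p, lab, length)
  pbar <- (p_macro / omega)[as.character(lab)]
  live <- p > 0
  max(0, sum(p[live] * log(p[live] / pbar[live])))
}

#' Sampled ensemble of configurations with potential energies
#'
#' @param frames Numeric array `frames x atoms x 3` of heavy-atom
#'   coordinates in nm.
#' @param energies Per-frame potential energies, kJ/mol.
#' @param beta Inverse temperature `1 / (k_B T)` in mol/kJ (default: 300 K).
#' @return A `cg_ensemble`.
#' @export
cg_ensemble <- function(frames, energies, beta = 1 / (KB_KJ_MOL_K * 300)) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L) {
    stop("frames must be a frames x atoms x 3 array")
  }
  if (dim(frames)[1] != length(energies)) stop("one energy per frame required")
  if (dim(frames)[1] < 2L) stop("need at least 2 frames")
  stopifnot(beta > 0)
  structure(list(frames = frames, energies = as.numeric(energies), beta = beta),
            class = "cg_ensemble")
}

#' Group ensemble frames into CG macrostates
#'
#' Two frames belong to the same macrostate when the retained atoms of the
#' mapping (nearly) coincide: frames are grouped by single linkage under the
#' distance `d(f, g) = max over retained atoms of |x_f - x_g|` (Euclidean
#' per atom), cut at `tolerance`. Grouping is therefore the transitive
#' closure of pairwise proximity; with `tolerance = 0` it reduces to exact
#' coordinate equality of the retained-atom sets.
#'
#' The tolerance has no default on purpose: it defines what counts as "the
#' same CG configuration" for a continuous ensemble and must be chosen by
#' the analyst (in nm).
#'
#' @param ensemble A [cg_ensemble()].
#' @param mapping A [cg_mapping()] over the ensemble's atoms.
#' @param tolerance Non-negative distance threshold in nm.
#' @return Integer vector of dense macrostate labels `0..K-1`, one per
#'   frame, numbered by first appearance.
#' @export
assign_macrostates <- function(ensemble, mapping, tolerance) {
  stopifnot(inherits(ensemble, "cg_ensemble"), inherits(mapping, "cg_mapping"))
  if (missing(tolerance)) stop("tolerance (nm) must be given explicitly")
  stopifnot(tolerance >= 0)
  if (mapping$N == 0L) stop("mapping retains zero atoms: macrostates undefined")
  na <- dim(ensemble$frames)[2]
  if (mapping$n != na) stop("mapping is over ", mapping$n, " atoms but frames have ", na)

  nf <- dim(ensemble$frames)[1]
  sel <- mapping$retained + 1L
  coords <- ensemble$frames[, sel, , drop = FALSE]
  # chebyshev-over-atoms metric between frames
  d <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      dd <- coords[i, , , drop = FALSE] - coords[j, , , drop = FALSE]
      per_atom <- sqrt(rowSums(matrix(dd, nrow = length(sel), ncol = 3)^2))
      d[i, j] <- d[j, i] <- max(per_atom)
    }
  }
  if (is.infinite(tolerance)) {
    lab <- rep(1L, nf)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    lab <- stats::cutree(hc, h = tolerance)
  }
  # dense labels in order of first appearance
  as.integer(factor(lab, levels = unique(lab))) - 1L
}

#' Variance-based mapping-entropy estimator for sampled ensembles
#'
#' Approximates `S_map` as a weighted average, over CG macrostates, of the
#' variances of the atomistic potential energies of the frames mapping onto
#' each macrostate: `prefactor * sum_R w_R * Var_R(u)`, with
#' `w_R = n_R / n_frames` and `Var_R` the population variance within
#' macrostate `R`. In `"cumulant"` mode the prefactor is `k_B * beta^2 / 2`
#' (the second-order term of the cumulant expansion of the KL divergence),
#' giving kJ/mol/K; `"unit"` mode uses prefactor 1 and isolates the
#' structural part for oracle testing.
#'
#' @param ensemble A [cg_ensemble()].
#' @param labels Per-frame macrostate labels, as from [assign_macrostates()].
#' @param prefactor_mode `"cumulant"` or `"unit"`.
#' @return Non-negative estimate; singleton macrostates contribute 0.
#' @export
estimate_smap <- function(ensemble, labels, prefactor_mode = c("cumulant", "unit")) {
  stopifnot(inherits(ensemble, "cg_ensemble"))
  prefactor_mode <- match.arg(prefactor_mode)
  u <- ensemble$energies
  if (length(labels) != length(u)) stop("labels and frames differ in length")
  nf <- length(u)
  pop_var <- function(x) mean((x - mean(x))^2)
  by_macro <- split(u, labels)
  w <- vapply(by_macro, length, numeric(1)) / nf
  v <- vapply(by_macro, pop_var, numeric(1))
  pref <- switch(prefactor_mode,
                 cumulant = KB_KJ_MOL_K * ensemble$beta^2 / 2,
                 unit = 1)
  pref * sum(w * v)
}

#' Save / load an ensemble as a single structured file
#'
#' One self-describing file (R native serialization) holding the
#' `frames x atoms x 3` coordinate block (nm), the per-frame energies
#' (kJ/mol) and the inverse temperature.
#'
#' @param ensemble A [cg_ensemble()].
#' @param path File path.
#' @return `read_ensemble` returns the [cg_ensemble()].
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cg_ensemble"))
  saveRDS(unclass(ensemble), path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- readRDS(path)
  cg_ensemble(x$frames, x$energies, x$beta)
}

#' Read an ensemble from a multi-model PDB plus an energy file
#'
#' Coordinates are taken from the models of a multi-model PDB (converted to
#' nm); energies from a one-value-per-line text file (kJ/mol).
#'
#' @param pdb_path Multi-model PDB file.
#' @param energy_path Text file with one potential energy per model.
#' @inheritParams cg_ensemble
#' @return A [cg_ensemble()].
#' @export
read_ensemble_pdb <- function(pdb_path, energy_path,
                              beta = 1 / (KB_KJ_MOL_K * 300)) {
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  frames <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf)) {
    frames[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  }
  energies <- scan(energy_path, what = numeric(), quiet = TRUE)
  cg_ensemble(frames, energies, beta)
}
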