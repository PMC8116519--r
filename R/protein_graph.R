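#' Residue classification into four physicochemical classes
#'
#' Every one of the 20 standard amino acids belongs to exactly one of the
#' classes used as vertex features: hydrophobic (`HPhob`), amphipathic
#' (`Amph`), polar (`Pol`) or charged (`Ch`). The assignment follows a
#' standard hydropathy grouping and is kept as a single documented constant
#' so it can be swapped wholesale if a different convention is preferred.
#'
#' @format Named character vector, residue 3-letter code -> class.
#' @export
RESIDUE_CLASS <- c(
  ALA = "HPhob", VAL = "HPhob", LEU = "HPhob", ILE = "HPhob",
  PRO = "HPhob", PHE = "HPhob", MET = "HPhob", GLY = "HPhob",
  TRP = "Amph", TYR = "Amph", THR = "Amph",
  SER = "Pol", CYS = "Pol", ASN = "Pol", GLN = "Pol", HIS = "Pol",
  ASP = "Ch", GLU = "Ch", LYS = "Ch", ARG = "Ch"
)

#' Names of the 10 binary vertex features, in column order
#' @export
VERTEX_FEATURE_NAMES <- c("C", "N", "O", "S",
                          "HPhob", "Amph", "Pol", "Ch", "Bkb", "Site")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")
.HEAVY_ELEMENTS <- c("C", "N", "O", "S")

#' Classify a residue
#'
#' @param residue_name 3-letter code of a standard amino acid (vectorized).
#' @return One of `"HPhob"`, `"Amph"`, `"Pol"`, `"Ch"` per input.
#' @examples
#' classify_residue(c("LEU", "ARG", "SER"))
#' @export
classify_residue <- function(residue_name) {
  residue_name <- toupper(residue_name)
  unknown <- setdiff(unique(residue_name), names(RESIDUE_CLASS))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         " (only the 20 standard amino acids are classified)")
  }
  unname(RESIDUE_CLASS[residue_name])
}

#' Assemble an atom table
#'
#' The heavy-atom record of one protein chain. Positions are in nm; indices
#' are contiguous and 0-based; only C, N, O, S elements are admitted
#' (hydrogens are excluded upstream by definition).
#'
#' @param element Element symbol per atom (C/N/O/S).
#' @param atom_name PDB atom name (e.g. `CA`, `OG`).
#' @param residue_name 3-letter residue code per atom.
#' @param residue_index Residue number per atom.
#' @param xyz Numeric `n x 3` matrix of coordinates in nm.
#' @return A data frame of class `atom_table` with columns `atom_index`,
#'   `element`, `atom_name`, `residue_name`, `residue_index`, `is_backbone`,
#'   `x`, `y`, `z`.
#' @export
atom_table <- function(element, atom_name, residue_name, residue_index, xyz) {
  n <- length(element)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == n, length(atom_name) == n,
            length(residue_name) == n, length(residue_index) == n)
  bad <- !(element %in% .HEAVY_ELEMENTS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unsupported element '", element[i], "' for atom ", atom_name[i],
         " in residue ", residue_name[i], " ", residue_index[i])
  }
  out <- data.frame(
    atom_index = seq_len(n) - 1L,
    element = element,
    atom_name = atom_name,
    residue_name = residue_name,
    residue_index = as.integer(residue_index),
    is_backbone = atom_name %in% .BACKBONE_ATOMS,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  class(out) <- c("atom_table", "data.frame")
  out
}

#' Load the heavy atoms of one protein chain from a PDB file
#'
#' Parses standard ATOM records (via \pkg{bio3d}), keeps the first model and
#' a single protein chain, and drops hydrogens, waters, ions and hetero
#' ligands. Alternate locations are resolved by highest occupancy (ties go
#' to altLoc `A`). Coordinates are converted from Angstrom to nm.
#'
#' @param pdb_source Path to a PDB file.
#' @param chain Optional chain identifier; default is the first protein
#'   chain in the file.
#' @return An [atom_table()].
#' @export
load_structure <- function(pdb_source, chain = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_source, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # protein residues only (standard amino acids)
  at <- at[toupper(at$resid) %in% names(RESIDUE_CLASS), , drop = FALSE]
  if (nrow(at) == 0) stop("no protein heavy atoms found in input")
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms on chain ", chain)

  # element: PDB element column when present, else first letter of the name
  ele <- toupper(trimws(at$elesy))
  fallback <- substr(gsub("^[0-9]+", "", trimws(at$elety)), 1, 1)
  ele[is.na(ele) | ele == ""] <- fallback[is.na(ele) | ele == ""]
  hyd <- ele == "H" | ele == "D"
  at <- at[!hyd, , drop = FALSE]
  ele <- ele[!hyd]
  if (nrow(at) == 0) stop("no protein heavy atoms left after hydrogen removal")

  # alternate locations: keep highest occupancy, tie -> 'A'
  alt <- trimws(at$alt); alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$resno, at$insert, at$elety, sep = "|")
    occ <- at$o; occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      cand <- idx[occ[idx] == max(occ[idx])]
      if (length(cand) > 1L) {
        a_alt <- cand[alt[cand] %in% c("", "A")]
        if (length(a_alt)) cand <- a_alt
      }
      cand[1]
    }), use.names = FALSE)
    keep <- sort(keep)
    at <- at[keep, , drop = FALSE]
    ele <- ele[keep]
  }

  bad <- !(ele %in% .HEAVY_ELEMENTS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unsupported heavy element '", ele[i], "' at atom ",
         trimws(at$elety[i]), " of residue ", at$resid[i], " ", at$resno[i])
  }
  atom_table(
    element = ele,
    atom_name = trimws(at$elety),
    residue_name = toupper(at$resid),
    residue_index = at$resno,
    xyz = cbind(at$x, at$y, at$z) / 10
  )
}

#' Compute the 10 binary features of one atom
#'
#' Feature layout (see [VERTEX_FEATURE_NAMES]): one-hot element class
#' (C, N, O, S), one-hot residue class (HPhob, Amph, Pol, Ch), the backbone
#' flag (`Bkb`, atom name in N/CA/C/O), and the CG-site flag (`Site`, atom
#' retained by the mapping).
#'
#' @param atom One row of an [atom_table()].
#' @param mapping A [cg_mapping()] (its `retained` set defines `Site`).
#' @return Named 0/1 vector of length 10.
#' @export
vertex_features <- function(atom, mapping) {
  bits <- stats::setNames(numeric(10), VERTEX_FEATURE_NAMES)
  bits[atom$element] <- 1
  bits[classify_residue(atom$residue_name)] <- 1
  bits["Bkb"] <- as.numeric(atom$is_backbone)
  bits["Site"] <- as.numeric(atom$atom_index %in% mapping$retained)
  bits
}

#' Build the attributed contact graph of a structure
#'
#' Vertices are heavy atoms; an undirected edge joins every pair of atoms
#' strictly closer than `cutoff` (nm), weighted by the inverse distance in
#' 1/nm. Each unordered pair is stored once; the directed (ordered-pair)
#' edge count conventionally reported alongside is twice that. The feature
#' matrix is initialized with `Site = 0` everywhere; use [encode_mapping()]
#' to write a mapping into it.
#'
#' @param atoms An [atom_table()].
#' @param cutoff Contact distance threshold in nm (default 1.0).
#' @return A `protein_graph`: list with `n_vertices`, `features`
#'   (`n x 10` matrix), `edges` (`m x 2` matrix of 0-based vertex pairs,
#'   u < v), `edge_weight` (1/nm), `cutoff`, `atoms`.
#' @export
build_graph <- function(atoms, cutoff = 1.0) {
  stopifnot(inherits(atoms, "atom_table"), cutoff > 0, nrow(atoms) >= 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup)) {
    stop("degenerate geometry: atoms ", dup[1, 1] - 1L, " and ", dup[1, 2] - 1L,
         " occupy identical positions")
  }
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  edges <- cbind(u = hit[, 1] - 1L, v = hit[, 2] - 1L)
  w <- if (nrow(hit)) 1 / d[hit] else numeric(0)

  feats <- matrix(0, n, 10, dimnames = list(NULL, VERTEX_FEATURE_NAMES))
  feats[cbind(seq_len(n), match(atoms$element, .HEAVY_ELEMENTS))] <- 1
  feats[cbind(seq_len(n), 4L + match(classify_residue(atoms$residue_name),
                                     c("HPhob", "Amph", "Pol", "Ch")))] <- 1
  feats[, "Bkb"] <- as.numeric(atoms$is_backbone)

  structure(list(n_vertices = n, features = feats, edges = edges,
                 edge_weight = w, cutoff = cutoff, atoms = atoms),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf("Protein contact graph: %d vertices, %d edges (directed count), avg. degree %d, cutoff %.2f nm\n",
              st$vertices, st$edges_directed, st$avg_degree, x$cutoff))
  invisible(x)
}

#' Graph bookkeeping statistics
#'
#' Reports the directed (ordered-pair) edge count `2 * stored pairs` and the
#' average degree as the integer part of edges/vertices — the convention
#' used when quoting contact-graph statistics for proteins.
#'
#' @param graph A `protein_graph`.
#' @return List with `vertices`, `edges_directed`, `avg_degree`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "protein_graph"))
  e <- 2L * nrow(graph$edges)
  list(vertices = graph$n_vertices, edges_directed = e,
       avg_degree = as.integer(e %/% graph$n_vertices))
}

#' Write a CG mapping into the graph's Site feature
#'
#' Overwrites the `Site` column of the feature matrix with the indicator of
#' the mapping's retained set; all other columns are untouched, and encoding
#' is idempotent (re-encoding the same mapping is a no-op).
#'
#' @param graph A `protein_graph`.
#' @param mapping A [cg_mapping()] with `mapping$n == graph$n_vertices`.
#' @return The graph with its `Site` column replaced.
#' @export
encode_mapping <- function(graph, mapping) {
  stopifnot(inherits(graph, "protein_graph"), inherits(mapping, "cg_mapping"))
  if (mapping$n != graph$n_vertices) {
    stop("mapping is over ", mapping$n, " atoms but graph has ", graph$n_vertices)
  }
  site <- numeric(graph$n_vertices)
  site[mapping$retained + 1L] <- 1
  graph$features[, "Site"] <- site
  graph
}

#' Save / load a graph cache
#'
#' `write_graph_cache` writes three text artifacts under `prefix`: an edge
#' list `<prefix>_edges.csv` (`u, v, weight`), a feature table
#' `<prefix>_features.csv`, and a single structured JSON
#' `<prefix>_graph.json` holding the same content plus the atom table for
#' fast reload. `read_graph_cache` restores the graph from the JSON.
#'
#' @param graph A `protein_graph`.
#' @param prefix Output path prefix.
#' @return `write_graph_cache`: the JSON path, invisibly.
#' @export
write_graph_cache <- function(graph, prefix) {
  stopifnot(inherits(graph, "protein_graph"))
  ed <- data.frame(u = graph$edges[, 1], v = graph$edges[, 2],
                   weight = graph$edge_weight)
  utils::write.csv(ed, paste0(prefix, "_edges.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(graph$features),
                   paste0(prefix, "_features.csv"), row.names = FALSE)
  payload <- list(
    n_vertices = graph$n_vertices, cutoff = graph$cutoff,
    features = graph$features, edges = graph$edges,
    edge_weight = graph$edge_weight,
    atoms = graph$atoms[, c("atom_index", "element", "atom_name",
                            "residue_name", "residue_index", "is_backbone",
                            "x", "y", "z")]
  )
  path <- paste0(prefix, "_graph.json")
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph_cache
#' @export
read_graph_cache <- function(prefix) {
  path <- if (file.exists(prefix)) prefix else paste0(prefix, "_graph.json")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  atoms <- atom_table(x$atoms$element, x$atoms$atom_name, x$atoms$residue_name,
                      x$atoms$residue_index,
                      cbind(x$atoms$x, x$atoms$y, x$atoms$z))
  feats <- matrix(unlist(x$features), ncol = 10,
                  dimnames = list(NULL, VERTEX_FEATURE_NAMES))
  edges <- matrix(as.integer(unlist(x$edges)), ncol = 2,
                  dimnames = list(NULL, c("u", "v")))
  structure(list(n_vertices = x$n_vertices, features = feats, edges = edges,
                 edge_weight = as.numeric(x$edge_weight), cutoff = x$cutoff,
                 atoms = atoms),
            class = "protein_graph")
}

#' Write an atom table as a minimal PDB file
#'
#' Emits standard ATOM records (coordinates converted nm -> Angstrom),
#' suitable for visualization and for round-tripping toy structures through
#' [load_structure()].
#'
#' @param atoms An [atom_table()].
#' @param path Output file.
#' @param chain Chain identifier to stamp on the records.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path, chain = "A") {
  stopifnot(inherits(atoms, "atom_table"))
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$atom_index + 1L,
    ifelse(nchar(atoms$atom_name) < 4, paste0(" ", atoms$atom_name), atoms$atom_name),
    atoms$residue_name, chain, atoms$residue_index,
    atoms$x * 10, atoms$y * 10, atoms$z * 10, 1, 0, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
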