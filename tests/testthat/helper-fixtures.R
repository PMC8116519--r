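# Shared fixtures, all built in code.

# hand-written one-residue PDB: glycine with 4 heavy atoms and 5 hydrogens
# (hydrogen count is deliberately unphysical; only heavy-atom filtering matters)
glycine_pdb_lines <- c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.400   0.300   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       3.100   1.200   0.500  1.00  0.00           O",
  "ATOM      5  H   GLY A   1       0.100   0.900   0.100  1.00  0.00           H",
  "ATOM      6  H2  GLY A   1      -0.500   0.200   0.700  1.00  0.00           H",
  "ATOM      7  HA1 GLY A   1       1.100  -0.900   0.300  1.00  0.00           H",
  "ATOM      8  HA2 GLY A   1       1.000   0.200  -1.000  1.00  0.00           H",
  "ATOM      9  HA3 GLY A   1       1.300   0.800   0.600  1.00  0.00           H",
  "END"
)

write_glycine_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(glycine_pdb_lines, path)
  path
}

# two-residue PDB with water, a hetero ligand, a second chain and an
# altloc pair on the serine OG (B has higher occupancy and must win)
mixed_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       3.000   0.400   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       3.800   1.300   0.400  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       1.600  -1.500   0.400  1.00  0.00           C",
  "ATOM      6  N   SER A   2       4.000  -0.500   0.000  1.00  0.00           N",
  "ATOM      7  CA  SER A   2       5.500  -0.400   0.100  1.00  0.00           C",
  "ATOM      8  C   SER A   2       6.900  -0.100   0.200  1.00  0.00           C",
  "ATOM      9  O   SER A   2       7.800   0.800   0.100  1.00  0.00           O",
  "ATOM     10  CB  SER A   2       5.600  -1.900   0.500  1.00  0.00           C",
  "ATOM     11  OG ASER A   2       5.100  -2.900   1.200  0.40  0.00           O",
  "ATOM     12  OG BSER A   2       5.200  -2.800  -1.300  0.60  0.00           O",
  "ATOM     13  N   GLY B   1      20.000   0.000   0.000  1.00  0.00           N",
  "ATOM     14  CA  GLY B   1      21.000   0.500   0.000  1.00  0.00           C",
  "HETATM   15  O   HOH A 101      10.000  10.000  10.000  1.00  0.00           O",
  "HETATM   16 ZN    ZN A 102      12.000  12.000  12.000  1.00  0.00          ZN",
  "END"
)

write_mixed_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(mixed_pdb_lines, path)
  path
}

# tiny deterministic atom table: k atoms on a line, spacing nm apart
line_atoms <- function(k, spacing = 0.5, element = "C", backbone = FALSE) {
  atom_table(
    element = rep(element, k),
    atom_name = if (backbone) rep("CA", k) else rep("CB", k),
    residue_name = rep("ALA", k),
    residue_index = seq_len(k),
    xyz = cbind((seq_len(k) - 1) * spacing, 0, 0)
  )
}

# toy spaces reused across test files
toy_structure_n <- function(n_atoms, seed = 11) {
  st <- make_toy_structure(ceiling(n_atoms / 2), seed)[seq_len(n_atoms), ]
  stopifnot(nrow(st) == n_atoms)
  st
}

# retained-set indicator as 0/1 vector of length n
site_indicator <- function(mapping) {
  s <- integer(mapping$n)
  s[mapping$retained + 1L] <- 1L
  s
}
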