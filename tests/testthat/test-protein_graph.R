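test_that("loading a structure keeps heavy atoms only and converts to nm", {
  at <- load_structure(write_glycine_pdb())
  expect_s3_class(at, "atom_table")
  expect_equal(nrow(at), 4)
  expect_setequal(at$atom_name, c("N", "CA", "C", "O"))
  expect_equal(at$atom_index, 0:3)
  # CA was written at (1, 0, 0) Angstrom
  expect_equal(unlist(at[at$atom_name == "CA", c("x", "y", "z")],
                      use.names = FALSE), c(0.1, 0, 0))
  expect_true(all(at$is_backbone))
})

test_that("waters, ligands and other chains are excluded; chain selection works", {
  path <- write_mixed_pdb()
  at <- load_structure(path)               # default: first protein chain (A)
  expect_equal(sort(unique(at$residue_name)), c("ALA", "SER"))
  expect_false(any(at$residue_name %in% c("HOH", "ZN")))
  atB <- load_structure(path, chain = "B")
  expect_equal(unique(at$residue_name)[1], "ALA")
  expect_equal(nrow(atB), 2)
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  at <- load_structure(write_mixed_pdb())
  og <- at[at$atom_name == "OG", ]
  expect_equal(nrow(og), 1)
  # the B copy (occupancy 0.60) sits at z = -1.3 Angstrom = -0.13 nm
  expect_equal(og$z, -0.13)
})

test_that("load errors are specific", {
  expect_error(load_structure(tempfile()), "parse|read|exist", ignore.case = TRUE)
  nohet <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), nohet)
  expect_error(load_structure(nohet), "no protein")
})

test_that("residue classification partitions the 20 amino acids into 4 classes", {
  all20 <- names(RESIDUE_CLASS)
  expect_length(all20, 20)
  cls <- classify_residue(all20)
  expect_setequal(unique(cls), c("HPhob", "Amph", "Pol", "Ch"))
  expect_identical(classify_residue(c("LEU", "ARG", "SER")),
                   c("HPhob", "Ch", "Pol"))
  expect_error(classify_residue("XYZ"), "unknown residue")
})

test_that("vertex features follow the documented 10-bit layout", {
  at <- atom_table(
    element = c("C", "S", "O"),
    atom_name = c("CA", "SD", "OG"),
    residue_name = c("ALA", "MET", "SER"),
    residue_index = 1:3,
    xyz = cbind(c(0, 1, 2), 0, 0)
  )
  m <- cg_mapping(3, 0L)  # retain only the CA
  expect_equal(unname(vertex_features(at[1, ], m)),
               c(1, 0, 0, 0, 1, 0, 0, 0, 1, 1))
  expect_equal(unname(vertex_features(at[2, ], m)),
               c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(vertex_features(at[3, ], m)),
               c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0))
})

test_that("feature matrix rows are one-hot in element and residue class", {
  st <- toy_structure_n(60)
  g <- build_graph(st)
  expect_equal(unname(rowSums(g$features[, 1:4])), rep(1, 60))
  expect_equal(unname(rowSums(g$features[, 5:8])), rep(1, 60))
  expect_true(all(g$features %in% c(0, 1)))
  # exhaustively: every residue x element combination stays one-hot
  combo <- expand.grid(res = names(RESIDUE_CLASS),
                       ele = c("C", "N", "O", "S"),
                       stringsAsFactors = FALSE)
  at <- atom_table(combo$ele, rep("CB", nrow(combo)), combo$res,
                   seq_len(nrow(combo)),
                   cbind(seq_len(nrow(combo)) * 0.2, 0, 0))
  f <- build_graph(at)$features
  expect_equal(unname(rowSums(f[, 1:4])), rep(1, 80))
  expect_equal(unname(rowSums(f[, 5:8])), rep(1, 80))
  expect_equal(f[cbind(seq_len(80), match(combo$ele, c("C", "N", "O", "S")))],
               rep(1, 80))
  expect_equal(f[cbind(seq_len(80),
                       4 + match(classify_residue(combo$res),
                                 c("HPhob", "Amph", "Pol", "Ch")))],
               rep(1, 80))
})

test_that("contact graph obeys the cutoff with inverse-distance weights", {
  at2 <- line_atoms(2, spacing = 0.5)
  g2 <- build_graph(at2)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edge_weight, 2.0)

  far <- line_atoms(2, spacing = 1.2)
  expect_equal(nrow(build_graph(far, cutoff = 1.0)$edges), 0)

  # equilateral triangle, side 0.3 nm
  tri <- atom_table(rep("C", 3), rep("CA", 3), rep("GLY", 3), 1:3,
                    0.3 * cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2), 0))
  g3 <- build_graph(tri)
  expect_equal(nrow(g3$edges), 3)
  expect_equal(graph_stats(g3)$edges_directed, 6)
  expect_equal(g3$edge_weight, rep(10 / 3, 3))
})

test_that("duplicate positions raise a degenerate-geometry error", {
  dup <- atom_table(rep("C", 2), c("CA", "CB"), rep("ALA", 2), c(1, 1),
                    rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(build_graph(dup), "degenerate geometry")
})

test_that("graph is symmetric, monotone in cutoff, with weights >= 1/cutoff", {
  st <- toy_structure_n(50)
  for (cut in c(0.6, 1.0)) {
    g <- build_graph(st, cutoff = cut)
    A <- matrix(0, 50, 50)
    A[g$edges + 1L] <- g$edge_weight
    A[g$edges[, 2:1] + 1L] <- g$edge_weight
    expect_identical(A, t(A))
    expect_true(all(g$edge_weight >= 1 / cut))
  }
  key <- function(g) paste(g$edges[, 1], g$edges[, 2])
  expect_true(all(key(build_graph(st, 0.6)) %in% key(build_graph(st, 1.0))))
})

test_that("encode_mapping writes exactly the Site column, idempotently", {
  st <- toy_structure_n(40)
  g <- build_graph(st)
  m1 <- cg_mapping(40, c(0, 5, 9))
  m2 <- cg_mapping(40, c(5, 9, 21, 33))
  g1 <- encode_mapping(g, m1)
  expect_equal(unname(g1$features[, "Site"]), as.numeric(site_indicator(m1)))
  expect_identical(g1$features[, 1:9], g$features[, 1:9])
  expect_identical(encode_mapping(g1, m1), g1)
  # re-encoding changes exactly the symmetric-difference rows
  g12 <- encode_mapping(g1, m2)
  changed <- which(g12$features[, "Site"] != g1$features[, "Site"]) - 1L
  expect_setequal(changed, setdiff(union(m1$retained, m2$retained),
                                   intersect(m1$retained, m2$retained)))
  expect_identical(g12, encode_mapping(g, m2))
  expect_error(encode_mapping(g, cg_mapping(41, 40L)), "41")
  # empty retained set is allowed for the encoding operation
  g0 <- encode_mapping(g, cg_mapping(40, integer(0)))
  expect_equal(sum(g0$features[, "Site"]), 0)
})

test_that("graph cache round-trips through text artifacts", {
  st <- toy_structure_n(25)
  g <- encode_mapping(build_graph(st), cg_mapping(25, c(1, 3)))
  pre <- file.path(tempdir(), "gcache")
  write_graph_cache(g, pre)
  expect_true(file.exists(paste0(pre, "_edges.csv")))
  expect_true(file.exists(paste0(pre, "_features.csv")))
  g2 <- read_graph_cache(pre)
  expect_equal(g2$edges, g$edges, ignore_attr = TRUE)
  expect_equal(g2$edge_weight, g$edge_weight)
  expect_equal(g2$features, g$features)
  expect_equal(g2$atoms$x, g$atoms$x)
})

test_that("toy structures round-trip through PDB within format precision", {
  st <- make_toy_structure(6, seed = 3)
  path <- tempfile(fileext = ".pdb")
  write_pdb(st, path)
  back <- load_structure(path)
  expect_equal(nrow(back), nrow(st))
  expect_equal(back$element, st$element)
  # PDB stores 3 decimals in Angstrom = 1e-4 nm
  expect_equal(back$x, st$x, tolerance = 1e-3)
  expect_equal(back$is_backbone, st$is_backbone)
})
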