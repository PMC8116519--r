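# small shared fixture: 5-vertex toy graph with hand-checkable geometry
small_graph <- function() {
  at <- atom_table(
    element = c("C", "N", "O", "C", "S"),
    atom_name = c("CA", "N", "O", "CB", "SD"),
    residue_name = c("ALA", "ALA", "ALA", "MET", "MET"),
    residue_index = c(1, 1, 1, 2, 2),
    xyz = cbind(c(0, 0.4, 0.8, 1.6, 2.0), 0, 0)
  )
  build_graph(at, cutoff = 0.5)
}

test_that("weight census formula matches the reference architecture and instances", {
  expect_equal(count_weights(surrogate_config(K = 64, L = 5)), 17350)
  expect_equal(count_weights(surrogate_config(K = 1, L = 1)), 13)
  expect_equal(count_weights(surrogate_config(K = 2, L = 2)), 31)
  set.seed(20)
  for (i in 1:20) {
    K <- sample(1:32, 1); L <- sample(1:6, 1)
    cfg <- surrogate_config(K = K, L = L, seed = i)
    expect_equal(model_weight_census(new_surrogate_model(cfg)),
                 count_weights(cfg))
  }
})

test_that("vertex embedding is an edge-independent affine+ReLU map", {
  g <- small_graph()
  cfg <- surrogate_config(K = 10, L = 2, seed = 1)
  mod <- new_surrogate_model(cfg)
  # zero weights, zero bias -> zero embedding
  mod0 <- mod
  mod0$W[[1]][] <- 0; mod0$b[[1]][] <- 0
  expect_equal(embed_vertices(g, mod0), matrix(0, 5, 10), ignore_attr = TRUE)
  # identical feature rows embed identically
  g2 <- g; g2$features[2, ] <- g2$features[1, ]
  h <- embed_vertices(g2, mod)
  expect_equal(h[1, ], h[2, ])
  # identity-like weights pass a one-hot through
  modI <- mod
  modI$W[[1]] <- diag(10); modI$b[[1]][] <- 0
  gI <- g; gI$features[1, ] <- c(1, rep(0, 9))
  expect_equal(embed_vertices(gI, modI)[1, ], c(1, rep(0, 9)))
  expect_error(embed_vertices(structure(list(features = matrix(0, 2, 7),
                                             n_vertices = 2),
                                        class = "protein_graph"), mod),
               "width")
})

test_that("graph convolution follows the weighted-GIN update rule", {
  cfg <- surrogate_config(K = 2, L = 2, seed = 2)
  mod <- new_surrogate_model(cfg)
  mod$W[[2]] <- diag(2); mod$b[[2]][] <- 0
  # isolated vertex with eps = 0: plain ReLU of its own state
  iso <- build_graph(line_atoms(2, spacing = 2), cutoff = 1)
  mod$eps[1] <- 0
  h <- rbind(c(1, -2), c(0.5, 3))
  expect_equal(gin_layer(h, iso, 1, mod), rbind(c(1, 0), c(0.5, 3)),
               ignore_attr = TRUE)
  # one neighbor at weight 0.25, eps = 0.5: hand evaluation
  pair <- build_graph(line_atoms(2, spacing = 0.5), cutoff = 1)
  pair$edge_weight <- 0.25
  mod$eps[1] <- 0.5
  h2 <- rbind(c(1, 0), c(2, 2))
  out <- gin_layer(h2, pair, 1, mod)
  expect_equal(out[1, ], c(1.5 * 1 + 0.25 * 2, 1.5 * 0 + 0.25 * 2))
  expect_equal(out[1, ], c(2.0, 0.5))
  # doubling the edge weight doubles the neighbor term
  pair2 <- pair; pair2$edge_weight <- 0.5
  out2 <- gin_layer(h2, pair2, 1, mod)
  expect_equal(out2[1, ] - 1.5 * c(1, 0), 2 * (out[1, ] - 1.5 * c(1, 0)))
  bad <- pair; bad$edges[1, 2] <- 5L
  expect_error(gin_layer(h2, bad, 1, mod), "missing vertex")
})

test_that("readout concatenates states with site/non-site scalar weights", {
  cfg <- surrogate_config(K = 1, L = 1, seed = 3)
  mod <- new_surrogate_model(cfg)
  mod$w_site <- 2; mod$w_nonsite <- -1; mod$w_out <- 1
  states <- list(matrix(c(3, 5), 2, 1))
  m <- cg_mapping(2, 0L)
  expect_equal(readout(states, m, mod), 2 * 3 + (-1) * 5)
  mod0 <- mod; mod0$w_site <- 0; mod0$w_nonsite <- 0
  expect_equal(readout(states, m, mod0), 0)
  modz <- mod; modz$w_out <- 0
  expect_equal(readout(states, m, modz), 0)
  # mean variant ignores site weights
  expect_equal(readout(states, m, mod, variant = "mean"), 4)
})

test_that("predict composes the three stages and is permutation invariant", {
  g <- small_graph()
  cfg <- surrogate_config(K = 4, L = 3, seed = 4)
  mod <- new_surrogate_model(cfg)
  m <- cg_mapping(5, c(0, 3))
  # manual composition oracle
  ge <- encode_mapping(g, m)
  h1 <- embed_vertices(ge, mod)
  h2 <- gin_layer(h1, ge, 1, mod)
  h3 <- gin_layer(h2, ge, 2, mod)
  manual <- readout(list(h1, h2, h3), m, mod)
  expect_equal(predict(mod, g, m), manual)
  # all-zero weights predict 0 for every mapping
  modz <- mod
  for (l in 1:3) { modz$W[[l]][] <- 0; modz$b[[l]][] <- 0 }
  modz$w_out[] <- 0
  expect_equal(predict(modz, g, cg_mapping(5, c(1, 4))), 0)
  # vertex relabeling applied consistently leaves the prediction unchanged
  set.seed(5)
  perm <- sample(5)
  at <- g$atoms[perm, ]
  at$atom_index <- 0:4
  class(at) <- c("atom_table", "data.frame")
  gp <- build_graph(at, cutoff = 0.5)
  mp <- cg_mapping(5, sort(match(c(0, 3), perm - 1L) - 1L))
  expect_equal(predict(mod, gp, mp), predict(mod, g, m))
})

test_that("compiled forward pass agrees with the R-level composition", {
  st <- toy_structure_n(30)
  g <- build_graph(st)
  cfg <- surrogate_config(K = 8, L = 4, seed = 6)
  mod <- new_surrogate_model(cfg)
  set.seed(7)
  maps <- lapply(1:10, function(i) random_mapping(30, 8))
  via_cpp <- predict(mod, g, maps)
  via_r <- vapply(maps, function(m) predict(mod, g, m), numeric(1))
  expect_equal(via_cpp, via_r, tolerance = 1e-12)
})

test_that("the prediction is sensitive to flipping one site bit", {
  g <- small_graph()
  mod <- new_surrogate_model(surrogate_config(K = 6, L = 3, seed = 8))
  base <- predict(mod, g, cg_mapping(5, c(0, 2)))
  flipped <- predict(mod, g, cg_mapping(5, c(0, 3)))
  expect_gt(abs(base - flipped), 1e-8)
})

test_that("training learns a constant target and is seed-deterministic", {
  st <- toy_structure_n(20)
  g <- build_graph(st)
  ds <- lapply(1:40, function(i) {
    set.seed(100 + i)
    list(mapping = random_mapping(20, 6), smap = 3.0, origin = "random")
  })
  cfg <- surrogate_config(K = 4, L = 2, max_epochs = 1500, patience = 1500,
                          batch_size = 8, seed = 9)
  fit <- train_surrogate(g, ds, cfg)
  expect_lt(utils::tail(fit$log$train_mae, 1), 1e-2 * 3.0)
  fit2 <- train_surrogate(g, ds, cfg)
  expect_identical(fit$log, fit2$log)
  # the running best validation MAE never worsens across epochs
  expect_true(all(diff(cummin(fit$log$val_mae)) <= 0))
  expect_equal(min(fit$log$val_mae), fit$best_val_mae)
})

test_that("regression metrics match their definitions", {
  ev <- evaluate_predictions(c(0, 1, 2), c(0, 1, 2))
  expect_equal(ev$r2, 1); expect_equal(ev$mae, 0)
  ev2 <- evaluate_predictions(c(0, 1, 2), rep(1, 3))
  expect_equal(ev2$r2, 0)
  ev3 <- evaluate_predictions(c(0, 1, 2), c(0, 0, 3))
  expect_equal(ev3$mae, 2 / 3); expect_equal(ev3$r2, 0)
  expect_error(evaluate_predictions(c(1, 1), c(0, 2)), "undefined")
})

test_that("surrogate checkpoints round-trip through JSON", {
  mod <- new_surrogate_model(surrogate_config(K = 3, L = 2, seed = 11))
  p <- tempfile(fileext = ".json")
  write_surrogate(mod, p)
  back <- read_surrogate(p)
  g <- small_graph()
  m <- cg_mapping(5, c(1, 2))
  expect_equal(predict(back, g, m), predict(mod, g, m))
  expect_equal(back$config$K, 3)
})

test_that("a surrogate oracle plugs into the samplers", {
  st <- toy_structure_n(15)
  g <- build_graph(st)
  mod <- new_surrogate_model(surrogate_config(K = 4, L = 2, seed = 12))
  orc <- surrogate_oracle(mod, g)
  m <- cg_mapping(15, c(0, 4, 9))
  expect_equal(orc(m), predict(mod, g, m))
  res <- simulated_annealing(orc, 15, 3, sa_config(steps = 300, seed = 13))
  expect_true(is.finite(res$best_score))
})
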