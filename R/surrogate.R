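#' Surrogate architecture and training configuration
#'
#' The surrogate is an edge-weighted graph isomorphism network: an embedding
#' layer (a one-layer MLP `in_dim -> K` with ReLU) followed by `L - 1` graph
#' convolutions, each a one-layer MLP `K -> K` with ReLU applied to
#' `(1 + eps_l) * h_v + sum_{u in N(v)} h_u * e_uv`, and a site-aware
#' readout over the concatenated per-layer vertex states. `L` counts the
#' embedding layer plus the `L - 1` convolutions.
#'
#' @param K Hidden width (default 64).
#' @param L Number of layers including the embedding layer (default 5).
#' @param in_dim Vertex feature width (10).
#' @param learning_rate Adam learning rate (default 0.001; no weight decay).
#' @param batch_size Mini-batch size (default 8).
#' @param max_epochs Maximum training epochs (default 10000).
#' @param patience Early-stopping patience in epochs (default 1000).
#' @param split Train/validation/test fractions, summing to 1
#'   (default 0.8/0.1/0.1 hold-out).
#' @param seed Seed controlling weight initialization, the data shuffle and
#'   the per-epoch batch order.
#' @param normalize Standardize targets during training (off by default;
#'   documented toggle, predictions are always returned on the original
#'   scale).
#' @return A `surrogate_config`.
#' @export
surrogate_config <- function(K = 64L, L = 5L, in_dim = 10L,
                             learning_rate = 0.001, batch_size = 8L,
                             max_epochs = 10000L, patience = 1000L,
                             split = c(0.8, 0.1, 0.1), seed = 1L,
                             normalize = FALSE) {
  stopifnot(K >= 1, L >= 1, in_dim >= 1, learning_rate > 0, batch_size >= 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-9)
  structure(list(K = as.integer(K), L = as.integer(L),
                 in_dim = as.integer(in_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), split = split,
                 seed = as.integer(seed), normalize = isTRUE(normalize)),
            class = "surrogate_config")
}

#' Closed-form census of trainable weights (biases excluded)
#'
#' `in_dim*K + K^2*(L-1) + K*L + (L-1) + 2`: the embedding MLP, the `L - 1`
#' convolution MLPs, the output vector over the `L` concatenated states, the
#' `L - 1` adaptive epsilons, and the two site/non-site readout scalars.
#' Bias terms exist in the instantiated MLPs but are excluded from the
#' census by convention.
#'
#' @param config A [surrogate_config()].
#' @return Integer weight count.
#' @examples
#' count_weights(surrogate_config(K = 64, L = 5)) # 17350
#' @export
count_weights <- function(config) {
  stopifnot(inherits(config, "surrogate_config"))
  with(config, in_dim * K + K^2 * (L - 1) + K * L + (L - 1) + 2)
}

#' Instantiate a surrogate model with fresh weights
#'
#' Affine weights use a symmetric fan-in-scaled uniform scheme
#' (`U(-sqrt(1/fan_in), sqrt(1/fan_in))`, biases alike), epsilons start at
#' 0, and the site/non-site readout scalars start at 1 (plain sum pooling).
#' Initialization is driven by `config$seed`.
#'
#' @param config A [surrogate_config()].
#' @return A `surrogate_model`: list with `config`, `W` (list of `L`
#'   matrices), `b` (list of `L` bias vectors), `eps` (`L - 1` scalars),
#'   `w_site`, `w_nonsite`, `w_out` (length `K * L`), and the target
#'   normalization constants `y_center`, `y_scale`.
#' @export
new_surrogate_model <- function(config) {
  stopifnot(inherits(config, "surrogate_config"))
  K <- config$K; L <- config$L
  with_local_seed(config$seed, {
    fan_unif <- function(nr, nc) {
      a <- sqrt(1 / nr)
      matrix(stats::runif(nr * nc, -a, a), nr, nc)
    }
    W <- vector("list", L); b <- vector("list", L)
    W[[1]] <- fan_unif(config$in_dim, K)
    b[[1]] <- stats::runif(K, -sqrt(1 / config$in_dim), sqrt(1 / config$in_dim))
    if (L > 1) {
      for (l in 2:L) {
        W[[l]] <- fan_unif(K, K)
        b[[l]] <- stats::runif(K, -sqrt(1 / K), sqrt(1 / K))
      }
    }
    a_out <- sqrt(1 / (K * L))
    structure(list(config = config, W = W, b = b,
                   eps = numeric(max(L - 1, 0)),
                   w_site = 1.0, w_nonsite = 1.0,
                   w_out = stats::runif(K * L, -a_out, a_out),
                   y_center = 0.0, y_scale = 1.0),
              class = "surrogate_model")
  })
}

#' Census of an instantiated model's trainable scalars, excluding biases
#'
#' Counts the actual weight entries of a [new_surrogate_model()] object;
#' equals [count_weights()] of its configuration by construction.
#'
#' @param model A `surrogate_model`.
#' @return Integer.
#' @export
model_weight_census <- function(model) {
  stopifnot(inherits(model, "surrogate_model"))
  sum(vapply(model$W, length, numeric(1))) + length(model$eps) +
    length(model$w_out) + 2L
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("GIN surrogate: L = %d layers, K = %d hidden units, %d weights (excl. biases)\n",
              x$config$L, x$config$K, model_weight_census(x)))
  invisible(x)
}

# dense symmetric inverse-distance adjacency of a protein_graph
graph_weight_matrix <- function(graph) {
  n <- graph$n_vertices
  A <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    u <- graph$edges[, 1] + 1L; v <- graph$edges[, 2] + 1L
    A[cbind(u, v)] <- graph$edge_weight
    A[cbind(v, u)] <- graph$edge_weight
  }
  A
}

relu <- function(x) pmax(x, 0)

#' Embed vertex features into the hidden space
#'
#' First layer of the surrogate: `h1_v = ReLU(W1' x_v + b1)`, independent of
#' the graph's edges.
#'
#' @param graph A `protein_graph` (its feature matrix is consumed as-is, so
#'   encode the mapping first).
#' @param model A `surrogate_model`.
#' @return `n x K` matrix of vertex states.
#' @export
embed_vertices <- function(graph, model) {
  X <- graph$features
  if (ncol(X) != model$config$in_dim) {
    stop("feature width ", ncol(X), " does not match model in_dim ",
         model$config$in_dim)
  }
  relu(sweep(X %*% model$W[[1]], 2, model$b[[1]], `+`))
}

#' One edge-weighted graph convolution
#'
#' Computes `h^{l+1}_v = ReLU(W' [(1 + eps_l) h_v + sum_u h_u e_uv] + b)`
#' over all vertices, where the sum runs over the neighbors of `v` and
#' `e_uv` is the inverse-distance edge weight. The same MLP is applied at
#' every vertex; weights are not shared across layers.
#'
#' @param h `n x K` matrix of current vertex states.
#' @param graph A `protein_graph`.
#' @param layer Convolution index `l` in `1..L-1` (layer `l` maps states
#'   `h^l` to `h^{l+1}`).
#' @param model A `surrogate_model`.
#' @return `n x K` matrix of updated states.
#' @export
gin_layer <- function(h, graph, layer, model) {
  L <- model$config$L
  stopifnot(layer >= 1, layer <= L - 1)
  if (nrow(h) != graph$n_vertices) stop("state/graph size mismatch")
  if (nrow(graph$edges) && max(graph$edges) >= graph$n_vertices) {
    stop("edge references a missing vertex")
  }
  A <- graph_weight_matrix(graph)
  pre <- (1 + model$eps[layer]) * h + A %*% h
  relu(sweep(pre %*% model$W[[layer + 1L]], 2, model$b[[layer + 1L]], `+`))
}

#' Site-aware readout of the per-layer vertex states
#'
#' Concatenates each vertex's `L` states into a length-`K*L` vector, scales
#' it by `w_site` for retained vertices and `w_nonsite` otherwise, sums over
#' vertices and takes the inner product with `w_out`. With
#' `variant = "mean"` the per-vertex concatenations are instead averaged
#' uniformly (no site weights) before the inner product — an alternative
#' permutation-invariant aggregation retained for comparison; the canonical
#' weighted sum is what training uses.
#'
#' @param states List of `L` matrices `n x K` (states of layers `1..L`).
#' @param mapping A [cg_mapping()]; defines which vertices are sites.
#' @param model A `surrogate_model`.
#' @param variant `"weighted"` (canonical) or `"mean"`.
#' @return Scalar prediction.
#' @export
readout <- function(states, mapping, model, variant = c("weighted", "mean")) {
  variant <- match.arg(variant)
  L <- model$config$L
  stopifnot(length(states) == L)
  n <- nrow(states[[1]])
  if (mapping$n != n) stop("mapping is over ", mapping$n,
                           " atoms but states cover ", n)
  concat <- do.call(cbind, states)          # n x (K*L)
  if (variant == "weighted") {
    s <- rep(model$w_nonsite, n)
    s[mapping$retained + 1L] <- model$w_site
    pooled <- colSums(concat * s)
  } else {
    pooled <- colMeans(concat)
  }
  drop(pooled %*% model$w_out)
}

# full forward pass; returns states and prediction
dgn_forward <- function(graph, mapping, model, variant = "weighted") {
  g <- encode_mapping(graph, mapping)
  L <- model$config$L
  states <- vector("list", L)
  states[[1]] <- embed_vertices(g, model)
  if (L > 1) {
    A <- graph_weight_matrix(g)
    for (l in 1:(L - 1)) {
      pre <- (1 + model$eps[l]) * states[[l]] + A %*% states[[l]]
      states[[l + 1L]] <- relu(sweep(pre %*% model$W[[l + 1L]], 2,
                                     model$b[[l + 1L]], `+`))
    }
  }
  list(states = states,
       prediction = readout(states, mapping, model, variant))
}

#' Predict the mapping entropy of a CG mapping
#'
#' Composes [encode_mapping()], [embed_vertices()], the `L - 1`
#' [gin_layer()] passes and [readout()]. Deterministic for fixed weights and
#' invariant under consistent vertex relabeling.
#'
#' @param object A `surrogate_model`.
#' @param graph A `protein_graph` matching the model dimensions.
#' @param mapping A [cg_mapping()] (or list of mappings, for batched
#'   prediction through the compiled forward pass).
#' @param ... Unused.
#' @return Predicted S_map (kJ/mol/K), one value per mapping.
#' @export
predict.surrogate_model <- function(object, graph, mapping, ...) {
  stopifnot(inherits(graph, "protein_graph"))
  if (inherits(mapping, "cg_mapping")) {
    pred <- dgn_forward(graph, mapping, object)$prediction
  } else {
    sites <- lapply(mapping, function(m) {
      stopifnot(inherits(m, "cg_mapping"), m$n == graph$n_vertices)
      as.integer(m$retained)
    })
    Xbase <- graph$features; Xbase[, "Site"] <- 0
    pred <- cpp_dgn_predict(Xbase, edge_imat(graph), graph$edge_weight,
                            sites, model_weights(object), object$config$L)
  }
  pred * object$y_scale + object$y_center
}

model_weights <- function(model) {
  list(W = model$W, b = model$b, eps = model$eps, w_site = model$w_site,
       w_nonsite = model$w_nonsite, w_out = model$w_out)
}

edge_imat <- function(graph) {
  e <- graph$edges
  storage.mode(e) <- "integer"
  matrix(e, ncol = 2)
}

#' Wrap a trained surrogate as a mapping-scoring oracle
#'
#' Returns a closure `cg_mapping -> predicted S_map` with the graph baked
#' in, suitable for [simulated_annealing()] and [wl_run()].
#'
#' @param model A `surrogate_model`.
#' @param graph The `protein_graph` it was trained on.
#' @return A scoring function.
#' @export
surrogate_oracle <- function(model, graph) {
  Xbase <- graph$features; Xbase[, "Site"] <- 0
  E <- edge_imat(graph); w <- graph$edge_weight
  wts <- model_weights(model); L <- model$config$L
  ysc <- model$y_scale; yc <- model$y_center
  function(mapping) {
    cpp_dgn_predict(Xbase, E, w, list(as.integer(mapping$retained)),
                    wts, L)[1] * ysc + yc
  }
}

#' Train the surrogate on labeled CG mappings
#'
#' Shuffles the samples with `config$seed`, splits them by the configured
#' hold-out fractions, and minimizes the mean absolute error with Adam at
#' the configured learning rate (no regularization), mini-batches of
#' `config$batch_size`. After every epoch the validation MAE is evaluated;
#' the returned model carries the weights of the epoch with the best
#' validation MAE, and training stops once that best has not improved for
#' `config$patience` epochs.
#'
#' @param graph A `protein_graph` of the structure the mappings live on.
#' @param samples List of samples `list(mapping, smap, origin)` (see
#'   [make_mapping_dataset()] / [read_mapping_dataset()]).
#' @param config A [surrogate_config()].
#' @return List of class `surrogate_fit`: `model` (best-epoch weights),
#'   `log` (data frame of per-epoch train/validation MAE), `best_epoch`,
#'   `split` (list of train/val/test sample indices), `config`.
#' @export
train_surrogate <- function(graph, samples, config = surrogate_config()) {
  stopifnot(inherits(graph, "protein_graph"), length(samples) >= 10)
  S <- length(samples)
  y <- vapply(samples, function(s) s$smap, numeric(1))
  if (any(!is.finite(y))) stop("non-finite target in samples")
  sites <- lapply(samples, function(s) {
    stopifnot(s$mapping$n == graph$n_vertices)
    as.integer(s$mapping$retained)
  })

  perm <- with_local_seed(config$seed, sample.int(S))
  n_tr <- floor(config$split[1] * S)
  n_va <- floor(config$split[2] * S)
  if (n_tr < 1 || S - n_tr - n_va < 0) stop("split infeasible for ", S, " samples")
  idx_tr <- perm[seq_len(n_tr)]
  idx_va <- perm[n_tr + seq_len(n_va)]
  idx_te <- perm[setdiff(seq_len(S), seq_len(n_tr + n_va))]

  y_center <- 0; y_scale <- 1
  if (config$normalize) {
    y_center <- mean(y[idx_tr]); y_scale <- stats::sd(y[idx_tr])
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  }
  y_fit <- (y - y_center) / y_scale

  model <- new_surrogate_model(config)
  Xbase <- graph$features; Xbase[, "Site"] <- 0
  fit <- cpp_dgn_train(Xbase, edge_imat(graph), graph$edge_weight, sites,
                       y_fit, idx_tr - 1L, idx_va - 1L,
                       model_weights(model), config$L,
                       config$learning_rate, config$batch_size,
                       config$max_epochs, config$patience,
                       as.numeric(config$seed))
  model$W <- fit$weights$W
  model$b <- fit$weights$b
  model$eps <- as.numeric(fit$weights$eps)
  model$w_site <- fit$weights$w_site
  model$w_nonsite <- fit$weights$w_nonsite
  model$w_out <- as.numeric(fit$weights$w_out)
  model$y_center <- y_center; model$y_scale <- y_scale

  structure(list(
    model = model,
    log = data.frame(epoch = seq_along(fit$train_mae),
                     train_mae = fit$train_mae * y_scale,
                     val_mae = fit$val_mae * y_scale),
    best_epoch = fit$best_epoch,
    best_val_mae = fit$best_val_mae * y_scale,
    split = list(train = idx_tr, val = idx_va, test = idx_te),
    config = config
  ), class = "surrogate_fit")
}

#' @export
print.surrogate_fit <- function(x, ...) {
  cat(sprintf("surrogate fit: %d epochs run, best epoch %d (val MAE %.4g)\n",
              nrow(x$log), x$best_epoch, x$best_val_mae))
  invisible(x)
}

#' Regression metrics for surrogate assessment
#'
#' `R2 = 1 - SS_res / SS_tot` (in `(-Inf, 1]`) and the mean absolute error.
#'
#' @param truth,predictions Equal-length numeric vectors (length >= 2);
#'   `truth` must not be constant (R2 undefined).
#' @return List with `r2` and `mae`.
#' @export
evaluate_predictions <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("R2 undefined: truth values are all identical")
  ss_res <- sum((truth - predictions)^2)
  list(r2 = 1 - ss_res / ss_tot, mae = mean(abs(truth - predictions)))
}

#' Save / load a surrogate checkpoint
#'
#' A single JSON file holding the configuration, seed and all weights at
#' full precision.
#'
#' @param model A `surrogate_model`.
#' @param path File path.
#' @return `read_surrogate` returns the `surrogate_model`.
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  payload <- list(config = unclass(model$config), W = model$W, b = model$b,
                  eps = model$eps, w_site = model$w_site,
                  w_nonsite = model$w_nonsite, w_out = model$w_out,
                  y_center = model$y_center, y_scale = model$y_scale)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cf <- lapply(x$config, unlist)
  cfg <- surrogate_config(K = cf$K, L = cf$L, in_dim = cf$in_dim,
                          learning_rate = cf$learning_rate,
                          batch_size = cf$batch_size,
                          max_epochs = cf$max_epochs,
                          patience = cf$patience,
                          split = as.numeric(cf$split), seed = cf$seed,
                          normalize = cf$normalize)
  structure(list(config = cfg,
                 W = lapply(x$W, function(w) do.call(rbind, lapply(w, unlist))),
                 b = lapply(x$b, function(v) as.numeric(unlist(v))),
                 eps = as.numeric(unlist(x$eps)),
                 w_site = x$w_site, w_nonsite = x$w_nonsite,
                 w_out = as.numeric(unlist(x$w_out)),
                 y_center = x$y_center, y_scale = x$y_scale),
            class = "surrogate_model")
}
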