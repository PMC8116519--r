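#' Wang-Landau sampler configuration
#'
#' The score axis `[s_min, s_max]` is discretized into half-open bins
#' `[s_min + i*delta_s, s_min + (i+1)*delta_s)` with the top edge closed.
#' Defaults follow the standard flat-histogram protocol: initial log
#' modification factor 1, halved at every flatness event down to `1e-6`
#' (exactly 20 halvings), flatness parameter 0.8, bin width 0.2.
#'
#' @param s_min,s_max Range of permitted scores (kJ/mol/K for S_map
#'   oracles); proposals outside are rejected moves.
#' @param delta_s Bin width (default 0.2).
#' @param p_flat Flatness parameter in (0, 1]: the histogram is flat when
#'   every (visited) bin count lies strictly between `p_flat * mean` and
#'   `(2 - p_flat) * mean` (default 0.8).
#' @param ln_f0 Initial log modification factor (default 1).
#' @param ln_f_end Convergence threshold on the log modification factor
#'   (default 1e-6).
#' @param check_interval Monte-Carlo moves between flatness checks
#'   (default 1000).
#' @param seed Integer seed for the whole run.
#' @return A `wl_config` with the derived bin count `n_bins`.
#' @export
wl_config <- function(s_min, s_max, delta_s = 0.2, p_flat = 0.8,
                      ln_f0 = 1.0, ln_f_end = 1e-6,
                      check_interval = 1000L, seed = 1L) {
  stopifnot(s_min < s_max, delta_s > 0, p_flat > 0, p_flat <= 1,
            ln_f_end < ln_f0, ln_f0 > 0, check_interval >= 1)
  n_bins <- as.integer(ceiling((s_max - s_min) / delta_s - 1e-9))
  structure(list(s_min = s_min, s_max = s_max, delta_s = delta_s,
                 p_flat = p_flat, ln_f0 = ln_f0, ln_f_end = ln_f_end,
                 check_interval = as.integer(check_interval),
                 seed = as.integer(seed), n_bins = n_bins),
            class = "wl_config")
}

#' Bin index of a score
#'
#' `floor((s - s_min) / delta_s)` for `s` in `[s_min, s_max)`; `s = s_max`
#' falls in the last bin (closed top edge); scores outside the range map to
#' the out-of-range marker `NA` (a rejected move, not an error).
#'
#' @param s Score value.
#' @param config A [wl_config()].
#' @return 0-based bin index, or `NA` if out of range.
#' @export
bin_index <- function(s, config) {
  stopifnot(inherits(config, "wl_config"))
  if (is.na(s) || s < config$s_min || s > config$s_max) return(NA_integer_)
  if (s == config$s_max) return(config$n_bins - 1L)
  min(as.integer(floor((s - config$s_min) / config$delta_s)),
      config$n_bins - 1L)
}

#' Wang-Landau acceptance of a move between bins
#'
#' Accepts with probability
#' `min(1, exp(sigma[current] - sigma[proposed]))`, i.e. the walk is biased
#' toward bins with a smaller running density-of-states estimate. Only
#' differences of `sigma` enter, so the estimate is defined up to an
#' additive constant.
#'
#' @param sigma Per-bin log density of states.
#' @param bin_current,bin_proposed 0-based in-range bin indices.
#' @return Logical: accept the move?
#' @export
wl_accept <- function(sigma, bin_current, bin_proposed) {
  d <- sigma[bin_current + 1L] - sigma[bin_proposed + 1L]
  d >= 0 || stats::runif(1) < exp(d)
}

#' Wang-Landau bookkeeping update after a move
#'
#' Increments the visit histogram and the log density of states of the bin
#' actually occupied after the move (the proposed bin on acceptance, the
#' current bin on rejection): `hist[b] += 1`, `sigma[b] += ln_f`.
#'
#' @param state A `wl_state` list with `sigma`, `hist`, `ln_f`.
#' @param visited_bin 0-based in-range bin index occupied after the move.
#' @return The updated state.
#' @export
wl_update <- function(state, visited_bin) {
  if (is.na(visited_bin)) stop("wl_update requires an in-range bin")
  b <- visited_bin + 1L
  state$hist[b] <- state$hist[b] + 1L
  state$sigma[b] <- state$sigma[b] + state$ln_f
  state
}

#' Histogram flatness test
#'
#' A histogram is flat when every bin count lies strictly between
#' `p_flat * mean` and `(2 - p_flat) * mean` over the bins considered.
#' An all-zero histogram is never flat.
#'
#' @param hist Per-bin visit counts.
#' @param p_flat Flatness parameter in (0, 1].
#' @return Logical.
#' @export
is_flat <- function(hist, p_flat) {
  if (length(hist) == 0 || all(hist == 0)) return(FALSE)
  m <- mean(hist)
  all(hist > p_flat * m & hist < (2 - p_flat) * m)
}

#' Wang-Landau reconstruction of the density of states
#'
#' Runs the self-consistent flat-histogram scheme over the fixed-`N` mapping
#' space: a random walk by [swap_move()]s, each proposal scored by the
#' oracle, rejected outright when the score leaves `[s_min, s_max]`, and
#' otherwise accepted per [wl_accept()]; after every move the occupied bin
#' is updated per [wl_update()]. Whenever the iteration's histogram is flat
#' (checked every `check_interval` moves, over the bins ever visited), the
#' histogram is reset and `ln_f` is halved; the run stops when
#' `ln_f < ln_f_end` (20 halvings at the defaults). The first in-range
#' mapping is found by repeated uniform draws (budget 1e5).
#'
#' @param oracle Function `cg_mapping -> numeric` (a trained surrogate via
#'   [surrogate_oracle()], or a toy oracle).
#' @param n,N Mapping-space dimensions.
#' @param config A [wl_config()].
#' @return List of class `wl_result`: `sigma` (log density of states, `-Inf`
#'   for never-visited bins, defined up to an additive constant), `hist`
#'   (final-iteration histogram), `mids` (bin centers), `ln_f_log` (the
#'   `ln_f` of each completed iteration), `moves_log` (moves per iteration),
#'   `total_moves`, `visited` (logical per bin), `config`.
#' @export
wl_run <- function(oracle, n, N, config) {
  stopifnot(inherits(config, "wl_config"))
  set.seed(config$seed)
  nb <- config$n_bins

  # fast scoring path: oracles may expose a raw-index scorer
  scorer <- attr(oracle, "score_retained")
  if (is.null(scorer)) scorer <- function(retained) oracle(cg_mapping(n, retained))

  cur <- NULL
  for (i in seq_len(1e5)) {
    cand <- random_mapping(n, N)
    s <- oracle(cand)
    if (!is.finite(s)) stop("oracle returned non-finite score")
    b <- bin_index(s, config)
    if (!is.na(b)) { cur <- cand; s_cur <- s; b_cur <- b; break }
  }
  if (is.null(cur)) {
    stop("no in-range starting mapping found in 1e5 random draws")
  }

  sigma <- numeric(nb)          # ln Omega, initialized to 0 (Omega = 1)
  visited <- logical(nb)
  ln_f <- config$ln_f0
  ln_f_log <- numeric(0)
  moves_log <- integer(0)
  total_moves <- 0L
  retained <- cur$retained
  is_ret <- logical(n); is_ret[retained + 1L] <- TRUE

  s_min <- config$s_min; s_max <- config$s_max; delta <- config$delta_s
  while (ln_f >= config$ln_f_end) {
    hist <- integer(nb)
    moves <- 0L
    repeat {
      for (k in seq_len(config$check_interval)) {
        # in-place swap proposal (equivalent to swap_move on cg_mapping)
        out_pos <- sample.int(N, 1L)
        out_atom <- retained[out_pos]
        repeat {
          in_atom <- sample.int(n, 1L) - 1L
          if (!is_ret[in_atom + 1L]) break
        }
        prop_ret <- retained
        prop_ret[out_pos] <- in_atom
        s_prop <- scorer(prop_ret)
        if (!is.finite(s_prop)) stop("oracle returned non-finite score")
        # inline bin_index: half-open bins, top edge closed, outside -> reject
        if (s_prop >= s_min && s_prop <= s_max) {
          b_prop <- if (s_prop == s_max) nb - 1L
                    else min(as.integer((s_prop - s_min) %/% delta), nb - 1L)
          d <- sigma[b_cur + 1L] - sigma[b_prop + 1L]
          if (d >= 0 || stats::runif(1) < exp(d)) {
            is_ret[out_atom + 1L] <- FALSE
            is_ret[in_atom + 1L] <- TRUE
            retained <- prop_ret
            s_cur <- s_prop
            b_cur <- b_prop
          }
        }
        bb <- b_cur + 1L
        hist[bb] <- hist[bb] + 1L
        sigma[bb] <- sigma[bb] + ln_f
        visited[bb] <- TRUE
        moves <- moves + 1L
      }
      if (is_flat(hist[visited], config$p_flat)) break
    }
    ln_f_log <- c(ln_f_log, ln_f)
    moves_log <- c(moves_log, moves)
    total_moves <- total_moves + moves
    ln_f <- ln_f / 2
  }

  sigma_out <- ifelse(visited, sigma, -Inf)
  mids <- config$s_min + config$delta_s * (seq_len(nb) - 0.5)
  structure(list(sigma = sigma_out, hist = hist, mids = mids,
                 ln_f_log = ln_f_log, moves_log = moves_log,
                 total_moves = total_moves, visited = visited,
                 config = config),
            class = "wl_result")
}

#' @export
print.wl_result <- function(x, ...) {
  cat(sprintf("Wang-Landau run: %d bins (%d visited), %d iterations, %d moves\n",
              length(x$sigma), sum(x$visited), length(x$ln_f_log),
              x$total_moves))
  invisible(x)
}

#' Normalize a log density of states into a probability distribution
#'
#' `P = exp(sigma - max(sigma))`, renormalized to sum to 1 (log-sum-exp
#' stabilized); never-visited bins (`sigma = -Inf`) get probability 0.
#' This is the distribution of scores expected under uniform random
#' sampling of mappings restricted to the binned range.
#'
#' @param sigma Per-bin log density of states.
#' @return Per-bin probabilities summing to 1.
#' @export
dos_to_probability <- function(sigma) {
  fin <- is.finite(sigma)
  if (!any(fin)) stop("all bins unvisited: no density of states to normalize")
  w <- numeric(length(sigma))
  w[fin] <- exp(sigma[fin] - max(sigma[fin]))
  w / sum(w)
}

#' Write a Wang-Landau result as text artifacts
#'
#' Emits `<prefix>_dos.csv` with per-bin center, Sigma, final histogram and
#' probability, and `<prefix>_run.json` with the configuration and the
#' iteration log.
#'
#' @param result A `wl_result`.
#' @param prefix Output path prefix.
#' @return The CSV path, invisibly.
#' @export
write_wl_result <- function(result, prefix) {
  stopifnot(inherits(result, "wl_result"))
  tab <- data.frame(bin_center = result$mids, sigma = result$sigma,
                    hist = result$hist, p = dos_to_probability(result$sigma))
  csv <- paste0(prefix, "_dos.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  meta <- list(config = unclass(result$config), ln_f_log = result$ln_f_log,
               moves_log = result$moves_log, total_moves = result$total_moves)
  jsonlite::write_json(meta, paste0(prefix, "_run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
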