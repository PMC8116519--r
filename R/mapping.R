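#' Coarse-grained mappings over a fixed-size atom subset
#'
#' A *CG mapping* is the unit of the combinatorial search space explored by
#' this package: out of `n` heavy atoms, exactly `N = length(retained)`
#' distinct atoms (0-based indices) are kept verbatim as CG sites and the
#' rest are integrated out.
#'
#' @param n Total number of atoms in the structure.
#' @param retained Integer vector of distinct 0-based atom indices to keep.
#' @return An object of class `cg_mapping` with fields `n`, `retained`
#'   (sorted) and `N`.
#' @examples
#' m <- cg_mapping(10, c(0, 3, 7))
#' m$N
#' @export
cg_mapping <- function(n, retained) {
  n <- as.integer(n)
  retained <- as.integer(retained)
  stopifnot(n >= 1L)
  if (anyDuplicated(retained)) stop("retained indices must be distinct")
  if (length(retained) && (min(retained) < 0L || max(retained) >= n)) {
    stop("retained index out of range [0, n): n = ", n)
  }
  structure(
    list(n = n, retained = sort(retained), N = length(retained)),
    class = "cg_mapping"
  )
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat(sprintf("CG mapping: %d of %d atoms retained\n", x$N, x$n))
  if (x$N <= 20L) cat("  retained:", paste(x$retained, collapse = " "), "\n")
  invisible(x)
}

#' Draw a uniformly random CG mapping
#'
#' Samples one of the `choose(n, N)` subsets of size `N` uniformly, using
#' R's global random-number stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @inheritParams cg_mapping
#' @param N Number of retained atoms, `0 < N <= n`.
#' @return A `cg_mapping`.
#' @export
random_mapping <- function(n, N) {
  n <- as.integer(n); N <- as.integer(N)
  if (N <= 0L || N > n) stop("require 0 < N <= n")
  cg_mapping(n, sample.int(n, N) - 1L)
}

#' Propose a swap move between a retained and a non-retained atom
#'
#' The elementary Monte-Carlo move of the mapping space: one retained atom
#' (chosen uniformly) leaves the CG representation and one non-retained atom
#' (chosen uniformly) enters, so `N` is preserved and the indicator vectors
#' of input and output differ in exactly two positions. The proposal is
#' symmetric: each of the `N * (n - N)` neighbours is proposed with equal
#' probability, in both directions.
#'
#' @param mapping A `cg_mapping` with `0 < N < n`.
#' @return A new `cg_mapping` one swap away from `mapping`.
#' @export
swap_move <- function(mapping) {
  stopifnot(inherits(mapping, "cg_mapping"))
  n <- mapping$n; N <- mapping$N
  if (N == 0L || N == n) stop("no swap move possible: N must satisfy 0 < N < n")
  out_atom <- mapping$retained[sample.int(N, 1L)]
  free <- setdiff(0:(n - 1L), mapping$retained)
  in_atom <- free[sample.int(n - N, 1L)]
  cg_mapping(n, c(setdiff(mapping$retained, out_atom), in_atom))
}

#' Count the CG mappings with N retained atoms, exactly
#'
#' Returns the binomial coefficient `choose(n, N)` as an exact decimal
#' string, computed with arbitrary-precision integer arithmetic (the
#' mapping spaces of even small proteins overflow double precision).
#' Internally uses the multiplicative formula with exact small-integer
#' division on a base-1e9 digit vector.
#'
#' @inheritParams random_mapping
#' @param N Number of retained atoms, `0 <= N <= n`.
#' @return Character scalar: the exact count in decimal. The numeric value
#'   is attached as attribute `"double"` (may be `Inf` past ~1e308).
#' @examples
#' count_mappings(4, 2)    # "6"
#' count_mappings(230, 31) # far beyond 2^53, still exact
#' @export
count_mappings <- function(n, N) {
  n <- as.integer(n); N <- as.integer(N)
  if (N < 0L || N > n) stop("require 0 <= N <= n")
  N <- min(N, n - N)
  acc <- big_from_int(1)
  if (N > 0L) {
    for (i in seq_len(N)) {
      acc <- big_mul_small(acc, n - N + i)
      acc <- big_div_small(acc, i) # exact at every step of the running product
    }
  }
  out <- big_to_string(acc)
  structure(out, double = as.numeric(out))
}

# --- minimal exact big-integer helpers (little-endian base-1e9 digits) ------

.BIG_BASE <- 1e9

big_from_int <- function(x) as.numeric(x)

big_mul_small <- function(digits, m) {
  # m and every digit < 1e9, so digit * m < 2^53 stays exact in doubles
  carry <- 0
  out <- numeric(length(digits))
  for (i in seq_along(digits)) {
    v <- digits[i] * m + carry
    out[i] <- v %% .BIG_BASE
    carry <- (v - out[i]) / .BIG_BASE
  }
  while (carry > 0) {
    d <- carry %% .BIG_BASE
    out <- c(out, d)
    carry <- (carry - d) / .BIG_BASE
  }
  out
}

big_div_small <- function(digits, d) {
  # exact division by a small integer, most-significant digit first
  rem <- 0
  out <- numeric(length(digits))
  for (i in rev(seq_along(digits))) {
    v <- rem * .BIG_BASE + digits[i]
    out[i] <- v %/% d
    rem <- v %% d
  }
  stopifnot(rem == 0)
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_to_string <- function(digits) {
  hi <- format(digits[length(digits)], scientific = FALSE)
  lo <- sprintf("%09.0f", rev(digits[-length(digits)]))
  paste0(hi, paste(lo, collapse = ""))
}

#' Simulated-annealing configuration
#'
#' The effective temperature decays exponentially with the step index,
#' `T(i) = T0 * exp(-i / v)`, with `i` counted from 0.
#'
#' @param T0 Initial effective temperature, in the units of the score being
#'   minimized. If `NULL`, [simulated_annealing()] calibrates it from the
#'   score spread over 100 random mappings.
#' @param v Decay constant in steps. If `NULL`, set to `steps / 5`.
#' @param steps Total number of Monte-Carlo steps (>= 1).
#' @param seed Integer seed controlling the whole run.
#' @return An `sa_config` list.
#' @export
sa_config <- function(T0 = NULL, v = NULL, steps = 20000L, seed = 1L) {
  steps <- as.integer(steps)
  stopifnot(steps >= 1L, is.null(T0) || T0 > 0, is.null(v) || v > 0)
  structure(list(T0 = T0, v = v, steps = steps, seed = as.integer(seed)),
            class = "sa_config")
}

#' Annealing temperature schedule
#'
#' @param i Step index (0-based); vectorized.
#' @param T0 Initial temperature.
#' @param v Decay constant in steps.
#' @return `T0 * exp(-i / v)`.
#' @export
sa_temperature <- function(i, T0, v) T0 * exp(-i / v)

#' Minimize a mapping score by simulated annealing
#'
#' Metropolis Monte-Carlo over the fixed-`N` mapping space: at step `i`
#' (0-based) a [swap_move()] is proposed and accepted with probability
#' `min(1, exp(-(S' - S) / T(i)))` under the exponential cooling schedule
#' `T(i) = T0 * exp(-i / v)`. The best mapping seen so far is tracked and
#' returned; its score trace is non-increasing by construction.
#'
#' @param oracle Function `cg_mapping -> finite numeric score` to minimize.
#' @param n,N Mapping-space dimensions.
#' @param config An [sa_config()]. `NULL` entries for `T0`/`v` are
#'   calibrated as documented there and reported in the result.
#' @param start Optional starting `cg_mapping` (default: uniform random).
#' @return List of class `sa_result`: `best_mapping`, `best_score`,
#'   `best_trace` (best-so-far score after every step), `accept_rate`,
#'   `T0`, `v`, `steps`, `seed`.
#' @export
simulated_annealing <- function(oracle, n, N, config = sa_config(), start = NULL) {
  stopifnot(inherits(config, "sa_config"))
  set.seed(config$seed)
  cur <- if (is.null(start)) random_mapping(n, N) else start
  stopifnot(cur$n == n, cur$N == N)

  T0 <- config$T0
  if (is.null(T0)) {
    spread <- stats::sd(vapply(seq_len(100), function(i) {
      oracle(random_mapping(n, N))
    }, numeric(1)))
    T0 <- if (spread > 0) spread else 1
  }
  v <- if (is.null(config$v)) config$steps / 5 else config$v

  # fast scoring path shared with the Wang-Landau sampler
  scorer <- attr(oracle, "score_retained")
  if (is.null(scorer)) scorer <- function(retained) oracle(cg_mapping(n, retained))

  retained <- cur$retained
  is_ret <- logical(n); is_ret[retained + 1L] <- TRUE
  s_cur <- scorer(retained)
  if (!is.finite(s_cur)) stop("oracle returned non-finite score at the start mapping")
  best <- retained; s_best <- s_cur
  trace <- numeric(config$steps)
  n_acc <- 0L
  for (i in seq_len(config$steps)) {
    temp <- sa_temperature(i - 1, T0, v)
    out_pos <- sample.int(N, 1L)
    out_atom <- retained[out_pos]
    repeat {
      in_atom <- sample.int(n, 1L) - 1L
      if (!is_ret[in_atom + 1L]) break
    }
    prop <- retained
    prop[out_pos] <- in_atom
    s_prop <- scorer(prop)
    if (!is.finite(s_prop)) {
      stop("oracle returned non-finite score for mapping {",
           paste(prop, collapse = ","), "}")
    }
    delta <- s_prop - s_cur
    accept <- delta <= 0 || (temp > 0 && stats::runif(1) < exp(-delta / temp))
    if (accept) {
      is_ret[out_atom + 1L] <- FALSE
      is_ret[in_atom + 1L] <- TRUE
      retained <- prop
      s_cur <- s_prop
      n_acc <- n_acc + 1L
      if (s_cur < s_best) { best <- retained; s_best <- s_cur }
    }
    trace[i] <- s_best
  }
  structure(list(best_mapping = cg_mapping(n, best), best_score = s_best,
                 best_trace = trace,
                 accept_rate = n_acc / config$steps, T0 = T0, v = v,
                 steps = config$steps, seed = config$seed),
            class = "sa_result")
}

#' Read or write a mapping as JSON
#'
#' File schema: `{"n": int, "retained": [0-based ints]}`.
#'
#' @param mapping A `cg_mapping`.
#' @param path File path.
#' @return `read_mapping` returns a `cg_mapping`; `write_mapping` its path,
#'   invisibly.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "cg_mapping"))
  jsonlite::write_json(list(n = mapping$n, retained = mapping$retained),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cg_mapping(x$n, x$retained)
}
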