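#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed for a named stage, derived from the run seed.
# Keeps generator stages on independent substreams so regenerating one
# stage does not perturb the others.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) * 69069 + h * 2654435) %% 2147483647)
}

is_simplex <- function(x, tol = 1e-9) {
  is.numeric(x) && all(x >= -tol) && abs(sum(x) - 1) <= tol
}

assert_simplex <- function(x, what = "proportion vector", tol = 1e-9) {
  if (!is_simplex(x, tol)) {
    stop(what, " must be nonnegative and sum to 1 (got sum ", format(sum(x)), ")",
         call. = FALSE)
  }
  invisible(x)
}

# Align two named vectors on a shared index; error if the indices differ.
align_index <- function(px, py) {
  if (is.null(names(px)) || is.null(names(py))) {
    if (length(px) != length(py)) {
      stop("vectors must share the same index (lengths differ)", call. = FALSE)
    }
    return(list(px = px, py = py))
  }
  if (!setequal(names(px), names(py))) {
    stop("vectors must share the same index (names differ)", call. = FALSE)
  }
  list(px = px, py = py[names(px)])
}

# One multivariate-hypergeometric draw: subsample `k` items without
# replacement from an urn with `counts` balls per colour (sequential
# conditional rhyper draws).
rmvhyper <- function(counts, k) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (k > total) stop("cannot subsample ", k, " from ", total, " items", call. = FALSE)
  out <- numeric(length(counts))
  remaining <- total
  left <- k
  for (i in seq_along(counts)) {
    if (left == 0) break
    if (remaining == counts[i]) {
      out[i] <- left
      left <- 0
      break
    }
    x <- stats::rhyper(1, counts[i], remaining - counts[i], left)
    out[i] <- x
    left <- left - x
    remaining <- remaining - counts[i]
  }
  out
}

# Dirichlet draw via gamma normalization.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
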