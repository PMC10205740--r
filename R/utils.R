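# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# stop() with a condition class so callers can catch specific failure modes
ep_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# population standard deviation (divisor n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x)

# Separable Gaussian blur of a matrix with reflected boundaries. Implemented
# with dense banded kernel matrices so one BLAS call does each pass; kernels
# wider than the image are supported (radius capped at n - 1).
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur1 <- function(n) {
    r <- min(ceiling(3 * sigma), n - 1)
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    M <- matrix(0, n, n + 2 * r)
    for (j in 0:(2 * r)) M[cbind(seq_len(n), seq_len(n) + j)] <- k[j + 1]
    # fold padded columns back with reflection
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    P <- matrix(0, n + 2 * r, n)
    P[cbind(seq_len(n + 2 * r), idx)] <- 1
    M %*% P
  }
  Kr <- blur1(nrow(x))
  Kc <- blur1(ncol(x))
  Kr %*% x %*% t(Kc)
}

# nearest-neighbour upsample of a matrix to given dims (used for label maps)
upsample_nearest <- function(m, out_h, out_w) {
  ri <- pmin(nrow(m), floor((seq_len(out_h) - 1) * nrow(m) / out_h) + 1)
  ci <- pmin(ncol(m), floor((seq_len(out_w) - 1) * ncol(m) / out_w) + 1)
  m[ri, ci, drop = FALSE]
}
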