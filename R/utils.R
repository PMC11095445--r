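# Internal geometry and error helpers.

hk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hk_error"), call = call))
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) hk_stop("cannot normalize a zero vector",
                                       "hk_degenerate_input")
  v / n
}

cross3 <- function(a, b) pracma::cross(a, b)

# Unwrap a phase sequence: remove 2*pi jumps so consecutive differences lie
# in (-pi, pi]. Assumes |true phase step| < pi between samples (Nyquist).
unwrap_phase <- function(theta) {
  theta - 2 * pi * cumsum(c(0, round(diff(theta) / (2 * pi))))
}

# Deterministic right-handed in-plane basis (e1, e2) perpendicular to unit u,
# with e1 x e2 = u.
plane_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitv(ref - sum(ref * u) * u)
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

# Total-least-squares line through 3D points (rows of m): principal direction
# of the centered cloud.
tls_line <- function(m) {
  centroid <- colMeans(m)
  x <- sweep(m, 2, centroid)
  sv <- svd(x, nu = 0)
  dir <- sv$v[, 1]
  proj <- (x %*% dir) %*% t(dir)
  rms <- sqrt(mean(rowSums((x - proj)^2)))
  list(point = centroid, direction = dir, rms = rms)
}

# Evaluate the package drift model (constant velocity + low-frequency
# sinusoid) at times t; returns an n x 3 matrix in mm.
drift_at <- function(drift, t) {
  n <- length(t)
  if (is.null(drift)) return(matrix(0, n, 3))
  if (is.matrix(drift)) {
    if (nrow(drift) != n) hk_stop("drift matrix must have one row per frame",
                                  "hk_parameter_error")
    return(drift)
  }
  vel <- drift$velocity %||% c(0, 0, 0)
  amp <- drift$amplitude %||% c(0, 0, 0)
  period <- drift$period %||% 5
  out <- outer(t, vel)
  out + outer(sin(2 * pi * t / period), amp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards (same contract as simulate.lm).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
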