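# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package: explicit loops and textbook formulas
# only, so agreement is evidence rather than tautology.

# Pearson r from the definitional sum formula.
naive_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))
  num / den
}

# Full CRITIC chain, step by step.
naive_critic <- function(x, directions) {
  n <- nrow(x); p <- ncol(x)
  norm <- matrix(0, n, p, dimnames = dimnames(x))
  for (j in 1:p) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi > lo) {
      norm[, j] <- if (directions[j] == "benefit") {
        (x[, j] - lo) / (hi - lo)
      } else {
        (hi - x[, j]) / (hi - lo)
      }
    }
  }
  sigma <- numeric(p)
  for (j in 1:p) sigma[j] <- sqrt(mean((norm[, j] - mean(norm[, j]))^2))
  active <- which(apply(x, 2, function(col) max(col) > min(col)))
  conflict <- info <- numeric(p)
  for (j in active) {
    s <- 0
    for (k in active) s <- s + (1 - naive_pearson(norm[, j], norm[, k]))
    conflict[j] <- s
    info[j] <- sigma[j] * s
  }
  w <- if (sum(info) > 0) info / sum(info) else rep(0, p)
  list(norm = norm, sigma = sigma, conflict = conflict, info = info, weight = w)
}

# Full VIKOR chain, step by step, on the raw matrix.
naive_vikor <- function(x, w, directions, v = 0.5) {
  n <- nrow(x); p <- ncol(x)
  s <- r <- numeric(n)
  for (i in 1:n) {
    terms <- c()
    for (j in 1:p) {
      lo <- min(x[, j]); hi <- max(x[, j])
      if (hi == lo) next
      if (directions[j] == "benefit") {
        fp <- hi; fm <- lo
      } else {
        fp <- lo; fm <- hi
      }
      terms <- c(terms, w[j] * (fp - x[i, j]) / (fp - fm))
    }
    s[i] <- sum(terms)
    r[i] <- max(terms)
  }
  sp <- min(s); sm <- max(s); rp <- min(r); rm <- max(r)
  q <- numeric(n)
  for (i in 1:n) {
    qs <- if (sm > sp) (s[i] - sp) / (sm - sp) else 0
    qr <- if (rm > rp) (r[i] - rp) / (rm - rp) else 0
    q[i] <- v * qs + (1 - v) * qr
  }
  list(s = s, r = r, q = q)
}

# Truncated-normal mean and SD by numerical quadrature on the density,
# independent of the package's inverse-CDF sampler.
truncnorm_moments <- function(mean, sd, lower, upper) {
  z <- stats::integrate(function(t) stats::dnorm(t, mean, sd),
                        lower, upper, rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(t) t * stats::dnorm(t, mean, sd) / z,
                         lower, upper, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(t) t^2 * stats::dnorm(t, mean, sd) / z,
                         lower, upper, rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Benefit/cost directions for a code vector, from the default registry.
indicator_dirs_for_test <- function(codes) {
  reg <- default_registry()
  reg$direction[match(codes, reg$code)]
}

# Random trait matrix over a random registry subset with random directions;
# returns the matrix and a matching ad-hoc registry.
random_instance <- function(n, p) {
  reg <- default_registry()
  codes <- sample(reg$code, p)
  x <- matrix(stats::rnorm(n * p, mean = 10, sd = 3), n, p,
              dimnames = list(paste0("V", 1:n), codes))
  trait_matrix(x, registry = reg)
}
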