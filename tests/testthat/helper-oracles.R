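# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the MEC oracle enumerates all support circles,
# and the gamma-GLM oracle is a from-scratch reweighted least-squares loop.

# Brute-force minimum enclosing circle: the optimum is determined by 2 or 3
# support points, so enumerate every 2-point (diameter) and 3-point
# (circumcircle) candidate and keep the smallest that contains all points.
mec_bruteforce <- function(x, y) {
  n <- length(x)
  if (n == 1) return(list(center = c(x, y), radius = 0))
  pts <- cbind(x, y)
  best_r <- Inf
  best_c <- NULL
  contains_all <- function(cx, cy, r) {
    all((x - cx)^2 + (y - cy)^2 <= (r + 1e-9)^2)
  }
  prs <- utils::combn(n, 2)
  for (k in seq_len(ncol(prs))) {
    a <- pts[prs[1, k], ]; b <- pts[prs[2, k], ]
    cx <- (a[1] + b[1]) / 2; cy <- (a[2] + b[2]) / 2
    r <- sqrt(sum((a - b)^2)) / 2
    if (r < best_r && contains_all(cx, cy, r)) {
      best_r <- r; best_c <- c(cx, cy)
    }
  }
  if (n >= 3) {
    trs <- utils::combn(n, 3)
    for (k in seq_len(ncol(trs))) {
      a <- pts[trs[1, k], ]; b <- pts[trs[2, k], ]; cc <- pts[trs[3, k], ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
               sum(cc^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
               sum(cc^2) * (b[1] - a[1])) / d
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (r < best_r && contains_all(ux, uy, r)) {
        best_r <- r; best_c <- c(ux, uy)
      }
    }
  }
  list(center = best_c, radius = best_r)
}

# Hand-rolled IRLS for a gamma GLM with log link (unit working weights
# for this family/link combination; the working response carries the fit).
irls_gamma_log <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y)), rep(0, ncol(X) - 1))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X), crossprod(X, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# Small deterministic ground truth / grid used by several tests (coarse
# grid keeps the suite fast).
test_grid <- function(cell_km = 20) study_grid(cell_km = cell_km)

test_gt <- function(...) ground_truth(...)
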