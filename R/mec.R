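#' Minimum enclosing circle of a point set
#'
#' Smallest circle containing all points, computed by the incremental
#' (Welzl-style) algorithm: points violating the current circle are
#' promoted to the boundary, and circles are rebuilt from at most three
#' support points. Exact for collinear and duplicate points; a single
#' point gives radius 0.
#'
#' @param x,y Numeric vectors of projected coordinates (km), or `x` may be
#'   a two-column matrix/data frame.
#' @return A list with `center` (length-2 numeric) and `radius`.
#' @export
#' @examples
#' # circumcircle of an equilateral triangle with side 1: radius 1/sqrt(3)
#' tri <- cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
#' minimum_enclosing_circle(tri)$radius
minimum_enclosing_circle <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2)
    y <- x[, 2]; x <- x[, 1]
  }
  n <- length(x)
  if (n == 0) abort("cannot compute the enclosing circle of an empty set")
  p <- cbind(x, y)

  inside <- function(circ, q) {
    sqrt(sum((q - circ$center)^2)) <= circ$radius + 1e-9
  }
  circ2 <- function(a, b) {
    list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      # collinear: fall back to the widest diameter pair
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }

  circ <- list(center = p[1, ], radius = 0)
  for (i in seq_len(n)[-1]) {
    if (inside(circ, p[i, ])) next
    circ <- list(center = p[i, ], radius = 0)
    for (j in seq_len(i - 1)) {
      if (inside(circ, p[j, ])) next
      circ <- circ2(p[i, ], p[j, ])
      for (k in seq_len(j - 1)) {
        if (inside(circ, p[k, ])) next
        circ <- circ3(p[i, ], p[j, ], p[k, ])
      }
    }
  }
  list(center = unname(circ$center), radius = unname(circ$radius))
}
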