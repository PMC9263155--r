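# Independent oracles used to cross-check the package's own algorithms.
# Each is a deliberately naive implementation of the textbook definition,
# sharing no code with the implementation it checks.

# Even-odd ray casting point-in-polygon (horizontal ray to +x).
rayCastInside <- function(points, polygon) {
  P <- rbind(points); V <- rbind(polygon); m <- nrow(V)
  vapply(seq_len(nrow(P)), function(i) {
    px <- P[i, 1]; py <- P[i, 2]
    crossings <- 0L
    for (e in seq_len(m)) {
      a <- V[e, ]; b <- V[(e %% m) + 1, ]
      if ((a[2] > py) != (b[2] > py)) {
        xInt <- a[1] + (py - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        if (xInt > px) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Cox-de Boor basis functions by direct recursion; curve as basis summation.
naiveBasis <- function(i, p, t, knots) {
  if (p == 0)
    return(as.numeric(knots[i] <= t & t < knots[i + 1]))
  d1 <- knots[i + p] - knots[i]
  d2 <- knots[i + p + 1] - knots[i + 1]
  a <- if (d1 > 0) (t - knots[i]) / d1 * naiveBasis(i, p - 1, t, knots) else 0
  b <- if (d2 > 0) (knots[i + p + 1] - t) / d2 *
         naiveBasis(i + 1, p - 1, t, knots) else 0
  a + b
}

naiveBSplineEval <- function(ts, knots, ctrl, degree = 3L) {
  out <- matrix(0, length(ts), ncol(ctrl))
  for (i in seq_len(nrow(ctrl))) {
    Ni <- naiveBasis(i, degree, ts, knots)
    out <- out + outer(Ni, ctrl[i, ])
  }
  out
}

# Convex hull membership by brute force over all point triples: a plane
# through 3 points is a hull facet iff all points lie on one side; a query
# is inside iff it is on the inner side of every facet plane.
hullPlanesOracle <- function(P) {
  n <- nrow(P)
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c3 <- P[k, ]
    nrm <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
             (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
             (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    if (sqrt(sum(nrm^2)) < 1e-12) next
    s <- as.numeric(P %*% nrm) - sum(nrm * a)
    tol <- 1e-9 * max(1, max(abs(s)))
    if (all(s <= tol)) planes[[length(planes) + 1L]] <- c(nrm, sum(nrm * a))
    else if (all(s >= -tol)) planes[[length(planes) + 1L]] <- c(-nrm, -sum(nrm * a))
  }
  do.call(rbind, planes)
}

inHullOracle <- function(queries, planes, tol = 1e-7) {
  q <- rbind(queries)
  inside <- rep(TRUE, nrow(q))
  for (r in seq_len(nrow(planes))) {
    nrm <- planes[r, 1:3]
    scale <- sqrt(sum(nrm^2))
    inside <- inside & (as.numeric(q %*% nrm) - planes[r, 4]) / scale <= tol
  }
  inside
}

# Exhaustive flood-fill component labeling (stack-based), 8- or 26-connected.
labelOracle <- function(mask) {
  dims <- dim(mask); nd <- length(dims)
  off <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  lab <- array(0L, dims)
  nextLab <- 0L
  idx <- which(mask != 0, arr.ind = TRUE)
  ord <- do.call(order, lapply(seq_len(nd), function(d) idx[, d]))
  for (r in ord) {
    p <- idx[r, ]
    if (lab[rbind(p)] != 0L) next
    nextLab <- nextLab + 1L
    stack <- list(p)
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (lab[rbind(q)] != 0L) next
      lab[rbind(q)] <- nextLab
      for (o in seq_len(nrow(off))) {
        nb <- q + off[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (mask[rbind(nb)] != 0 && lab[rbind(nb)] == 0L)
          stack[[length(stack) + 1L]] <- nb
      }
    }
  }
  lab
}

# Small phantom spec for unit tests (2 cm x 4 cm zone on a 48^3 mm grid).
testSpec <- function(...) {
  args <- list(gridShape = c(48L, 48L, 48L), seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(phantomSpec, args)
}

# Random simple (star-shaped) polygon around the origin.
randomSimplePolygon <- function(n = 20) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 2, 10)
  cbind(r * cos(th), r * sin(th))
}
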