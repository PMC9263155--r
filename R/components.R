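# Connected-component analysis used to denoise thresholded necrosis masks.
# 8-connectivity in 2D, 26-connectivity in 3D (the most permissive standard
# choice). Ties between equal-size components are broken deterministically
# toward the component containing the lexicographically smallest pixel.

neighborOffsets <- function(ndim) {
  if (ndim == 2L) {
    off <- expand.grid(di = -1:1, dj = -1:1)
    off <- as.matrix(off[!(off$di == 0 & off$dj == 0), ])
  } else {
    off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    off <- as.matrix(off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ])
  }
  # Half of the symmetric set suffices for undirected adjacency.
  keep <- apply(off, 1, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' 8-connected in 2D, 26-connected in 3D. Labels are assigned in order of
#' each component's lexicographically smallest pixel (first index fastest).
#'
#' @param mask logical/0-1 matrix or 3D array.
#' @return integer array of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  dims <- dim(mask)
  ndim <- length(dims)
  stopifnot(ndim %in% c(2L, 3L))
  lab <- array(0L, dim = dims)
  fg <- which(mask != 0)
  if (!length(fg)) return(lab)
  coords <- arrayInd(fg, dims)
  off <- neighborOffsets(ndim)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (d in seq_len(ndim))
      ok <- ok & nb[, d] >= 1L & nb[, d] <= dims[d]
    if (!any(ok)) next
    mult <- cumprod(c(1L, dims[-ndim]))
    nlin <- as.integer(1 + (nb[ok, , drop = FALSE] - 1) %*% mult)
    j <- match(nlin, fg)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  if (length(from)) {
    g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # Relabel by lexicographic order of each component's smallest pixel.
  # Pixel lexicographic order: first coordinate most significant.
  lexKey <- coords[, ndim]
  for (d in rev(seq_len(ndim - 1L)))
    lexKey <- lexKey + coords[, d] * prod(dims) ^ (ndim - d)
  firstSeen <- tapply(lexKey, memb, min)
  newId <- rank(firstSeen, ties.method = "first")
  lab[fg] <- as.integer(newId[as.character(memb)])
  lab
}

#' Retain only the largest connected component
#'
#' Removes background speckle from a thresholded necrosis mask. Equal-size
#' ties are broken toward the component containing the lexicographically
#' smallest pixel. An empty mask is returned unchanged.
#'
#' @param mask binary matrix (8-connected) or 3D array (26-connected).
#' @return binary array of the same shape.
#' @export
largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (!any(lab > 0)) return(array(0, dim = dim(mask)))
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))[1]  # labels are in lexicographic order
  out <- array(0, dim = dim(mask))
  out[lab == best] <- 1
  out
}
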