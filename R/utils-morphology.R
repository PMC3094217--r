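## Low-level array morphology shared across modules: shifted views, 3D
## connected components by frontier expansion, border extraction, per-slice
## hole filling and signed distance fields.

# shift a 3D array by (dz, dy, dx), zero-filling exposed planes
shift3 <- function(a, dz = 0, dy = 0, dx = 0) {
  d <- dim(a)
  out <- array(0, d)
  src <- list(max(1, 1 - dz):min(d[1], d[1] - dz),
              max(1, 1 - dy):min(d[2], d[2] - dy),
              max(1, 1 - dx):min(d[3], d[3] - dx))
  dst <- list(src[[1]] + dz, src[[2]] + dy, src[[3]] + dx)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# neighbor offset table in (dz, dy, dx); connectivity 6 or 26
neighborOffsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# linear-index offsets for a padded array of dims pd
linearOffsets <- function(pd, connectivity = 26L) {
  off <- neighborOffsets(connectivity)
  off[, 1] + off[, 2] * pd[1] + off[, 3] * pd[1] * pd[2]
}

padZero3 <- function(a) {
  d <- dim(a)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (a != 0)
  p
}

unpad3 <- function(p) {
  d <- dim(p) - 2L
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

# label the connected components of a 3D binary array; returns an integer
# array of the same shape, labels 1..n in decreasing component size order
labelComponents3D <- function(a, connectivity = 26L) {
  d <- dim(a)
  p <- padZero3(a != 0)
  pd <- dim(p)
  offs <- linearOffsets(pd, connectivity)
  labels <- integer(length(p))
  fg <- which(p)
  nextLab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    nextLab <- nextLab + 1L
    labels[seed] <- nextLab
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[p[nb] & labels[nb] == 0L]
      labels[nb] <- nextLab
      frontier <- nb
    }
  }
  lab <- array(labels, pd)
  lab <- unpad3(lab)
  if (nextLab > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = nextLab)
    # relabel so that label 1 is the biggest component (deterministic:
    # ties keep first-seen order, which follows linear index order)
    ord <- order(-sizes, seq_len(nextLab))
    remap <- integer(nextLab)
    remap[ord] <- seq_len(nextLab)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# flood fill from seed linear indices through an acceptance region
floodFrom3D <- function(accept, seeds, connectivity = 26L) {
  d <- dim(accept)
  p <- padZero3(accept != 0)
  pd <- dim(p)
  # map original linear indices into padded space
  ai <- arrayInd(seeds, d) + 1L
  pseeds <- ai[, 1] + (ai[, 2] - 1L) * pd[1] + (ai[, 3] - 1L) * pd[1] * pd[2]
  offs <- linearOffsets(pd, connectivity)
  visited <- logical(length(p))
  pseeds <- pseeds[p[pseeds]]
  visited[pseeds] <- TRUE
  frontier <- pseeds
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, "+")))
    nb <- nb[p[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  unpad3(array(as.integer(visited), pd))
}

# border voxels of a 3D binary array: foreground with a 6-neighbor outside
# (the array edge counts as outside)
borderVoxels3D <- function(a) {
  m <- a != 0
  inside <- shift3(m, 1, 0, 0) & shift3(m, -1, 0, 0) &
            shift3(m, 0, 1, 0) & shift3(m, 0, -1, 0) &
            shift3(m, 0, 0, 1) & shift3(m, 0, 0, -1)
  m & !inside
}

# 2D fill-holes on one axial slice (4-connected background)
fillHoles2D <- function(m) {
  out <- EBImage::fillHull(matrix(as.integer(m != 0), nrow(m), ncol(m)))
  matrix(as.integer(out != 0), nrow(m), ncol(m))
}

# signed distance (pixels) to the boundary of a 2D binary mask,
# negative inside, via two Euclidean distance transforms
signedDistance2D <- function(m) {
  m <- matrix(as.numeric(m != 0), nrow(m), ncol(m))
  if (all(m == 0)) return(matrix(1e6, nrow(m), ncol(m)))
  if (all(m == 1)) return(matrix(-1e6, nrow(m), ncol(m)))
  outside <- EBImage::distmap(1 - m)
  inside <- EBImage::distmap(m)
  outside - inside
}

# largest connected component of a 2D binary matrix (8-connectivity);
# ties broken by smaller label (scan order)
largestComponent2D <- function(m) {
  lab <- EBImage::bwlabel(matrix(as.integer(m != 0), nrow(m), ncol(m)))
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(m), ncol(m)))
  sizes <- tabulate(lab[lab > 0], nbins = n)
  best <- which.max(sizes)
  matrix(as.integer(lab == best), nrow(m), ncol(m))
}
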