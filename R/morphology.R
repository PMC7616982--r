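# Vectorised 3D binary morphology on logical arrays, plus connected
# components via voxel-adjacency graphs. Structuring elements are digital
# balls; shifts run as whole-array moves so no per-voxel loops occur.

shift_array <- function(x, off, fill = FALSE) {
  d <- dim(x)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - off[a]
    i[i < 1 | i > d[a]] <- NA
    i
  })
  out <- x[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out[is.na(out)] <- fill
  dim(out) <- d
  out
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

binary_dilate <- function(mask, radius = 1) {
  offs <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out | shift_array(mask, offs[i, ], FALSE)
  out
}

binary_erode <- function(mask, radius = 1) {
  offs <- ball_offsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out & shift_array(mask, offs[i, ], FALSE)
  out
}

binary_close <- function(mask, radius = 1) binary_erode(binary_dilate(mask, radius), radius)

# Neighbour offsets for 6- or 26-connectivity (half set; edges are undirected).
conn_offsets <- function(connectivity = 26) {
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
  if (connectivity == 6) g <- g[abs(g$x) + abs(g$y) + abs(g$z) == 1, ]
  g <- as.matrix(g)
  # keep one direction per unordered pair
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns an integer array
# with 0 = background, components numbered by decreasing size.
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  offs <- conn_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nb <- shift_array(mask, offs[i, ], FALSE)
    both <- which(mask & nb)
    if (length(both)) {
      sh <- shift_array(vid, offs[i, ], 0L)
      from <- c(from, vid[both]); to <- c(to, sh[both])
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  rank <- integer(comp$no); rank[ord] <- seq_len(comp$no)
  lab[idx] <- rank[comp$membership]
  lab
}

largest_component <- function(mask, connectivity = 26) {
  label_components(mask, connectivity) == 1L
}

# 6-connected flood fill of TRUE voxels of `free` reachable from the grid
# border, as a frontier BFS with vectorised neighbour expansion.
flood_from_border <- function(free) {
  d <- dim(free); nx <- d[1]; nxy <- d[1] * d[2]
  border <- array(FALSE, d)
  border[1, , ] <- TRUE; border[nx, , ] <- TRUE
  border[, 1, ] <- TRUE; border[, d[2], ] <- TRUE
  border[, , 1] <- TRUE; border[, , d[3]] <- TRUE
  reached <- array(FALSE, d)
  frontier <- which(border & free)
  reached[frontier] <- TRUE
  while (length(frontier)) {
    f <- frontier
    i <- (f - 1L) %% nx + 1L
    j <- ((f - 1L) %/% nx) %% d[2] + 1L
    k <- (f - 1L) %/% nxy + 1L
    nb <- c(f[i < nx] + 1L, f[i > 1L] - 1L,
            f[j < d[2]] + nx, f[j > 1L] - nx,
            f[k < d[3]] + nxy, f[k > 1L] - nxy)
    nb <- unique(nb)
    nb <- nb[free[nb] & !reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  reached
}

# Fill enclosed 3D cavities that are small relative to the mask itself
# (intra-bone holes), leaving large enclosed spaces such as the cranial
# cavity untouched.
fill_small_holes_3d <- function(mask, max_frac = 0.25) {
  free <- !mask
  enclosed <- free & !flood_from_border(free)
  if (!any(enclosed)) return(mask)
  lab <- label_components(enclosed, connectivity = 6)
  limit <- max_frac * sum(mask)
  sizes <- tabulate(lab[lab > 0L])
  fill_ids <- which(sizes <= limit)
  mask | (lab > 0L & array(lab %in% fill_ids, dim(mask)))
}

# Fill every enclosed 3D cavity (anything not reachable from the border).
fill_holes_3d <- function(mask) {
  free <- !mask
  mask | (free & !flood_from_border(free))
}
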