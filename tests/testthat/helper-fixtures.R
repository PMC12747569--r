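# Shared fixture builders; everything is generated in code at test time.

# Small, fast tube-tree spec used across mesh/centerline/capping tests.
small_tree <- function(n, open = TRUE, res = 12L) {
  tree_spec(n, root_radius = 3, segment_length = 14, resolution = res,
            open_ends = open)
}

# Solid ball mask of radius r voxels in an n^3 grid.
ball_mask <- function(n, r, ctr = (n - 1) / 2) {
  xs <- 0:(n - 1)
  d2 <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  d2 <= r^2
}

# Smooth strictly positive random field: trilinear interpolation of a
# coarse uniform grid; emulates a slowly varying inscribed-radius field.
smooth_field <- function(n, nc = 4, lo = 0.75, hi = 1.35, seed = 1) {
  set.seed(seed)
  base <- array(runif(nc^3, lo, hi), c(nc, nc, nc))
  xs <- seq(1, nc, length.out = n)
  i0 <- pmin(floor(xs), nc - 1)
  fr <- xs - i0
  r <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    a <- i0[i]; b <- i0[j]; cc <- i0[k]
    fx <- fr[i]; fy <- fr[j]; fz <- fr[k]
    r[i, j, k] <-
      (1 - fx) * (1 - fy) * (1 - fz) * base[a, b, cc] +
      fx * (1 - fy) * (1 - fz) * base[a + 1, b, cc] +
      (1 - fx) * fy * (1 - fz) * base[a, b + 1, cc] +
      (1 - fx) * (1 - fy) * fz * base[a, b, cc + 1] +
      fx * fy * (1 - fz) * base[a + 1, b + 1, cc] +
      fx * (1 - fy) * fz * base[a + 1, b, cc + 1] +
      (1 - fx) * fy * fz * base[a, b + 1, cc + 1] +
      fx * fy * fz * base[a + 1, b + 1, cc + 1]
  }
  r
}

# Independent shortest-path oracle for the weighted Eikonal equation:
# Dijkstra over a 5x5x5 voxel neighborhood (coprime moves), edge cost =
# segment length times the mean slowness of its endpoints.
dijkstra_arrival <- function(r, src_idx) {
  n <- dim(r)[1]
  offs <- as.matrix(expand.grid(di = -2:2, dj = -2:2, dk = -2:2))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  gcd2 <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }
  g3 <- apply(abs(offs), 1, function(x) Reduce(gcd2, x[x > 0]))
  offs <- offs[g3 == 1, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  coords <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  slow <- 1 / r
  edges <- vector("list", nrow(offs)); ws <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    di <- offs[o, 1]; dj <- offs[o, 2]; dk <- offs[o, 3]
    ok <- coords[, 1] + di >= 1 & coords[, 1] + di <= n &
      coords[, 2] + dj >= 1 & coords[, 2] + dj <= n &
      coords[, 3] + dk >= 1 & coords[, 3] + dk <= n
    a <- which(ok)
    b <- a + di + n * dj + n * n * dk
    edges[[o]] <- cbind(a, b)
    ws[[o]] <- sqrt(di^2 + dj^2 + dk^2) * (slow[a] + slow[b]) / 2
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  src <- src_idx[1] + n * (src_idx[2] - 1) + n * n * (src_idx[3] - 1)
  array(igraph::distances(g, v = src, weights = unlist(ws))[1, ], dim(r))
}

# Brute-force triangle shape factor via Heron's formula.
heron_sq <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2)); b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  s <- (a + b + c) / 2
  A2 <- s * (s - a) * (s - b) * (s - c)
  A <- sqrt(max(A2, 0))
  4 * sqrt(3) * A / (a^2 + b^2 + c^2)
}
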