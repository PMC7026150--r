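# planar rectangular grid mesh in z = 0, SW-NE diagonals: the main diagonal
# of a square grid is an exact edge path, so corner-to-corner geodesics on it
# have a closed form
make_grid_mesh <- function(nx, ny, h = 1) {
  xy <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(xy$x * h, xy$y * h, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- do.call(rbind, lapply(seq_len(ny - 1), function(j) {
    do.call(rbind, lapply(seq_len(nx - 1), function(i) {
      rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
            c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }))
  }))
  face_mesh(v, faces, subject_id = "grid")
}

# independent O(n^3) Floyd-Warshall over the same node/edge set the
# implementation searches; the dual route for the Dijkstra result
floyd_warshall_dist <- function(graph_obj) {
  g <- graph_obj$graph
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    D[i, j] <- min(D[i, j], w[e])
    D[j, i] <- min(D[j, i], w[e])
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# rigid transform: fixed rotation (axis-angle) plus translation
rigid_transform <- function(pts, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(10, -4, 25)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(pts %*% t(R), 2, shift, "+")
}

# canonical-name landmark set laid out flat on a grid-mesh surface (z = 0);
# coordinates chosen to sit exactly on vertices of make_grid_mesh(41, 41, 4)
flat_landmarks <- function(h = 4) {
  snap <- function(x, y) c(round(x / h) * h, round(y / h) * h, 0)
  landmark_set(list(
    trichion = snap(80, 150), nasion = snap(80, 100),
    pronasale = snap(80, 72), subnasale = snap(80, 64),
    labiale_superius = snap(80, 52), stomion = snap(80, 40),
    exocanthion_l = snap(36, 100), exocanthion_r = snap(124, 100),
    alare_l = snap(72, 68), alare_r = snap(88, 68),
    frontotemporale_l = snap(20, 136), frontotemporale_r = snap(140, 136),
    zygion_r = snap(144, 80)), subject_id = "flat")
}
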