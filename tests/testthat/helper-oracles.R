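# Independent pure-R geometry oracles. These deliberately re-derive distances
# from first principles (vectorised point-triangle distance over all
# triangles) so the compiled implementation is checked against a separate
# code path.

# Squared distances from many points (n x 3) to ONE triangle, vectorised
# over points. Region classification follows the standard closest-point
# decomposition of the triangle's plane.
oracle_pt_tri_dist2 <- function(P, a, b, c) {
  ab <- b - a; ac <- c - a
  n <- nrow(P)
  Ap <- sweep(P, 2, a)
  d1 <- Ap %*% ab; d2 <- Ap %*% ac
  Bp <- sweep(P, 2, b)
  d3 <- Bp %*% ab; d4 <- Bp %*% ac
  Cp <- sweep(P, 2, c)
  d5 <- Cp %*% ab; d6 <- Cp %*% ac
  Q <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_q <- function(idx, M) { Q[idx, ] <<- M; done[idx] <<- TRUE }
  r1 <- !done & d1 <= 0 & d2 <= 0
  if (any(r1)) set_q(r1, matrix(a, sum(r1), 3, byrow = TRUE))
  r2 <- !done & d3 >= 0 & d4 <= d3
  if (any(r2)) set_q(r2, matrix(b, sum(r2), 3, byrow = TRUE))
  vc <- d1 * d4 - d3 * d2
  r3 <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r3)) {
    v <- (d1[r3] / (d1[r3] - d3[r3]))
    set_q(r3, matrix(a, sum(r3), 3, byrow = TRUE) + outer(as.vector(v), ab))
  }
  r4 <- !done & d6 >= 0 & d5 <= d6
  if (any(r4)) set_q(r4, matrix(c, sum(r4), 3, byrow = TRUE))
  vb <- d5 * d2 - d1 * d6
  r5 <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r5)) {
    w <- (d2[r5] / (d2[r5] - d6[r5]))
    set_q(r5, matrix(a, sum(r5), 3, byrow = TRUE) + outer(as.vector(w), ac))
  }
  va <- d3 * d6 - d5 * d4
  r6 <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r6)) {
    w <- ((d4 - d3)[r6] / ((d4 - d3)[r6] + (d5 - d6)[r6]))
    set_q(r6, matrix(b, sum(r6), 3, byrow = TRUE) + outer(as.vector(w), c - b))
  }
  rest <- !done
  if (any(rest)) {
    denom <- 1 / (va[rest] + vb[rest] + vc[rest])
    v <- vb[rest] * denom
    w <- vc[rest] * denom
    set_q(rest, matrix(a, sum(rest), 3, byrow = TRUE) +
            outer(as.vector(v), ab) + outer(as.vector(w), ac))
  }
  rowSums((P - Q)^2)
}

# Unsigned min distance from points to a whole mesh, brute force.
oracle_mesh_dist <- function(mesh, P) {
  V <- mesh$vertices
  F <- mesh$faces
  best <- rep(Inf, nrow(P))
  for (t in seq_len(nrow(F))) {
    d2 <- oracle_pt_tri_dist2(P, V[F[t, 1], ], V[F[t, 2], ], V[F[t, 3], ])
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Brute-force unique nearest-cell attribution: exact distances to every cell,
# assign to the closest iff within t, ties to lexicographically smallest id.
oracle_attribution <- function(cells, P, t) {
  ids <- vapply(cells, function(m) as.character(attr(m, "cell_id")), character(1))
  D <- vapply(cells, function(m) oracle_mesh_dist(m, P), numeric(nrow(P)))
  D <- matrix(D, nrow = nrow(P))
  winner <- rep(NA_character_, nrow(P))
  for (i in seq_len(nrow(P))) {
    j <- which(D[i, ] == min(D[i, ]))
    if (length(j) > 1) j <- j[order(ids[j])][1]
    if (D[i, j] <= t) winner[i] <- ids[j]
  }
  winner
}

# Hand Pearson chi-square from the textbook formula.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Random small scene: a few well-separated ellipsoid cells plus spots thrown
# around their surfaces and into open space.
random_test_scene <- function(n_cells, n_spots, subdiv = 1, spread = 26) {
  cells <- lapply(seq_len(n_cells), function(i) {
    ctr <- c((i - 1) %% 3, (i - 1) %/% 3, 0) * spread +
      stats::runif(3, -2, 2)
    ellipsoid_mesh(stats::runif(3, 3.5, 7), center = ctr,
                   rotation = random_rotation(), subdiv = subdiv,
                   cell_id = sprintf("c%02d", i))
  })
  allv <- do.call(rbind, lapply(cells, function(m) m$vertices))
  lo <- apply(allv, 2, min) - 4
  hi <- apply(allv, 2, max) + 4
  # bias spots toward the surfaces so attribution is actually contested
  surface_pts <- do.call(rbind, lapply(cells, function(m) {
    k <- ceiling(n_spots / (2 * n_cells))
    idx <- sample(nrow(m$vertices), k, replace = TRUE)
    m$vertices[idx, , drop = FALSE] + matrix(stats::rnorm(3 * k, 0, 1.2), k, 3)
  }))
  free_pts <- cbind(stats::runif(n_spots - nrow(surface_pts), lo[1], hi[1]),
                    stats::runif(n_spots - nrow(surface_pts), lo[2], hi[2]),
                    stats::runif(n_spots - nrow(surface_pts), lo[3], hi[3]))
  P <- rbind(surface_pts, free_pts)[seq_len(n_spots), , drop = FALSE]
  spots <- tibble::tibble(
    marker = sample(c("TH", "ENK"), n_spots, replace = TRUE),
    x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
  list(cells = cells, spots = spots)
}

# Minimal label table for a set of cell ids.
make_labels <- function(ids, chat = TRUE, nos = FALSE, excluded = FALSE,
                        reason = ifelse(excluded, "manual", "")) {
  tibble::tibble(cell_id = ids, chat = chat, nos = nos,
                 excluded = excluded, exclusion_reason = reason,
                 basket_th = NA, basket_enk = NA)
}
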