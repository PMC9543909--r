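# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (direct enumeration, igraph shortest paths, bisection) so
# they never share code paths with the implementation they check.

# Scalar bisection solve of the coupled operating point An = model(Ci - An/gm).
bisection_operating_point <- function(Ci, p, k, tol = 1e-12) {
  g <- function(An) {
    Cc <- if (is.finite(p$gm)) Ci - An / p$gm else Ci
    model_assimilation(Cc, p, k)$An - An
  }
  lo <- -p$Rd - 1
  hi <- min(p$Vcmax, 3 * p$TPU, p$Jmax / 4) + 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Multi-source Dijkstra on the IAS voxel graph via igraph, 26-connectivity,
# chamfer weights. Returns distances for the open voxels (linear indices).
oracle_geodesic <- function(v, sources) {
  arr <- v$voxels
  d <- dim(arr)
  open <- which(arr == 4L)
  key <- match(seq_len(prod(d)), open)  # linear index -> vertex id
  coords <- arrayInd(open, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
            (offs[, 1] == 0 & offs[, 2] > 0) |
            (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)), , drop = FALSE]
  ed <- c(); w <- c()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * ((nb[ok, 2] - 1) + d[2] * (nb[ok, 3] - 1))
    tgt <- key[lin]
    src <- which(ok)[!is.na(tgt)]
    tgt <- tgt[!is.na(tgt)]
    ed <- c(ed, rbind(src, tgt))
    w <- c(w, rep(sqrt(sum(offs[r, ]^2)) * v$voxel_size, length(tgt)))
  }
  g <- igraph::make_empty_graph(length(open), directed = FALSE)
  g <- igraph::add_edges(g, ed, weight = w)
  D <- igraph::distances(g, v = match(sources, open))
  out <- rep(Inf, prod(d))
  out[open] <- apply(D, 2, min)
  out
}

# Unobstructed slab: a thin cell sheet under the adaxial epidermis, IAS
# everywhere else, no labelled stomata (sources fall back to the whole
# abaxial-adjacent IAS layer).
slab_phantom <- function(nz = 24, nx = 16, ny = 16, voxel = 0.65) {
  a <- array(4L, c(nz, nx, ny))
  a[1:2, , ] <- 1L
  a[(nz - 1):nz, , ] <- 2L
  a[3:4, , ] <- 3L
  labeled_volume(a, voxel)
}

# U-shaped channel around a solid wall with a single stoma at the entrance;
# geodesic and Euclidean distances separate strongly.
u_channel_phantom <- function() {
  nz <- 12; nx <- 9; ny <- 5
  a <- array(3L, c(nz, nx, ny))
  a[1, , ] <- 1L
  a[nz, , ] <- 2L
  a[2:(nz - 1), 2, 3] <- 4L
  a[2:3, 2:8, 3] <- 4L
  a[2:(nz - 1), 8, 3] <- 4L
  a[nz, 2, 3] <- 6L
  labeled_volume(a, 1)
}

# Wall/no-wall pair for the obstacle-monotonicity property.
wall_phantom <- function(with_wall = TRUE) {
  nz <- 14; nx <- 15; ny <- 7
  a <- array(4L, c(nz, nx, ny))
  a[1, , ] <- 1L
  a[2, , ] <- 3L
  a[nz, , ] <- 2L
  if (with_wall) a[4:(nz - 2), 8, ] <- 3L
  a[nz, 3, 4] <- 6L
  labeled_volume(a, 1)
}

# Laisk fixture: three low-CO2 response lines through (ci_star, -rd).
laisk_lines <- function(ci_star = 38.18, rd = 0.73,
                        slopes = c(`100` = 0.03, `200` = 0.06, `500` = 0.12),
                        noise_sd = 0) {
  ci <- c(35, 40, 50, 60, 70, 80, 90, 100, 110, 120, 140, 160, 180)
  do.call(rbind, lapply(names(slopes), function(irr) {
    b <- slopes[[irr]]
    data.frame(irradiance = as.numeric(irr), Ci = ci,
               An = -rd + b * (ci - ci_star) + rnorm(length(ci), sd = noise_sd))
  }))
}

# Walnut-calibrated truth used by the recovery studies: Amax = 3*9.08 - 0.73
# = 26.51 umol m-2 s-1, inside the range printed for the best accessions.
walnut_truth <- function() fvcb_params(Vcmax = 100, Jmax = 150, TPU = 9.08,
                                       Rd = 0.73, gm = 0.2, Gammastar = 38.18)
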