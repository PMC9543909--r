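test_that("voxel-count traits match an independent histogram oracle", {
  set.seed(31)
  arr <- array(sample(0:6, 20 * 12 * 12, replace = TRUE,
                      prob = c(1, 2, 2, 5, 4, 1, 0.5)), c(20, 12, 12))
  v <- labeled_volume(arr, 0.65)
  h <- table(factor(arr, levels = 0:6))
  expect_equal(porosity(v), unname(h["4"] / (h["3"] + h["4"] + h["5"])))
  expect_equal(ias_to_cell_ratio(v), unname(h["4"] / h["3"]))
  expect_equal(vein_fraction(v), unname(h["5"] / sum(h[as.character(1:6)])))
  # counts are a partition of the mesophyll
  expect_equal(porosity(v) + h[["3"]] / (h[["3"]] + h[["4"]] + h[["5"]]) +
                 h[["5"]] / (h[["3"]] + h[["4"]] + h[["5"]]), 1)

  # symmetric half/half case and the all-IAS limit
  a2 <- array(c(rep(3L, 500), rep(4L, 500)), c(10, 10, 10))
  expect_equal(porosity(labeled_volume(a2, 1)), 0.5)
  expect_equal(porosity(labeled_volume(array(4L, c(4, 4, 4)), 1)), 1)
  expect_error(porosity(labeled_volume(array(0L, c(3, 3, 3)), 1)), "empty")
})

test_that("labeled volumes reject unknown labels and anisotropic voxels", {
  expect_error(labeled_volume(array(9L, c(3, 3, 3)), 1), "unknown labels")
  expect_error(labeled_volume(array(4L, c(3, 3, 3)), c(0.65, 0.65, 0.9)),
               "anisotropic")
  expect_silent(labeled_volume(array(4L, c(3, 3, 3)), c(0.65, 0.65, 0.65)))
})

test_that("raw face counting reproduces hand-counted surface areas", {
  # single 1-voxel cell surrounded by IAS: 6 faces
  a <- array(4L, c(5, 5, 5)); a[3, 3, 3] <- 3L
  v <- labeled_volume(a, 1)
  expect_equal(surface_area_density(v, mode = "raw"), 6 / 125)
  # 10^3 cube in a 14^3 IAS bath: 600 faces, voxel scaling by 1/voxel
  a2 <- array(4L, c(14, 14, 14)); a2[3:12, 3:12, 3:12] <- 3L
  v2 <- labeled_volume(a2, 0.65)
  expect_equal(surface_area_density(v2, mode = "raw"),
               600 * 0.65^2 / (14^3 * 0.65^3))
  # weighted mode applies the configurable factor; empty interface gives 0
  expect_equal(surface_area_density(v2, correction = 2 / 3),
               surface_area_density(v2, mode = "raw") * 2 / 3)
  expect_equal(surface_area_density(labeled_volume(array(4L, c(4, 4, 4)), 1)), 0)
})

test_that("geodesic maps equal an independent Dijkstra and bound Euclidean", {
  vu <- u_channel_phantom()
  maps <- distance_maps(vu)
  open <- which(vu$voxels == 4L)
  oracle <- oracle_geodesic(vu, maps$sources)
  expect_equal(maps$L_geo[open], oracle[open], tolerance = 1e-12)
  expect_true(any(maps$L_Euc[open] < maps$L_geo[open] - 1e-9))
  expect_true(all(maps$L_geo[open] >= maps$L_Euc[open] - 1e-9))
  # source voxels sit at distance zero
  expect_equal(max(maps$L_geo[maps$sources]), 0)
  expect_equal(max(maps$L_Euc[maps$sources]), 0)

  # a random porous phantom, same exact agreement
  ph <- make_leaf_phantom(leaf_phantom_spec(dims = c(20, 12, 12),
                                            n_stomata = 2, seed = 404))
  vr <- ph$volume
  mr <- distance_maps(vr)
  openr <- which(vr$voxels == 4L)
  oracler <- oracle_geodesic(vr, mr$sources)
  expect_equal(mr$L_geo[openr], oracler[openr], tolerance = 1e-12)
})

test_that("a straight open channel has equal geodesic and Euclidean lengths", {
  nz <- 54; nx <- 7; ny <- 7
  a <- array(3L, c(nz, nx, ny))
  a[1, , ] <- 1L; a[nz, , ] <- 2L
  a[2:(nz - 1), 4, 4] <- 4L
  a[nz, 4, 4] <- 6L
  v <- labeled_volume(a, 0.65)
  m <- distance_maps(v)
  # the source voxel sits at z = 53 next to the pore; the far end is 51
  # straight steps away
  far <- m$L_geo[2, 4, 4]
  expect_equal(far, 51 * 0.65)
  expect_equal(m$L_Euc[2, 4, 4], 51 * 0.65)
})

test_that("removing an obstacle never increases geodesic distance", {
  vw <- wall_phantom(TRUE)
  vo <- wall_phantom(FALSE)
  mw <- distance_maps(vw)
  mo <- distance_maps(vo)
  common <- which(vw$voxels == 4L & vo$voxels == 4L)
  finite <- common[is.finite(mw$L_geo[common])]
  expect_true(all(mo$L_geo[finite] <= mw$L_geo[finite] + 1e-9))
})

test_that("tortuosity is unity on the unobstructed slab and above unity always", {
  vs <- slab_phantom()
  ms <- distance_maps(vs)
  expect_equal(tortuosity_leaf(vs, ms), 1, tolerance = 0.05)
  expect_equal(lateral_path_leaf(vs, ms), 1, tolerance = 0.05)

  for (sd in c(101, 202)) {
    ph <- make_leaf_phantom(leaf_phantom_spec(dims = c(40, 24, 24), seed = sd))
    m <- distance_maps(ph$volume)
    expect_gte(tortuosity_leaf(ph$volume, m), 1 - 1e-9)
    expect_gte(lateral_path_leaf(ph$volume, m), 1 - 0.05)
  }
})

test_that("a serpentine channel has tortuosity near its squared path ratio", {
  vu <- u_channel_phantom()
  m <- distance_maps(vu)
  sel <- m$surface & is.finite(m$L_geo) & m$L_Euc >= m$voxel_size
  tau <- tortuosity_leaf(vu, m)
  # every included voxel obeys tau >= 1; the far arm dominates the mean
  expect_gte(tau, 1)
  ratio <- m$L_geo[sel] / m$L_Euc[sel]
  expect_equal(tau, mean(ratio^2), tolerance = 1e-12)
  expect_gt(max(ratio), 1.5)  # the wall forces a genuine detour
})

test_that("lateral path lengthening matches hand geometry for an offset stoma", {
  # open mesophyll, one cell column at x=16, one stoma at x=3: paths to the
  # column surface run diagonally while L_epi is the vertical drop.
  nz <- 12; nx <- 21; ny <- 5
  a <- array(4L, c(nz, nx, ny))
  a[1, , ] <- 1L; a[nz, , ] <- 2L
  a[2:(nz - 1), 16, 3] <- 3L
  a[nz, 3, 3] <- 6L
  v <- labeled_volume(a, 1)
  m <- distance_maps(v)

  # oracle: direct coordinate arithmetic, independent of the EDT code
  src <- arrayInd(m$sources, dim(a))
  inner <- arrayInd(which(a %in% c(3L, 4L, 5L, 6L) &
                            array(seq_len(nz) == nz - 1, dim(a))), dim(a))
  surf <- which(m$surface & is.finite(m$L_geo) & m$L_Euc >= 1 & m$L_epi >= 1)
  sc <- arrayInd(surf, dim(a))
  euc <- function(p, set) min(sqrt(colSums((t(set) - p)^2)))
  lam_oracle <- mean(vapply(seq_len(nrow(sc)), function(i) {
    euc(sc[i, ], src) / euc(sc[i, ], inner)
  }, numeric(1)))
  expect_equal(lateral_path_leaf(v, m), lam_oracle, tolerance = 1e-9)
  expect_gt(lateral_path_leaf(v, m), 1)
})

test_that("thickness means follow the column-extent oracle", {
  # uniform slab: 100 voxels thick at 0.65 um
  a <- array(3L, c(100, 6, 6))
  a[1:10, , ] <- 1L; a[91:100, , ] <- 2L
  v <- labeled_volume(a, 0.65)
  th <- thicknesses(v)
  expect_equal(th$L_leaf, 65)
  expect_equal(th$L_mes, 80 * 0.65)

  # wedge: mesophyll extent varies across columns; mean equals the oracle
  b <- array(0L, c(30, 8, 4))
  for (x in 1:8) {
    depth <- 10 + 2 * x
    b[1:2, x, ] <- 1L
    b[3:(2 + depth), x, ] <- 3L
    b[(3 + depth):(4 + depth), x, ] <- 2L
  }
  vw <- labeled_volume(b, 1)
  thw <- thicknesses(vw)
  expect_equal(thw$L_mes, mean(10 + 2 * (1:8)))
  expect_equal(thw$L_leaf, mean(10 + 2 * (1:8) + 4))

  expect_error(thicknesses(labeled_volume(array(3L, c(5, 5, 5)), 1)),
               "epidermis")
})

test_that("airspace conductance matches the closed form and its scalings", {
  g <- gias(0.3, L_mes = 200, tau_leaf = 1.5, lambda_leaf = 1.2)
  g_ms_expected <- 0.3 * 1.54e-5 / (0.5 * 200e-6 * 1.5 * 1.2)
  expect_equal(attr(g, "g_ms"), g_ms_expected, tolerance = 1e-12)
  expect_equal(as.numeric(g), g_ms_expected / 0.024465, tolerance = 1e-12)
  expect_equal(as.numeric(g), 1.049, tolerance = 1e-3)
  expect_equal(as.numeric(gias(0, 200, 1.5, 1.2)), 0)

  # inverse proportionality sweeps
  for (c in c(2, 3.5)) {
    expect_equal(as.numeric(gias(0.3, 200, c * 1.5, 1.2)),
                 as.numeric(g) / c, tolerance = 1e-12)
    expect_equal(as.numeric(gias(0.3, 200, 1.5, c * 1.2)),
                 as.numeric(g) / c, tolerance = 1e-12)
    expect_equal(as.numeric(gias(0.3, c * 200, 1.5, 1.2)),
                 as.numeric(g) / c, tolerance = 1e-12)
  }
  expect_error(gias(0.3, -1, 1.5, 1.2), ">")
})

test_that("stomatal counting uses 8-connected components above a size floor", {
  m <- matrix(FALSE, 40, 40)
  expect_equal(stomatal_density(m)$density, 0)

  # 20 isolated stomata in a 0.04 mm2 field
  set.seed(5)
  centers <- expand.grid(r = seq(3, 39, by = 9), c = seq(3, 39, by = 9))[1:20, ]
  for (i in seq_len(nrow(centers))) {
    m[centers$r[i] + (-1:1), centers$c[i] + (-1:1)] <- TRUE
  }
  res <- stomatal_density(m, area_mm2 = 0.04)
  expect_equal(res$count, 20)
  expect_equal(res$density, 500)
  expect_equal(res$mean_size, 9 * 0.65^2)

  # diagonal touching merges under 8-connectivity
  m2 <- matrix(FALSE, 10, 10)
  m2[3, 3] <- TRUE; m2[4, 4] <- TRUE
  expect_equal(stomatal_density(m2, 0.04)$count, 1)
  # size floor removes single-pixel specks
  m2[8, 8] <- TRUE
  expect_equal(stomatal_density(m2, 0.04, min_size = 2)$count, 1)
})

test_that("distance maps refuse volumes with no reachable stomatal sources", {
  # abaxial side sealed by a full cell sheet and no pores labelled
  a <- array(4L, c(10, 6, 6))
  a[1, , ] <- 1L
  a[9, , ] <- 3L
  a[10, , ] <- 2L
  expect_error(distance_maps(labeled_volume(a, 1)), "no stomata")
})
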