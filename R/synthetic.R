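# Seeded generators for all fixture data with known ground truth: labeled
# leaf phantoms, FvCB gas-exchange curves with fluorescence, dehydration
# transforms, and monthly climate tables.

#' Leaf phantom specification
#'
#' Parameters of the synthetic labeled leaf volume: grid shape (z first,
#' adaxial to abaxial), epidermis thicknesses, a palisade layer of cell
#' cylinders, a spongy layer of random cell blobs, vein cylinders, stomatal
#' pores through the abaxial epidermis, and a target mesophyll porosity that
#' the generator reaches by seeded boundary-voxel flipping.
#'
#' @param dims Grid shape `c(nz, nx, ny)` in voxels.
#' @param voxel_size Isotropic voxel edge (um).
#' @param epidermis Adaxial and abaxial epidermis thickness (voxels).
#' @param palisade_frac Fraction of mesophyll depth occupied by palisade.
#' @param palisade_radius,palisade_spacing Cell cylinder geometry (voxels).
#' @param spongy_cell_frac Initial cell volume fraction of the spongy layer.
#' @param target_porosity Target `theta_IAS` of the final mesophyll.
#' @param n_veins,vein_radius Vein cylinders along the y axis.
#' @param n_stomata,stoma_radius Stomatal pores through the abaxial epidermis.
#' @param seed Mandatory RNG seed.
#' @return A list of class `leaf_phantom_spec`.
#' @export
leaf_phantom_spec <- function(dims = c(60, 40, 40), voxel_size = 0.65,
                              epidermis = c(4, 4), palisade_frac = 0.4,
                              palisade_radius = 2, palisade_spacing = 7,
                              spongy_cell_frac = 0.55, target_porosity = 0.3,
                              n_veins = 1, vein_radius = 3,
                              n_stomata = 4, stoma_radius = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory for phantom generation")
  stopifnot(length(dims) == 3, all(dims >= 8),
            sum(epidermis) < dims[1],
            target_porosity > 0, target_porosity < 1,
            n_stomata >= 0)
  structure(as.list(environment()), class = "leaf_phantom_spec")
}

#' Generate a labeled leaf phantom
#'
#' Builds a leaf volume matching the spec and returns it together with its
#' exact, by-construction ground truth (porosity, vein fraction, thicknesses).
#' The mesophyll porosity is tuned to `target_porosity` by flipping randomly
#' chosen cell/IAS boundary voxels; if the target is not reached within 100
#' adjustment iterations the generator fails. The same seed always yields a
#' bit-identical volume.
#'
#' @param spec A [leaf_phantom_spec()].
#' @return A list with `volume` ([labeled_volume()]) and `truth` (named list
#'   with `theta_IAS`, `vein_fraction`, `L_leaf`, `L_mes`, all exact).
#' @export
make_leaf_phantom <- function(spec) {
  stopifnot(inherits(spec, "leaf_phantom_spec"))
  with_seed(spec$seed, build_phantom(spec))
}

build_phantom <- function(spec) {
  d <- spec$dims
  nz <- d[1]; nx <- d[2]; ny <- d[3]
  e1 <- spec$epidermis[1]; e2 <- spec$epidermis[2]
  arr <- array(4L, dim = d)
  arr[1:e1, , ] <- 1L
  arr[(nz - e2 + 1):nz, , ] <- 2L
  mz <- (e1 + 1):(nz - e2)
  n_pal <- round(spec$palisade_frac * length(mz))
  pal_z <- if (n_pal > 0) mz[seq_len(n_pal)] else integer(0)
  spo_z <- setdiff(mz, pal_z)

  # palisade: cell cylinders on a square grid of centres
  if (length(pal_z)) {
    cx <- seq(ceiling(spec$palisade_spacing / 2), nx,
              by = spec$palisade_spacing)
    cy <- seq(ceiling(spec$palisade_spacing / 2), ny,
              by = spec$palisade_spacing)
    xg <- matrix(rep(seq_len(nx), ny), nx, ny)
    yg <- matrix(rep(seq_len(ny), each = nx), nx, ny)
    incell <- matrix(FALSE, nx, ny)
    for (x0 in cx) for (y0 in cy) {
      incell <- incell |
        ((xg - x0)^2 + (yg - y0)^2 <= spec$palisade_radius^2)
    }
    for (z in pal_z) arr[z, , ][incell] <- 3L
  }

  # spongy: random cell ellipsoids until the requested cell fraction
  if (length(spo_z)) {
    n_target <- round(spec$spongy_cell_frac * length(spo_z) * nx * ny)
    guard <- 0
    while (sum(arr[spo_z, , ] == 3L) < n_target && guard < 5000) {
      guard <- guard + 1
      z0 <- sample(spo_z, 1); x0 <- sample(nx, 1); y0 <- sample(ny, 1)
      r <- runif(3, 1.5, 4)
      zr <- max(1, floor(z0 - r[1])):min(nz, ceiling(z0 + r[1]))
      zr <- intersect(zr, spo_z)
      xr <- max(1, floor(x0 - r[2])):min(nx, ceiling(x0 + r[2]))
      yr <- max(1, floor(y0 - r[3])):min(ny, ceiling(y0 + r[3]))
      for (z in zr) for (x in xr) for (y in yr) {
        if (((z - z0) / r[1])^2 + ((x - x0) / r[2])^2 +
            ((y - y0) / r[3])^2 <= 1 && arr[z, x, y] == 4L) {
          arr[z, x, y] <- 3L
        }
      }
    }
  }

  # veins: cylinders along the y axis in the lower mesophyll
  if (spec$n_veins > 0) {
    zc <- spo_z[max(1, round(length(spo_z) / 2))]
    xs <- round(seq(nx / (spec$n_veins + 1), nx - nx / (spec$n_veins + 1),
                    length.out = spec$n_veins))
    for (x0 in xs) {
      zr <- max(min(mz), zc - spec$vein_radius):min(max(mz), zc + spec$vein_radius)
      xr <- max(1, x0 - spec$vein_radius):min(nx, x0 + spec$vein_radius)
      for (z in zr) for (x in xr) {
        if ((z - zc)^2 + (x - x0)^2 <= spec$vein_radius^2) {
          arr[z, x, ] <- 5L
        }
      }
    }
  }

  # stomata: pores through the abaxial epidermis with a substomatal cavity
  if (spec$n_stomata > 0) {
    sx <- sample(seq(2, nx - 1), spec$n_stomata, replace = spec$n_stomata > nx - 2)
    sy <- sample(seq(2, ny - 1), spec$n_stomata, replace = spec$n_stomata > ny - 2)
    ez <- (nz - e2 + 1):nz
    for (s in seq_len(spec$n_stomata)) {
      xr <- max(1, sx[s] - spec$stoma_radius):min(nx, sx[s] + spec$stoma_radius)
      yr <- max(1, sy[s] - spec$stoma_radius):min(ny, sy[s] + spec$stoma_radius)
      for (x in xr) for (y in yr) {
        if ((x - sx[s])^2 + (y - sy[s])^2 <= spec$stoma_radius^2) {
          arr[ez, x, y] <- 6L
        }
      }
      # open the substomatal cavity
      cav_z <- max(min(mz), nz - e2 - 2):(nz - e2)
      xr2 <- max(1, sx[s] - spec$stoma_radius - 1):min(nx, sx[s] + spec$stoma_radius + 1)
      yr2 <- max(1, sy[s] - spec$stoma_radius - 1):min(ny, sy[s] + spec$stoma_radius + 1)
      for (z in cav_z) for (x in xr2) for (y in yr2) {
        if (arr[z, x, y] %in% c(3L, 4L)) arr[z, x, y] <- 4L
      }
    }
  }

  # porosity tuning by boundary-voxel flipping
  tol <- 0.005
  converged <- FALSE
  for (it in 1:100) {
    mes_n <- sum(arr %in% 3:5)
    theta <- sum(arr == 4L) / mes_n
    if (abs(theta - spec$target_porosity) <= tol) {
      converged <- TRUE
      break
    }
    need <- round(abs(theta - spec$target_porosity) * mes_n)
    if (theta < spec$target_porosity) {
      cand <- adjacent_to(arr, 3L, 4L, connectivity = 6)
      if (!length(cand)) break
      flip <- if (length(cand) <= need) cand else sample(cand, need)
      arr[flip] <- 4L
    } else {
      cand <- adjacent_to(arr, 4L, 3L, connectivity = 6)
      # keep substomatal IAS open so sources stay connected
      near_pore <- adjacent_to(arr, 4L, 6L, connectivity = 26)
      cand <- setdiff(cand, near_pore)
      if (!length(cand)) break
      flip <- if (length(cand) <= need) cand else sample(cand, need)
      arr[flip] <- 3L
    }
  }
  if (!converged) {
    stop(sprintf("phantom generator failed to reach porosity %.3f",
                 spec$target_porosity))
  }

  v <- labeled_volume(arr, spec$voxel_size)
  truth <- list(
    theta_IAS = sum(arr == 4L) / sum(arr %in% 3:5),
    vein_fraction = sum(arr == 5L) / sum(arr %in% 1:6),
    L_leaf = nz * spec$voxel_size,
    L_mes = length(mz) * spec$voxel_size
  )
  list(volume = v, truth = truth)
}

#' Gas-exchange simulation specification
#'
#' @param params True [fvcb_params()].
#' @param ca_setpoints Ambient CO2 setpoints (umol mol-1); the default is the
#'   12-step measurement sequence 400, 50, 80, ..., 1500.
#' @param gs Stomatal conductance to CO2-free water vapour basis
#'   (mol m-2 s-1), held constant across the curve.
#' @param noise_sd Gaussian noise SD added to `An` only (umol m-2 s-1).
#' @param ppfd,alpha,beta,T_leaf Light and fluorescence constants.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(params,
                     ca_setpoints = c(400, 50, 80, 100, 150, 200, 400, 600,
                                      800, 1000, 1200, 1500),
                     gs = 0.3, noise_sd = 0, ppfd = 1500,
                     alpha = 0.853, beta = 0.5, T_leaf = 25, seed) {
  if (missing(seed)) stop("a seed is mandatory for gas-exchange simulation")
  stopifnot(inherits(params, "fvcb_params"), noise_sd >= 0, gs > 0,
            all(ca_setpoints > 0))
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate an A-Ci curve with fluorescence records
#'
#' For each ambient CO2 setpoint the intercellular CO2 is found jointly with
#' the FvCB operating point from the stomatal diffusion relation
#' `An = gs (Ca - Ci) / 1.6` (1.6 is the H2O:CO2 diffusivity ratio), so the
#' simulated curve carries the same internal consistency a gas-exchange
#' instrument enforces. The PSII yield is back-computed by inverting
#' `Jflu = PhiPSII * PPFD * alpha * beta` from the electron transport that
#' supports the modelled carboxylation and photorespiration at the operating
#' point, which makes the variable-J estimator an exact algebraic inverse on
#' noiseless points with `Cc > Gammastar`. Gaussian noise is added to `An`
#' only.
#'
#' @param spec A [sim_spec()].
#' @param k A [kinetic_constants()] object.
#' @return An [aci_curve()] with columns `Ca`, `Ci`, `An`, `PPFD`, `PhiPSII`,
#'   `T_leaf` and attribute `truth` (true params, gs, per-point noiseless
#'   values and states).
#' @export
simulate_gas_exchange <- function(spec, k = kinetic_constants()) {
  stopifnot(inherits(spec, "sim_spec"))
  p <- spec$params
  n <- length(spec$ca_setpoints)
  Ci <- numeric(n); An <- numeric(n); Cc <- numeric(n); state <- character(n)
  for (i in seq_len(n)) {
    Ca <- spec$ca_setpoints[i]
    f <- function(ci) {
      spec$gs * (Ca - ci) / 1.6 - solve_operating_point(ci, p, k)$An
    }
    upper <- Ca + 1.6 * (p$Rd + 3) / spec$gs
    root <- tryCatch(
      uniroot(f, c(1e-3, upper), tol = 1e-10)$root,
      error = function(e) {
        stop(sprintf("simulation failed at Ca = %g: %s", Ca, conditionMessage(e)),
             call. = FALSE)
      }
    )
    Ci[i] <- root
    op <- solve_operating_point(root, p, k)
    An[i] <- op$An; Cc[i] <- op$Cc; state[i] <- op$state
  }
  # invert the fluorescence relation from the modelled electron transport
  Jflu <- ifelse(Cc > p$Gammastar + 1e-9,
                 (An + p$Rd) * (4 * Cc + 8 * p$Gammastar) / (Cc - p$Gammastar),
                 NA_real_)
  phi <- Jflu / (spec$ppfd * spec$alpha * spec$beta)
  phi[!is.na(phi) & (phi < 0 | phi > 1)] <- NA_real_
  An_obs <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, An + rnorm(n, sd = spec$noise_sd))
  } else {
    An
  }
  curve <- aci_curve(
    data.frame(Ca = spec$ca_setpoints, Ci = Ci, An = An_obs,
               PPFD = spec$ppfd, PhiPSII = phi, T_leaf = spec$T_leaf)
  )
  attr(curve, "truth") <- list(params = p, gs = spec$gs, An = An, Cc = Cc,
                               Jflu = Jflu, state = state)
  curve
}

#' Apply a dehydration transform to a leaf phantom
#'
#' Emulates the anatomical response to water stress: the mesophyll is
#' down-sampled along z by `shrink_z` (leaf thickness decreases) and cell
#' voxels at the cell/IAS boundary are flipped into airspace until a fraction
#' `cell_erode` of the cell volume is converted (porosity strictly increases).
#' Cells shrink more than the airspace, as observed in dehydrated leaves.
#'
#' @param v A [labeled_volume()].
#' @param shrink_z Fraction of mesophyll z-slices removed, in `[0, 0.5]`.
#' @param cell_erode Fraction of cell voxels eroded into IAS, in `[0, 0.5]`.
#' @param seed RNG seed for the surface flips and slice choice.
#' @return A [labeled_volume()].
#' @export
apply_dehydration <- function(v, shrink_z = 0.1, cell_erode = 0.1, seed = 1L) {
  stopifnot(shrink_z >= 0, shrink_z <= 0.5, cell_erode >= 0, cell_erode <= 0.5)
  if (shrink_z == 0 && cell_erode == 0) return(v)
  with_seed(seed, {
    arr <- v$voxels
    if (shrink_z > 0) {
      has_mes <- which(apply(arr, 1, function(s) any(s %in% 3:5)))
      k <- round(shrink_z * length(has_mes))
      if (k > 0) {
        drop <- has_mes[unique(round(seq(1, length(has_mes), length.out = k)))]
        arr <- arr[-drop, , , drop = FALSE]
      }
    }
    if (cell_erode > 0) {
      quota <- max(1, ceiling(cell_erode * sum(arr == 3L)))
      for (pass in 1:50) {
        if (quota <= 0) break
        cand <- adjacent_to(arr, 3L, 4L, connectivity = 6)
        if (!length(cand)) break
        flip <- if (length(cand) <= quota) cand else sample(cand, quota)
        arr[flip] <- 4L
        quota <- quota - length(flip)
      }
    }
    labeled_volume(arr, v$voxel_size)
  })
}

#' Generate monthly climate tables with known seasonality
#'
#' Sinusoidal monthly mean temperature and precipitation per site with seeded
#' noise. For a noiseless sampled sinusoid with mean `m` and amplitude `a` the
#' 12-month coefficient of variation is exactly
#' `100 * a * sqrt(6/11) / m` (n-1 SD), which is attached as ground truth.
#'
#' @param n_sites Number of sites (>= 1).
#' @param temp_mean_range,temp_amp_range Uniform ranges for the temperature
#'   mean and seasonal amplitude (degC).
#' @param precip_mean_range,precip_amp_range Same for precipitation (mm).
#' @param noise_sd_temp,noise_sd_precip Gaussian noise SDs per month.
#' @param latitude_range,frost_free_range Uniform ranges for site metadata.
#' @param seed Mandatory RNG seed.
#' @return A wide data frame (one row per site: `site_id`, `latitude`,
#'   `t01..t12`, `p01..p12`, `frost_free_days`) with attribute `truth`
#'   (analytic `cv_temp`, `cv_precip` per site, exact when noise is zero).
#' @export
make_climate_table <- function(n_sites = 11,
                               temp_mean_range = c(8, 18),
                               temp_amp_range = c(4, 12),
                               precip_mean_range = c(40, 120),
                               precip_amp_range = c(10, 35),
                               noise_sd_temp = 0, noise_sd_precip = 0,
                               latitude_range = c(30, 46),
                               frost_free_range = c(150, 365), seed) {
  if (missing(seed)) stop("a seed is mandatory for climate generation")
  stopifnot(n_sites >= 1)
  with_seed(seed, {
    months <- 1:12
    rows <- vector("list", n_sites)
    truth <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      tm <- runif(1, temp_mean_range[1], temp_mean_range[2])
      ta <- runif(1, temp_amp_range[1], temp_amp_range[2])
      pm <- runif(1, precip_mean_range[1], precip_mean_range[2])
      pa <- runif(1, precip_amp_range[1], precip_amp_range[2])
      phase_t <- runif(1, 0, 12)
      phase_p <- runif(1, 0, 12)
      temp <- tm + ta * sin(2 * pi * (months - phase_t) / 12) +
        rnorm(12, sd = noise_sd_temp)
      prec <- pm + pa * sin(2 * pi * (months - phase_p) / 12) +
        rnorm(12, sd = noise_sd_precip)
      lat <- runif(1, latitude_range[1], latitude_range[2])
      ffd <- round(runif(1, frost_free_range[1], frost_free_range[2]))
      rows[[s]] <- data.frame(
        site_id = sprintf("S%02d", s), latitude = lat,
        as.list(setNames(temp, sprintf("t%02d", months))),
        as.list(setNames(prec, sprintf("p%02d", months))),
        frost_free_days = ffd
      )
      truth[[s]] <- data.frame(
        site_id = sprintf("S%02d", s),
        cv_temp = 100 * ta * sqrt(6 / 11) / tm,
        cv_precip = 100 * pa * sqrt(6 / 11) / pm
      )
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}
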