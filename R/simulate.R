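# Synthetic multi-channel diffusion phantom: multi-compartment geometry with
# stated diffusivities, per-channel sensitivity maps, sinusoidal background
# phase, spatially varying complex Gaussian noise, and the planted-spike
# matrix toy used to contrast shrinkage strategies.

#' Single-tensor diffusion attenuation
#'
#' Axially symmetric tensor signal \code{exp(-b (D_perp + (D_par - D_perp)
#' (g . u)^2))} for a fiber with orientation \code{u}; equals 1 at
#' \code{b = 0} and decreases with b.
#'
#' @param bval diffusion weighting (s/mm^2); vectorized.
#' @param bvec gradient direction(s), 3-vector or 3 x V matrix.
#' @param orientation unit fiber orientation (3-vector).
#' @param d_par,d_perp parallel and perpendicular diffusivities (mm^2/s);
#'   defaults 1.7e-3 and 0.4e-3, typical human white matter.
#' @return Attenuation in (0, 1], one value per volume.
#' @export
tensor_signal <- function(bval, bvec, orientation, d_par = 1.7e-3,
                          d_perp = 0.4e-3) {
  bvec <- matrix(bvec, nrow = 3)
  u <- orientation / sqrt(sum(orientation^2))
  proj2 <- as.numeric(crossprod(bvec, u))^2
  exp(-bval * (d_perp + (d_par - d_perp) * proj2))
}

#' Isotropic diffusion attenuation
#'
#' \code{exp(-b D_iso)}; the default diffusivity 3.0e-3 mm^2/s is free water
#' (CSF-like), whose signal at b = 3000 s/mm^2 is exp(-9), far below any
#' realistic noise floor.
#'
#' @param bval diffusion weighting (s/mm^2); vectorized.
#' @param d_iso isotropic diffusivity (mm^2/s).
#' @return Attenuation in (0, 1].
#' @export
isotropic_signal <- function(bval, d_iso = 3.0e-3) {
  exp(-bval * d_iso)
}

#' Diffusion protocol of the in-silico study
#'
#' Shells at b = 0, 1000, 2000, 3000 s/mm^2 with 5, 24, 48 and 96 volumes
#' (173 in total).  Directions per shell are spread on the sphere with a
#' deterministic golden-angle (Fibonacci) arrangement; b = 0 volumes carry
#' zero vectors.
#'
#' @param bvals shell b-values.
#' @param counts volumes per shell.
#' @return List with \code{bvals} (length V) and \code{bvecs} (3 x V).
#' @export
dwi_protocol <- function(bvals = c(0, 1000, 2000, 3000),
                         counts = c(5, 24, 48, 96)) {
  stopifnot(length(bvals) == length(counts))
  all_b <- rep(bvals, counts)
  vecs <- matrix(0, 3, sum(counts))
  idx <- cumsum(counts)
  for (s in seq_along(bvals)) {
    if (bvals[s] == 0) next
    nv <- counts[s]
    i <- seq_len(nv)
    # Fibonacci sphere, offset per shell so shells are not collinear
    zc <- (2 * i - 1) / nv - 1
    th <- pi * (1 + sqrt(5)) * i + s
    r <- sqrt(pmax(1 - zc^2, 0))
    vecs[, (idx[s] - nv + 1):idx[s]] <- rbind(r * cos(th), r * sin(th), zc)
  }
  list(bvals = all_b, bvecs = vecs)
}

#' Smooth complex channel sensitivity maps
#'
#' One Gaussian lobe per channel, centered on points arranged around the
#' field of view, with a smooth linear phase per channel; normalized so the
#' sum of squared magnitudes is 1 at the FOV center.  \code{C = 1} returns a
#' uniform map of ones.
#'
#' @param C number of channels returned.
#' @param grid length-3 spatial dimensions.
#' @param seed integer seed (controls small jitter of the lobe centers).
#' @param array_size total number of coils in the (virtual) array the
#'   channels are drawn from; defaults to \code{C}.  The full array is
#'   normalized so the sum of squared magnitudes is 1 at the FOV center, and
#'   the first \code{C} elements are returned.  Passing a fixed
#'   \code{array_size} while varying \code{C} emulates sub-sampling the
#'   channels of one physical coil array: each retained coil keeps its
#'   sensitivity, so the collected signal scales with the channel count.
#' @return Complex array \code{(x, y, z, C)}.
#' @export
make_sensitivity_maps <- function(C, grid, seed = 1, array_size = C) {
  stopifnot(C >= 1, array_size >= C)
  if (array_size == 1)
    return(array(1 + 0i, c(grid, 1)))
  with_seed(seed, {
    ctr <- (grid + 1) / 2
    rad <- max(grid) * 0.75
    gold <- pi * (3 - sqrt(5))
    maps <- array(0 + 0i, c(grid, array_size))
    ax <- seq_len(grid[1]); ay <- seq_len(grid[2]); az <- seq_len(grid[3])
    width <- max(grid) * 0.6
    for (cc in seq_len(array_size)) {
      zc <- (2 * cc - 1) / array_size - 1
      r <- sqrt(max(1 - zc^2, 0))
      th <- gold * cc + runif(1, -0.1, 0.1)
      lobe <- ctr + rad * c(r * cos(th), r * sin(th), zc)
      gx <- exp(-(ax - lobe[1])^2 / (2 * width^2))
      gy <- exp(-(ay - lobe[2])^2 / (2 * width^2))
      gz <- exp(-(az - lobe[3])^2 / (2 * width^2))
      mag <- outer(outer(gx, gy), gz)
      ph <- runif(1, 0, 2 * pi) +
        outer(outer(ax * runif(1, -1, 1), ay * runif(1, -1, 1), "+"),
              az * runif(1, -1, 1), "+") * (0.5 / max(grid))
      maps[, , , cc] <- mag * exp(1i * ph)
    }
    norm <- sqrt(sum(Mod(maps[ceiling(ctr[1]), ceiling(ctr[2]),
                              ceiling(ctr[3]), ])^2))
    maps <- maps / norm
    maps[, , , seq_len(C), drop = FALSE]
  })
}

#' Bidimensional sinusoidal background phase
#'
#' \code{amp * sin(2 pi fx x / nx + psi) * sin(2 pi fy y / ny + chi)} with
#' independent random shifts \code{psi, chi} per slice: smooth within a
#' slice, discontinuous across slices, mimicking coil and slowly varying
#' physiological phase.  By default the slice shifts are static across
#' volumes (the background phase is a property of the acquisition, not of
#' the diffusion weighting); \code{per_volume = TRUE} redraws them for every
#' volume, emulating fully dynamic phase.  Note that fully dynamic shifts
#' make the real and imaginary parts of the data effectively full-rank
#' (every slice-volume pair contributes an independent pattern), which
#' removes the redundancy that two-pass phase estimation relies on.
#'
#' @param grid length-3 spatial dimensions.
#' @param V number of volumes.
#' @param seed integer seed.
#' @param amp amplitude in radians (default pi/2).
#' @param fx,fy spatial frequencies in cycles per field of view.
#' @param per_volume redraw the slice shifts for every volume.
#' @return Numeric array \code{(x, y, z, V)} of phases.
#' @export
make_background_phase <- function(grid, V, seed = 1, amp = pi / 2,
                                  fx = 1.5, fy = 1.5, per_volume = FALSE) {
  if (amp == 0) return(array(0, c(grid, V)))
  with_seed(seed, {
    out <- array(0, c(grid, V))
    ax <- 2 * pi * fx * seq_len(grid[1]) / grid[1]
    ay <- 2 * pi * fy * seq_len(grid[2]) / grid[2]
    ndraw <- if (per_volume) V else 1
    slice <- array(0, c(grid[1], grid[2], grid[3], ndraw))
    for (dr in seq_len(ndraw))
      for (z in seq_len(grid[3])) {
        psi <- runif(1, 0, 2 * pi)
        chi <- runif(1, 0, 2 * pi)
        slice[, , z, dr] <- amp * outer(sin(ax + psi), sin(ay + chi))
      }
    for (v in seq_len(V))
      out[, , , v] <- slice[, , , if (per_volume) v else 1]
    out
  })
}

#' Spatially varying noise map
#'
#' Noise is highest at the center of the field of view and decreases towards
#' the periphery: the non-diffusion-weighted SNR \code{s0 / sigma(x)} rises
#' monotonically with the distance from the grid center, spanning
#' \code{snr_range} between center and the farthest corner.
#'
#' The radial profile is plateaued rather than strictly linear: SNR is
#' constant at \code{snr_range[1]} inside \code{plateau[1]} of the maximal
#' radius, constant at \code{snr_range[2]} outside \code{plateau[2]}, with a
#' smooth cosine ramp between.  On a desk-scale grid this keeps the noise
#' level approximately constant within any local block away from the single
#' transition shell, which is the regime a full-size field of view is in
#' everywhere (there the SNR changes by only a small fraction across one
#' block); a strictly linear ramp on a small grid would instead make every
#' block's noise strongly non-stationary.
#'
#' @param grid length-3 spatial dimensions.
#' @param snr_range length-2 (center, periphery) SNR; a degenerate range
#'   gives a constant map.
#' @param s0 non-diffusion-weighted signal amplitude the SNR refers to.
#' @param plateau inner/outer plateau radii as fractions of the maximal
#'   radius.
#' @return Numeric array \code{(x, y, z)} of per-voxel sigma.
#' @export
make_noise_map <- function(grid, snr_range = c(2, 15), s0 = 1,
                           plateau = c(0.55, 0.8)) {
  if (snr_range[1] == snr_range[2])
    return(array(s0 / snr_range[1], grid))
  ctr <- (grid + 1) / 2
  dx2 <- (seq_len(grid[1]) - ctr[1])^2
  dy2 <- (seq_len(grid[2]) - ctr[2])^2
  dz2 <- (seq_len(grid[3]) - ctr[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  rho <- r / max(r)
  ramp <- pmin(pmax((rho - plateau[1]) / (plateau[2] - plateau[1]), 0), 1)
  smooth <- (1 - cos(pi * ramp)) / 2
  snr <- snr_range[1] + (snr_range[2] - snr_range[1]) * smooth
  s0 / snr
}

#' Phantom configuration
#'
#' Assembles the parameters of the digital phantom: grid, fiber bundles,
#' isotropic regions, diffusivities, acquisition protocol, channel count,
#' noise and phase models, and the root seed.
#'
#' @param grid length-3 spatial dimensions.
#' @param bundles list of bundle descriptions; each a list with \code{from},
#'   \code{to} (endpoints in relative 0-1 coordinates), \code{radius}
#'   (voxels), optional \code{via} (control point bending the centerline)
#'   and optional \code{radius_to} (for fanning bundles).
#' @param iso_regions list of spheres: \code{center} (relative), \code{radius}
#'   (voxels), \code{d_iso} diffusivity.
#' @param channels number of receiver channels.
#' @param coil_array size of the physical coil array the channels are drawn
#'   from (default \code{channels}); set it larger than \code{channels} to
#'   emulate channel sub-sampling at fixed coil sensitivities, as in
#'   channel-count sweeps.
#' @param shells,counts acquisition shells (see \code{\link{dwi_protocol}}).
#' @param d_par,d_perp fiber diffusivities (mm^2/s).
#' @param snr_range center-to-periphery SNR span of the noise map.
#' @param phase_amp,phase_fx,phase_fy background-phase amplitude (rad) and
#'   frequencies (cycles/FOV); \code{phase_amp = 0} disables the phase.
#' @param seed root seed; all randomness (noise, phase shifts, map jitter)
#'   derives from it deterministically.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid = c(16, 16, 16), bundles = list(),
                           iso_regions = list(), channels = 32,
                           coil_array = channels,
                           shells = c(0, 1000, 2000, 3000),
                           counts = c(5, 24, 48, 96),
                           d_par = 1.7e-3, d_perp = 0.4e-3,
                           snr_range = c(2, 15),
                           phase_amp = pi / 2, phase_fx = 1.5,
                           phase_fy = 1.5, seed = 1) {
  stopifnot(length(grid) == 3, all(grid >= 4), d_par > 0, d_perp > 0,
            channels >= 1, coil_array >= channels,
            length(shells) == length(counts))
  structure(list(grid = as.integer(grid), bundles = bundles,
                 iso_regions = iso_regions, channels = as.integer(channels),
                 coil_array = as.integer(coil_array),
                 shells = shells, counts = counts, d_par = d_par,
                 d_perp = d_perp, snr_range = snr_range,
                 phase_amp = phase_amp, phase_fx = phase_fx,
                 phase_fy = phase_fy, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("Phantom: %s grid, %d bundle(s), %d isotropic region(s), C = %d, V = %d\n",
              paste(x$grid, collapse = "x"), length(x$bundles),
              length(x$iso_regions), x$channels, sum(x$counts)))
  invisible(x)
}

#' Default phantom configurations
#'
#' \code{"mini"} is the desk-scale in-silico study: a 16^3 grid with a
#' straight bundle, a crossing bundle pair, a bending bundle and a CSF-like
#' free-water sphere, 32 channels, the full 173-volume protocol, SNR 2-15
#' and the sinusoidal background phase.  \code{"full"} reproduces the
#' full-scale geometry: 27 size-varying bundles (straight, bending, fanning,
#' kissing, crossing) and 3 isotropic regions on a 64^3 grid.
#'
#' @param scale \code{"mini"} or \code{"full"}.
#' @param channels,seed overrides for the channel count and seed.
#' @param coil_array coil-array size the channels are drawn from (default
#'   \code{channels}); see \code{\link{phantom_config}}.
#' @return A \code{\link{phantom_config}}.
#' @export
default_phantom <- function(scale = c("mini", "full"), channels = 32,
                            seed = 1, coil_array = channels) {
  scale <- match.arg(scale)
  if (scale == "mini") {
    # the free-water probe sits at the grid center, inside the inner
    # (worst-SNR) plateau of the noise map; bundles avoid the probe
    bundles <- list(
      list(from = c(0.05, 0.30, 0.30), to = c(0.95, 0.30, 0.30),
           radius = 1.8),                                        # straight
      list(from = c(0.05, 0.05, 0.80), to = c(0.95, 0.95, 0.80),
           radius = 1.6),                                        # crossing A
      list(from = c(0.05, 0.95, 0.80), to = c(0.95, 0.05, 0.80),
           radius = 1.6),                                        # crossing B
      list(from = c(0.70, 0.05, 0.18), to = c(0.70, 0.95, 0.18),
           via = c(0.45, 0.50, 0.24), radius = 1.5))             # bending
    iso <- list(list(center = c(0.5, 0.5, 0.5), radius = 2.6,
                     d_iso = 3.0e-3))
    phantom_config(grid = c(16, 16, 16), bundles = bundles,
                   iso_regions = iso, channels = channels,
                   coil_array = coil_array, seed = seed)
  } else {
    bundles <- list()
    # 9 straight bundles of 3 sizes and 3 orientations
    for (i in 1:9) {
      o <- (i - 1) %% 3
      lvl <- 0.15 + 0.08 * ((i - 1) %/% 3)
      r <- 1.5 + 0.8 * ((i - 1) %/% 3)
      from <- switch(o + 1, c(0.05, lvl, lvl), c(lvl, 0.05, lvl + 0.3),
                     c(lvl + 0.3, lvl, 0.05))
      to <- switch(o + 1, c(0.95, lvl, lvl), c(lvl, 0.95, lvl + 0.3),
                   c(lvl + 0.3, lvl, 0.95))
      bundles[[length(bundles) + 1]] <- list(from = from, to = to, radius = r)
    }
    # 6 bending
    for (i in 1:6) {
      lvl <- 0.45 + 0.06 * i
      bundles[[length(bundles) + 1]] <-
        list(from = c(0.05, lvl, 0.5), to = c(lvl, 0.95, 0.5),
             via = c(lvl, lvl, 0.5), radius = 1.4 + 0.2 * (i %% 3))
    }
    # 4 fanning
    for (i in 1:4) {
      lvl <- 0.15 + 0.1 * i
      bundles[[length(bundles) + 1]] <-
        list(from = c(0.5, 0.05, lvl), to = c(0.5, 0.95, lvl),
             radius = 1.2, radius_to = 3.0)
    }
    # 4 kissing (two tangent arcs, twice)
    for (i in 1:2) {
      z <- 0.2 + 0.4 * i
      bundles[[length(bundles) + 1]] <-
        list(from = c(0.05, 0.3, z), to = c(0.95, 0.3, z),
             via = c(0.5, 0.5, z), radius = 1.4)
      bundles[[length(bundles) + 1]] <-
        list(from = c(0.05, 0.7, z), to = c(0.95, 0.7, z),
             via = c(0.5, 0.5, z), radius = 1.4)
    }
    # 4 crossing (two pairs)
    for (i in 1:2) {
      z <- 0.3 + 0.3 * i
      bundles[[length(bundles) + 1]] <-
        list(from = c(0.05, 0.05, z), to = c(0.95, 0.95, z), radius = 1.6)
      bundles[[length(bundles) + 1]] <-
        list(from = c(0.05, 0.95, z), to = c(0.95, 0.05, z), radius = 1.6)
    }
    iso <- list(list(center = c(0.8, 0.2, 0.8), radius = 4, d_iso = 3.0e-3),
                list(center = c(0.2, 0.8, 0.2), radius = 4, d_iso = 3.0e-3),
                list(center = c(0.85, 0.85, 0.15), radius = 3, d_iso = 3.0e-3))
    phantom_config(grid = c(64, 64, 64), bundles = bundles,
                   iso_regions = iso, channels = channels,
                   coil_array = coil_array, seed = seed)
  }
}

# Rasterize one bundle: voxels within `radius` of the (possibly curved)
# centerline; returns linear voxel indices and per-voxel tangent directions.
rasterize_bundle <- function(bundle, grid) {
  from <- bundle$from * grid
  to <- bundle$to * grid
  nseg <- 64
  tt <- seq(0, 1, length.out = nseg)
  if (is.null(bundle$via)) {
    pts <- outer(1 - tt, from) + outer(tt, to)
    tans <- matrix(rep(to - from, each = nseg), nseg, 3)
  } else {
    via <- bundle$via * grid
    pts <- outer((1 - tt)^2, from) + outer(2 * tt * (1 - tt), via) +
      outer(tt^2, to)
    tans <- outer(2 * (1 - tt), via - from) + outer(2 * tt, to - via)
  }
  tans <- tans / sqrt(rowSums(tans^2))
  radius <- if (is.null(bundle$radius_to)) rep(bundle$radius, nseg)
            else bundle$radius + tt * (bundle$radius_to - bundle$radius)
  coords <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                                  z = seq_len(grid[3])))
  best_d <- rep(Inf, nrow(coords))
  best_i <- rep(NA_integer_, nrow(coords))
  for (s in seq_len(nseg)) {
    d <- sqrt((coords[, 1] - pts[s, 1])^2 + (coords[, 2] - pts[s, 2])^2 +
                (coords[, 3] - pts[s, 3])^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- s
  }
  inside <- which(best_d <= radius[best_i])
  list(voxels = inside, tangents = tans[best_i[inside], , drop = FALSE])
}

#' Simulate a noisy multi-channel phantom acquisition
#'
#' Builds the noise-free compartment signal (single-tensor fibers, isotropic
#' free-water spheres; overlapping compartments mix with equal fractions),
#' modulates it by the channel sensitivity maps and background phase, and
#' adds independent complex Gaussian noise with the spatially varying sigma
#' map: \code{S_c = R_c S exp(i phi) + eps_r + i eps_i}.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return List with \code{image} (the noisy \code{\link{mcc_image}}) and
#'   \code{truth}: noise-free channel-free signal \code{signal} (x,y,z,V),
#'   sensitivity maps \code{sens}, background phase \code{phase} (x,y,z,V),
#'   noise map \code{sigma}, compartment \code{labels} (0 background,
#'   bundle index, 100 + region index for isotropic regions), \code{support}
#'   mask, \code{csf} mask of the isotropic free-water voxels, and the
#'   protocol.
#' @export
simulate_mcc <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  proto <- dwi_protocol(config$shells, config$counts)
  V <- length(proto$bvals)
  C <- config$channels
  nvox <- prod(grid)

  sig <- matrix(0, nvox, V)
  frac <- numeric(nvox)
  labels <- integer(nvox)
  for (bi in seq_along(config$bundles)) {
    rb <- rasterize_bundle(config$bundles[[bi]], grid)
    if (length(rb$voxels) == 0) next
    proj2 <- (rb$tangents %*% proto$bvecs)^2
    att <- exp(-(matrix(proto$bvals, length(rb$voxels), V, byrow = TRUE) *
                   (config$d_perp + (config$d_par - config$d_perp) * proj2)))
    sig[rb$voxels, ] <- sig[rb$voxels, ] + att
    frac[rb$voxels] <- frac[rb$voxels] + 1
    labels[rb$voxels] <- bi
  }
  for (ri in seq_along(config$iso_regions)) {
    reg <- config$iso_regions[[ri]]
    ctr <- reg$center * grid
    coords <- as.matrix(expand.grid(x = seq_len(grid[1]),
                                    y = seq_len(grid[2]),
                                    z = seq_len(grid[3])))
    inside <- which(sqrt(rowSums(sweep(coords, 2, ctr)^2)) <= reg$radius)
    att <- isotropic_signal(proto$bvals, reg$d_iso)
    sig[inside, ] <- sig[inside, ] +
      matrix(att, length(inside), V, byrow = TRUE)
    frac[inside] <- frac[inside] + 1
    labels[inside] <- 100L + ri
  }
  covered <- frac > 0
  sig[covered, ] <- sig[covered, ] / frac[covered] # equal-fraction mixing

  signal <- array(sig, c(grid, V))
  labels <- array(labels, grid)
  support <- array(covered, grid)
  csf <- labels >= 100L

  sens <- make_sensitivity_maps(C, grid, seed = config$seed + 11L,
                                array_size = config$coil_array)
  phase <- make_background_phase(grid, V, seed = config$seed + 23L,
                                 amp = config$phase_amp,
                                 fx = config$phase_fx, fy = config$phase_fy)
  sigma <- make_noise_map(grid, config$snr_range)

  data <- array(0 + 0i, c(grid, C, V))
  ph <- exp(1i * phase)
  with_seed(config$seed + 37L, {
    for (cc in seq_len(C)) {
      clean <- array(rep(sens[, , , cc], V), c(grid, V)) * signal * ph
      noise <- array(rnorm(nvox * V), c(grid, V)) * array(sigma, c(grid, V)) +
        1i * array(rnorm(nvox * V), c(grid, V)) * array(sigma, c(grid, V))
      data[, , , cc, ] <- clean + noise
    }
  })
  img <- mcc_image(data, bvals = proto$bvals, bvecs = proto$bvecs)
  list(image = img,
       truth = list(signal = signal, sens = sens, phase = phase,
                    sigma = sigma, labels = labels, support = support,
                    csf = csf, bvals = proto$bvals, bvecs = proto$bvecs,
                    config = config))
}

#' Planted-spike matrix
#'
#' A rank-1 noise-free matrix (one non-zero singular value) plus iid
#' Gaussian noise; the standard toy for studying how shrinkage strategies
#' separate a signal component from the noise bulk.
#'
#' @param size matrix edge (square \code{size x size}).
#' @param spike the non-zero singular value of the truth.
#' @param sigma noise standard deviation.
#' @param seed integer seed.
#' @return List with \code{noisy}, \code{truth}, and the singular vectors
#'   \code{u}, \code{v}.
#' @export
planted_spike_matrix <- function(size, spike, sigma = 1, seed = 1) {
  with_seed(seed, {
    u <- rnorm(size); u <- u / sqrt(sum(u^2))
    v <- rnorm(size); v <- v / sqrt(sum(v^2))
    truth <- spike * tcrossprod(u, v)
    noisy <- truth + if (sigma > 0)
      matrix(rnorm(size^2, sd = sigma), size, size) else 0
    list(noisy = noisy, truth = truth, u = u, v = v)
  })
}

#' Planted-spike denoising study
#'
#' Monte-Carlo comparison of shrinkage strategies on square planted-spike
#' matrices: for each matrix size and strategy, the retained rank and the
#' Frobenius error to the rank-1 truth are recorded over seeded draws,
#' together with the error of the noisy matrix itself (no denoising).
#' The spike is placed at \code{spike_factor} times the pure-noise bulk
#' edge \code{sigma (sqrt(M) + sqrt(N))}, well above detectability.
#'
#' @param sizes square matrix sizes.
#' @param n_draws draws per size.
#' @param strategies strategies to compare.
#' @param spike_factor spike position in bulk-edge units.
#' @param sigma noise level.
#' @param seed root seed; draw d uses seed + d.
#' @return Data frame with one row per (size, strategy, draw): \code{rank},
#'   \code{fro_error}, \code{noisy_error}.
#' @export
planted_spike_study <- function(sizes = c(20, 50, 100), n_draws = 100,
                                strategies = c("mp_pca", "fro", "nuc"),
                                spike_factor = 5, sigma = 1, seed = 1) {
  rows <- list()
  for (size in sizes) {
    spike <- spike_factor * sigma * 2 * sqrt(size)
    for (d in seq_len(n_draws)) {
      ps <- planted_spike_matrix(size, spike, sigma, seed = seed + d)
      noisy_err <- norm(ps$noisy - ps$truth, "F")
      for (st in strategies) {
        den <- denoise_matrix(ps$noisy, strategy = st)
        rows[[length(rows) + 1]] <-
          data.frame(size = size, strategy = st, draw = d, rank = den$rank,
                     fro_error = norm(den$X - ps$truth, "F"),
                     noisy_error = noisy_err)
      }
    }
  }
  do.call(rbind, rows)
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
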