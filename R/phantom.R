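#' Synthetic chest phantom specification
#'
#' Describes a simple chest-like CT phantom: an elliptical soft-tissue body
#' with a bony shell, two lung fields, and optional textured lesions placed
#' inside the lungs. The phantom is a stand-in for clinical chest cohorts:
#' it reproduces the HU strata of a chest slice (air / lung / soft tissue /
#' bone), smooth slice-to-slice anatomical variation (so slice position is
#' informative, which the slice-paired training strategy relies on), and a
#' tunable body size (so cohorts with different habitus can be generated).
#'
#' @param image_size pixels per side of the square slices (>= 32).
#' @param n_slices number of slices.
#' @param body_scale fraction of the field of view occupied by the body
#'   ellipse, in (0, 1].
#' @param lesion_count number of lesions to place inside the lungs.
#' @param lesion_texture_strength standard deviation (HU) of the intra-lesion
#'   texture.
#' @param hu_palette named list of mean HU per tissue role; defaults are
#'   air -1000, lung -800, soft tissue 40, bone 700, lesion 20.
#' @param seed RNG seed; phantom generation is deterministic given the seed.
#' @param spacing voxel spacing in mm. The default puts a 350 mm field of
#'   view across the slice and uses 5 mm slices, typical of the thick-slice
#'   chest protocols the method targets.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_slices = 8L, body_scale = 0.85,
                         lesion_count = 2L, lesion_texture_strength = 40,
                         hu_palette = list(air = -1000, lung = -800,
                                           soft = 40, bone = 700, lesion = 20),
                         seed = 1L,
                         spacing = c(350 / image_size, 350 / image_size, 5)) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stopf("`image_size` must be >= 32")
  if (!is_scalar_number(body_scale) || body_scale <= 0 || body_scale > 1) {
    stopf("`body_scale` must lie in (0, 1]")
  }
  if (n_slices < 1L) stopf("`n_slices` must be >= 1")
  if (lesion_count < 0L) stopf("`lesion_count` must be >= 0")
  needed <- c("air", "lung", "soft", "bone", "lesion")
  if (!all(needed %in% names(hu_palette))) {
    stopf("`hu_palette` must name: %s", paste(needed, collapse = ", "))
  }
  structure(
    list(image_size = image_size, n_slices = as.integer(n_slices),
         body_scale = body_scale, lesion_count = as.integer(lesion_count),
         lesion_texture_strength = lesion_texture_strength,
         hu_palette = hu_palette, seed = as.integer(seed),
         spacing = as.numeric(spacing)),
    class = "phantom_spec"
  )
}

# smooth, monotone slice-to-slice anatomy scaling: slice index correlates
# with body/lung size, mimicking the apex-to-base taper of a chest
slice_anatomy_scale <- function(iz, n_slices) {
  pz <- if (n_slices > 1L) (iz - 1) / (n_slices - 1) else 0.5
  0.80 + 0.20 * pz
}

# per-slice tissue masks for the body / bone shell / lungs
phantom_slice_masks <- function(spec, iz) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  sz <- slice_anatomy_scale(iz, spec$n_slices)
  ax <- spec$body_scale * (n / 2 - 1) * sz
  ay <- 0.78 * ax
  x <- matrix(seq_len(n) - ctr, n, n)
  y <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  r2 <- (x / ax)^2 + (y / ay)^2
  body <- r2 <= 1
  bone <- r2 > 0.90^2 & r2 <= 0.97^2
  lung <- array(FALSE, dim(body))
  for (sgn in c(-1, 1)) {
    lx <- 0.42 * ax * sgn
    la <- 0.33 * ax
    lb <- 0.58 * ay
    lr2 <- ((x - lx) / la)^2 + (y / lb)^2
    lung <- lung | (lr2 <= 1)
  }
  lung <- lung & body & !bone
  list(body = body, bone = bone, lung = lung)
}

# spatially smoothed gaussian field rescaled to a target sd; `cell` sets
# the correlation length in pixels (texture is drawn on a coarse grid and
# bilinearly upsampled, so blobs of ~`cell` pixels survive the imaging
# chain's resolution limit)
smooth_noise <- function(d, sd_target, cell = 1L) {
  if (cell > 1L) {
    nc <- ceiling(d / cell) + 1L
    z <- matrix(rnorm(prod(nc)), nc[1], nc[2])
    xi <- (seq_len(d[1]) - 1) / cell + 1
    yi <- (seq_len(d[2]) - 1) / cell + 1
    x0 <- pmin(floor(xi), nc[1] - 1L); fx <- xi - x0
    y0 <- pmin(floor(yi), nc[2] - 1L); fy <- yi - y0
    sm <- outer(seq_len(d[1]), seq_len(d[2]), function(i, j) {
      z[cbind(x0[i], y0[j])] * (1 - fx[i]) * (1 - fy[j]) +
        z[cbind(x0[i] + 1L, y0[j])] * fx[i] * (1 - fy[j]) +
        z[cbind(x0[i], y0[j] + 1L)] * (1 - fx[i]) * fy[j] +
        z[cbind(x0[i] + 1L, y0[j] + 1L)] * fx[i] * fy[j]
    })
  } else {
    z <- matrix(rnorm(prod(d)), d[1], d[2])
    k <- matrix(1 / 9, 3, 3)
    zp <- rbind(z[1, ], z, z[d[1], ])
    zp <- cbind(zp[, 1], zp, zp[, d[2]])
    sm <- z
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        sm[i, j] <- sum(zp[i:(i + 2), j:(j + 2)] * k)
      }
    }
  }
  if (sd(as.vector(sm)) > 0) sm <- sm / sd(as.vector(sm))
  sm * sd_target
}

#' Generate a synthetic chest phantom volume
#'
#' Builds the HU volume described by a [phantom_spec()]: air background,
#' elliptical soft-tissue body with mild texture, a bone shell, two lung
#' fields with faint parenchymal texture, and `lesion_count` ellipsoidal
#' soft-tissue lesions with controllable internal texture placed fully
#' inside the lungs. Generation is deterministic for a fixed seed. HU
#' values are clamped to the valid CT range [-1024, 3071].
#'
#' @param spec a [phantom_spec()].
#' @return A [ct_volume()] with attributes `lesion_mask` (logical array),
#'   `lung_mask`, `body_mask` and `lesions` (a data frame of lesion centres
#'   and semi-axes in voxels, for analytic checks).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  nz <- spec$n_slices
  pal <- spec$hu_palette
  vox <- array(pal$air, dim = c(n, n, nz))
  lung_mask <- array(FALSE, dim = c(n, n, nz))
  body_mask <- array(FALSE, dim = c(n, n, nz))
  with_seed(spec$seed, {
    for (iz in seq_len(nz)) {
      m <- phantom_slice_masks(spec, iz)
      sl <- matrix(pal$air, n, n)
      sl[m$body] <- pal$soft + smooth_noise(c(n, n), 8)[m$body]
      sl[m$bone] <- pal$bone + smooth_noise(c(n, n), 20)[m$bone]
      sl[m$lung] <- pal$lung + smooth_noise(c(n, n), 15)[m$lung]
      vox[, , iz] <- sl
      lung_mask[, , iz] <- m$lung
      body_mask[, , iz] <- m$body
    }
    lesion_mask <- array(FALSE, dim = c(n, n, nz))
    lesions <- NULL
    if (spec$lesion_count > 0L) {
      for (li in seq_len(spec$lesion_count)) {
        placed <- FALSE
        # per-lesion heterogeneity: real tumour populations vary strongly in
        # size, attenuation and texture, and between-subject feature variance
        # is what concordance analysis measures against
        lesion_hu <- pal$lesion + runif(1, -170, 80)
        tex_scale <- runif(1, 0.5, 2.0)
        px_mm <- spec$spacing[1]
        for (try in seq_len(200L)) {
          # semi-axes drawn in mm (tumour diameters ~3-6.5 cm) and converted
          # to pixels, so lesion size is independent of phantom resolution
          a <- max(runif(1, 16, 33) / px_mm, 1.2)
          b <- max(runif(1, 16, 33) / px_mm, 1.2)
          cz_hi <- min(2.5, max(1.0, (nz - 1) / 2))
          cz_lo <- min(1.5, cz_hi)
          cz <- runif(1, cz_lo, cz_hi)
          zmid <- (nz + 1) / 2
          zc <- if (nz > 1L) {
            runif(1, min(1 + cz, zmid), max(nz - cz, zmid))
          } else 1
          iz0 <- max(1L, floor(zc - cz))
          iz1 <- min(nz, ceiling(zc + cz))
          mid <- lung_mask[, , max(1L, min(nz, round(zc)))]
          cand <- which(mid, arr.ind = TRUE)
          if (nrow(cand) == 0L) break
          cc <- cand[sample.int(nrow(cand), 1L), ]
          xc <- cc[1]; yc <- cc[2]
          les <- array(FALSE, dim = c(n, n, nz))
          ok <- TRUE
          for (iz in iz0:iz1) {
            dz2 <- ((iz - zc) / cz)^2
            if (dz2 >= 1) next
            xg <- matrix(seq_len(n) - xc, n, n)
            yg <- matrix(seq_len(n) - yc, n, n, byrow = TRUE)
            inside <- (xg / a)^2 + (yg / b)^2 <= 1 - dz2
            if (any(inside & (!lung_mask[, , iz] | lesion_mask[, , iz]))) {
              ok <- FALSE
              break
            }
            les[, , iz] <- inside
          }
          if (ok && any(les)) {
            tex <- spec$lesion_texture_strength * tex_scale
            for (iz in iz0:iz1) {
              sel <- les[, , iz]
              if (!any(sel)) next
              sl <- vox[, , iz]
              # centimetre-scale intra-lesion heterogeneity that the imaging
              # chain can resolve, plus a finer component
              sl[sel] <- lesion_hu + smooth_noise(c(n, n), tex, cell = 3L)[sel] +
                smooth_noise(c(n, n), 0.3 * tex)[sel]
              vox[, , iz] <- sl
            }
            lesion_mask <- lesion_mask | les
            lesions <- rbind(lesions,
                             data.frame(x = xc, y = yc, z = zc,
                                        a = a, b = b, c = cz))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stopf("could not place lesion %d inside the lung regions after 200 attempts (lungs too small for the requested lesion size)", li)
        }
      }
    }
    vox <- clamp(vox, -1024, 3071)
    vol <- ct_volume(vox, spacing = spec$spacing,
                     subject_id = sprintf("phantom_seed%d", spec$seed))
    attr(vol, "lesion_mask") <- lesion_mask
    attr(vol, "lung_mask") <- lung_mask
    attr(vol, "body_mask") <- body_mask
    attr(vol, "lesions") <- lesions
    vol
  })
}
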