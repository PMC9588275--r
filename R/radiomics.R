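#' Radiomics extraction configuration
#'
#' Settings of the feature-extraction pipeline: images and masks are
#' resampled to isotropic voxels (2 mm by default) before extraction, and
#' intensities inside the ROI are discretised with a fixed bin width
#' (25 HU by default, the common radiomics choice) for histogram and
#' texture features.
#'
#' @param resample_spacing isotropic target spacing in mm, or `NULL` to
#'   skip resampling.
#' @param bin_width HU per gray level for discretisation.
#' @param feature_classes classes to extract.
#' @param backend `"builtin"` (formula-level implementation of shape,
#'   first-order and a documented GLCM subset) or `"external_adapter"`
#'   (delegates to pyradiomics through `python`, when installed).
#' @param manifest optional data frame (`class`, `name`) restricting the
#'   features; defaults to everything the backend supports within
#'   `feature_classes`.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(resample_spacing = 2, bin_width = 25,
                              feature_classes = c("shape", "firstorder", "glcm"),
                              backend = c("builtin", "external_adapter"),
                              manifest = NULL) {
  backend <- match.arg(backend)
  if (!is.null(resample_spacing) &&
      (!is_scalar_number(resample_spacing) || resample_spacing <= 0)) {
    stopf("`resample_spacing` must be positive or NULL")
  }
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    stopf("`bin_width` must be positive")
  }
  unknown <- setdiff(feature_classes, names(manifest_names))
  if (length(unknown) > 0L) {
    stopf("unknown feature class(es): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(manifest)) {
    manifest <- feature_manifest(classes = feature_classes)
    if (backend == "builtin") {
      manifest <- manifest[manifest$class != "glcm" |
                             manifest$name %in% builtin_glcm_features, ]
    }
  }
  if (anyDuplicated(manifest$feature)) stopf("manifest names must be unique")
  structure(list(resample_spacing = resample_spacing, bin_width = bin_width,
                 feature_classes = feature_classes, backend = backend,
                 manifest = manifest),
            class = "extraction_config")
}

# trilinear interpolation of `arr` at grid positions given by per-axis
# fractional indices (1-based)
trilinear_grid <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  f <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- f(floor(xi), d[1]); x1 <- f(x0 + 1, d[1]); fx <- f(xi, d[1]) - x0
  y0 <- f(floor(yi), d[2]); y1 <- f(y0 + 1, d[2]); fy <- f(yi, d[2]) - y0
  z0 <- f(floor(zi), d[3]); z1 <- f(z0 + 1, d[3]); fz <- f(zi, d[3]) - z0
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  ex <- function(v) rep(v, times = ny * nz)
  ey <- function(v) rep(rep(v, each = nx), times = nz)
  ez <- function(v) rep(v, each = nx * ny)
  corner <- function(ix, iy, iz) arr[cbind(ex(ix), ey(iy), ez(iz))]
  wx <- ex(fx); wy <- ey(fy); wz <- ez(fz)
  out <- corner(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
    corner(x1, y0, z0) * wx * (1 - wy) * (1 - wz) +
    corner(x0, y1, z0) * (1 - wx) * wy * (1 - wz) +
    corner(x1, y1, z0) * wx * wy * (1 - wz) +
    corner(x0, y0, z1) * (1 - wx) * (1 - wy) * wz +
    corner(x1, y0, z1) * wx * (1 - wy) * wz +
    corner(x0, y1, z1) * (1 - wx) * wy * wz +
    corner(x1, y1, z1) * wx * wy * wz
  array(out, dim = c(nx, ny, nz))
}

#' Resample a volume and ROI mask to isotropic spacing
#'
#' Trilinear interpolation for intensities, nearest neighbour for the
#' mask. Voxel centres sit at `(i - 1) * spacing`; the output grid spans
#' the same physical extent at the target spacing.
#'
#' @param volume a [ct_volume()].
#' @param mask logical array of the same shape (the ROI).
#' @param spacing isotropic target spacing in mm.
#' @return A list with the resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, spacing = 2) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  if (!identical(dim(mask), d)) stopf("mask shape must match volume shape")
  sp <- volume$spacing
  newd <- pmax(1L, floor((d - 1) * sp / spacing) + 1L)
  xi <- (seq_len(newd[1]) - 1) * spacing / sp[1] + 1
  yi <- (seq_len(newd[2]) - 1) * spacing / sp[2] + 1
  zi <- (seq_len(newd[3]) - 1) * spacing / sp[3] + 1
  vox <- trilinear_grid(volume$voxels, xi, yi, zi)
  nn <- function(v, n) pmin(pmax(round(v), 1), n)
  m2 <- array(mask[cbind(rep(nn(xi, d[1]), times = newd[2] * newd[3]),
                         rep(rep(nn(yi, d[2]), each = newd[1]), times = newd[3]),
                         rep(nn(zi, d[3]), each = newd[1] * newd[2]))],
              dim = newd)
  if (!any(m2)) stopf("resampled mask is empty; ROI smaller than the target spacing")
  list(volume = ct_volume(vox, spacing = rep(spacing, 3),
                          subject_id = volume$subject_id),
       mask = m2)
}

#' Fixed-bin-width discretisation
#'
#' Gray level `floor((x - min(x)) / bin_width) + 1`; a constant region
#' maps to level 1.
#'
#' @param intensities numeric vector (HU values inside the ROI).
#' @param bin_width positive bin width in HU.
#' @return Integer gray levels starting at 1.
#' @export
discretize <- function(intensities, bin_width = 25) {
  if (length(intensities) == 0L) stopf("no intensities to discretise")
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    stopf("`bin_width` must be positive")
  }
  as.integer(floor((intensities - min(intensities)) / bin_width) + 1L)
}

#' First-order (intensity histogram) features
#'
#' The 17 first-order features of the default manifest, each following its
#' standard formula: energy is the plain sum of squares, entropy and
#' uniformity are computed on the fixed-bin-width discretised histogram,
#' variance/skewness/kurtosis use population moments (kurtosis is
#' non-excess), and the robust mean absolute deviation restricts to values
#' within the 10th-90th percentile range. A single-voxel region is valid:
#' moment-based features degenerate to 0 and the result carries a
#' `degenerate` attribute instead of silent NaNs.
#'
#' @param intensities numeric vector of HU values inside the ROI.
#' @param config an [extraction_config()] (for the histogram bin width).
#' @return Named numeric vector of 17 features.
#' @export
extract_first_order <- function(intensities, config = extraction_config()) {
  x <- as.numeric(intensities)
  if (length(x) == 0L) stopf("empty region")
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  degenerate <- m2 == 0
  lv <- discretize(x, config$bin_width)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7, names = FALSE)
  inr <- x[x >= q[1] & x <= q[5]]
  out <- c(
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(inr - mean(inr))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (degenerate) 0 else mean((x - m)^3) / m2^1.5,
    Kurtosis = if (degenerate) 0 else mean((x - m)^4) / m2^2,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

# the 13 unique 3-D direction offsets at distance 1 (up to sign)
glcm_directions <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- apply(dirs, 1, function(d) {
    d <- as.numeric(d)
    first <- d[match(TRUE, d != 0)]
    first > 0
  })
  dirs[keep, ]
}

# symmetric co-occurrence counts of one direction on a level array with NA
# outside the ROI
glcm_counts_direction <- function(levels, ng, dx, dy, dz) {
  d <- dim(levels)
  lo <- pmax(1, 1 + c(dx, dy, dz))
  hi <- pmin(d, d + c(dx, dy, dz))
  if (any(lo > hi)) return(matrix(0, ng, ng))
  x1 <- lo[1]:hi[1]
  y1 <- lo[2]:hi[2]
  z1 <- lo[3]:hi[3]
  a <- levels[x1, y1, z1, drop = FALSE]
  b <- levels[x1 - dx, y1 - dy, z1 - dz, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  counts <- matrix(0, ng, ng)
  tab <- table(factor(a[ok], levels = seq_len(ng)),
               factor(b[ok], levels = seq_len(ng)))
  counts <- counts + tab + t(tab)
  counts
}

glcm_features_from_p <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(i * P)
  sx2 <- sum((i - mu)^2 * P)
  kd <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(P[kd == k]), numeric(1))
  ks <- 2:(2 * ng)
  ps <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  corr <- if (sx2 == 0) 1 else (sum(i * j * P) - mu^2) / sx2
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceEntropy = ent(pd),
    Id = sum(P / (1 + kd)),
    Idm = sum(P / (1 + kd^2)),
    JointEnergy = sum(P^2),
    JointEntropy = ent(P),
    MaximumProbability = max(P),
    SumEntropy = ent(ps))
}

#' Gray-level co-occurrence (GLCM) texture features
#'
#' Builds symmetric co-occurrence matrices over the 13 unique 3-D
#' directions at distance 1, normalises each to a probability matrix, and
#' averages the per-direction feature values. The builtin subset covers
#' `r paste(builtin_glcm_features, collapse = ", ")`.
#'
#' @param levels integer 3-D array of gray levels with `NA` outside the
#'   ROI (see [discretize()]).
#' @param config an [extraction_config()].
#' @return Named numeric vector of GLCM features.
#' @export
extract_glcm <- function(levels, config = extraction_config()) {
  if (!any(!is.na(levels))) stopf("empty region")
  ng <- max(levels, na.rm = TRUE)
  dirs <- glcm_directions()
  feats <- NULL
  nd <- 0L
  for (r in seq_len(nrow(dirs))) {
    cnt <- glcm_counts_direction(levels, ng, dirs$dx[r], dirs$dy[r], dirs$dz[r])
    tot <- sum(cnt)
    if (tot == 0) next
    f <- glcm_features_from_p(cnt / tot)
    feats <- if (is.null(feats)) f else feats + f
    nd <- nd + 1L
  }
  if (nd == 0L) stopf("region has no co-occurring voxel pairs")
  feats / nd
}

# morphology features from the mask alone (voxel-based approximations)
extract_shape <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stopf("empty mask")
  voxvol <- prod(spacing)
  vol <- n * voxvol
  d <- dim(mask)
  # exposed faces
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  faces <- 0
  areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
             spacing[1] * spacing[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  sa <- 0
  for (s in shifts) {
    nb <- pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3]]
    exposed <- sum(mask & !nb)
    ax <- which(s != 0)
    sa <- sa + exposed * areas[ax]
  }
  coords <- sweep(idx, 2, spacing[c(1, 2, 3)], "*")
  # surface voxels only, for diameters
  is_surface <- rep(FALSE, n)
  for (s in shifts) {
    nb <- pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3]]
    is_surface <- is_surface | !nb[idx]
  }
  sc <- coords[is_surface, , drop = FALSE]
  if (nrow(sc) > 2000L) sc <- sc[seq(1, nrow(sc), length.out = 2000L), ]
  maxd <- function(m) if (nrow(m) < 2) 0 else max(dist(m))
  d3 <- maxd(sc)
  plane_max <- function(keep_axis) {
    z <- sc[, keep_axis]
    m <- sc[, -keep_axis, drop = FALSE]
    max(vapply(unique(z), function(u) maxd(m[z == u, , drop = FALSE]),
               numeric(1)))
  }
  d_slice <- plane_max(3)   # in-plane (x, y)
  d_col <- plane_max(2)     # (x, z)
  d_row <- plane_max(1)     # (y, z)
  ev <- if (n > 1) {
    cv <- stats::cov.wt(coords, method = "ML")$cov
    pmax(sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE), 0)
  } else c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  c(MeshVolume = vol,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / sa,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row,
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

crop_to_mask <- function(volume, mask, margin = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  vox <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(volume = ct_volume(vox, volume$spacing, volume$subject_id), mask = m)
}

#' Extract radiomic features from one volume and ROI
#'
#' Crops to the ROI bounding box, resamples to isotropic voxels,
#' discretises the masked intensities and computes the configured feature
#' classes. The builtin backend evaluates shape, first-order and the
#' documented GLCM subset at formula level; the `external_adapter`
#' backend delegates to pyradiomics via `python` when that library is
#' installed and errors informatively otherwise.
#'
#' @param volume a [ct_volume()] in HU.
#' @param mask logical array of the same shape (ROI).
#' @param config an [extraction_config()].
#' @return A one-row data frame of features named `class_Name`, with
#'   attribute `feature_class`.
#' @export
extract_features <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!identical(dim(mask), dim(volume$voxels))) {
    stopf("mask shape must match volume shape")
  }
  if (!any(mask)) stopf("empty ROI mask")
  if (config$backend == "external_adapter") {
    return(extract_features_adapter(volume, mask, config))
  }
  supported <- list(
    shape = manifest_names$shape,
    firstorder = manifest_names$firstorder,
    glcm = builtin_glcm_features
  )
  man <- config$manifest
  gaps <- vapply(seq_len(nrow(man)), function(r) {
    cl <- man$class[r]
    !(cl %in% names(supported)) || !(man$name[r] %in% supported[[cl]])
  }, logical(1))
  if (any(gaps)) {
    stopf("builtin backend does not provide: %s",
          paste(man$feature[gaps], collapse = ", "))
  }
  cr <- crop_to_mask(volume, mask)
  if (!is.null(config$resample_spacing)) {
    rs <- resample_isotropic(cr$volume, cr$mask, config$resample_spacing)
  } else {
    rs <- cr
  }
  vals <- numeric(0)
  classes <- unique(man$class)
  if ("shape" %in% classes) {
    sh <- extract_shape(rs$mask, rs$volume$spacing)
    names(sh) <- paste0("shape_", names(sh))
    vals <- c(vals, sh)
  }
  roi <- rs$volume$voxels[rs$mask]
  if ("firstorder" %in% classes) {
    fo <- extract_first_order(roi, config)
    names(fo) <- paste0("firstorder_", names(fo))
    vals <- c(vals, fo)
  }
  if ("glcm" %in% classes) {
    lv <- array(NA_integer_, dim(rs$mask))
    lv[rs$mask] <- discretize(roi, config$bin_width)
    gl <- extract_glcm(lv, config)
    names(gl) <- paste0("glcm_", names(gl))
    vals <- c(vals, gl)
  }
  vals <- vals[man$feature]
  out <- as.data.frame(as.list(vals), check.names = FALSE)
  attr(out, "feature_class") <- stats::setNames(man$class, man$feature)
  out
}

extract_features_adapter <- function(volume, mask, config) {
  py <- Sys.which("python")
  has <- FALSE
  if (nzchar(py)) {
    has <- identical(
      suppressWarnings(system2(py, c("-c", shQuote("import radiomics")),
                               stdout = FALSE, stderr = FALSE)), 0L)
  }
  if (!has) {
    stopf(paste("backend 'external_adapter' requires the pyradiomics Python",
                "library, which is not importable from `python` on this",
                "system; use backend = 'builtin' or install pyradiomics."))
  }
  stopf("external_adapter: pyradiomics bridge not implemented for this manifest; use backend = 'builtin'")
}

#' Extract a cohort feature table
#'
#' Applies [extract_features()] to each subject and binds the rows into a
#' feature table (subjects x features). Extraction is deterministic and
#' invariant to subject order.
#'
#' @param volumes list of [ct_volume()]s.
#' @param masks list of logical arrays, parallel to `volumes`.
#' @param config an [extraction_config()].
#' @return A data frame with a `subject_id` column and one column per
#'   feature; attribute `feature_class` maps columns to classes.
#' @export
extract_feature_table <- function(volumes, masks, config = extraction_config()) {
  stopifnot(length(volumes) == length(masks))
  rows <- lapply(seq_along(volumes), function(i) {
    extract_features(volumes[[i]], masks[[i]], config)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = vapply(volumes, function(v) v$subject_id,
                                   character(1)),
               out)
  attr(out, "feature_class") <- attr(rows[[1]], "feature_class")
  attr(out, "extraction_config") <- config
  out
}
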