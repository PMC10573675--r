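#' Stone shape primitives for synthetic phantoms
#'
#' Building blocks for [phantom_spec()]. All coordinates and lengths are in
#' mm, in the phantom's physical frame. `hu_shell` (optional) gives the
#' outer 20% of the stone a different attenuation, emulating internal
#' heterogeneity (core/shell composition); `rotation_deg` are extrinsic
#' z-y-x Euler angles.
#'
#' `stone_staghorn()` builds a branched, staghorn-like calculus as the union
#' of a central "pelvis" ellipsoid and three calyceal branch ellipsoids at
#' fixed template angles, all scaled by `size_mm` (the pelvis semi-major
#' axis).
#'
#' @param center_mm length-3 center (mm).
#' @param radius_mm sphere radius (mm), > 0.
#' @param semi_axes_mm length-3 ellipsoid semi-axes (mm), all > 0.
#' @param rotation_deg length-3 Euler angles (degrees).
#' @param size_mm staghorn scale: pelvis semi-major axis (mm), > 0.
#' @param hu_core core attenuation (HU).
#' @param hu_shell optional shell attenuation (HU).
#' @return A `stone_shape` list usable in `phantom_spec(stones = ...)`.
#' @name stone_shapes
NULL

#' @rdname stone_shapes
#' @export
stone_sphere <- function(center_mm, radius_mm, hu_core = 1300, hu_shell = NULL) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(shape = "sphere", center = as.numeric(center_mm),
                 components = list(list(center = as.numeric(center_mm),
                                        semi_axes = rep(radius_mm, 3),
                                        rotation = c(0, 0, 0))),
                 hu_core = hu_core, hu_shell = hu_shell),
            class = "stone_shape")
}

#' @rdname stone_shapes
#' @export
stone_ellipsoid <- function(center_mm, semi_axes_mm, hu_core = 1300,
                            hu_shell = NULL, rotation_deg = c(0, 0, 0)) {
  stopifnot(length(center_mm) == 3, length(semi_axes_mm) == 3,
            all(semi_axes_mm > 0))
  structure(list(shape = "ellipsoid", center = as.numeric(center_mm),
                 components = list(list(center = as.numeric(center_mm),
                                        semi_axes = as.numeric(semi_axes_mm),
                                        rotation = as.numeric(rotation_deg))),
                 hu_core = hu_core, hu_shell = hu_shell),
            class = "stone_shape")
}

# fixed branching template: branch direction (unit-ish), relative length and
# girth of the three calyceal branches, relative to the pelvis size
.staghorn_template <- list(
  pelvis = list(semi = c(1.0, 0.65, 0.6)),
  branches = list(
    list(dir = c(0.85, 0.5, 0.2), len = 0.9, girth = 0.35),
    list(dir = c(0.8, -0.55, 0.0), len = 0.85, girth = 0.32),
    list(dir = c(0.75, 0.1, -0.6), len = 0.8, girth = 0.30)
  )
)

#' @rdname stone_shapes
#' @export
stone_staghorn <- function(center_mm, size_mm, hu_core = 1300, hu_shell = NULL) {
  stopifnot(length(center_mm) == 3, size_mm > 0)
  tpl <- .staghorn_template
  center_mm <- as.numeric(center_mm)
  comps <- list(list(center = center_mm, semi_axes = size_mm * tpl$pelvis$semi,
                     rotation = c(0, 0, 0)))
  for (b in tpl$branches) {
    d <- b$dir / sqrt(sum(b$dir^2))
    bc <- center_mm + d * size_mm * (0.8 + 0.5 * b$len)
    # branch ellipsoid elongated along d: encode via rotation aligning x to d
    yaw <- atan2(d[2], d[1]) * 180 / pi
    pitch <- -asin(d[3]) * 180 / pi
    comps <- c(comps, list(list(
      center = bc,
      semi_axes = size_mm * c(b$len, b$girth, b$girth),
      rotation = c(yaw, pitch, 0))))
  }
  structure(list(shape = "staghorn", center = center_mm,
                 components = comps, hu_core = hu_core, hu_shell = hu_shell),
            class = "stone_shape")
}

# z-y-x extrinsic rotation matrix from degrees c(yaw_z, pitch_y, roll_x)
.rotmat <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# for points (n x 3, mm): normalized ellipsoid radius^2 per component,
# returned as n x n_components matrix
.component_rho2 <- function(pts, comps) {
  vapply(comps, function(cp) {
    q <- sweep(pts, 2, cp$center) %*% .rotmat(cp$rotation)  # p' = R^T (p - c)
    (q[, 1] / cp$semi_axes[1])^2 + (q[, 2] / cp$semi_axes[2])^2 +
      (q[, 3] / cp$semi_axes[3])^2
  }, numeric(nrow(pts)))
}

# min over components of normalized radius^2 (inside union iff <= 1)
.stone_rho2 <- function(pts, stone) {
  rho2 <- .component_rho2(pts, stone$components)
  if (ncol(rho2) == 1L) rho2[, 1] else do.call(pmin, asplit(rho2, 2))
}

.stone_bbox <- function(stone) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (cp in stone$components) {
    # loose but safe: center +/- max semi-axis in every direction
    r <- max(cp$semi_axes)
    lo <- pmin(lo, cp$center - r)
    hi <- pmax(hi, cp$center + r)
  }
  rbind(lo, hi)
}

#' Analytic (or high-resolution numeric) true stone volume
#'
#' Spheres and ellipsoids have closed-form volumes (`4/3 pi a b c`). For
#' branched unions (staghorn) the truth is computed by fine voxelization of
#' the union indicator at `1/oversample` of the stated spacing over the
#' stone's bounding box; overlap between components is counted once.
#'
#' @param stone a `stone_shape`.
#' @param spacing_mm reference spacing the oversampling is relative to.
#'   Default 1.
#' @param oversample subdivision factor for the numeric path. Default 8.
#' @return True volume in mm^3.
#' @export
true_stone_volume <- function(stone, spacing_mm = 1, oversample = 8) {
  stopifnot(inherits(stone, "stone_shape"))
  if (stone$shape %in% c("sphere", "ellipsoid")) {
    a <- stone$components[[1]]$semi_axes
    return(4 / 3 * pi * prod(a))
  }
  h <- min(spacing_mm) / oversample
  bb <- .stone_bbox(stone)
  gx <- seq(bb[1, 1] + h / 2, bb[2, 1], by = h)
  gy <- seq(bb[1, 2] + h / 2, bb[2, 2], by = h)
  gz <- seq(bb[1, 3] + h / 2, bb[2, 3], by = h)
  # slab-wise to bound memory
  total <- 0
  for (z in gz) {
    pts <- cbind(rep(gx, times = length(gy)),
                 rep(gy, each = length(gx)), z)
    total <- total + sum(.stone_rho2(pts, stone) <= 1)
  }
  total * h^3
}

#' Synthetic CT phantom specification
#'
#' Describes a synthetic non-contrast CT volume containing stones with known
#' geometry: a noisy soft-tissue background, one or more high-attenuation
#' stones (sphere / ellipsoid / staghorn union), optional core/shell HU
#' heterogeneity, Gaussian blur as a partial-volume surrogate, and additive
#' Gaussian HU noise. Stone HU must exceed background by more than 300 HU so
#' a separating density window always exists.
#'
#' @param dim length-3 grid size (voxels).
#' @param spacing length-3 voxel spacing (mm). Default `c(0.75, 0.75, 0.75)`.
#' @param stones list of [stone_shapes] objects (may be empty).
#' @param background_hu_mean,background_hu_sd soft-tissue background HU
#'   (default 40 +/- 15).
#' @param blur_sigma_mm isotropic Gaussian blur sigma (mm); 0 disables.
#' @param noise_sd_hu additive HU noise SD; 0 disables.
#' @param seed integer seed stored with the spec (can be overridden at
#'   simulation time).
#' @param location optional anatomical label (`"pelvis"`, `"calyx"`,
#'   `"other"`) carried into study metadata.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim, spacing = c(0.75, 0.75, 0.75), stones = list(),
                         background_hu_mean = 40, background_hu_sd = 15,
                         blur_sigma_mm = 0, noise_sd_hu = 0, seed = NULL,
                         location = "other") {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), length(spacing) == 3,
            all(spacing > 0), blur_sigma_mm >= 0, noise_sd_hu >= 0)
  extent <- dim * spacing
  for (s in stones) {
    if (!inherits(s, "stone_shape")) stop("each stone must be a stone_shape")
    hu_min_stone <- min(s$hu_core, s$hu_shell %||% s$hu_core)
    if (hu_min_stone <= background_hu_mean + 300)
      stop("stone HU must exceed background mean by more than 300 HU")
    bb <- .stone_bbox(s)
    if (any(bb[1, ] < 0) || any(bb[2, ] > extent))
      stop("stone extends outside the phantom grid")
  }
  structure(list(dim = dim, spacing = as.numeric(spacing), stones = stones,
                 background_hu_mean = background_hu_mean,
                 background_hu_sd = background_hu_sd,
                 blur_sigma_mm = blur_sigma_mm, noise_sd_hu = noise_sd_hu,
                 seed = seed, location = location),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable Gaussian blur with replicate-edge padding; sigma in voxels per dim
.gaussian_blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-((-r:r)^2) / (2 * s^2)); w <- w / sum(w)
    out <- array(0, d)
    n <- d[ax]
    for (k in -r:r) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)  # clamp at edges
      shifted <- switch(ax,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[k + r + 1] * shifted
    }
    arr <- out
  }
  arr
}

#' Simulate a CT phantom with known ground truth
#'
#' Renders the spec into an [hu_volume()]: voxels whose centers fall inside a
#' stone get the stone HU (shell HU in the outer 20% of the normalized
#' radius when heterogeneity is requested), the rest get Gaussian background;
#' the image is then blurred (partial-volume surrogate) and HU noise is
#' added. True per-stone volumes come from [true_stone_volume()] and are
#' independent of the noise realization. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides `spec$seed`.
#' @return An object of class `stone_phantom`: list with `volume`
#'   (`hu_volume`), `truth` (data.frame: stone, shape, true_volume_mm3),
#'   `spec`.
#' @examples
#' sp <- phantom_spec(c(24, 24, 24), spacing = c(1, 1, 1),
#'                    stones = list(stone_sphere(c(12, 12, 12), 6)))
#' ph <- simulate_phantom(sp, seed = 1)
#' ph$truth$true_volume_mm3  # 4/3 * pi * 6^3
#' @export
simulate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  d <- spec$dim; sp <- spec$spacing

  vox <- array(rnorm(prod(d), spec$background_hu_mean, spec$background_hu_sd), d)

  # paint stones (voxel centers at (i - 0.5) * spacing in the physical frame)
  ax_x <- (seq_len(d[1]) - 0.5) * sp[1]
  ax_y <- (seq_len(d[2]) - 0.5) * sp[2]
  ax_z <- (seq_len(d[3]) - 0.5) * sp[3]
  truth <- list()
  for (si in seq_along(spec$stones)) {
    st <- spec$stones[[si]]
    bb <- .stone_bbox(st)
    ix <- which(ax_x >= bb[1, 1] & ax_x <= bb[2, 1])
    iy <- which(ax_y >= bb[1, 2] & ax_y <= bb[2, 2])
    iz <- which(ax_z >= bb[1, 3] & ax_z <= bb[2, 3])
    if (length(ix) && length(iy) && length(iz)) {
      pts <- cbind(rep(ax_x[ix], times = length(iy) * length(iz)),
                   rep(rep(ax_y[iy], each = length(ix)), times = length(iz)),
                   rep(ax_z[iz], each = length(ix) * length(iy)))
      rho2 <- .stone_rho2(pts, st)
      inside <- rho2 <= 1
      if (any(inside)) {
        hu <- rep(st$hu_core, sum(inside))
        if (!is.null(st$hu_shell))
          hu[rho2[inside] > 0.8^2] <- st$hu_shell
        sub <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
        vox[sub] <- hu
      }
    }
    truth[[si]] <- data.frame(
      stone = si, shape = st$shape,
      true_volume_mm3 = true_stone_volume(st, spacing_mm = sp))
  }

  if (spec$blur_sigma_mm > 0)
    vox <- .gaussian_blur3d(vox, spec$blur_sigma_mm / sp)
  if (spec$noise_sd_hu > 0)
    vox <- vox + array(rnorm(prod(d), 0, spec$noise_sd_hu), d)

  structure(list(
    volume = hu_volume(vox, spacing = sp),
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(stone = integer(), shape = character(),
                 true_volume_mm3 = numeric()),
    spec = spec
  ), class = "stone_phantom")
}

#' @export
print.stone_phantom <- function(x, ...) {
  cat(sprintf("<stone_phantom> %s, %d stone(s), true total %.1f mm^3\n",
              paste(x$spec$dim, collapse = "x"), nrow(x$truth),
              sum(x$truth$true_volume_mm3)))
  invisible(x)
}

#' Observer model for simulated re-measurement
#'
#' One simulated operator re-measuring stones with the density-window
#' method. The only degree of freedom the method gives the operator is the
#' window, so observer variability is modeled as jitter of the lower
#' threshold: each replicate draws `hu_low ~ Normal(hu_low_mean, hu_low_sd)`
#' while `hu_high` stays fixed.
#'
#' @param observer_id label.
#' @param hu_low_mean observer's habitual lower threshold (HU).
#' @param hu_low_sd replicate-to-replicate jitter SD (HU), >= 0.
#' @return A one-row data.frame; rbind several to form a panel.
#' @export
observer_model <- function(observer_id, hu_low_mean, hu_low_sd) {
  stopifnot(hu_low_sd >= 0)
  data.frame(observer_id = observer_id, hu_low_mean = hu_low_mean,
             hu_low_sd = hu_low_sd, stringsAsFactors = FALSE)
}

#' Simulate an observer re-measurement study
#'
#' For every (case, observer, replicate) a lower threshold is drawn from the
#' observer's jitter model, the phantom is segmented with the resulting
#' window, and the total segmented volume is recorded. The result is a
#' long-format measurement table (cases x observers x replicates rows) with
#' per-case metadata derived from the phantom specs (`is_complex`: any
#' staghorn; `is_homogeneous`: no shell heterogeneity; `is_multiple`: more
#' than one stone; `location` from the spec), ready for [agreement_study()].
#'
#' A drawn threshold above `hu_high` would be a degenerate window; it is
#' redrawn (bounded retries) with a warning.
#'
#' @param phantoms list of `stone_phantom` objects (the cases).
#' @param observers data.frame of [observer_model()] rows.
#' @param n_replicates measurements per case and observer. Default 5.
#' @param hu_high fixed upper threshold (HU). Default 3000.
#' @param connectivity,min_voxels passed to [segment_stones()].
#' @param seed RNG seed for the threshold draws.
#' @return A measurement table data.frame (see [read_measurement_table()])
#'   with an attribute `"truth"` holding per-case true total volumes.
#' @export
simulate_observer_measurements <- function(phantoms, observers,
                                           n_replicates = 5, hu_high = 3000,
                                           connectivity = 26, min_voxels = 1,
                                           seed = NULL) {
  stopifnot(length(phantoms) >= 1, nrow(observers) >= 1, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(phantoms) * nrow(observers) * n_replicates)
  truth <- numeric(length(phantoms))
  ri <- 0L
  for (ci in seq_along(phantoms)) {
    ph <- phantoms[[ci]]
    stopifnot(inherits(ph, "stone_phantom"))
    truth[ci] <- sum(ph$truth$true_volume_mm3)
    meta <- list(
      is_complex = any(ph$truth$shape == "staghorn"),
      is_homogeneous = !any(vapply(ph$spec$stones,
                                   function(s) !is.null(s$hu_shell), logical(1))),
      is_multiple = nrow(ph$truth) > 1,
      location = ph$spec$location
    )
    for (oi in seq_len(nrow(observers))) {
      for (rep_i in seq_len(n_replicates)) {
        hu_low <- rnorm(1, observers$hu_low_mean[oi], observers$hu_low_sd[oi])
        tries <- 0L
        while (hu_low > hu_high && tries < 100L) {
          hu_low <- rnorm(1, observers$hu_low_mean[oi], observers$hu_low_sd[oi])
          tries <- tries + 1L
        }
        if (hu_low > hu_high) {
          warning("degenerate window persisted after retries; clamping to hu_high")
          hu_low <- hu_high
        } else if (tries > 0L) {
          warning("degenerate window drawn; redrawn")
        }
        seg <- segment_stones(ph$volume, c(hu_low, hu_high),
                              connectivity = connectivity,
                              min_voxels = min_voxels,
                              measure_diameters = FALSE)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          case_id = ci, observer_id = observers$observer_id[oi],
          replicate = rep_i, volume_mm3 = seg$total_volume_mm3,
          is_complex = meta$is_complex, is_homogeneous = meta$is_homogeneous,
          is_multiple = meta$is_multiple, location = meta$location,
          hu_low = hu_low, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- data.frame(case_id = seq_along(phantoms),
                                   true_volume_mm3 = truth)
  out
}

#' Reference synthetic study: phantom set and observer panel
#'
#' Builds a study mirroring a three-observer, five-replicate repeated
#' measurement design on a mixed stone cohort: spheres, ellipsoids,
#' multi-stone cases and branched staghorn-like calculi with sizes spanning
#' roughly 150--10,000 mm^3, some with core/shell heterogeneity, all with
#' partial-volume blur and HU noise. Defaults are illustrative, chosen so
#' simulated replicate CVs land in the low single-digit percent range
#' typical of trained operators.
#'
#' @param n_cases number of phantoms. Default 50.
#' @param seed RNG seed for phantom geometry sampling.
#' @param spacing voxel spacing (mm).
#' @param blur_sigma_mm partial-volume blur. Default 0.8.
#' @param noise_sd_hu HU noise. Default 20.
#' @return List of `stone_phantom` objects.
#' @seealso [default_observer_panel()], [simulate_observer_measurements()]
#' @export
default_phantom_cohort <- function(n_cases = 50, seed = 1,
                                   spacing = c(0.75, 0.75, 0.75),
                                   blur_sigma_mm = 0.8, noise_sd_hu = 20) {
  set.seed(seed)
  phantoms <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    kind <- sample(c("sphere", "ellipsoid", "staghorn", "multiple"), 1,
                   prob = c(0.35, 0.25, 0.2, 0.2))
    hu_core <- runif(1, 900, 1600)
    hu_shell <- if (runif(1) < 0.4) hu_core - runif(1, 350, 650) else NULL
    if (!is.null(hu_shell) && hu_shell < 500) hu_shell <- 500
    margin <- 6  # mm of background around the stone
    if (kind == "sphere") {
      r <- runif(1, 3.5, 12)
      ext <- 2 * r + 2 * margin
      ctr <- rep(ext / 2, 3)
      stones <- list(stone_sphere(ctr, r, hu_core, hu_shell))
    } else if (kind == "ellipsoid") {
      a <- runif(3, 3, 11)
      ext <- 2 * max(a) + 2 * margin
      ctr <- rep(ext / 2, 3)
      stones <- list(stone_ellipsoid(ctr, a, hu_core, hu_shell,
                                     rotation_deg = runif(3, 0, 90)))
    } else if (kind == "staghorn") {
      s <- runif(1, 5, 9)
      ext <- 5 * s + 2 * margin  # branches extend ~2.2x size from center
      ctr <- rep(ext / 2, 3)
      stones <- list(stone_staghorn(ctr, s, hu_core, hu_shell))
    } else {
      r1 <- runif(1, 3, 7); r2 <- runif(1, 3, 6)
      ext <- 2 * (r1 + r2) + 3 * margin
      stones <- list(
        stone_sphere(c(r1 + margin, ext / 2, ext / 2), r1, hu_core, hu_shell),
        stone_sphere(c(ext - r2 - margin, ext / 2, ext / 2), r2, hu_core))
    }
    dims <- ceiling(rep(ext, 3) / spacing)
    loc <- sample(c("pelvis", "calyx", "other"), 1, prob = c(0.3, 0.5, 0.2))
    spec <- phantom_spec(dims, spacing = spacing, stones = stones,
                         blur_sigma_mm = blur_sigma_mm,
                         noise_sd_hu = noise_sd_hu, location = loc)
    phantoms[[i]] <- simulate_phantom(spec, seed = seed + i)
  }
  phantoms
}

#' @rdname default_phantom_cohort
#' @param hu_low_sd per-observer lower-threshold jitter (HU). Default 40.
#' @export
default_observer_panel <- function(hu_low_sd = 40) {
  rbind(
    observer_model("junior", hu_low_mean = 560, hu_low_sd = hu_low_sd * 1.3),
    observer_model("senior", hu_low_mean = 600, hu_low_sd = hu_low_sd),
    observer_model("expert", hu_low_mean = 620, hu_low_sd = hu_low_sd * 0.9)
  )
}

#' Read / write phantom specs and observer panels as JSON
#'
#' @param path JSON file path.
#' @param x the object to write.
#' @return the parsed object / `path` invisibly.
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  stones <- lapply(j$stones %||% list(), function(s) {
    switch(s$shape,
           sphere = stone_sphere(unlist(s$center), s$radius,
                                 s$hu_core %||% 1300, s$hu_shell),
           ellipsoid = stone_ellipsoid(unlist(s$center), unlist(s$semi_axes),
                                       s$hu_core %||% 1300, s$hu_shell,
                                       unlist(s$rotation %||% c(0, 0, 0))),
           staghorn = stone_staghorn(unlist(s$center), s$size,
                                     s$hu_core %||% 1300, s$hu_shell),
           stop("unknown stone shape: ", s$shape))
  })
  phantom_spec(unlist(j$dim), spacing = unlist(j$spacing %||% c(0.75, 0.75, 0.75)),
               stones = stones,
               background_hu_mean = j$background_hu_mean %||% 40,
               background_hu_sd = j$background_hu_sd %||% 15,
               blur_sigma_mm = j$blur_sigma_mm %||% 0,
               noise_sd_hu = j$noise_sd_hu %||% 0,
               seed = j$seed, location = j$location %||% "other")
}

#' @rdname read_phantom_spec
#' @export
read_observer_panel <- function(path) {
  j <- jsonlite::fromJSON(path)
  do.call(rbind, lapply(seq_len(nrow(j)), function(i)
    observer_model(j$observer_id[i], j$hu_low_mean[i], j$hu_low_sd[i])))
}
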