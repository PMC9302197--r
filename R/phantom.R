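#' Generate a schematic L3 CT phantom with known compartment areas
#'
#' Paints a 2-D CT slice containing air background, an elliptical body
#' outline, a central vertebral body (bone), four muscle-group blobs, a
#' subcutaneous fat ring, and residual soft tissue, with exact
#' ground-truth pixel counts per compartment. The geometry is schematic
#' rather than anatomical: ground truth is carried explicitly, so
#' segmentation accuracy is assessed against known labels, never against
#' realism.
#'
#' Pixel counts are `round(area_mm2 / pixel_area_mm2)`, so the painted
#' area matches the requested area to within one pixel's area.
#' Hounsfield values are drawn uniformly inside each compartment's
#' attenuation range: muscle within -29 to +150 HU, fat within -190 to
#' -30 HU, bone above +150, residual soft tissue in a band outside both
#' tissue windows, air at -1000.
#'
#' @param true_muscle_area_cm2 Requested skeletal muscle area, cm^2 >= 0.
#' @param true_fat_area_cm2 Requested fat area, cm^2 >= 0.
#' @param pixel_spacing_mm Isotropic pixel spacing in mm (default 1).
#' @param dim_px Slice dimensions in pixels (default 512 x 512).
#' @param seed Integer seed; the phantom is deterministic given all
#'   arguments.
#' @return A list with `slice` (a [ct_slice()]), and `truth`: compartment
#'   pixel counts, achieved areas in cm^2 (pixel count x pixel area,
#'   exact), and a `labels` matrix with values `"air"`, `"other"`,
#'   `"muscle"`, `"fat"`, `"bone"`.
#' @examples
#' ph <- generate_l3_phantom(150, 300, seed = 1)
#' ph$truth$muscle_px # 15000 at 1 mm spacing
#' @export
generate_l3_phantom <- function(true_muscle_area_cm2, true_fat_area_cm2,
                                pixel_spacing_mm = 1, dim_px = c(512, 512),
                                seed = 1) {
  if (true_muscle_area_cm2 < 0 || true_fat_area_cm2 < 0)
    stop("areas must be non-negative")
  if (pixel_spacing_mm <= 0) stop("pixel spacing must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nr <- dim_px[1]; nc <- dim_px[2]
  px_area_mm2 <- pixel_spacing_mm^2
  n_muscle <- round(true_muscle_area_cm2 * 100 / px_area_mm2)
  n_fat <- round(true_fat_area_cm2 * 100 / px_area_mm2)

  # mm coordinates of pixel centres; ellipse fills most of the slice
  x <- (seq_len(nr) - 0.5) * pixel_spacing_mm
  y <- (seq_len(nc) - 0.5) * pixel_spacing_mm
  cx <- mean(range(x)); cy <- mean(range(y))
  rx <- 0.46 * diff(range(x)); ry <- 0.40 * diff(range(y))
  X <- matrix(x, nr, nc)
  Y <- matrix(y, nr, nc, byrow = TRUE)
  # normalized elliptical radius: <= 1 inside the body
  er <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
  body <- er <= 1

  # vertebral body: bone disk slightly posterior of centre
  bone <- sqrt((X - cx)^2 + (Y - (cy + 0.25 * ry))^2) <= min(18, 0.15 * ry)

  labels <- matrix("air", nr, nc)
  labels[body] <- "other"
  labels[body & bone] <- "bone"

  candidates <- which(body & !bone)
  if (n_muscle + n_fat > length(candidates))
    stop("requested areas exceed the phantom body extent; enlarge dim_px")

  # four muscle-group blobs: nearest-to-centre growth gives exact counts
  centers <- rbind(
    c(cx, cy - 0.45 * ry),              # rectus abdominis (anterior)
    c(cx - 0.45 * rx, cy + 0.10 * ry),  # left abdominal/psoas
    c(cx + 0.45 * rx, cy + 0.10 * ry),  # right abdominal/psoas
    c(cx, cy + 0.55 * ry)               # paraspinal (posterior)
  )
  if (n_muscle > 0) {
    dmin <- rep(Inf, length(candidates))
    for (g in seq_len(nrow(centers))) {
      d <- sqrt((X[candidates] - centers[g, 1])^2 +
                (Y[candidates] - centers[g, 2])^2)
      dmin <- pmin(dmin, d)
    }
    muscle_idx <- candidates[order(dmin)[seq_len(n_muscle)]]
    labels[muscle_idx] <- "muscle"
  }

  # subcutaneous fat: outermost remaining body pixels, exact count
  remaining <- which(body & !bone & labels != "muscle")
  if (n_fat > 0) {
    fat_idx <- remaining[order(er[remaining], decreasing = TRUE)[seq_len(n_fat)]]
    labels[fat_idx] <- "fat"
  }

  hu <- matrix(-1000, nr, nc)
  paint <- function(lab, lo, hi) {
    i <- which(labels == lab)
    if (length(i)) hu[i] <<- stats::runif(length(i), lo, hi)
  }
  paint("muscle", -29, 150)
  paint("fat", -190, -30)
  paint("bone", 250, 1000)
  paint("other", -260, -210)   # residual soft tissue band outside both windows

  truth <- list(
    muscle_px = sum(labels == "muscle"),
    fat_px = sum(labels == "fat"),
    bone_px = sum(labels == "bone"),
    muscle_area_cm2 = sum(labels == "muscle") * px_area_mm2 / 100,
    fat_area_cm2 = sum(labels == "fat") * px_area_mm2 / 100,
    requested_muscle_area_cm2 = true_muscle_area_cm2,
    requested_fat_area_cm2 = true_fat_area_cm2,
    labels = labels
  )
  list(slice = ct_slice(hu, pixel_spacing_mm,
                        source = sprintf("l3_phantom(seed=%d)", seed)),
       truth = truth)
}

#' Generate a PET liver phantom with known activity concentration
#'
#' Builds a 3-D activity-concentration volume containing an ellipsoidal
#' liver compartment at a target concentration with additive Gaussian
#' voxel noise (truncated at zero, since concentrations are physically
#' non-negative) over a zero background. The default liver holds about
#' 25,000 voxels at 2 mm spacing, comfortably enclosing a 15-mm-radius
#' reference sphere at its centre.
#'
#' @param target_conc_kbq_ml Liver activity concentration, kBq/ml >= 0.
#' @param noise_sd_kbq_ml SD of the additive voxel noise, >= 0.
#' @param voxel_spacing_mm Isotropic voxel spacing in mm (default 2).
#' @param dim_vox Volume dimensions in voxels (default 80 x 80 x 60).
#' @param seed Integer seed.
#' @return A list with `volume` (a [pet_volume()]), `voi` (a
#'   [spherical_voi()] centred in the liver), and `truth`: the target
#'   concentration, liver voxel count, and a logical `liver` mask array.
#' @examples
#' ph <- generate_liver_phantom(5.0, 0.5, seed = 1)
#' voi_mean(ph$volume, ph$voi)$mean_kbq_ml
#' @export
generate_liver_phantom <- function(target_conc_kbq_ml, noise_sd_kbq_ml = 0,
                                   voxel_spacing_mm = 2,
                                   dim_vox = c(80, 80, 60), seed = 1) {
  if (target_conc_kbq_ml < 0) stop("target concentration must be non-negative")
  if (noise_sd_kbq_ml < 0) stop("noise SD must be non-negative")
  if (voxel_spacing_mm <= 0) stop("voxel spacing must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sp <- rep(voxel_spacing_mm, 3)
  ext <- (dim_vox - 1) * sp
  ctr <- ext / 2
  # liver ellipsoid semi-axes in mm, scaled to the volume extent
  semi <- pmin(c(45, 35, 30), 0.45 * ext)
  co <- lapply(1:3, function(a) (seq_len(dim_vox[a]) - 1) * sp[a] - ctr[a])
  r2 <- outer(outer((co[[1]] / semi[1])^2, (co[[2]] / semi[2])^2, "+"),
              (co[[3]] / semi[3])^2, "+")
  liver <- r2 <= 1

  vol <- array(0, dim_vox)
  nl <- sum(liver)
  vals <- target_conc_kbq_ml
  if (noise_sd_kbq_ml > 0)
    vals <- pmax(0, stats::rnorm(nl, target_conc_kbq_ml, noise_sd_kbq_ml))
  vol[liver] <- vals

  list(
    volume = pet_volume(vol, sp),
    voi = spherical_voi(ctr, radius_mm = 15),
    truth = list(target_conc_kbq_ml = target_conc_kbq_ml,
                 noise_sd_kbq_ml = noise_sd_kbq_ml,
                 liver_voxels = nl,
                 liver = liver)
  )
}
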