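#' Construct a PET activity-concentration volume
#'
#' Wraps a 3-D array of activity concentrations (kBq/ml) with its voxel
#' spacing and origin. World coordinates follow the convention that voxel
#' `(i, j, k)` has its centre at `origin + (c(i, j, k) - 1) * spacing` mm.
#'
#' @param data 3-D numeric array of activity concentration in kBq/ml,
#'   non-negative.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param origin World coordinate (mm) of the centre of voxel (1,1,1).
#' @return Object of class `pet_volume`.
#' @export
pet_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) stop("data must be a 3-D array")
  if (any(!is.finite(data)) || any(data < 0))
    stop("activity concentrations must be finite and non-negative")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be positive, length 1 or 3")
  if (length(origin) != 3) stop("origin must have length 3")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("PET volume ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "] kBq/ml\n", sep = "")
  invisible(x)
}

#' Define a spherical volume of interest
#'
#' A sphere in world (mm) coordinates, by default of 15 mm radius -- the
#' standard 1.5-cm sphere placed in a lesion-free central portion of the
#' liver for reference-region SUV measurements.
#'
#' @param center Sphere centre in mm world coordinates, length 3.
#' @param radius_mm Sphere radius in mm, positive (default 15).
#' @return Object of class `spherical_voi`.
#' @export
spherical_voi <- function(center, radius_mm = 15) {
  if (length(center) != 3 || any(!is.finite(center)))
    stop("center must be 3 finite coordinates (mm)")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("radius_mm must be positive")
  structure(list(center = as.numeric(center), radius_mm = radius_mm),
            class = "spherical_voi")
}

#' Radioactive decay correction of the injected activity
#'
#' Decays the injected activity over the elapsed time:
#' `injected * 2^(-elapsed / half_life)`. The default half-life is that of
#' F-18 (109.77 min); configurable for other nuclides.
#'
#' @param injected_mbq Injected activity in MBq, non-negative.
#' @param elapsed_min Minutes from injection to the time point of interest
#'   (typically acquisition start), non-negative.
#' @param half_life_min Radionuclide half-life in minutes.
#' @return Decay-corrected activity in MBq.
#' @examples
#' decay_correct(400, 109.77) # one half-life -> 200
#' @export
decay_correct <- function(injected_mbq, elapsed_min, half_life_min = 109.77) {
  if (any(!is.finite(injected_mbq)) || any(injected_mbq < 0))
    stop("injected_mbq must be non-negative")
  if (any(!is.finite(elapsed_min)) || any(elapsed_min < 0))
    stop("elapsed_min must be non-negative")
  if (!is.finite(half_life_min) || half_life_min <= 0)
    stop("half_life_min must be positive")
  injected_mbq * 2^(-elapsed_min / half_life_min)
}

#' Mean activity concentration within a spherical VOI
#'
#' Averages the concentration over all voxels whose centres lie within the
#' sphere (centre-in-sphere inclusion, boundary included). The sphere must
#' lie fully inside the volume bounds.
#'
#' @param volume A [pet_volume()].
#' @param voi A [spherical_voi()].
#' @return A list with `mean_kbq_ml` and `n_voxels`.
#' @export
voi_mean <- function(volume, voi) {
  stopifnot(inherits(volume, "pet_volume"), inherits(voi, "spherical_voi"))
  dims <- dim(volume$data)
  lo <- volume$origin
  hi <- volume$origin + (dims - 1) * volume$spacing
  if (any(voi$center - voi$radius_mm < lo) ||
      any(voi$center + voi$radius_mm > hi))
    stop("sphere extends outside the volume bounds")
  # candidate index window around the sphere, then exact centre-distance test
  idx <- lapply(1:3, function(a) {
    r <- (voi$center[a] + c(-1, 1) * voi$radius_mm - lo[a]) / volume$spacing[a]
    seq(max(1L, floor(r[1]) + 1L), min(dims[a], ceiling(r[2]) + 1L))
  })
  cx <- lo[1] + (idx[[1]] - 1) * volume$spacing[1]
  cy <- lo[2] + (idx[[2]] - 1) * volume$spacing[2]
  cz <- lo[3] + (idx[[3]] - 1) * volume$spacing[3]
  d2 <- outer(outer((cx - voi$center[1])^2, (cy - voi$center[2])^2, "+"),
              (cz - voi$center[3])^2, "+")
  inside <- d2 <= voi$radius_mm^2
  if (!any(inside)) stop("no voxel centre falls inside the sphere")
  vals <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE][inside]
  list(mean_kbq_ml = mean(vals), n_voxels = sum(inside))
}

#' Mean standardized uptake value
#'
#' SUV normalizes the tissue activity concentration by the injected dose
#' per total body mass: `SUV = conc / (dose / weight)` with concentration
#' in kBq/ml, dose in MBq and weight in kg. Taking 1 g of tissue as 1 ml,
#' the kilo prefixes cancel and SUV carries units of g/ml.
#'
#' @param conc_kbq_ml Mean activity concentration in the VOI, kBq/ml.
#' @param dose_mbq Injected dose in MBq (decay-corrected to the reference
#'   time point), positive.
#' @param weight_kg Total body mass in kg, positive.
#' @return SUV_mean in g/ml.
#' @examples
#' suv_mean(5.0, 400, 80) # 1.0
#' @export
suv_mean <- function(conc_kbq_ml, dose_mbq, weight_kg) {
  if (any(!is.finite(conc_kbq_ml)) || any(conc_kbq_ml < 0))
    stop("conc_kbq_ml must be non-negative")
  if (any(!is.finite(dose_mbq)) || any(dose_mbq <= 0))
    stop("dose_mbq must be positive")
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("weight_kg must be positive")
  conc_kbq_ml * weight_kg / dose_mbq
}

#' Lean-body-mass-normalized uptake (SUL)
#'
#' Rescales a total-body-mass SUV to the lean compartment:
#' `SUL = SUV * LBM / TBM`. Identical to recomputing the SUV with LBM in
#' place of total body mass in the denominator.
#'
#' @param suv SUV_mean in g/ml, non-negative.
#' @param lbm_kg Lean body mass in kg, positive. A warning is issued when
#'   LBM exceeds total body mass.
#' @param tbm_kg Total body mass in kg, positive.
#' @return SUL in g/ml.
#' @examples
#' sul(2.0, 54.8, 82.2)
#' @export
sul <- function(suv, lbm_kg, tbm_kg) {
  if (any(!is.finite(suv)) || any(suv < 0)) stop("suv must be non-negative")
  if (any(!is.finite(lbm_kg)) || any(lbm_kg <= 0))
    stop("lbm_kg must be positive")
  if (any(!is.finite(tbm_kg)) || any(tbm_kg <= 0))
    stop("tbm_kg must be positive")
  if (any(lbm_kg > tbm_kg))
    warning("lean body mass exceeds total body mass for some subjects")
  suv * lbm_kg / tbm_kg
}
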