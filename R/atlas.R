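# Planted-activation truth atlases.
#
# A truth atlas lists spherical regions with a conjunction category (which
# tasks respond there) and per-task effect sizes in percent signal change.
# The default atlas reuses published choice-phase peak coordinates as plant
# sites, one or two per category, with amplitudes chosen a priori to encode
# the study's qualitative structure: a strong bilateral striatal overlap of
# the Value and Mathematical tasks, weaker Value-unique territory, and an
# expansive Emotion response. See the methods vignette for the rationale.

.cat_letters <- c(Value = "V", Mathematical = "M", Emotion = "E")

# expand "VM" -> c("Value", "Mathematical")
.category_tasks <- function(category) {
  lets <- strsplit(category, "")[[1]]
  if (!all(lets %in% .cat_letters)) stop("bad category: ", category)
  names(.cat_letters)[match(lets, .cat_letters)]
}

#' Truth atlas of planted spherical effects
#'
#' @param regions data.frame with columns `name`, `x`, `y`, `z` (MNI mm
#'   centre), `radius_mm`, `category` (a compact task subset such as
#'   `"VME"`, `"VM"`, `"E"`), `effect_V`, `effect_M`, `effect_E` (percent
#'   signal change; must be nonzero exactly for the tasks the category
#'   includes) and optionally `exclude_structure` (logical; regions whose
#'   sphere should enter the excluded-structures mask).
#' @return A `truth_atlas`.
#' @export
truth_atlas <- function(regions) {
  need <- c("name", "x", "y", "z", "radius_mm", "category",
            "effect_V", "effect_M", "effect_E")
  stopifnot(all(need %in% names(regions)))
  if (is.null(regions$exclude_structure))
    regions$exclude_structure <- rep(FALSE, nrow(regions))
  eff <- as.matrix(regions[, c("effect_V", "effect_M", "effect_E")])
  for (i in seq_len(nrow(regions))) {
    inc <- .cat_letters[.category_tasks(regions$category[i])]
    on <- colnames(eff) %in% paste0("effect_", inc)
    if (any(eff[i, on] == 0) || any(eff[i, !on] != 0))
      stop("region '", regions$name[i],
           "': effects must be nonzero exactly for tasks in its category")
  }
  structure(list(regions = regions), class = "truth_atlas")
}

.default_atlas_regions <- data.frame(
  name = c("L_SMA", "L_putamen", "R_putamen", "R_IPL", "R_fusiform",
           "L_precentral", "L_amSFG", "R_calcarine"),
  x = c(-8, -18, 26, 32, 38, -32, -6, 18),
  y = c(6, 12, 9, -54, -44, -17, 60, -89),
  z = c(54, 2, 11, 48, -14, 57, 26, 2),
  radius_mm = 8,
  category = c("VME", "VM", "VM", "VE", "ME", "V", "M", "E"),
  effect_V = c(1, 1, 0.8, 0.6, 0, 0.6, 0, 0),
  effect_M = c(1, 1, 0.8, 0, 0.8, 0, 1, 0),
  effect_E = c(1, 0, 0, 0.6, 0.8, 0, 0, 1),
  exclude_structure = FALSE,
  stringsAsFactors = FALSE)

#' Default truth atlas on the acquisition grid
#'
#' Eight spherical regions (8 mm radius) covering every conjunction
#' category, centred on published choice-phase peaks in MNI mm.
#' @export
default_truth_atlas <- function() truth_atlas(.default_atlas_regions)

#' Scaled-down synthetic truth atlas for a reduced grid
#'
#' Places the same category/effect structure as [default_truth_atlas()] at
#' synthetic, well-separated positions inside an arbitrary (typically
#' reduced) grid; centres are fixed fractions of the grid bounding box, not
#' anatomical coordinates.
#'
#' @param grid an [acq_grid()].
#' @param radius_mm sphere radius (default 8 mm).
#' @export
demo_truth_atlas <- function(grid, radius_mm = 8) {
  fr <- matrix(c(0.25, 0.25, 0.30,
                 0.70, 0.25, 0.30,
                 0.25, 0.70, 0.30,
                 0.70, 0.70, 0.30,
                 0.25, 0.25, 0.72,
                 0.70, 0.25, 0.72,
                 0.25, 0.70, 0.72,
                 0.70, 0.70, 0.72), ncol = 3, byrow = TRUE)
  ijk <- sweep(fr, 2, grid$dims - 1, `*`)
  xyz <- voxel_to_world(grid, ijk)
  reg <- .default_atlas_regions
  reg$x <- xyz[, 1]; reg$y <- xyz[, 2]; reg$z <- xyz[, 3]
  reg$radius_mm <- radius_mm
  reg$name <- paste0("synthetic_", reg$category,
                     ave(reg$category, reg$category, FUN = seq_along))
  truth_atlas(reg)
}

#' Plant per-task effect volumes
#'
#' Superposes each region's spherical effect (uniform amplitude within
#' `radius_mm` of the centre, by voxel-centre distance) into one volume per
#' task. Category-implied zeros are exactly zero.
#'
#' @param atlas a [truth_atlas()].
#' @param grid an [acq_grid()].
#' @param scale optional per-region amplitude multipliers (e.g. a subject's
#'   regional responsiveness), length `nrow(atlas$regions)`.
#' @return Named list of [fmri_volume()] (Value, Mathematical, Emotion).
#' @export
plant_truth <- function(atlas, grid, scale = NULL) {
  stopifnot(inherits(atlas, "truth_atlas"))
  reg <- atlas$regions
  if (is.null(scale)) scale <- rep(1, nrow(reg))
  centers <- voxel_centers_mm(grid)
  out <- lapply(names(.cat_letters), function(task) {
    v <- numeric(prod(grid$dims))
    effcol <- paste0("effect_", .cat_letters[[task]])
    for (i in seq_len(nrow(reg))) {
      if (reg[[effcol]][i] == 0) next
      d2 <- (centers[, 1] - reg$x[i])^2 + (centers[, 2] - reg$y[i])^2 +
        (centers[, 3] - reg$z[i])^2
      inside <- d2 <= reg$radius_mm[i]^2
      if (!any(inside))
        stop("region '", reg$name[i], "' lies entirely outside the grid")
      v[inside] <- v[inside] + reg[[effcol]][i] * scale[i]
    }
    fmri_volume(v, grid)
  })
  names(out) <- names(.cat_letters)
  out
}

#' Mask of true region membership
#'
#' @param atlas a [truth_atlas()].
#' @param grid an [acq_grid()].
#' @param which_regions row indices (default all).
#' @return An [fmri_mask()] covering the selected regions' spheres.
#' @export
atlas_mask <- function(atlas, grid, which_regions = NULL) {
  reg <- atlas$regions
  if (is.null(which_regions)) which_regions <- seq_len(nrow(reg))
  centers <- voxel_centers_mm(grid)
  v <- logical(prod(grid$dims))
  for (i in which_regions) {
    d2 <- (centers[, 1] - reg$x[i])^2 + (centers[, 2] - reg$y[i])^2 +
      (centers[, 3] - reg$z[i])^2
    v <- v | (d2 <= reg$radius_mm[i]^2)
  }
  fmri_mask(v, grid)
}

#' Dice overlap coefficient of two masks
#' @param a,b [fmri_mask()]s on the same grid.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}
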