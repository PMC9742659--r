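# Preprocessing: SUV conversion, resampling to a common grid, and the fixed
# intensity normalization that harmonises intensity ranges across centres
# (divide NAC by 3 and ASC by 9, keeping all training inputs in [0, 5]).

#' SUV conversion parameters
#'
#' @param injected_activity_MBq injected dose (MBq), > 0.
#' @param body_weight_kg patient weight (kg), > 0.
#' @param decay_correction_factor multiplicative decay correction (default 1;
#'   the synthetic studies need none).
#' @return an `suv_parameters` list.
#' @export
suv_parameters <- function(injected_activity_MBq, body_weight_kg,
                           decay_correction_factor = 1) {
  if (injected_activity_MBq <= 0) stop("injected activity must be positive")
  if (body_weight_kg <= 0) stop("body weight must be positive")
  if (decay_correction_factor <= 0) stop("decay factor must be positive")
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 body_weight_kg = body_weight_kg,
                 decay_correction_factor = decay_correction_factor),
            class = "suv_parameters")
}

#' Convert an activity-concentration image to SUV
#'
#' `suv = image * body_weight_kg * decay_correction_factor /
#' injected_activity_MBq`, the standard body-weight SUV up to the unit
#' convention that images carry activity per unit weight-normalised volume (a
#' uniform image whose concentration times weight equals the dose maps to
#' SUV 1). Linear and order-preserving in the image.
#'
#' @param image numeric matrix/array.
#' @param params an [suv_parameters()] (or a `paired_study`, whose metadata
#'   are used).
#' @return SUV image with the same shape.
#' @export
to_suv <- function(image, params) {
  if (inherits(params, "paired_study"))
    params <- suv_parameters(params$injected_activity_MBq,
                             params$body_weight_kg)
  stopifnot(inherits(params, "suv_parameters"))
  image * params$body_weight_kg * params$decay_correction_factor /
    params$injected_activity_MBq
}

#' Image grid specification
#'
#' @param spacing voxel spacing (mm); the study default target is
#'   `c(3, 3, 4)`. For 2D slices the third entry is the slice thickness.
#' @param size grid size (voxels).
#' @param origin world coordinate of the first voxel centre (mm).
#' @return a `grid_spec`.
#' @export
grid_spec <- function(spacing = c(3, 3, 4), size, origin = NULL) {
  stopifnot(all(spacing > 0), all(size >= 1))
  if (is.null(origin)) {
    # centred field of view in-plane
    origin <- c(-(size[1] - 1) / 2 * spacing[1],
                -(size[2] - 1) / 2 * spacing[2],
                if (length(size) > 2) 0 else NULL)
  }
  structure(list(spacing = spacing, size = as.integer(size), origin = origin),
            class = "grid_spec")
}

grid_coords <- function(g, axis) {
  g$origin[axis] + (seq_len(g$size[axis]) - 1) * g$spacing[axis]
}

#' Resample a 2D slice between grids
#'
#' Bilinear interpolation at the target pixel centres; values outside the
#' source extent are 0. A constant image stays constant in the interior and
#' resampling onto the identical grid is the identity.
#'
#' @param image matrix on `source`.
#' @param source,target [grid_spec()] objects (in-plane part is used).
#' @return matrix on `target`.
#' @export
resample <- function(image, source, target) {
  stopifnot(nrow(image) == source$size[1], ncol(image) == source$size[2])
  if (any(target$size[1:2] < 1)) stop("degenerate target grid")
  sx <- grid_coords(source, 1); sy <- grid_coords(source, 2)
  tx <- grid_coords(target, 1); ty <- grid_coords(target, 2)
  if (identical(sx, tx) && identical(sy, ty)) return(image)
  xg <- matrix(tx, length(tx), length(ty))
  yg <- matrix(ty, length(tx), length(ty), byrow = TRUE)
  inside <- xg >= min(sx) & xg <= max(sx) & yg >= min(sy) & yg <= max(sy)
  out <- matrix(0, length(tx), length(ty))
  if (any(inside)) {
    # pracma::interp2 interpolates z indexed as z[y, x]
    vals <- pracma::interp2(x = sx, y = sy, Z = t(image),
                            xp = xg[inside], yp = yg[inside],
                            method = "linear")
    out[inside] <- vals
  }
  out
}

#' Intensity normalization rule
#'
#' Fixed empirical divisors harmonise the intensity range across centres:
#' NAC SUV images are divided by 3 and ASC SUV images by 9, then clipped to
#' `[0, 5]`, so every training input lies in the same 0-5 range.
#'
#' @param role `"NAC"` or `"ASC"`.
#' @param divisor override the default divisor (3 for NAC, 9 for ASC).
#' @param clip_range two-element numeric, default `c(0, 5)`.
#' @return a `normalization_rule`.
#' @export
normalization_rule <- function(role = c("NAC", "ASC"), divisor = NULL,
                               clip_range = c(0, 5)) {
  role <- match.arg(role)
  divisor <- divisor %||% if (role == "NAC") 3 else 9
  stopifnot(divisor > 0, length(clip_range) == 2, clip_range[1] < clip_range[2])
  structure(list(role = role, divisor = divisor, clip_range = clip_range),
            class = "normalization_rule")
}

#' Normalize / denormalize an SUV image
#'
#' `normalize()` divides by the rule's divisor and clips to the rule's range
#' (clipped-pixel count in attribute `"clipped"` for auditability);
#' `denormalize()` inverts it exactly for values that were not clipped.
#'
#' @param image SUV matrix.
#' @param rule a [normalization_rule()].
#' @return matrix of the same shape.
#' @export
normalize <- function(image, rule) {
  stopifnot(inherits(rule, "normalization_rule"))
  x <- image / rule$divisor
  clipped <- sum(x < rule$clip_range[1] | x > rule$clip_range[2])
  out <- clip01(x, rule$clip_range[1], rule$clip_range[2])
  attr(out, "clipped") <- clipped
  out
}

#' @rdname normalize
#' @export
denormalize <- function(image, rule) {
  stopifnot(inherits(rule, "normalization_rule"))
  image * rule$divisor
}

#' Preprocess one paired study for training
#'
#' SUV conversion, resampling of both images to the common target grid
#' (study default 3 x 3 mm in-plane), then the fixed NAC/ASC normalization.
#'
#' @param study a `paired_study`.
#' @param target a [grid_spec()]; default 64 x 64 at 3 mm.
#' @param nac_rule,asc_rule [normalization_rule()] overrides.
#' @return list with `x` (normalized NAC), `y` (normalized ASC), the rules,
#'   and the target grid.
#' @export
preprocess_study <- function(study, target = grid_spec(c(3, 3, 4), c(64, 64, 1)),
                             nac_rule = normalization_rule("NAC"),
                             asc_rule = normalization_rule("ASC")) {
  src <- study$grid
  nac_suv <- to_suv(study$nac_image, study)
  asc_suv <- to_suv(study$asc_image, study)
  x <- normalize(resample(nac_suv, src, target), nac_rule)
  y <- normalize(resample(asc_suv, src, target), asc_rule)
  list(x = x, y = y, nac_rule = nac_rule, asc_rule = asc_rule, grid = target,
       study_id = study$study_id %||% NA_character_,
       center_id = study$center_id)
}
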