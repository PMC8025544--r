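# HU accuracy and overlap metrics between sCT and CT: MAE/ME per region,
# bone Dice overlap at the 250 HU threshold, and the post-surgical
# volume-of-interest sub-analysis (resection region + 1 cm margin).

#' Bone segmentation threshold (HU)
#' @export
BONE_HU_THRESHOLD <- 250

#' Mean absolute error and mean error over a region
#'
#' Voxel-wise comparison sCT vs CT on a shared grid. The sign convention is
#' ME = mean(sCT - CT): systematic bone underestimation in the sCT gives a
#' negative ME.
#'
#' @param ct,sct [image_volume()] objects (HU) on the same grid.
#' @param mask a non-empty [binary_mask()] on the same grid.
#' @param region region name for the output row.
#' @return A one-row tibble: region, mae, me, n_voxels.
#' @export
mae_me <- function(ct, sct, mask, region = "region") {
  check_same_grid(ct, sct, "CT and sCT")
  check_same_grid(ct, mask, "CT and mask")
  sel <- mask$values
  if (!any(sel)) stop("empty mask", call. = FALSE)
  d <- sct$values[sel] - ct$values[sel]
  tibble::tibble(region = region, mae = mean(abs(d)), me = mean(d),
                 n_voxels = sum(sel))
}

#' Dice similarity coefficient of two masks
#'
#' DSC = 2|A intersect B| / (|A| + |B|). When both masks are empty the
#' coefficient is defined as 1 with a warning (the masks agree trivially).
#'
#' @param mask_a,mask_b [binary_mask()] objects on the same grid.
#' @return A one-row tibble: dsc, n_a, n_b, n_intersect, both_empty.
#' @export
dice <- function(mask_a, mask_b) {
  check_same_grid(mask_a, mask_b, "masks")
  na <- sum(mask_a$values); nb <- sum(mask_b$values)
  ni <- sum(mask_a$values & mask_b$values)
  both_empty <- na + nb == 0
  if (both_empty) warning("both masks empty; DSC defined as 1")
  tibble::tibble(dsc = if (both_empty) 1 else 2 * ni / (na + nb),
                 n_a = na, n_b = nb, n_intersect = ni,
                 both_empty = both_empty)
}

#' Standard three-region HU evaluation plus bone overlap
#'
#' MAE/ME within the intersection of the body contours ("body"), the brain,
#' and bone (CT >= 250 HU, teeth/jaw excluded), plus the bone Dice overlap
#' with both images thresholded at 250 HU.
#'
#' @param ct,sct HU [image_volume()] objects on the same grid.
#' @param body_ct,body_sct body-contour [binary_mask()]s of each image.
#' @param brain brain [binary_mask()].
#' @param jaw_exclusion optional [binary_mask()] removed from the bone
#'   region (caudal teeth/jaw region).
#' @return A list: `metrics` (tibble with rows body/brain/bone) and
#'   `bone_overlap` (the [dice()] tibble).
#' @export
region_suite <- function(ct, sct, body_ct, body_sct, brain,
                         jaw_exclusion = NULL) {
  for (m in list(body_ct, body_sct, brain))
    check_same_grid(ct, m, "CT and mask")
  body <- binary_mask(body_ct$values & body_sct$values, ct$spacing,
                      ct$origin)
  rule <- mask_rule(BONE_HU_THRESHOLD, exclusion = jaw_exclusion)
  bone_ct <- threshold_mask(ct, rule)
  bone_sct <- threshold_mask(sct, rule)
  metrics <- rbind(mae_me(ct, sct, body, "body"),
                   mae_me(ct, sct, brain, "brain"),
                   mae_me(ct, sct, bone_ct, "bone"))
  list(metrics = metrics, bone_overlap = dice(bone_ct, bone_sct))
}

#' Post-surgical volume-of-interest sub-analysis
#'
#' The VOI is the resection region dilated by 10 mm, restricted to the
#' transverse slices the dilated region intersects. Bone MAE (over CT bone
#' within the VOI) and bone DSC (both images at 250 HU, within the VOI) are
#' reported.
#'
#' @param ct,sct HU [image_volume()] objects on the same grid.
#' @param resection_region non-empty [binary_mask()] of the resected bone.
#' @param margin_mm dilation margin, mm (default the conventional 1 cm).
#' @return A list: `metrics` (one-row MAE/ME tibble for bone-in-VOI),
#'   `bone_overlap` ([dice()] within the VOI), `voi` (the VOI mask).
#' @export
resection_voi_suite <- function(ct, sct, resection_region, margin_mm = 10) {
  if (!any(resection_region$values)) stop("empty resection region",
                                          call. = FALSE)
  check_same_grid(ct, resection_region, "CT and resection region")
  voi <- dilate_mask(resection_region, margin_mm)
  slices <- apply(voi$values, 3, any)
  vv <- voi$values
  vv[, , !slices] <- FALSE
  voi <- binary_mask(vv, voi$spacing, voi$origin)
  bone_ct <- threshold_mask(ct, mask_rule(BONE_HU_THRESHOLD))
  bone_sct <- threshold_mask(sct, mask_rule(BONE_HU_THRESHOLD))
  bone_in_voi <- binary_mask(bone_ct$values & voi$values, ct$spacing,
                             ct$origin)
  metrics <- if (any(bone_in_voi$values))
    mae_me(ct, sct, bone_in_voi, "bone_voi")
  else
    tibble::tibble(region = "bone_voi", mae = NA_real_, me = NA_real_,
                   n_voxels = 0L)
  ov <- dice(binary_mask(bone_ct$values & voi$values, ct$spacing, ct$origin),
             binary_mask(bone_sct$values & voi$values, ct$spacing,
                         ct$origin))
  list(metrics = metrics, bone_overlap = ov, voi = voi)
}
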