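#' Sample a unilateral focal lesion
#'
#' Grows a face-connected blob of exactly \code{target_volume_vox} voxels by
#' seeded random region growing, confined to one hemisphere of the scheme's
#' grid (the lesions modelled are unilateral and focal).
#'
#' @param scheme a \code{parcel_scheme}.
#' @param side "left" or "right".
#' @param target_volume_vox integer >= 1, at most the hemisphere voxel count.
#' @param seed integer seed; the mask is deterministic given its arguments.
#' @param patient_id identifier stored on the mask.
#' @return An object of class \code{lesion_mask}: a list with \code{volume}
#'   (3-D 0/1 integer array on the scheme grid), \code{patient_id} and
#'   \code{side}.
#' @export
sample_lesion <- function(scheme, side = c("left", "right"),
                          target_volume_vox, seed = 1L,
                          patient_id = NA_character_) {
  side <- match.arg(side)
  dims <- dim(scheme$labels)
  hemi <- voxel_hemisphere(scheme)
  hv <- which(hemi == side)
  target_volume_vox <- as.integer(target_volume_vox)
  if (target_volume_vox < 1L)
    stop("sizing error: target volume must be >= 1 voxel")
  if (target_volume_vox > length(hv))
    stop("sizing error: target volume ", target_volume_vox,
         " exceeds hemisphere size ", length(hv))

  set.seed(seed)
  in_hemi <- logical(prod(dims))
  in_hemi[hv] <- TRUE
  lesion <- logical(prod(dims))
  start <- sample(hv, 1L)
  lesion[start] <- TRUE
  frontier <- .face_neighbours(start, dims)
  frontier <- unique(frontier[in_hemi[frontier]])
  n <- 1L
  while (n < target_volume_vox) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    lesion[pick] <- TRUE
    n <- n + 1L
    nb <- .face_neighbours(pick, dims)
    frontier <- unique(c(frontier, nb[in_hemi[nb] & !lesion[nb]]))
    frontier <- frontier[!lesion[frontier]]
  }
  vol <- array(0L, dim = dims)
  vol[lesion] <- 1L
  structure(list(volume = vol, patient_id = patient_id, side = side),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("Lesion mask (", x$side, " hemisphere): ", sum(x$volume),
      " voxels on a ", paste(dim(x$volume), collapse = "x"), " grid\n",
      sep = "")
  invisible(x)
}

#' Read and write binary lesion masks
#'
#' Round-trips binary lesion volumes through NIfTI. When a \code{scheme} is
#' given, masks whose grid does not match the scheme are rejected with an
#' alignment error; no resampling is performed, inputs must already be
#' registered to the scheme grid.
#'
#' @param path NIfTI file path.
#' @param scheme optional \code{parcel_scheme} for grid verification.
#' @param patient_id identifier stored on the returned mask.
#' @return \code{read_mask} returns a \code{lesion_mask} (its \code{side} is
#'   the hemisphere holding the majority of lesioned voxels, or \code{NA} for
#'   an empty volume); \code{write_mask} and \code{write_map} return the path
#'   invisibly.
#' @export
read_mask <- function(path, scheme = NULL, patient_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vol <- array(as.integer(as.array(img) != 0), dim = dim(img))
  if (!is.null(scheme) && !identical(dim(vol), dim(scheme$labels)))
    stop("alignment error: mask grid ", paste(dim(vol), collapse = "x"),
         " does not match scheme grid ",
         paste(dim(scheme$labels), collapse = "x"))
  side <- NA_character_
  if (!is.null(scheme) && sum(vol) > 0) {
    hemi <- voxel_hemisphere(scheme)
    side <- names(which.max(table(hemi[vol == 1L])))
  }
  structure(list(volume = vol, patient_id = patient_id, side = side),
            class = "lesion_mask")
}

#' @rdname read_mask
#' @param mask a \code{lesion_mask}.
#' @param voxel_size_mm voxel edge lengths written to the header.
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(2, 2, 2)) {
  vol <- mask$volume
  attr(vol, "pixdim") <- voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname read_mask
#' @param volume a numeric 3-D array.
#' @export
write_map <- function(volume, path, voxel_size_mm = c(2, 2, 2)) {
  attr(volume, "pixdim") <- voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(volume, datatype = "double"), path)
  invisible(path)
}

#' Per-parcel damage fractions
#'
#' For each parcel, the fraction of its voxels covered by the lesion:
#' |lesion intersect parcel| / |parcel|. Summing fraction times parcel size
#' over parcels recovers the lesion voxel count exactly.
#'
#' @param mask a \code{lesion_mask} on the scheme grid.
#' @param scheme a \code{parcel_scheme}.
#' @return numeric vector over parcels, entries in [0, 1].
#' @export
damage_fractions <- function(mask, scheme) {
  if (!identical(dim(mask$volume), dim(scheme$labels)))
    stop("alignment error: mask and scheme grids differ")
  n_parcels <- nrow(scheme$parcels)
  if (any(scheme$parcels$n_vox == 0L))
    stop("scheme invariant violation: empty parcel")
  hit <- tabulate(scheme$labels[mask$volume == 1L], n_parcels)
  hit / scheme$parcels$n_vox
}

#' Patient-by-parcel damage matrix
#'
#' Stacks \code{\link{damage_fractions}} over a list of masks into the
#' patients x parcels matrix that bridges images and graphs. Row order
#' follows the list; columns follow the scheme's parcel ids.
#'
#' @param masks list of \code{lesion_mask}.
#' @param scheme a \code{parcel_scheme}.
#' @return numeric matrix with patient ids as rownames.
#' @export
damage_matrix <- function(masks, scheme) {
  m <- t(vapply(masks, damage_fractions, numeric(nrow(scheme$parcels)),
                scheme = scheme))
  rownames(m) <- vapply(masks, function(x) as.character(x$patient_id),
                        character(1))
  colnames(m) <- scheme$parcels$parcel_id
  m
}

#' Frontal/posterior and laterality group assignment
#'
#' Classifies a patient by where the lesion volume falls: the lobe group is
#' \code{frontal} (\code{posterior}) when at least \code{threshold} of the
#' lesioned voxels lie in frontal (posterior) parcels, and \code{excluded}
#' otherwise; the side is the hemisphere holding the majority of lesioned
#' voxels. Lobe shares are computed over lesioned voxels (fraction times
#' parcel size), not over parcel fractions, so the rule follows lesion
#' volume.
#'
#' @param fractions per-parcel damage fractions (from
#'   \code{\link{damage_fractions}}).
#' @param scheme a \code{parcel_scheme}.
#' @param threshold lesion-volume share required, default 0.70; the rule
#'   is \code{>=}.
#' @return list with \code{lobe_group} ("frontal", "posterior" or
#'   "excluded"), \code{side}, and the frontal lesion-volume \code{share}.
#' @export
classify_patient <- function(fractions, scheme, threshold = 0.70) {
  vox <- fractions * scheme$parcels$n_vox
  total <- sum(vox)
  if (total == 0) stop("empty-lesion error: no damaged voxels")
  frontal_share <- sum(vox[scheme$parcels$lobe == "frontal"]) / total
  lobe_group <- if (frontal_share >= threshold) "frontal"
    else if (1 - frontal_share >= threshold) "posterior"
    else "excluded"
  right_share <- sum(vox[scheme$parcels$hemisphere == "right"]) / total
  list(lobe_group = lobe_group,
       side = if (right_share > 0.5) "right" else "left",
       share = frontal_share)
}

#' Binarize a damage matrix
#'
#' Entry is 1 when the damage fraction is \code{>= tau}. The default 0.1
#' ("substantive damage": at least a tenth of the parcel's voxels lesioned)
#' keeps per-patient damaged-parcel counts high enough that co-occurrence
#' supports carry real information; a majority criterion (tau = 0.5) leaves
#' focal lesions touching almost no parcel and starves the graph.
#'
#' @param matrix patients x parcels damage-fraction matrix.
#' @param tau threshold in (0, 1].
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize_damage <- function(matrix, tau = 0.1) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  out <- (matrix >= tau) + 0L
  dimnames(out) <- dimnames(matrix)
  out
}
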