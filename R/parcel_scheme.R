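#' Synthetic parcellation schemes
#'
#' A parcel scheme is a 3-D integer label volume (0 = background, here absent:
#' every voxel belongs to a parcel) together with per-parcel hemisphere and
#' lobe metadata. The first array axis is sagittal: the grid is split at its
#' midplane into left and right hemispheres, and no parcel straddles the
#' midplane. Within each hemisphere parcels are grown from random seed voxels
#' by balanced multi-source face-connected region growing, so every parcel is
#' a non-empty, face-connected, disjoint voxel set and the parcels tile the
#' grid. The anterior half of each hemisphere's parcels (ranked by centroid
#' position along the second axis) is labelled \code{frontal}, the rest
#' \code{posterior}.
#'
#' @param grid_shape integer triple; the sagittal (first) extent must be even.
#' @param n_parcels even integer >= 4, at most the number of voxels.
#' @param seed integer seed; the scheme is deterministic given
#'   \code{grid_shape}, \code{n_parcels} and \code{seed}.
#' @param voxel_size_mm positive real triple, voxel edge lengths.
#' @return An object of class \code{parcel_scheme}: a list with
#'   \code{labels} (3-D integer array), \code{parcels} (data frame with
#'   \code{parcel_id}, \code{hemisphere}, \code{lobe}, \code{n_vox}),
#'   \code{voxel_size_mm} and \code{seed}.
#' @examples
#' sch <- make_parcel_scheme(c(8, 8, 8), n_parcels = 8, seed = 1)
#' table(sch$parcels$hemisphere)
#' @export
make_parcel_scheme <- function(grid_shape = c(16L, 16L, 16L), n_parcels = 64L,
                               seed = 1L, voxel_size_mm = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  n_parcels <- as.integer(n_parcels)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be a positive integer triple")
  if (grid_shape[1L] %% 2L != 0L)
    stop("sagittal (first) extent must be even so the midplane splits voxels cleanly")
  if (n_parcels < 4L || n_parcels %% 2L != 0L)
    stop("n_parcels must be an even integer >= 4")
  n_vox <- prod(grid_shape)
  if (n_parcels > n_vox)
    stop("sizing error: ", n_parcels, " parcels cannot tile ", n_vox, " voxels")
  per_hemi <- n_parcels %/% 2L
  hemi_vox <- n_vox %/% 2L
  if (per_hemi > hemi_vox)
    stop("sizing error: ", per_hemi, " parcels per hemisphere exceed ",
         hemi_vox, " voxels")
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")

  set.seed(seed)
  labels <- array(0L, dim = grid_shape)
  coords <- arrayInd(seq_len(n_vox), grid_shape)
  half <- grid_shape[1L] %/% 2L
  hemi_of_voxel <- ifelse(coords[, 1L] <= half, "left", "right")

  offset <- 0L
  for (h in c("left", "right")) {
    vox <- which(hemi_of_voxel == h)
    labs <- .grow_parcels(vox, per_hemi, grid_shape, hemi_of_voxel, h)
    labels[vox] <- labs + offset
    offset <- offset + per_hemi
  }

  ids <- seq_len(n_parcels)
  hemisphere <- ifelse(ids <= per_hemi, "left", "right")
  # anterior = low coordinate on the second axis; exactly half of each
  # hemisphere's parcels become frontal, ranked by centroid
  cy <- vapply(ids, function(p) mean(coords[labels == p, 2L]), numeric(1))
  lobe <- character(n_parcels)
  for (h in c("left", "right")) {
    idx <- which(hemisphere == h)
    rk <- rank(cy[idx], ties.method = "first")
    lobe[idx] <- ifelse(rk <= length(idx) / 2, "frontal", "posterior")
  }
  n_parc_vox <- tabulate(labels, n_parcels)

  structure(list(
    labels = labels,
    parcels = data.frame(parcel_id = ids, hemisphere = hemisphere,
                         lobe = lobe, n_vox = n_parc_vox,
                         stringsAsFactors = FALSE),
    voxel_size_mm = as.numeric(voxel_size_mm),
    seed = seed
  ), class = "parcel_scheme")
}

# balanced multi-source region growing over the voxel linear indices `vox`
# (all in one hemisphere); returns parcel label 1..k per element of vox
.grow_parcels <- function(vox, k, dim, hemi_of_voxel, hemi) {
  lab <- integer(prod(dim))         # 0 = unassigned, indexed by linear voxel
  inside <- logical(prod(dim))
  inside[vox] <- TRUE
  seeds <- sample(vox, k)
  lab[seeds] <- seq_len(k)
  frontier <- as.list(seeds)
  n_left <- length(vox) - k
  while (n_left > 0L) {
    grew <- FALSE
    for (r in seq_len(k)) {
      fr <- frontier[[r]]
      if (length(fr) == 0L) next
      nb <- .face_neighbours(fr, dim)
      nb <- nb[inside[nb] & lab[nb] == 0L]
      if (length(nb) == 0L) { frontier[[r]] <- integer(0); next }
      nb <- unique(nb)
      lab[nb] <- r
      n_left <- n_left - length(nb)
      frontier[[r]] <- nb
      grew <- TRUE
    }
    if (!grew && n_left > 0L)
      stop("internal error: region growing stalled")  # hemisphere is connected
  }
  lab[vox]
}

# face (6-)neighbours of linear indices, staying inside the grid
.face_neighbours <- function(idx, dim) {
  ai <- arrayInd(idx, dim)
  out <- vector("list", 6L)
  j <- 0L
  for (ax in 1:3) for (d in c(-1L, 1L)) {
    j <- j + 1L
    nb <- ai
    nb[, ax] <- nb[, ax] + d
    ok <- nb[, ax] >= 1L & nb[, ax] <= dim[ax]
    out[[j]] <- (nb[ok, 1L] - 1L) + dim[1L] * ((nb[ok, 2L] - 1L) +
                  dim[2L] * (nb[ok, 3L] - 1L)) + 1L
  }
  unlist(out, use.names = FALSE)
}

#' @export
print.parcel_scheme <- function(x, ...) {
  cat("Parcel scheme:", nrow(x$parcels), "parcels on a",
      paste(dim(x$labels), collapse = "x"), "grid\n")
  print(table(hemisphere = x$parcels$hemisphere, lobe = x$parcels$lobe))
  invisible(x)
}

#' Hemisphere membership of each voxel
#'
#' @param scheme a \code{parcel_scheme}.
#' @return character vector over linear voxel indices, "left" or "right".
#' @keywords internal
voxel_hemisphere <- function(scheme) {
  dims <- dim(scheme$labels)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  ifelse(coords[, 1L] <= dims[1L] %/% 2L, "left", "right")
}

#' Write / read a parcel scheme as NIfTI plus a metadata table
#'
#' The label volume is written as an integer NIfTI image and the per-parcel
#' metadata (id, hemisphere, lobe, voxel count) as a tab-separated side-car.
#'
#' @param scheme a \code{parcel_scheme}.
#' @param path path to the NIfTI file; the metadata table is written next to
#'   it with extension \code{.tsv}.
#' @return \code{write_parcel_scheme} returns \code{path} invisibly;
#'   \code{read_parcel_scheme} returns a \code{parcel_scheme}.
#' @export
write_parcel_scheme <- function(scheme, path) {
  vol <- scheme$labels
  attr(vol, "pixdim") <- scheme$voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "int16"), path)
  utils::write.table(scheme$parcels, .sidecar_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcel_scheme
#' @export
read_parcel_scheme <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- utils::read.delim(.sidecar_path(path), stringsAsFactors = FALSE)
  labels <- array(as.integer(img), dim = dim(img))
  structure(list(labels = labels, parcels = meta,
                 voxel_size_mm = RNifti::pixdim(img)[1:3], seed = NA_integer_),
            class = "parcel_scheme")
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".tsv", path)
}
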