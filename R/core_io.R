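#' Acquisition protocol for a multi-echo dynamic gradient-echo series
#'
#' Defaults mirror the low-field (0.55T) fetal-body protocol this package
#' targets: three echoes at 46/120/194 ms, 3.125 mm in-plane resolution,
#' 3 mm slices, and a whole-uterus dynamic (time-resolved) acquisition.
#'
#' @param echo_times echo times in ms, strictly increasing, length >= 2
#' @param repetition_time repetition time in ms
#' @param in_plane_resolution in-plane voxel size in mm
#' @param slice_thickness slice thickness in mm
#' @param n_slices number of slices per stack (NULL = determined by the data)
#' @param n_dynamics number of dynamics
#' @param flip_angle flip angle in degrees
#' @param field_of_view field of view in mm
#' @return an object of class `acquisition_protocol`
#' @export
acquisition_protocol <- function(echo_times = c(46, 120, 194),
                                 repetition_time = 12000,
                                 in_plane_resolution = 3.125,
                                 slice_thickness = 3,
                                 n_slices = NULL,
                                 n_dynamics = 20,
                                 flip_angle = 90,
                                 field_of_view = 400) {
  if (length(echo_times) < 2 || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0))
    stop("protocol error: echo_times must be strictly increasing and > 0, length >= 2")
  stopifnot(in_plane_resolution > 0, slice_thickness > 0, n_dynamics >= 1)
  structure(list(echo_times = as.numeric(echo_times),
                 repetition_time = repetition_time,
                 in_plane_resolution = in_plane_resolution,
                 slice_thickness = slice_thickness,
                 n_slices = n_slices,
                 n_dynamics = as.integer(n_dynamics),
                 flip_angle = flip_angle,
                 field_of_view = field_of_view),
            class = "acquisition_protocol")
}

#' A 3D scalar volume with world geometry
#'
#' @param values 3D numeric array
#' @param affine 4x4 voxel-to-world matrix (mm, RAS+, 0-based voxel indices)
#' @param mask optional 3D logical array of the same shape
#' @return an object of class `voxel_volume`
#' @export
voxel_volume <- function(values, affine = diag(4), mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("geometry error: affine must be an invertible 4x4 matrix")
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(values)))
      stop("geometry error: mask shape differs from values")
    mask <- array(as.logical(mask), dim(values))
  }
  structure(list(values = values, affine = affine, mask = mask),
            class = "voxel_volume")
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume: %s voxels, spacing [%s] mm%s\n",
              paste(dim(x$values), collapse = " x "),
              paste(sprintf("%.3g", voxel_spacing(x$affine)), collapse = ", "),
              if (is.null(x$mask)) "" else ", with mask"))
  invisible(x)
}

# Effective mask: stored mask, or all finite voxels.
volume_mask <- function(vol) {
  if (!is.null(vol$mask)) vol$mask else is.finite(vol$values)
}

#' Integer organ label map
#'
#' Background is 0; the default dictionary covers the ten fetal body organs
#' this package quantifies.
#'
#' @param labels 3D integer array
#' @param affine 4x4 voxel-to-world matrix
#' @param dictionary named integer vector mapping organ name -> label id
#' @return an object of class `label_map`
#' @export
label_map <- function(labels, affine = diag(4), dictionary = organ_labels()) {
  labels <- array(as.integer(labels), dim(as.array(labels)))
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  structure(list(labels = labels, affine = as.matrix(affine),
                 dictionary = dictionary),
            class = "label_map")
}

#' Canonical organ label dictionary
#'
#' The ten fetal body organs quantified by the pipeline.
#' @return named integer vector (organ name -> label id)
#' @export
organ_labels <- function() {
  c(lungs = 1L, thymus = 2L, gall_bladder = 3L, kidney_pelvis = 4L,
    kidney_parenchyma = 5L, spleen = 6L, adrenal_gland = 7L,
    stomach = 8L, bladder = 9L, liver = 10L)
}

#' Multi-echo dynamic series
#'
#' @param stacks list (by dynamic) of lists (by echo) of `voxel_volume`,
#'   all sharing one affine and shape
#' @param protocol an `acquisition_protocol` whose echo count matches
#' @param included integer vector of included dynamic indices
#' @return an object of class `multi_echo_series`
#' @export
multi_echo_series <- function(stacks, protocol,
                              included = seq_along(stacks)) {
  stopifnot(length(stacks) >= 1)
  ne <- length(stacks[[1]])
  if (ne != length(protocol$echo_times))
    stop(sprintf("protocol error: %d echoes in data but %d echo times",
                 ne, length(protocol$echo_times)))
  ref <- stacks[[1]][[1]]
  for (d in seq_along(stacks)) {
    if (length(stacks[[d]]) != ne)
      stop("geometry error: unequal echo counts across dynamics")
    for (e in seq_len(ne)) {
      v <- stacks[[d]][[e]]
      if (!all(dim(v$values) == dim(ref$values)) ||
          !affines_equal(v$affine, ref$affine))
        stop(sprintf("geometry error: stack (dynamic %d, echo %d) disagrees with the first stack", d, e))
    }
  }
  included <- sort(unique(as.integer(included)))
  if (length(included) == 0 || any(included < 1) ||
      any(included > length(stacks)))
    stop("included_dynamics must be a non-empty subset of available dynamics")
  structure(list(stacks = stacks, protocol = protocol, included = included),
            class = "multi_echo_series")
}

#' @export
print.multi_echo_series <- function(x, ...) {
  cat(sprintf("multi_echo_series: %d dynamics (%d included) x %d echoes, %s voxels\n",
              n_dynamics(x), length(x$included), n_echoes(x),
              paste(dim(x$stacks[[1]][[1]]$values), collapse = " x ")))
  invisible(x)
}

#' Number of dynamics in a series
#' @param series a `multi_echo_series`
#' @return integer count
#' @export
n_dynamics <- function(series) length(series$stacks)

#' Number of echoes in a series
#' @param series a `multi_echo_series`
#' @return integer count
#' @export
n_echoes <- function(series) length(series$stacks[[1]])

#' Extract one stack from a series
#' @param series a `multi_echo_series`
#' @param dynamic dynamic index
#' @param echo echo index
#' @return a `voxel_volume`
#' @export
get_stack <- function(series, dynamic, echo) series$stacks[[dynamic]][[echo]]

#' Read a 3D volume from a NIfTI file
#' @param path NIfTI file (.nii or .nii.gz)
#' @return a `voxel_volume`; a companion `<stem>_mask` file, if present,
#'   is loaded as the mask
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: file not found: %s", path))
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3) stop(sprintf("%s is not a 3D NIfTI", path))
  aff <- read_xform(img)
  mask <- NULL
  mpath <- companion_mask_path(path)
  if (file.exists(mpath))
    mask <- as.array(RNifti::readNifti(mpath)) > 0.5
  voxel_volume(vals, aff, mask)
}

companion_mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' Write a volume as NIfTI-1
#'
#' Values and affine survive a round trip (values exactly, the affine at
#' NIfTI's float32 header precision). A mask, if present, is written as a
#' companion `<stem>_mask` NIfTI.
#'
#' @param vol a `voxel_volume`
#' @param path output path (.nii or .nii.gz); parent directory must exist
#' @return the path, invisibly
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("I/O error: directory does not exist: %s", dirname(path)))
  write_nifti_array(vol$values, vol$affine, path)
  if (!is.null(vol$mask))
    write_nifti_array(vol$mask * 1L, vol$affine, companion_mask_path(path))
  invisible(path)
}

# Write an array with an explicit voxel-to-world affine. The geometry is
# carried in the sform (code 2); the qform is left unset because NIfTI-1
# quaternions cannot represent shears and RNifti pins their pixdim.
write_nifti_array <- function(arr, affine, path, datatype = "double") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  img <- RNifti::`qform<-`(img, structure(diag(4), code = 0L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_xform <- function(img) {
  matrix(RNifti::xform(img, useQuaternionFirst = FALSE), 4, 4)
}

#' Read a multi-echo dynamic series from NIfTI files
#'
#' Two layouts are accepted: one 4D file per echo (dynamics stacked on the
#' 4th axis, `paths` ordered by echo), or a single 5D file
#' (x, y, z, dynamic, echo). 3D files are treated as single-dynamic stacks.
#'
#' @param paths character vector of NIfTI paths
#' @param echo_times echo times in ms, one per echo
#' @param protocol optional `acquisition_protocol`; defaults are derived from
#'   `echo_times` and the data geometry
#' @return a `multi_echo_series` with all dynamics included
#' @export
read_series <- function(paths, echo_times, protocol = NULL) {
  for (p in paths)
    if (!file.exists(p)) stop(sprintf("I/O error: file not found: %s", p))
  imgs <- lapply(paths, RNifti::readNifti)
  affs <- lapply(imgs, read_xform)
  dims <- lapply(imgs, function(i) dim(as.array(i)))
  for (k in seq_along(imgs)) {
    if (!affines_equal(affs[[k]], affs[[1]]) ||
        !all(dims[[k]][1:3] == dims[[1]][1:3]))
      stop(sprintf("geometry error: %s disagrees with %s", paths[k], paths[1]))
  }
  aff <- affs[[1]]
  arrs <- lapply(imgs, as.array)
  nd <- length(dims[[1]])
  if (length(paths) == 1 && nd == 5) {
    a <- arrs[[1]]
    n_dyn <- dim(a)[4]; n_echo <- dim(a)[5]
    if (n_echo != length(echo_times))
      stop(sprintf("protocol error: file has %d echoes but %d echo times given",
                   n_echo, length(echo_times)))
    stacks <- lapply(seq_len(n_dyn), function(d)
      lapply(seq_len(n_echo), function(e)
        voxel_volume(a[, , , d, e], aff)))
  } else {
    if (length(paths) != length(echo_times))
      stop(sprintf("protocol error: %d files but %d echo times",
                   length(paths), length(echo_times)))
    ndyn <- vapply(arrs, function(a)
      if (length(dim(a)) == 3) 1L else dim(a)[4], integer(1))
    if (length(unique(ndyn)) != 1)
      stop(sprintf("geometry error: %s has a different dynamic count",
                   paths[which(ndyn != ndyn[1])[1]]))
    stacks <- lapply(seq_len(ndyn[1]), function(d)
      lapply(seq_along(arrs), function(e) {
        a <- arrs[[e]]
        v <- if (length(dim(a)) == 3) a else a[, , , d]
        voxel_volume(array(v, dims[[1]][1:3]), aff)
      }))
  }
  proto <- protocol %||% acquisition_protocol(
    echo_times = echo_times,
    in_plane_resolution = mean(voxel_spacing(aff)[1:2]),
    slice_thickness = voxel_spacing(aff)[3],
    n_slices = dims[[1]][3],
    n_dynamics = length(stacks))
  multi_echo_series(stacks, proto)
}

#' Write a series as one 4D NIfTI per echo
#' @param series a `multi_echo_series`
#' @param dir output directory
#' @param prefix file name prefix
#' @return character vector of written paths
#' @export
write_series <- function(series, dir, prefix = "series") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aff <- series$stacks[[1]][[1]]$affine
  d3 <- dim(series$stacks[[1]][[1]]$values)
  paths <- character(n_echoes(series))
  for (e in seq_len(n_echoes(series))) {
    a <- array(0, c(d3, n_dynamics(series)))
    for (d in seq_len(n_dynamics(series)))
      a[, , , d] <- series$stacks[[d]][[e]]$values
    paths[e] <- file.path(dir, sprintf("%s_echo%d.nii.gz", prefix, e))
    write_nifti_array(a, aff, paths[e])
  }
  paths
}

#' Automated motion quality control of a dynamic series
#'
#' Scores each dynamic by normalized cross-correlation (NCC) of its
#' first-echo stack against the voxelwise median stack, and excludes
#' dynamics scoring below `threshold`. This is a documented automated
#' surrogate for a manual review of motion-corrupted dynamics. The
#' best-scoring dynamic is always retained.
#'
#' @param series a `multi_echo_series` (>= 2 dynamics for scoring)
#' @param threshold NCC threshold below which a dynamic is excluded
#' @return sorted integer vector of included dynamic indices, with
#'   attributes `scores` (per-dynamic NCC) and, for a single-dynamic
#'   series, `warning = TRUE`
#' @export
motion_qc <- function(series, threshold = 0.8) {
  nd <- n_dynamics(series)
  if (nd < 2) {
    warning("motion_qc: single dynamic, returned unchanged")
    return(structure(seq_len(nd), scores = rep(NA_real_, nd), warning = TRUE))
  }
  arrs <- vapply(seq_len(nd),
                 function(d) series$stacks[[d]][[1]]$values,
                 series$stacks[[1]][[1]]$values)
  med <- apply(arrs, 1:3, stats::median)
  scores <- vapply(seq_len(nd),
                   function(d) ncc(arrs[, , , d], med), numeric(1))
  sc <- ifelse(is.finite(scores), scores, -Inf)
  keep <- which(sc >= threshold)
  if (length(keep) == 0) keep <- which.max(sc)
  structure(sort(keep), scores = scores)
}

#' Restrict a series to a set of included dynamics
#' @param series a `multi_echo_series`
#' @param included integer vector of dynamic indices to include
#' @return the series with its inclusion set replaced
#' @export
set_included <- function(series, included) {
  multi_echo_series(series$stacks, series$protocol, included)
}
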