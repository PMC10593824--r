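#' Read and write CEST volumes, masks and metric maps (NIfTI)
#'
#' Volumes are stored as standard NIfTI files with the voxel size carried in
#' the header; the offset schedule and scan provenance, which NIfTI cannot
#' hold, travel in a JSON sidecar written next to the volume
#' (\code{<path>.json}). \code{writeCestVolume} followed by
#' \code{readCestVolume} is lossless on data, schedule and geometry.
#'
#' @param x a [RawCestVolume-class].
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{readCestVolume}: a [RawCestVolume-class];
#'   \code{writeCestVolume}: the path, invisibly.
#' @name cest-io
NULL

sidecarPath <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' @rdname cest-io
#' @export
writeCestVolume <- function(x, path) {
  stopifnot(is(x, "RawCestVolume"))
  img <- RNifti::asNifti(x@data, pixdim = c(x@voxelSize, 1))
  RNifti::writeNifti(img, path)
  sc <- x@schedule
  jsonlite::write_json(
    list(offsets = sc@offsets,
         referenceOffset = sc@referenceOffset,
         nReferenceImages = sc@nReferenceImages,
         referenceSelection = sc@referenceSelection,
         voxelSize = x@voxelSize,
         provenance = x@provenance),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cest-io
#' @export
readCestVolume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  sched <- buildOffsetSchedule(offsets = meta$offsets,
                               referenceOffset = meta$referenceOffset,
                               nReferenceImages = meta$nReferenceImages,
                               referenceSelection = meta$referenceSelection)
  prov <- as.list(meta$provenance)
  new("RawCestVolume", data = unclass(img)[, , , , drop = FALSE],
      schedule = sched, voxelSize = as.numeric(meta$voxelSize),
      provenance = prov)
}

#' Read a binary ROI mask on the CEST grid
#'
#' @param path NIfTI file of zeros/ones.
#' @param grid expected integer(3) grid dimensions; a mismatch is an error
#'   naming both shapes.
#' @return logical 3D array.
#' @export
readMask <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  m <- unclass(img) != 0
  if (length(dim(m)) == 4L && dim(m)[4L] == 1L) m <- m[, , , 1L]
  if (!is.null(grid) && !identical(dim(m), as.integer(grid)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dim(m), collapse = "x"),
                 paste(grid, collapse = "x")))
  m
}

#' Write a mask as NIfTI
#' @param mask logical 3D array.
#' @param path output path.
#' @param voxelSize numeric(3), mm.
#' @export
writeMask <- function(mask, path, voxelSize = c(1.7, 1.7, 3)) {
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dim(mask)),
                                     pixdim = voxelSize), path)
  invisible(path)
}

#' Write APT metric maps as NIfTI volumes
#'
#' Writes \code{<prefix>_ld_apt.nii.gz}, \code{<prefix>_mtrasym_apt.nii.gz}
#' and \code{<prefix>_mtrrex_apt.nii.gz} (percent units; invalid voxels are
#' NA) plus a JSON sidecar with the target offset.
#'
#' @param maps a [MetricMaps-class].
#' @param prefix output path prefix.
#' @param voxelSize numeric(3), mm.
#' @return character vector of the three paths, invisibly.
#' @export
writeMetricMaps <- function(maps, prefix, voxelSize = c(1.7, 1.7, 3)) {
  stopifnot(is(maps, "MetricMaps"))
  paths <- paste0(prefix, "_", c("ld", "mtrasym", "mtrrex"), "_apt.nii.gz")
  arrs <- list(maps@ldApt, maps@mtrAsymApt, maps@mtrRexApt)
  for (i in 1:3) {
    a <- arrs[[i]]
    a[!maps@valid] <- NA_real_
    RNifti::writeNifti(RNifti::asNifti(a, pixdim = voxelSize), paths[i])
  }
  jsonlite::write_json(list(targetOffset = maps@targetOffset, units = "percent"),
                       paste0(prefix, "_apt.json"), auto_unbox = TRUE)
  invisible(paths)
}

#' Write a synthetic dataset to disk
#'
#' One NIfTI volume + sidecar per scan, one NIfTI mask per tissue, the scan
#' manifest and realized ground truth as TSV, and the configuration echo
#' (with seed) as JSON.
#'
#' @param dataset a [CestDataset-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "CestDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset@scans))
    writeCestVolume(dataset@scans[[id]], file.path(dir, paste0(id, ".nii.gz")))
  for (t in names(dataset@masks))
    writeMask(dataset@masks[[t]], file.path(dir, paste0("mask_", t, ".nii.gz")))
  utils::write.table(dataset@manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset@truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  RNifti::writeNifti(RNifti::asNifti(dataset@b0Field),
                     file.path(dir, "b0_field.nii.gz"))
  cfg <- dataset@config
  cfg$tissues <- lapply(cfg$tissues, unclass)
  cfg$schedule <- list(offsets = cfg$schedule@offsets,
                       referenceOffset = cfg$schedule@referenceOffset,
                       nReferenceImages = cfg$schedule@nReferenceImages,
                       referenceSelection = cfg$schedule@referenceSelection)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
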