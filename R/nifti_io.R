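#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file and returns a [scalar_volume()] with the grid
#' geometry (spacing, origin, orientation) taken from the sform/qform.
#' The NIfTI affine maps 0-based voxel indices to world mm, which matches
#' the package's voxel-centre convention directly.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind Passed to [scalar_volume()] (`"image"` or `"dose"`).
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path, kind = "image") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume, got ", length(dim(img)), "-D: ", path)
  vals <- array(as.numeric(img), dim(img))  # strip image attributes
  scalar_volume(vals, grid_from_xform(img), kind = kind)
}

grid_from_xform <- function(img) {
  xf <- RNifti::xform(img)
  A <- unclass(xf)[1:3, 1:3]
  origin <- unclass(xf)[1:3, 4]
  spacing <- sqrt(colSums(A^2))
  grid_spec(dim(img), spacing, origin, sweep(A, 2, spacing, "/"))
}

nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  A <- grid$direction %*% diag(grid$spacing)
  sf <- rbind(cbind(A, grid$origin), c(0, 0, 0, 1))
  RNifti::`sform<-`(img, structure(sf, code = 2L))
}

#' Write a 3-D volume as NIfTI
#'
#' @param vol A `scalar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  RNifti::writeNifti(nifti_with_grid(vol$values, vol$grid), path,
                     datatype = "double")
  invisible(path)
}

#' Read a structure mask from NIfTI
#'
#' Nonzero voxels become TRUE.
#'
#' @param path Path to a NIfTI file.
#' @param label Structure label to attach.
#' @return A `structure_mask`.
#' @export
read_structure_mask <- function(path, label) {
  vol <- read_volume(path)
  structure_mask(vol$values != 0, vol$grid, label)
}

#' Write a structure mask as NIfTI (uint8, 0/1)
#'
#' @param mask A `structure_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_mask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  vals <- array(as.integer(mask$values), dim(mask$values))
  RNifti::writeNifti(nifti_with_grid(vals, mask$grid), path,
                     datatype = "uint8")
  invisible(path)
}

#' Write a displacement field as three scalar NIfTI volumes
#'
#' The field is stored as `<prefix>_dx.nii.gz`, `<prefix>_dy.nii.gz`,
#' `<prefix>_dz.nii.gz`, displacement in mm, world coordinates.
#'
#' @param dvf A `vector_field`.
#' @param prefix Path prefix (without suffix).
#' @return The three paths, invisibly.
#' @export
write_vector_field <- function(dvf, prefix) {
  sfx <- c("_dx.nii.gz", "_dy.nii.gz", "_dz.nii.gz")
  paths <- paste0(prefix, sfx)
  for (a in 1:3)
    write_volume(scalar_volume(dvf$values[, , , a], dvf$grid), paths[a])
  invisible(paths)
}

#' Read a displacement field stored as three scalar NIfTI volumes
#'
#' @param prefix Path prefix used by [write_vector_field()].
#' @return A `vector_field`.
#' @export
read_vector_field <- function(prefix) {
  sfx <- c("_dx.nii.gz", "_dy.nii.gz", "_dz.nii.gz")
  comps <- lapply(paste0(prefix, sfx), read_volume)
  grid <- comps[[1]]$grid
  vals <- array(0, c(grid$shape, 3))
  for (a in 1:3) vals[, , , a] <- comps[[a]]$values
  vector_field(vals, grid)
}

#' Write a patient case to a directory in the on-disk case layout
#'
#' Creates `ref/` with the reference image, structures and total dose, and
#' `fx_01/` ... `fx_NN/` with each fraction's image, structures,
#' ground-truth displacement field (if present) and the two arms' fraction
#' doses, plus a `manifest.json` listing every file and its role.
#'
#' @param case A `patient_case` (see [generate_reference_case()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_fractions = length(case$fractions), structures = list())
  refdir <- file.path(dir, "ref")
  dir.create(refdir, showWarnings = FALSE)
  write_volume(case$ref_image, file.path(refdir, "image.nii.gz"))
  write_volume(case$ref_dose, file.path(refdir, "dose.nii.gz"))
  for (lab in names(case$ref_structures))
    write_structure_mask(case$ref_structures[[lab]],
                         file.path(refdir, paste0("mask_", lab, ".nii.gz")))
  manifest$ref <- list(image = "ref/image.nii.gz", dose = "ref/dose.nii.gz",
                       masks = as.list(stats::setNames(
                         paste0("ref/mask_", names(case$ref_structures),
                                ".nii.gz"),
                         names(case$ref_structures))))
  manifest$fractions <- list()
  for (fx in case$fractions) {
    fdir <- file.path(dir, sprintf("fx_%02d", fx$index))
    dir.create(fdir, showWarnings = FALSE)
    write_volume(fx$image, file.path(fdir, "image.nii.gz"))
    for (lab in names(fx$structures))
      write_structure_mask(fx$structures[[lab]],
                           file.path(fdir, paste0("mask_", lab, ".nii.gz")))
    ent <- list(image = file.path(basename(fdir), "image.nii.gz"),
                applied_shift = fx$applied_shift)
    if (!is.null(fx$gt_dvf_ref_to_fx)) {
      write_vector_field(fx$gt_dvf_ref_to_fx, file.path(fdir, "gt_dvf"))
      ent$gt_dvf <- file.path(basename(fdir), "gt_dvf")
    }
    if (!is.null(fx$dose_oa)) {
      write_volume(fx$dose_oa, file.path(fdir, "dose_oa.nii.gz"))
      write_volume(fx$dose_conv, file.path(fdir, "dose_conv.nii.gz"))
      ent$dose_oa <- file.path(basename(fdir), "dose_oa.nii.gz")
      ent$dose_conv <- file.path(basename(fdir), "dose_conv.nii.gz")
    }
    manifest$fractions[[sprintf("fx_%02d", fx$index)]] <- ent
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a patient case from the on-disk case layout
#'
#' @param dir Directory written by [write_patient_case()].
#' @return A `patient_case`.
#' @export
read_patient_case <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  read_masks <- function(sub) {
    paths <- list.files(file.path(dir, sub), pattern = "^mask_.*\\.nii\\.gz$",
                        full.names = TRUE)
    labs <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", basename(paths))
    stats::setNames(Map(read_structure_mask, paths, labs), labs)
  }
  fractions <- lapply(sort(names(mf$fractions)), function(nm) {
    ent <- mf$fractions[[nm]]
    fdir <- file.path(dir, nm)
    fx <- list(index = as.integer(sub("fx_", "", nm)),
               image = read_volume(file.path(fdir, "image.nii.gz")),
               structures = read_masks(nm),
               applied_shift = as.numeric(ent$applied_shift))
    if (!is.null(ent$gt_dvf))
      fx$gt_dvf_ref_to_fx <- read_vector_field(file.path(dir, ent$gt_dvf))
    if (!is.null(ent$dose_oa)) {
      fx$dose_oa <- read_volume(file.path(dir, ent$dose_oa), kind = "dose")
      fx$dose_conv <- read_volume(file.path(dir, ent$dose_conv),
                                  kind = "dose")
    }
    class(fx) <- "fraction_record"
    fx
  })
  structure(list(ref_image = read_volume(file.path(dir, "ref/image.nii.gz")),
                 ref_structures = read_masks("ref"),
                 ref_dose = read_volume(file.path(dir, "ref/dose.nii.gz"),
                                        kind = "dose"),
                 fractions = fractions),
            class = "patient_case")
}
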