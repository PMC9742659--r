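# NIfTI + JSON-sidecar I/O for paired studies.

#' Write a paired study as NIfTI files with a JSON sidecar
#'
#' Writes `<stem>_nac.nii.gz` and `<stem>_asc.nii.gz` (single-slice volumes
#' whose affine encodes the in-plane pixel size and slice thickness) plus
#' `<stem>.json` carrying the SUV metadata, centre id and seed.
#'
#' @param study a `paired_study`.
#' @param stem output path stem (directories are created).
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  sp <- study$grid$spacing
  as_vol <- function(img) {
    v <- array(img, c(dim(img), 1L))
    RNifti::asNifti(v, reference = NULL)
  }
  paths <- c(nac = paste0(stem, "_nac.nii.gz"),
             asc = paste0(stem, "_asc.nii.gz"),
             json = paste0(stem, ".json"))
  for (role in c("nac", "asc")) {
    img <- if (role == "nac") study$nac_image else study$asc_image
    vol <- as_vol(img)
    RNifti::pixdim(vol) <- sp[1:3]
    RNifti::writeNifti(vol, paths[[role]])
  }
  meta <- list(injected_activity_MBq = study$injected_activity_MBq,
               body_weight_kg = study$body_weight_kg,
               center_id = study$center_id, seed = study$seed,
               study_id = study$study_id %||% NA_character_,
               spacing_mm = sp)
  jsonlite::write_json(meta, paths[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a paired study written by [write_study()]
#'
#' @param stem path stem used when writing.
#' @return a `paired_study` (without simulator components).
#' @export
read_study <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  rd <- function(p) {
    v <- RNifti::readNifti(p)
    # single-slice volumes may come back 2D
    if (length(dim(v)) == 2) matrix(as.numeric(v), dim(v)[1], dim(v)[2])
    else matrix(v[, , 1], dim(v)[1], dim(v)[2])
  }
  nac <- rd(paste0(stem, "_nac.nii.gz"))
  asc <- rd(paste0(stem, "_asc.nii.gz"))
  structure(list(
    nac_image = nac, asc_image = asc,
    injected_activity_MBq = meta$injected_activity_MBq,
    body_weight_kg = meta$body_weight_kg,
    grid = grid_spec(spacing = meta$spacing_mm,
                     size = c(dim(nac), 1L)),
    center_id = meta$center_id, seed = meta$seed,
    study_id = meta$study_id),
    class = "paired_study")
}

#' Write a whole centre dataset
#'
#' One file stem per study under `dir/<center_id>/`.
#'
#' @param dataset a `center_dataset`.
#' @param dir output directory.
#' @return invisibly, the study stems.
#' @export
write_center_dataset <- function(dataset, dir) {
  stems <- character(length(dataset$studies))
  for (i in seq_along(dataset$studies)) {
    s <- dataset$studies[[i]]
    stems[i] <- file.path(dir, dataset$profile$center_id,
                          s$study_id %||% sprintf("study_%03d", i))
    write_study(s, stems[i])
  }
  invisible(stems)
}
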