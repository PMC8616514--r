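# Cohort serialization: NIfTI volumes, clinical CSV and a JSON manifest.
#
# Per subject two files are written: `<id>_image.nii.gz` (HU volume) and
# `<id>_labels.nii.gz`, a single multi-label 4D volume with three layers:
# layer 1 = liver mask (0/1), layer 2 = lobe labels (1 left, 2 right),
# layer 3 = lesion labels (one integer per 26-connected lesion). Voxel
# spacing is carried in the NIfTI pixdim.

#' Write a cohort to disk
#'
#' @param dir output directory (created if missing).
#' @param phantoms list of subjects, each a list with `image`
#'   ([image_volume()]) and `seg` ([segmentation_set()]).
#' @param clinical data.frame with `subject_id` and the clinical/outcome
#'   columns (`ecog`, `crp_mg_dl`, `bilirubin_mg_dl`, `ca19_9_u_ml`, and
#'   `time_months`, `event` when survival has been simulated).
#' @param seed the root seed that produced the cohort (recorded in the
#'   manifest).
#' @param config optional configuration object; its [config_hash()] is
#'   recorded so outputs can be matched to their configuration.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
write_cohort <- function(dir, phantoms, clinical, seed = NA_integer_,
                         config = NULL) {
  stopifnot(length(phantoms) == nrow(clinical))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  files <- list()
  for (i in seq_along(phantoms)) {
    id <- clinical$subject_id[i]
    ph <- phantoms[[i]]
    sp <- ph$image$spacing
    img_path <- file.path(dir, paste0(id, "_image.nii.gz"))
    lab_path <- file.path(dir, paste0(id, "_labels.nii.gz"))
    ok <- tryCatch({
      vol <- ph$image$values
      attr(vol, "pixdim") <- sp
      RNifti::writeNifti(RNifti::asNifti(vol), img_path)
      lab <- array(0L, dim = c(dim(ph$seg$liver_mask), 3L))
      lab[, , , 1] <- ph$seg$liver_mask * 1L
      lab[, , , 2] <- ph$seg$lobe_labels
      lab[, , , 3] <- ph$seg$lesion_labels
      attr(lab, "pixdim") <- c(sp, 1)
      RNifti::writeNifti(RNifti::asNifti(lab), lab_path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("I/O failure writing subject ", id, " to ", dir, ": ",
           conditionMessage(ok))
    files[[id]] <- list(image = basename(img_path),
                        labels = basename(lab_path))
  }
  csv_path <- file.path(dir, "clinical.csv")
  write_table_csv(clinical, csv_path)
  manifest <- list(
    package = "wltb",
    version = pkg_version(),
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    axis_order = c("x=left-right", "y=anterior-posterior", "z=cranio-caudal"),
    n_subjects = length(phantoms),
    clinical_csv = basename(csv_path),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return list with `subjects` (named list of `image` + `seg`),
#'   `clinical` (data.frame) and `manifest`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  clinical <- utils::read.csv(file.path(dir, manifest$clinical_csv))
  subjects <- list()
  for (id in names(manifest$files)) {
    f <- manifest$files[[id]]
    img <- RNifti::readNifti(file.path(dir, f$image))
    lab <- RNifti::readNifti(file.path(dir, f$labels))
    sp <- RNifti::pixdim(img)[1:3]
    lab <- array(as.integer(lab), dim = dim(lab))
    subjects[[id]] <- list(
      image = image_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp),
      seg = segmentation_set(lab[, , , 1] > 0, lab[, , , 2], lab[, , , 3],
                             sp, relabel = FALSE))
  }
  list(subjects = subjects, clinical = clinical, manifest = manifest)
}

#' Validate and ingest an external cohort
#'
#' Entry point for real image data: checks that each image/label pair
#' shares grid shape and voxel spacing (within tolerance), that no lesion
#' voxel lies outside the liver mask, that required clinical fields are
#' present, and excludes subjects with an empty lesion mask (reason:
#' no visible metastases). Subjects failing a check are rejected and
#' listed in the validation report; accepted subjects form the cohort
#' handle.
#'
#' @param image_files,label_files named character vectors of NIfTI paths
#'   (names = subject ids; labels in the 4D layout of [write_cohort()]).
#' @param clinical data.frame or CSV path with `subject_id` and clinical
#'   columns.
#' @param spacing_tol relative tolerance on voxel-spacing agreement.
#' @return list with `subjects` (accepted), `clinical` (matching rows),
#'   `validation` (data.frame: `subject_id`, `status`, `reason`).
#' @export
ingest_external <- function(image_files, label_files, clinical,
                            spacing_tol = 1e-4) {
  stopifnot(length(image_files) == length(label_files),
            !is.null(names(image_files)))
  if (is.character(clinical)) clinical <- utils::read.csv(clinical)
  need <- c("subject_id", "ecog", "crp_mg_dl", "bilirubin_mg_dl",
            "ca19_9_u_ml")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  subjects <- list()
  val <- data.frame(subject_id = character(0), status = character(0),
                    reason = character(0))
  note <- function(id, status, reason) {
    val <<- rbind(val, data.frame(subject_id = id, status = status,
                                  reason = reason))
  }
  for (id in names(image_files)) {
    img <- RNifti::readNifti(image_files[[id]])
    lab <- RNifti::readNifti(label_files[[id]])
    sp_i <- RNifti::pixdim(img)[1:3]
    sp_l <- RNifti::pixdim(lab)[1:3]
    if (!identical(dim(img)[1:3], dim(lab)[1:3])) {
      note(id, "rejected", "grid shape mismatch between image and labels")
      next
    }
    if (any(abs(sp_i - sp_l) / sp_i > spacing_tol)) {
      note(id, "rejected", "voxel spacing mismatch beyond tolerance")
      next
    }
    lab <- array(as.integer(lab), dim = dim(lab))
    liver <- lab[, , , 1] > 0
    lesions <- lab[, , , 3]
    n_out <- sum(lesions[!liver] != 0)
    if (n_out > 0) {
      note(id, "rejected",
           sprintf("%d lesion voxel(s) outside the liver mask", n_out))
      next
    }
    if (!any(lesions > 0)) {
      note(id, "excluded", "no visible metastases")
      next
    }
    if (!id %in% clinical$subject_id) {
      note(id, "rejected", "no clinical record")
      next
    }
    subjects[[id]] <- list(
      image = image_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp_i),
      seg = segmentation_set(liver, lab[, , , 2], lesions, sp_i,
                             relabel = FALSE))
    note(id, "accepted", "")
  }
  list(subjects = subjects,
       clinical = clinical[match(names(subjects), clinical$subject_id), ],
       validation = val)
}
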