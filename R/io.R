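# On-disk formats: per-patient image/mask volumes plus a manifest.csv that
# indexes every (slice, structure) pair.

#' Write a cohort (or patient list) to disk
#'
#' Creates one directory per patient. With `format = "nifti"` each patient
#' gets a single `image.nii.gz` volume (slices stacked) and one
#' `mask_<structure>.nii.gz` binary volume per structure — lossless for the
#' real-valued images. With `format = "png"` each slice is written as an
#' 8-bit grayscale `image_<k>.png` and `mask_<structure>_<k>.png` (0/255);
#' note 8-bit PNG quantizes the image intensities. A `manifest.csv` with
#' columns `patient_id`, `slice_index`, `structure`, `image_path`,
#' `mask_path` indexes everything.
#'
#' @param cohort A `cqa_cohort`, or a plain list of `cqa_patient`s.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"png"`.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  patients <- if (inherits(cohort, "cqa_cohort"))
    c(cohort$train, cohort$val, cohort$test) else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  # manifest paths are stored relative to `dir` so the cohort is portable
  for (p in patients) {
    dir.create(file.path(dir, p$patient_id), showWarnings = FALSE)
    structs <- names(p$slices[[1]]$masks)
    if (format == "nifti") {
      img_rel <- file.path(p$patient_id, "image.nii.gz")
      vol <- simplify2array(lapply(p$slices, `[[`, "image"))
      RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, img_rel))
      mask_rel <- vapply(structs, function(st) {
        mp <- file.path(p$patient_id, sprintf("mask_%s.nii.gz", st))
        mv <- simplify2array(lapply(p$slices, function(sl) sl$masks[[st]]))
        RNifti::writeNifti(RNifti::asNifti(mv), file.path(dir, mp))
        mp
      }, "")
      for (k in seq_along(p$slices))
        for (st in structs)
          rows[[length(rows) + 1]] <- tibble(
            patient_id = p$patient_id, slice_index = k, structure = st,
            image_path = img_rel, mask_path = unname(mask_rel[st]))
    } else {
      for (k in seq_along(p$slices)) {
        ip <- file.path(p$patient_id, sprintf("image_%03d.png", k))
        png::writePNG(p$slices[[k]]$image, file.path(dir, ip))
        for (st in structs) {
          mp <- file.path(p$patient_id, sprintf("mask_%s_%03d.png", st, k))
          png::writePNG(p$slices[[k]]$masks[[st]], file.path(dir, mp))
          rows[[length(rows) + 1]] <- tibble(
            patient_id = p$patient_id, slice_index = k, structure = st,
            image_path = ip, mask_path = mp)
        }
      }
    }
  }
  manifest <- bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a slice-sample table from a cohort manifest
#'
#' Loads the `manifest.csv` dialect written by [write_cohort()] back into
#' the acceptable-sample tibble consumed by [build_epoch()].
#'
#' @param manifest_path Path to `manifest.csv` (or a directory containing
#'   one).
#' @return A sample tibble like [cohort_samples()].
#' @export
read_manifest <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.csv")
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  root <- dirname(manifest_path)
  mf$image_path <- file.path(root, mf$image_path)
  mf$mask_path <- file.path(root, mf$mask_path)
  nifti <- grepl("\\.nii(\\.gz)?$", mf$image_path[1])
  vol_cache <- new.env(parent = emptyenv())
  load_slice <- function(path, k) {
    if (nifti) {
      if (is.null(vol_cache[[path]]))
        vol_cache[[path]] <- as.array(RNifti::readNifti(path))
      v <- vol_cache[[path]]
      if (length(dim(v)) == 2) v else v[, , k]
    } else {
      png::readPNG(path)
    }
  }
  tibble(
    patient_id = mf$patient_id,
    slice_index = mf$slice_index,
    structure = mf$structure,
    image = purrr::map2(mf$image_path, mf$slice_index, load_slice),
    mask = purrr::map2(mf$mask_path, mf$slice_index, function(p, k) {
      m <- load_slice(p, k)
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    }),
    label = 0L,
    perturbation = vector("list", nrow(mf))
  )
}

#' Write predictions to CSV
#'
#' Per-pass probabilities are serialized as a JSON list per row so the file
#' stays a flat CSV.
#'
#' @param predictions A `cqa_predictions` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  out <- predictions
  out$per_pass <- vapply(out$per_pass, function(p)
    as.character(jsonlite::toJSON(p, digits = NA)), "")
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Write a threshold table to JSON
#'
#' One JSON object per structure:
#' `{tau, target_recall, recall_below_tau, population_below_tau}`.
#'
#' @param thresholds A [threshold_table()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(thresholds, path) {
  obj <- lapply(split(thresholds, thresholds$structure), function(r)
    list(tau = r$tau, target_recall = r$target_recall,
         recall_below_tau = r$recall_below_tau,
         population_below_tau = r$population_below_tau))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
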