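# Format plumbing: NIfTI volume/mask IO, clinical CSV, ground-truth JSON
# sidecar, and the demographic-table arithmetic fixture.

#' Write a synthetic cohort to disk
#'
#' Per subject: `<id>_{pre,post}.nii.gz` and `<id>_{pre,post}_mask.nii.gz`
#' NIfTI files (when images exist); plus one `clinical.csv` (subject_id,
#' time_days, event, scan dates ISO-8601, interval, covariates) and one
#' `ground_truth.json` sidecar with the planted effects.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    if (!is.null(s$pre_volume)) {
      for (tp in c("pre", "post")) {
        v <- s[[paste0(tp, "_volume")]]
        m <- s[[paste0(tp, "_mask")]]
        img <- RNifti::asNifti(v$intensities, reference = NULL)
        RNifti::pixdim(img) <- v$spacing_mm
        RNifti::writeNifti(img, file.path(dir, paste0(s$subject_id, "_", tp,
                                                      ".nii.gz")))
        mi <- RNifti::asNifti(array(as.integer(m$voxels), dim(m$voxels)))
        RNifti::pixdim(mi) <- v$spacing_mm
        RNifti::writeNifti(mi, file.path(dir, paste0(s$subject_id, "_", tp,
                                                     "_mask.nii.gz")))
      }
    }
  }
  clin <- cohort_clinical(cohort)
  oc <- cohort_outcomes(cohort)
  meta <- data.frame(
    subject_id = oc$subject_id,
    time_days = oc$time, event = oc$event,
    scan_date_pre = vapply(cohort$subjects,
                           function(s) format(s$scan_date_pre), ""),
    scan_date_post = vapply(cohort$subjects,
                            function(s) format(s$scan_date_post), ""),
    interval_days = vapply(cohort$subjects, `[[`, 0, "scan_interval_days"),
    stringsAsFactors = FALSE)
  utils::write.csv(merge(meta, clin, by = "subject_id", sort = FALSE),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Expects the layout written by [write_cohort()]. Schema violations are
#' collected and reported: subjects with a missing timepoint are excluded
#' with a logged reason, a volume/mask shape mismatch or non-positive
#' survival time is an error.
#'
#' @param dir Directory containing `clinical.csv` and NIfTI pairs.
#' @param images Load image volumes (default TRUE if any NIfTI present).
#' @return A `synthetic_cohort`-shaped list (without ground truth unless
#'   the sidecar exists); excluded subjects are listed in
#'   `attr(, "excluded")`.
#' @export
read_cohort <- function(dir, images = TRUE) {
  csv <- file.path(dir, "clinical.csv")
  if (!file.exists(csv)) stop("clinical.csv not found in ", dir)
  meta <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_days", "event")
  if (!all(need %in% names(meta)))
    stop("clinical.csv missing columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  if (any(meta$time_days <= 0))
    stop("validation error: non-positive survival time")
  excluded <- data.frame(subject_id = character(0), reason = character(0))
  subjects <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$subject_id[i]
    sub <- list(
      subject_id = id,
      scan_interval_days = meta$interval_days[i] %||% NA_real_,
      scan_date_pre = as.Date(meta$scan_date_pre[i]),
      scan_date_post = as.Date(meta$scan_date_post[i]),
      clinical = meta[i, setdiff(names(meta),
                                 c("subject_id", "time_days", "event",
                                   "scan_date_pre", "scan_date_post",
                                   "interval_days")),
                      drop = FALSE],
      outcome = list(time = meta$time_days[i], event = meta$event[i])
    )
    if (images) {
      files <- file.path(dir, paste0(id, "_", c("pre", "post"), ".nii.gz"))
      masks <- file.path(dir, paste0(id, "_", c("pre", "post"),
                                     "_mask.nii.gz"))
      if (!all(file.exists(c(files, masks)))) {
        excluded <- rbind(excluded,
                          data.frame(subject_id = id,
                                     reason = "missing timepoint scan"))
        next
      }
      for (tp in 1:2) {
        img <- RNifti::readNifti(files[tp])
        msk <- RNifti::readNifti(masks[tp])
        if (!identical(dim(img)[1:3], dim(msk)[1:3]))
          stop("validation error: mask shape does not match volume for ", id)
        sp <- RNifti::pixdim(img)[1:3]
        nm <- c("pre", "post")[tp]
        sub[[paste0(nm, "_volume")]] <-
          image_volume(array(as.numeric(img), dim(img)[1:3]), sp)
        sub[[paste0(nm, "_mask")]] <-
          roi_mask(array(as.numeric(msk) > 0.5, dim(msk)[1:3]))
      }
    }
    subjects[[length(subjects) + 1L]] <- structure(sub,
                                                   class = "synthetic_subject")
  }
  gt <- NULL
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf)) gt <- jsonlite::read_json(gtf, simplifyVector = TRUE)
  structure(list(subjects = subjects, config = NULL, ground_truth = gt),
            class = "synthetic_cohort", excluded = excluded)
}

#' Recompute percentages of a demographic count table
#'
#' Given a table with `count` and `group_size` columns, returns
#' `100 * count / group_size` rounded to one decimal, the convention of
#' published cohort-characteristics tables.
#'
#' @param counts Data frame with numeric `count` and `group_size`.
#' @return The input with a `recomputed_percent` column appended.
#' @export
recompute_percentages <- function(counts) {
  stopifnot(all(c("count", "group_size") %in% names(counts)))
  counts$recomputed_percent <- round(100 * counts$count / counts$group_size, 1)
  counts
}

#' Load the bundled NSCLC cohort characteristics fixture
#'
#' A small plain-text table of demographic counts (with group sizes and
#' the percentages as printed) from a three-center advanced-NSCLC
#' EGFR-TKI cohort, used to exercise table arithmetic.
#'
#' @return Data frame with columns `group`, `characteristic`, `count`,
#'   `group_size`, `printed_percent`.
#' @export
nsclc_cohort_counts <- function() {
  utils::read.csv(system.file("extdata", "nsclc_cohort_counts.csv",
                              package = "deltarad"),
                  stringsAsFactors = FALSE)
}
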