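#' In-memory feature table for one view
#'
#' Plain subjects x regions table with unique subject ids, finite values,
#' and a view tag; the validated form of the package's delimited-text
#' interchange format (first column `subject_id`, then one column per
#' region).
#'
#' @slot ids ordered unique subject identifiers.
#' @slot regions ordered region (feature) names.
#' @slot values subjects x regions numeric matrix, all finite.
#' @slot viewTag `"CT"` or `"CV"`.
#' @export
setClass("FeatureTable",
  representation(ids = "character", regions = "character",
                 values = "matrix", viewTag = "character")
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "subject ids must be unique")
  if (nrow(object@values) != length(object@ids) ||
      ncol(object@values) != length(object@regions))
    msg <- c(msg, "values must be subjects x regions")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite, no missing entries")
  if (length(msg)) msg else TRUE
})

#' Read a per-view feature table from CSV
#'
#' Expects a header row, first column of subject ids, remaining columns
#' numeric region features. Missing, non-numeric or duplicate-id content is
#' rejected with an error naming the offending cells; row order is
#' preserved.
#'
#' @param path CSV file path.
#' @param viewTag `"CT"` or `"CV"`.
#' @return a validated [FeatureTable-class].
#' @export
readFeatureTable <- function(path, viewTag = "CT") {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("feature table needs an id column plus >= 1 feature column",
         call. = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  regions <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(regions),
                 dimnames = list(ids, regions))
  bad <- character(0)
  for (j in seq_along(regions)) {
    raw <- df[[j + 1L]]
    empty <- is.na(raw) | !nzchar(trimws(raw))
    num <- suppressWarnings(as.numeric(raw))
    offending <- which(empty | is.na(num))
    if (length(offending))
      bad <- c(bad, sprintf("row %d, column '%s'", offending, regions[j]))
    vals[, j] <- num
  }
  if (length(bad))
    stop("missing or non-numeric cell(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  new("FeatureTable", ids = ids, regions = regions, values = vals,
      viewTag = as.character(viewTag))
}

#' Write a feature table to CSV
#'
#' Values are written with 17 significant digits so the numeric text
#' round-trips to identical doubles.
#'
#' @param ft a [FeatureTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  txt <- matrix(sprintf("%.17g", ft@values), nrow(ft@values),
                dimnames = list(NULL, ft@regions))
  df <- data.frame(subject_id = ft@ids, txt, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject-to-group label table
#'
#' @param path CSV with columns `subject_id` and `group`.
#' @return data.frame with character columns `subject_id`, `group`.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("subject_id", "group") %in% colnames(df)))
    stop("label table must have columns 'subject_id' and 'group'",
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id(s) in label table", call. = FALSE)
  df[, c("subject_id", "group")]
}

#' Align two feature views and labels into a cohort
#'
#' Verifies that the thickness table, volume table and label table cover
#' exactly the same subjects, reorders the volume view and labels to the
#' thickness table's subject order, and assembles a
#' [MultiViewCohort-class] (features in rows).
#'
#' @param ct,cv [FeatureTable-class] objects for the two views.
#' @param labels data.frame from [readLabels()] (or with columns
#'   `subject_id`, `group`).
#' @return a [MultiViewCohort-class].
#' @export
alignViews <- function(ct, cv, labels) {
  stopifnot(is(ct, "FeatureTable"), is(cv, "FeatureTable"))
  idSets <- list(thickness = ct@ids, volume = cv@ids,
                 labels = labels$subject_id)
  for (a in names(idSets)) for (b in names(idSets)) {
    missing <- setdiff(idSets[[a]], idSets[[b]])
    if (length(missing))
      stop("subject(s) present in ", a, " but missing from ", b, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(ct@regions, cv@regions) &&
      length(ct@regions) != length(cv@regions))
    stop("views must have the same number of region features", call. = FALSE)
  ord <- ct@ids
  cvVals <- cv@values[match(ord, cv@ids), , drop = FALSE]
  grp <- labels$group[match(ord, labels$subject_id)]
  MultiViewCohort(t(ct@values), t(cvVals), grp, subjectIds = ord)
}

#' Write a cohort as three CSV tables
#'
#' Emits `<prefix>thickness.csv`, `<prefix>volume.csv` (rows = subjects,
#' columns = region features, first column subject id) and
#' `<prefix>labels.csv` (subject id, group) under `dir`.
#'
#' @param cohort a [MultiViewCohort-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisible character vector of the three paths.
#' @export
writeCohort <- function(cohort, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- colnames(cohort)
  regions <- rownames(cohort) %||%
    sprintf("region_%03d", seq_len(nrow(cohort)))
  paths <- file.path(dir, paste0(prefix, c("thickness.csv", "volume.csv",
                                           "labels.csv")))
  ftCT <- new("FeatureTable", ids = ids, regions = regions,
              values = t(thicknessView(cohort)), viewTag = "CT")
  ftCV <- new("FeatureTable", ids = ids, regions = regions,
              values = t(volumeView(cohort)), viewTag = "CV")
  writeFeatureTable(ftCT, paths[1])
  writeFeatureTable(ftCV, paths[2])
  write.csv(data.frame(subject_id = ids, group = groupLabels(cohort)),
            paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a cohort from the three CSV tables
#'
#' @param thicknessPath,volumePath,labelsPath paths as written by
#'   [writeCohort()].
#' @return a [MultiViewCohort-class].
#' @export
readCohort <- function(thicknessPath, volumePath, labelsPath) {
  alignViews(readFeatureTable(thicknessPath, "CT"),
             readFeatureTable(volumePath, "CV"),
             readLabels(labelsPath))
}
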