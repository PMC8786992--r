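#' Feature table: the pipeline's universal currency
#'
#' A `feature_table` holds long-format radiomic feature values — one row per
#' (patient, reconstruction setting, feature) — together with the
#' reconstruction design, per-patient metadata and per-feature descriptors.
#' Every analysis stage consumes and, where relevant, returns this container.
#'
#' @param values Tibble/data frame with columns `patient_id`, `setting`,
#'   `feature`, `value` (numeric).
#' @param patients Tibble with one row per patient: `patient_id`, `scanner`,
#'   `tube_voltage`, `tumour_volume_cm3`, plus any extra covariate columns
#'   (age, gender, side, position, histology, ...).
#' @param features Tibble with one row per feature: `name`, `image_type`
#'   (`original`, `wavelet` or `log`), `image_subtype` (wavelet band or LoG
#'   sigma label, empty for original), `category` (`shape`, `firstorder`,
#'   `glcm`, `glrlm`, `glszm`, `ngtdm`, `gldm`), `is_volume_like` (logical).
#'   If `NULL`, descriptors are parsed from the feature names with
#'   [parse_feature_names()].
#' @param design A [recon_design()] declaring the settings present.
#'
#' @return An object of class `feature_table`: a list with elements `design`,
#'   `patients`, `features`, `values` and attribute-free accounting via
#'   [n_missing_cells()].
#'
#' @details Missing cells (patient x setting x feature combinations without a
#' value) are tolerated at I/O time and counted; each analysis resolves them
#' by complete-case restriction within the setting subset it uses. Duplicated
#' keys, unknown settings and non-numeric values are hard errors.
#'
#' @export
feature_table <- function(values, patients, features = NULL, design = recon_design()) {
  stopifnot(inherits(design, "recon_design"))
  values <- tibble::as_tibble(values)
  need <- c("patient_id", "setting", "feature", "value")
  if (!all(need %in% names(values))) {
    stop("`values` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  values <- values[need]
  values$patient_id <- as.character(values$patient_id)
  values$setting <- as.character(values$setting)
  values$feature <- as.character(values$feature)
  if (!is.numeric(values$value)) {
    bad <- suppressWarnings(as.numeric(values$value))
    idx <- which(is.na(bad) & !is.na(values$value))
    if (length(idx)) {
      stop("non-numeric feature value at row ", idx[[1L]], call. = FALSE)
    }
    values$value <- bad
  }
  unknown <- setdiff(unique(values$setting), design$settings)
  if (length(unknown)) {
    stop("unknown setting label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(values$patient_id, values$setting, values$feature, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][[1L]]
    stop("duplicated (patient, setting, feature) key: ",
         gsub("\r", " / ", dup), call. = FALSE)
  }

  patients <- tibble::as_tibble(patients)
  if (!"patient_id" %in% names(patients)) {
    stop("`patients` must have a patient_id column", call. = FALSE)
  }
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id in metadata", call. = FALSE)
  }
  meta_need <- c("scanner", "tube_voltage", "tumour_volume_cm3")
  miss <- setdiff(meta_need, names(patients))
  if (length(miss)) {
    stop("patient metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(patients$scanner) || anyNA(patients$tube_voltage)) {
    stop("scanner and tube_voltage must be non-missing", call. = FALSE)
  }
  if (any(!is.na(patients$tumour_volume_cm3) & patients$tumour_volume_cm3 <= 0)) {
    stop("tumour_volume_cm3 must be positive", call. = FALSE)
  }
  orphan <- setdiff(unique(values$patient_id), patients$patient_id)
  if (length(orphan)) {
    stop("values reference undeclared patient(s): ",
         paste(utils::head(orphan, 3L), collapse = ", "), call. = FALSE)
  }

  if (is.null(features)) {
    features <- parse_feature_names(unique(values$feature))
  } else {
    features <- tibble::as_tibble(features)
    fneed <- c("name", "image_type", "image_subtype", "category", "is_volume_like")
    fmiss <- setdiff(fneed, names(features))
    if (length(fmiss)) {
      stop("feature descriptors lack column(s): ", paste(fmiss, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(features$name)) {
      stop("duplicated feature name in descriptors", call. = FALSE)
    }
    undeclared <- setdiff(unique(values$feature), features$name)
    if (length(undeclared)) {
      stop("values reference undeclared feature(s): ",
           paste(utils::head(undeclared, 3L), collapse = ", "), call. = FALSE)
    }
  }
  bad_shape <- features$category == "shape" & features$image_type != "original"
  if (any(bad_shape)) {
    stop("shape features are only defined for original images: ",
         paste(utils::head(features$name[bad_shape], 3L), collapse = ", "),
         call. = FALSE)
  }

  structure(
    list(design = design, patients = patients, features = features,
         values = values),
    class = "feature_table"
  )
}

#' Parse Pyradiomics-style feature names into descriptors
#'
#' Splits names of the form `<imagetype>_<category>_<featurename>` (e.g.
#' `original_glrlm_RunVariance`, `wavelet-HH_firstorder_Mean`,
#' `log-sigma-1-0-mm_glcm_Contrast`) into image type, subtype and category.
#'
#' @param names Character vector of feature names.
#' @param volume_like Feature names whose value is the segmented volume itself
#'   (these later drop the tumour-volume covariate from their mixed model).
#' @return Tibble of feature descriptors.
#' @export
parse_feature_names <- function(names,
                                volume_like = "original_shape_VoxelVolume") {
  categories <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
  parts <- strsplit(names, "_", fixed = TRUE)
  parse1 <- function(nm, pp) {
    img <- pp[[1L]]
    cat_idx <- which(pp %in% categories)[1L]
    category <- if (is.na(cat_idx)) "firstorder" else pp[[cat_idx]]
    if (startsWith(img, "wavelet")) {
      type <- "wavelet"
      subtype <- sub("^wavelet-?", "", img)
    } else if (startsWith(tolower(img), "log")) {
      type <- "log"
      subtype <- sub("^log-?", "", tolower(img))
    } else {
      type <- "original"
      subtype <- ""
    }
    tibble::tibble(name = nm, image_type = type, image_subtype = subtype,
                   category = category)
  }
  out <- purrr::map2_dfr(names, parts, parse1)
  out$is_volume_like <- out$name %in% volume_like
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$patients), " patients x ",
      length(x$design$settings), " settings x ", nrow(x$features),
      " features (", n_missing_cells(x), " missing cells)\n", sep = "")
  invisible(x)
}

#' Count missing (patient, setting, feature) cells
#'
#' @param table A [feature_table()].
#' @return Integer count of absent cells relative to the full
#'   patients x settings x features grid.
#' @export
n_missing_cells <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  full <- nrow(table$patients) * length(table$design$settings) *
    nrow(table$features)
  as.integer(full - nrow(table$values))
}

#' Read a long-format feature table from CSV
#'
#' @param values_path CSV with header `patient_id,setting,feature,value`.
#' @param metadata_path CSV with one row per patient, header
#'   `patient_id,scanner,tube_voltage,tumour_volume_cm3,...`.
#' @param design A [recon_design()]; rows with settings outside it error.
#' @return A validated [feature_table()]. The number of missing cells is
#'   reported via a message and retrievable with [n_missing_cells()].
#' @export
read_feature_table <- function(values_path, metadata_path,
                               design = recon_design()) {
  values <- readr::read_csv(values_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              patient_id = readr::col_character(),
                              setting = readr::col_character(),
                              feature = readr::col_character(),
                              value = readr::col_character()
                            ))
  num <- suppressWarnings(as.numeric(values$value))
  bad <- which(is.na(num) & !is.na(values$value))
  if (length(bad)) {
    stop("non-numeric value in ", values_path, " at data row ", bad[[1L]],
         call. = FALSE)
  }
  values$value <- num
  patients <- readr::read_csv(metadata_path, show_col_types = FALSE,
                              col_types = readr::cols(
                                patient_id = readr::col_character(),
                                scanner = readr::col_character(),
                                tube_voltage = readr::col_character(),
                                .default = readr::col_guess()
                              ))
  tab <- feature_table(values, patients, design = design)
  nm <- n_missing_cells(tab)
  if (nm > 0L) {
    message(nm, " missing (patient, setting, feature) cell(s)")
  }
  tab
}

#' Write a feature table to long-format CSVs
#'
#' @param table A [feature_table()].
#' @param values_path,metadata_path Output CSV paths.
#' @return `table`, invisibly.
#' @export
write_feature_table <- function(table, values_path, metadata_path) {
  stopifnot(inherits(table, "feature_table"))
  readr::write_csv(table$values, values_path)
  readr::write_csv(table$patients, metadata_path)
  invisible(table)
}

#' Per-feature patient-by-setting value matrix
#'
#' Reshapes one feature's values into a numeric matrix with one row per
#' patient and one column per requested setting, keeping only patients with a
#' value at every requested setting (complete case within the subset).
#'
#' @param table A [feature_table()].
#' @param feature Feature name.
#' @param settings Setting labels (default: all in the design); column order
#'   follows this argument.
#' @return Numeric matrix with `patient_id` rownames, rows ordered by
#'   patient_id.
#' @export
feature_matrix <- function(table, feature, settings = table$design$settings) {
  stopifnot(inherits(table, "feature_table"))
  if (!feature %in% table$features$name) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  unknown <- setdiff(settings, table$design$settings)
  if (length(unknown)) {
    stop("unknown setting label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  v <- table$values[table$values$feature == feature &
                      table$values$setting %in% settings, ]
  wide <- tidyr::pivot_wider(v[c("patient_id", "setting", "value")],
                             names_from = "setting", values_from = "value")
  have <- intersect(settings, names(wide))
  if (length(have) < length(settings)) {
    wide[setdiff(settings, have)] <- NA_real_
  }
  wide <- wide[order(wide$patient_id), c("patient_id", settings)]
  m <- as.matrix(wide[settings])
  rownames(m) <- wide$patient_id
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("no patient has complete values for feature ", feature,
         " over the requested settings", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Long values joined with patient metadata for one feature
#'
#' Internal convenience used by the mixed model and the group tests.
#' @noRd
feature_long <- function(table, feature, settings = table$design$settings) {
  v <- table$values[table$values$feature == feature &
                      table$values$setting %in% settings, ]
  dplyr::inner_join(v, table$patients, by = "patient_id")
}
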