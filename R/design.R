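#' Reconstruction design
#'
#' Describes the set of reconstruction settings a feature table is expected to
#' contain: the ordered setting labels, the iterative-reconstruction (IR)
#' blending percentage behind each label, and the reference category used by
#' the mixed models and the harmonization step.
#'
#' The default mirrors a common clinical protocol: six ASIR blending levels
#' 0% (pure filtered backprojection, FBP), 20%, 40%, 50%, 60% and 80%, with
#' FBP as reference. Statistics treat the labels as categorical; the blending
#' percentages only order the settings for plots and trend summaries.
#'
#' @param settings Character vector of unique setting labels, ordered by
#'   increasing blending percentage.
#' @param blending_percent Integer vector (0-100), same length as `settings`,
#'   giving the IR blending percentage of each label. Must be injective.
#' @param reference Reference setting label; must be one of `settings`.
#'
#' @return An object of class `recon_design`: a list with elements
#'   `settings`, `blending_percent` (named integer) and `reference`.
#'
#' @examples
#' recon_design()
#' recon_design(c("IR40", "IR50", "IR60", "IR80"), c(40, 50, 60, 80), "IR40")
#' @export
recon_design <- function(settings = c("FBP", "IR20", "IR40", "IR50", "IR60", "IR80"),
                         blending_percent = c(0L, 20L, 40L, 50L, 60L, 80L),
                         reference = settings[[1L]]) {
  settings <- as.character(settings)
  if (anyDuplicated(settings)) {
    stop("setting labels must be unique", call. = FALSE)
  }
  if (length(blending_percent) != length(settings)) {
    stop("`blending_percent` must have one entry per setting", call. = FALSE)
  }
  blending_percent <- as.integer(blending_percent)
  if (any(is.na(blending_percent)) ||
      any(blending_percent < 0L) || any(blending_percent > 100L)) {
    stop("blending percentages must be integers in [0, 100]", call. = FALSE)
  }
  if (anyDuplicated(blending_percent)) {
    stop("blending percentages must be distinct across settings", call. = FALSE)
  }
  reference <- as.character(reference)
  if (length(reference) != 1L || !reference %in% settings) {
    stop("`reference` must be a single member of `settings`", call. = FALSE)
  }
  names(blending_percent) <- settings
  structure(
    list(settings = settings, blending_percent = blending_percent,
         reference = reference),
    class = "recon_design"
  )
}

#' @export
print.recon_design <- function(x, ...) {
  lab <- paste0(x$settings, " (", x$blending_percent, "%)")
  lab[x$settings == x$reference] <- paste0(lab[x$settings == x$reference], " [ref]")
  cat("<recon_design> ", paste(lab, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restrict a design to a subset of settings
#'
#' Used for subgroup analyses on fewer blending levels (e.g. the IR40-IR80
#' range with IR40 as the new reference).
#'
#' @param design A [recon_design()].
#' @param settings Labels to keep (subset of `design$settings`).
#' @param reference New reference label; must belong to `settings`.
#' @return A new `recon_design`.
#' @export
restrict_design <- function(design, settings, reference = settings[[1L]]) {
  stopifnot(inherits(design, "recon_design"))
  settings <- as.character(settings)
  missing <- setdiff(settings, design$settings)
  if (length(missing)) {
    stop("unknown setting label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- design$settings[design$settings %in% settings]
  recon_design(keep, design$blending_percent[keep], reference)
}
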