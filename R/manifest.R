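# Manifest I/O: the CSV schema shared by real and synthetic datasets.

#' Read a dataset manifest
#'
#' A manifest is a UTF-8 CSV with header columns
#' `image_path,patient_id,label` and labels in
#' `c("normal", "benign", "malignant")`. Additional columns are preserved.
#'
#' @param path CSV file.
#' @param require_labels If `FALSE`, a missing or empty label column is
#'   allowed (Phases 1-2 never need one).
#' @return Data frame.
#' @export
read_manifest <- function(path, require_labels = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("image_path", "patient_id")
  if (require_labels) need <- c(need, "label")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if ("label" %in% names(m)) {
    bad <- setdiff(unique(m$label), phantom_classes)
    if (length(bad)) stop("manifest has unknown label(s): ",
                          paste(bad, collapse = ", "))
  }
  # relative image paths are interpreted relative to the manifest location
  rel <- !grepl("^(/|[A-Za-z]:)", m$image_path)
  m$image_path[rel] <- file.path(dirname(path), m$image_path[rel])
  m
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with the manifest columns.
#' @param path Output CSV file.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
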