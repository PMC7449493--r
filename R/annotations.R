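#' Read a nodule annotation CSV
#'
#' Reads annotations in the public lung-CT challenge dialect: a header row
#' `seriesuid,coordX,coordY,coordZ,diameter_mm` followed by one nodule per
#' row, with centres in world millimetres and diameters in millimetres
#' (annotated nodules span 3-30 mm). Malformed rows are reported with their
#' line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `seriesuid` (character), `coordX`,
#'   `coordY`, `coordZ`, `diameter_mm` (double).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    abort(sprintf("annotation file not found: %s", path), class = "lungcad_io_error")
  cols <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    abort(sprintf("annotation file %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "lungcad_format_error")
  raw <- raw[cols]
  if (nrow(raw) == 0)
    return(tibble(seriesuid = character(), coordX = double(), coordY = double(),
                  coordZ = double(), diameter_mm = double()))
  num <- lapply(cols[-1], function(cn) suppressWarnings(as.numeric(raw[[cn]])))
  names(num) <- cols[-1]
  bad <- Reduce(`|`, lapply(num, function(v) !is.finite(v)))
  bad <- bad | !is.finite(num$diameter_mm) | (num$diameter_mm <= 0) %in% TRUE
  if (any(bad))
    abort(sprintf("annotation file %s has malformed row(s) at line(s): %s",
                  path, paste(which(bad) + 1L, collapse = ", ")),
          class = "lungcad_format_error")
  tibble(seriesuid = raw$seriesuid, coordX = num$coordX, coordY = num$coordY,
         coordZ = num$coordZ, diameter_mm = num$diameter_mm)
}

#' Write a nodule annotation CSV
#'
#' @param annotations Tibble/data frame with columns `seriesuid`, `coordX`,
#'   `coordY`, `coordZ`, `diameter_mm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  stopifnot(all(cols %in% names(annotations)))
  utils::write.csv(as.data.frame(annotations)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
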