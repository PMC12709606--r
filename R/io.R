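#' Write / read a cohort table as CSV
#'
#' The mass table is written to `path`; per-reader gCNR scores (if present)
#' go to `scores_path` (default: `path` with a `_scores` suffix).
#'
#' @param cohort a cohort table.
#' @param path CSV path for the mass records.
#' @param scores_path CSV path for the long per-reader score table.
#' @return the input, invisibly.
#' @export
write_cohort_csv <- function(cohort, path,
                             scores_path = sub("\\.csv$", "_scores.csv", path)) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  scores <- reader_scores(cohort)
  if (!is.null(scores)) {
    utils::write.csv(scores, scores_path, row.names = FALSE, na = "")
  }
  invisible(cohort)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path,
                            scores_path = sub("\\.csv$", "_scores.csv", path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  scores <- if (file.exists(scores_path)) {
    utils::read.csv(scores_path, stringsAsFactors = FALSE, na.strings = "")
  } else {
    NULL
  }
  as_cohort_table(df, scores)
}

#' Write / read a reader panel as CSV
#' @param panel a reader panel data frame.
#' @param path CSV path.
#' @return the panel, invisibly (write) or the panel (read).
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "reader_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(panel)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  class(df) <- c("reader_panel", "data.frame")
  df
}

#' Write / read an ultrasound image as plain-text TSV
#'
#' Pixel values as a tab-separated matrix preceded by commented metadata
#' lines (`# key: value`) carrying the image kind, pixel spacings, depth
#' offset and display range.
#'
#' @param image an [ultrasound_image()].
#' @param path file path.
#' @return the image, invisibly (write) or the image (read).
#' @export
write_image_tsv <- function(image, path) {
  stopifnot(inherits(image, "ultrasound_image"))
  meta <- c(
    sprintf("# kind: %s", image$kind),
    sprintf("# axial_spacing: %.17g", image$axial_spacing),
    sprintf("# lateral_spacing: %.17g", image$lateral_spacing),
    sprintf("# depth_offset: %.17g", image$depth_offset),
    sprintf("# dynamic_range_db: %.17g", image$dynamic_range_db)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(image$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(image)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  vals <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  ultrasound_image(
    as.matrix(vals), meta$kind,
    axial_spacing = as.numeric(meta$axial_spacing),
    lateral_spacing = as.numeric(meta$lateral_spacing),
    depth_offset = as.numeric(meta$depth_offset),
    dynamic_range_db = as.numeric(meta$dynamic_range_db)
  )
}

#' Export an image as 8-bit PNG
#'
#' Linear B-mode images are log-compressed at their display range before
#' export; SLSC images are written on a linear scale normalized to their
#' maximum.
#'
#' @param image an [ultrasound_image()].
#' @param path PNG path.
#' @param dynamic_range_db display range for B-mode export.
#' @return the path, invisibly.
#' @export
write_image_png <- function(image, path, dynamic_range_db = 60) {
  stopifnot(inherits(image, "ultrasound_image"))
  v <- switch(image$kind,
    bmode_linear = {
      lg <- log_compress(image, dynamic_range_db)
      (lg$values + dynamic_range_db) / dynamic_range_db
    },
    bmode_log = (image$values + image$dynamic_range_db) / image$dynamic_range_db,
    slsc = {
      mx <- max(image$values)
      if (mx > 0) pmin(image$values / mx, 1) else image$values
    }
  )
  png::writePNG(pmax(pmin(v, 1), 0), path)
  invisible(path)
}
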