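#' Read a micrograph (TIFF or PNG)
#'
#' Grayscale images come back as a numeric matrix (rows = y, cols = x),
#' RGB(A) images as a 3-d array; intensities are on `[0, 1]` whatever the
#' stored bit depth, which is recorded in the `bit_depth` attribute.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix or array with attributes `bit_depth` and `path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(paste("image file not found:", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path, info = TRUE),
      png = png::readPNG(path, info = TRUE),
      abort(paste("unsupported image format:", ext, "-", path))
    ),
    error = function(e) abort(paste("cannot read image", path, ":",
                                    conditionMessage(e)))
  )
  info <- attr(img, "info")
  bits <- if (!is.null(info$bit.depth)) info$bit.depth
          else if (!is.null(info$bits.per.sample)) info$bits.per.sample
          else NA_integer_
  attributes(img) <- list(dim = dim(img))
  attr(img, "bit_depth") <- bits
  attr(img, "path") <- path
  img
}

#' Write a binary mask as an 8-bit PNG (audit output)
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

log_required <- c("Document", "Area", "Perimeter", "Circularity",
                  "Height", "Width")

#' Import a manual measurement log into the canonical table
#'
#' Parses the tab-delimited log exported from interactive mask measurement
#' (columns `Document`, `Area`, `Perimeter`, `Circularity`, `Height`,
#' `Width`; any extra columns are ignored by name). Pixel values are
#' converted to micrometres via the calibration scale (areas by the squared
#' factor, lengths linearly) and the lumen/outer rows of each fiber are
#' merged into one canonical row, with `Outer True Area` and `Outer/Lumen`
#' computed on the way.
#'
#' Two pairing conventions are supported. `"alternating"` follows the manual
#' recording order — for each fiber the lumen mask is recorded first, then
#' the outer mask — so rows of one document alternate lumen, outer, lumen,
#' outer, and fibers are lettered A, B, ... in recording order. `"by_label"`
#' expects exactly two rows per distinct `Document` value (one fiber per
#' label); the smaller-area row is the lumen.
#'
#' @param path Tab-delimited log file.
#' @param scale A [calibration_scale()] or um-per-px factor.
#' @param pairing `"alternating"` or `"by_label"`.
#' @param line Cotton line label recorded in the `Line` column.
#' @return A canonical tibble ([canonical_columns()]).
#' @export
import_measurement_log <- function(path, scale,
                                   pairing = c("alternating", "by_label"),
                                   line = NA_character_) {
  pairing <- match.arg(pairing)
  s <- as_scale_factor(scale)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  missing <- setdiff(log_required, names(raw))
  if (length(missing)) {
    abort(paste("measurement log lacks column(s):",
                paste(missing, collapse = ", ")))
  }
  raw <- raw[log_required]
  num <- log_required[-1]
  raw[num] <- lapply(raw[num], as.numeric)
  if (anyNA(raw[num]) || any(as.matrix(raw[num]) <= 0)) {
    abort("measurement log contains missing or non-positive values")
  }

  pair_one <- function(lum, out, name) {
    if (out$Area <= lum$Area) {
      abort(paste0("outer area <= lumen area for fiber '", name,
                   "'; are the lumen/outer rows swapped?"))
    }
    fiber_record(
      name,
      lumen = shape_measures(lum$Area * s^2, lum$Perimeter * s,
                             lum$Circularity, lum$Height * s, lum$Width * s),
      outer = shape_measures(out$Area * s^2, out$Perimeter * s,
                             out$Circularity, out$Height * s, out$Width * s),
      line = line
    )
  }

  if (pairing == "alternating") {
    parts <- split(raw, factor(raw$Document, levels = unique(raw$Document)))
    rows <- purrr::imap(parts, function(d, doc) {
      if (nrow(d) %% 2 != 0) {
        abort(paste0("document '", doc, "' has an odd number of rows; ",
                     "expected alternating lumen/outer pairs"))
      }
      k <- nrow(d) %/% 2
      letters_k <- position_letters(k)
      purrr::map(seq_len(k), function(i) {
        pair_one(d[2 * i - 1, ], d[2 * i, ],
                 paste0(doc, "_", letters_k[i]))
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  } else {
    parts <- split(raw, factor(raw$Document, levels = unique(raw$Document)))
    rows <- purrr::imap(parts, function(d, doc) {
      if (nrow(d) != 2) {
        abort(paste0("document '", doc, "' has ", nrow(d),
                     " rows; by_label pairing expects exactly 2"))
      }
      o <- order(d$Area)
      pair_one(d[o[1], ], d[o[2], ], doc)
    })
    dplyr::bind_rows(rows)
  }
}

check_canonical <- function(data) {
  if (!identical(names(data)[seq_along(canonical_names)], canonical_names)) {
    abort("not a canonical table: first 14 columns must match canonical_columns()")
  }
  invisible(data)
}

#' Write a canonical measurement table to CSV
#'
#' Writes the table with its exact column header. The decimal separator is
#' always a point, independent of locale. `digits = 2` produces the
#' two-decimal report formatting; by default full precision is written so
#' that a write/re-import round trip is the identity.
#'
#' @param data Canonical tibble (derived columns, if present, are written
#'   too).
#' @param path Output CSV path.
#' @param digits Optional rounding applied to numeric columns at write time.
#' @export
write_canonical_table <- function(data, path, digits = NULL) {
  check_canonical(data)
  if (!is.null(digits)) {
    data <- dplyr::mutate(data,
      dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a canonical measurement table from CSV
#'
#' @param path CSV written by [write_canonical_table()].
#' @return Canonical tibble.
#' @export
read_canonical_table <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
  check_canonical(data)
  as_tibble(data)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numbers or logicals (`true`/`false`) where possible, strings
#' otherwise.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) abort(paste("config line without '=':", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  parse_val <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  stats::setNames(lapply(vals, parse_val), keys)
}
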