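# Image, table and ROI file I/O.
#
# The DICOM code is a deliberately minimal single-frame codec (explicit VR
# little endian, MONOCHROME2, 16-bit unsigned) covering exactly the tags
# the pipeline consumes; it is not a general DICOM implementation.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16_bytes <- function(v) {
  as.raw(rbind(v %% 256L, v %/% 256L))
}

uint32_bytes <- function(v) {
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

dicom_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1L
  }
  head <- c(uint16_bytes(group), uint16_bytes(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), uint32_bytes(len), value_raw)
  } else {
    if (len > 65535L) stop("element too long for short VR", call. = FALSE)
    c(head, uint16_bytes(len), value_raw)
  }
}

dicom_str_element <- function(group, elem, vr, s) {
  dicom_element(group, elem, vr, charToRaw(s))
}

#' Write a single-frame DICOM slice
#'
#' Stores the image as 16-bit unsigned MONOCHROME2 pixels with a rescale
#' transform, so that `pixel = stored * slope + intercept`. With the
#' default `rescale = "auto"`, integer-valued images in `[0, 65535]` are
#' stored losslessly (slope 1, intercept 0); other images are linearly
#' quantized into the 16-bit range with a warning. Acquisition metadata
#' (TR/TE/FA/TI, pixel spacing) and the pipeline modality (via the series
#' description) are written to standard tags.
#'
#' @param image an [image2d()].
#' @param path output file path.
#' @param rescale `"auto"`, or a length-2 numeric `(slope, intercept)`;
#'   with an explicit rescale the scaled stored values must land on
#'   integers in `[0, 65535]`.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path, rescale = "auto") {
  stopifnot(inherits(image, "image2d"))
  px <- image$pixels
  if (identical(rescale, "auto")) {
    if (all(px == round(px)) && min(px) >= 0 && max(px) <= 65535) {
      slope <- 1
      intercept <- 0
    } else {
      intercept <- min(px)
      slope <- if (max(px) > min(px)) (max(px) - min(px)) / 65535 else 1
      warning("non-integer pixel values quantized to 16 bits")
    }
  } else {
    slope <- rescale[1]
    intercept <- rescale[2]
  }
  stored <- round((px - intercept) / slope)
  if (min(stored) < 0 || max(stored) > 65535) {
    stop("stored values fall outside the unsigned 16-bit range",
         call. = FALSE)
  }
  ds <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

  body <- c(
    dicom_str_element(0x0008L, 0x0016L, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    # deterministic instance UID derived from the image content
    dicom_str_element(0x0008L, 0x0018L, "UI",
                      sprintf("1.2.826.0.1.3680043.9.7435.%d.%d.%.0f",
                              nrow(px), ncol(px),
                              sum(stored) %% 1e9)),
    dicom_str_element(0x0008L, 0x0060L, "CS", "MR"),
    dicom_str_element(0x0008L, 0x103EL, "LO", image$modality),
    if (is.finite(image$tr)) {
      dicom_str_element(0x0018L, 0x0080L, "DS", ds(image$tr))
    },
    if (is.finite(image$te)) {
      dicom_str_element(0x0018L, 0x0081L, "DS", ds(image$te))
    },
    if (is.finite(image$ti)) {
      dicom_str_element(0x0018L, 0x0082L, "DS", ds(image$ti))
    },
    if (is.finite(image$fa)) {
      dicom_str_element(0x0018L, 0x1314L, "DS", ds(image$fa))
    },
    dicom_element(0x0028L, 0x0002L, "US", uint16_bytes(1L)),
    dicom_str_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dicom_element(0x0028L, 0x0010L, "US", uint16_bytes(nrow(px))),
    dicom_element(0x0028L, 0x0011L, "US", uint16_bytes(ncol(px))),
    dicom_str_element(0x0028L, 0x0030L, "DS",
                      paste(ds(image$pixel_spacing[1]),
                            ds(image$pixel_spacing[2]), sep = "\\")),
    dicom_element(0x0028L, 0x0100L, "US", uint16_bytes(16L)),
    dicom_element(0x0028L, 0x0101L, "US", uint16_bytes(16L)),
    dicom_element(0x0028L, 0x0102L, "US", uint16_bytes(15L)),
    dicom_element(0x0028L, 0x0103L, "US", uint16_bytes(0L)),
    dicom_str_element(0x0028L, 0x1052L, "DS", ds(intercept)),
    dicom_str_element(0x0028L, 0x1053L, "DS", ds(slope)),
    # pixel data in DICOM row-major order
    dicom_element(0x7FE0L, 0x0010L, "OW",
                  uint16_bytes(as.integer(t(stored))))
  )
  ts <- dicom_str_element(0x0002L, 0x0010L, "UI", DICOM_EXPLICIT_LE)
  meta <- c(dicom_element(0x0002L, 0x0000L, "UL",
                          uint32_bytes(length(ts))), ts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 128)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_uint16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

read_uint32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

raw_to_str <- function(raw) {
  trimws(rawToChar(raw[raw != as.raw(0L)]))
}

parse_ds <- function(raw) {
  as.numeric(strsplit(raw_to_str(raw), "\\\\")[[1]])
}

#' Read a single-frame DICOM slice
#'
#' Parses an explicit-VR little-endian single-frame DICOM file (such as
#' those written by [write_dicom()]), applies the rescale slope/intercept,
#' and maps TR/TE/TI/flip-angle tags onto [image2d()] metadata. The series
#' description is used to recover the pipeline modality (`IR` / `SPGR`),
#' defaulting to `other`.
#'
#' @param path DICOM file path.
#' @return An [image2d()].
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM marker)", call. = FALSE)
  }
  pos <- 133L
  tags <- list()
  pixel_raw <- NULL
  while (pos + 7L <= length(bytes)) {
    group <- read_uint16(bytes, pos)
    elem <- read_uint16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_uint32(bytes, pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- read_uint16(bytes, pos + 6L)
      val_at <- pos + 8L
    }
    if (val_at + len - 1L > length(bytes)) {
      stop("truncated DICOM element", call. = FALSE)
    }
    value <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    if (key == "7FE00010") {
      pixel_raw <- value
    } else if (key == "00020010") {
      ts <- raw_to_str(value)
      if (ts != DICOM_EXPLICIT_LE) {
        stop(sprintf("unsupported transfer syntax '%s'", ts), call. = FALSE)
      }
    } else {
      tags[[key]] <- value
    }
    pos <- val_at + as.integer(len)
  }
  if (!is.null(tags[["00280008"]])) {
    nframes <- suppressWarnings(as.integer(trimws(rawToChar(tags[["00280008"]]))))
    if (!is.na(nframes) && nframes > 1L) {
      stop("multi-frame DICOM objects are unsupported", call. = FALSE)
    }
  }
  if (is.null(pixel_raw)) stop("DICOM file has no PixelData", call. = FALSE)
  if (is.null(tags[["00280010"]]) || is.null(tags[["00280011"]])) {
    stop("DICOM file lacks Rows/Columns", call. = FALSE)
  }
  nr <- read_uint16(tags[["00280010"]], 1L)
  nc <- read_uint16(tags[["00280011"]], 1L)
  if (length(pixel_raw) != 2L * nr * nc) {
    stop("PixelData length does not match Rows x Columns", call. = FALSE)
  }
  stored <- read_uint16(pixel_raw, seq(1L, length(pixel_raw), by = 2L))
  slope <- if (!is.null(tags[["00281053"]])) parse_ds(tags[["00281053"]]) else 1
  intercept <- if (!is.null(tags[["00281052"]])) {
    parse_ds(tags[["00281052"]])
  } else {
    0
  }
  px <- t(matrix(stored * slope + intercept, nc, nr))
  get_ds <- function(key) {
    if (is.null(tags[[key]])) NA_real_ else parse_ds(tags[[key]])[1]
  }
  desc <- if (is.null(tags[["0008103E"]])) "" else raw_to_str(tags[["0008103E"]])
  modality <- if (desc %in% c("IR", "SPGR")) desc else "other"
  spacing <- if (is.null(tags[["00280030"]])) {
    c(1, 1)
  } else {
    parse_ds(tags[["00280030"]])
  }
  image2d(px, modality,
          tr = get_ds("00180080"), te = get_ds("00180081"),
          fa = get_ds("00181314"), ti = get_ds("00180082"),
          pixel_spacing = spacing)
}

#' Window an image to 8 bits by min-max scaling
#'
#' Linear min-to-0, max-to-255 windowing. A constant image maps to all
#' zeros with a warning.
#'
#' @param pixels numeric matrix.
#' @return Integer matrix with values in `0..255`.
#' @export
window_minmax <- function(pixels) {
  lo <- min(pixels)
  hi <- max(pixels)
  if (hi == lo) {
    warning("constant image; windowed output is all zeros")
    return(matrix(0L, nrow(pixels), ncol(pixels)))
  }
  matrix(as.integer(round((pixels - lo) / (hi - lo) * 255)),
         nrow(pixels), ncol(pixels))
}

#' Convert a DICOM slice to an 8-bit grayscale JPEG
#'
#' Reads the slice, applies min-max windowing to `0..255` and writes a
#' grayscale JPEG at maximum quality (lossless-leaning; residual JPEG
#' quantization error remains).
#'
#' @param path_in DICOM input path.
#' @param path_out JPEG output path.
#' @param quality JPEG quality in (0, 1], default 1.
#' @return `path_out`, invisibly.
#' @export
dicom_to_jpeg <- function(path_in, path_out, quality = 1) {
  image <- read_dicom_slice(path_in)
  u8 <- window_minmax(image$pixels)
  jpeg::writeJPEG(u8 / 255, target = path_out, quality = quality)
  invisible(path_out)
}

#' Read a two-column rater measurement table
#'
#' Accepts csv/tsv or xlsx sheets holding one qT1 column per rater (or per
#' session). Columns are identified by header name first (observer/rater
#' 1 and 2, or first/second session variants); if no headers match, the
#' first two numeric columns are used with a warning. Values must be
#' positive with no gaps; offending rows are reported.
#'
#' @param path file path (`.csv`, `.tsv`, `.txt` or `.xlsx`).
#' @param sheet xlsx sheet (default first).
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(
    ext,
    xlsx = ,
    xls = as.data.frame(readxl::read_excel(path, sheet = sheet)),
    tsv = utils::read.delim(path),
    utils::read.csv(path)
  )
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("measurement table is empty", call. = FALSE)
  }
  nm <- tolower(names(df))
  pat1 <- "obs(erver)?[._ ]?1|rater[._ ]?1|first|1st|session[._ ]?1|value1"
  pat2 <- "obs(erver)?[._ ]?2|rater[._ ]?2|second|2nd|session[._ ]?2|value2"
  i1 <- grep(pat1, nm)
  i2 <- grep(pat2, nm)
  if (length(i1) == 1L && length(i2) == 1L && i1 != i2) {
    c1 <- df[[i1]]
    c2 <- df[[i2]]
    labels <- names(df)[c(i1, i2)]
  } else {
    numcols <- which(vapply(df, is.numeric, TRUE))
    numcols <- setdiff(numcols, grep("subject|^id$|case", nm))
    if (length(numcols) < 2L) {
      stop("could not find two numeric measurement columns", call. = FALSE)
    }
    warning("no recognisable rater/session headers; using first two numeric columns")
    c1 <- df[[numcols[1]]]
    c2 <- df[[numcols[2]]]
    labels <- names(df)[numcols[1:2]]
  }
  isub <- grep("subject|^id$|case", nm)
  subject <- if (length(isub)) df[[isub[1]]] else seq_along(c1)
  tab <- measurement_table(c1, c2, subject = subject, labels = labels)
  message(sprintf("read_measurement_table: %d subjects from %s",
                  nrow(tab), basename(path)))
  tab
}

#' Write a measurement table as csv
#'
#' @param table a [measurement_table()].
#' @param path output csv path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  labels <- attr(table, "labels")
  out <- data.frame(subject = table$subject, table$value1, table$value2)
  names(out)[2:3] <- labels
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an ROI coordinate file
#'
#' JSON schema (0-based coordinates, x = column, y = row):
#' ```
#' {"seed": [x, y],
#'  "polygons": {"whole": {"x": [...], "y": [...]}, ...}}
#' ```
#' Either part may be absent. Polygons need at least 3 vertices; with
#' `shape` given, all coordinates (and the seed) must lie inside the
#' image bounds.
#'
#' @param path JSON file path.
#' @param shape optional `(rows, cols)` for bounds checking.
#' @return List with `seed` (length-2 numeric or `NULL`) and `polygons`
#'   (named list of [roi_polygon()]).
#' @export
read_roi_file <- function(path, shape = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- if (!is.null(raw$seed)) as.numeric(raw$seed) else NULL
  polys <- list()
  if (!is.null(raw$polygons)) {
    polys <- lapply(raw$polygons, function(p) {
      roi_polygon(as.numeric(p$x), as.numeric(p$y))
    })
  }
  if (!is.null(shape)) {
    nr <- shape[1]
    nc <- shape[2]
    for (nmp in names(polys)) {
      p <- polys[[nmp]]
      if (any(p$x < 0 | p$x > nc - 1 | p$y < 0 | p$y > nr - 1)) {
        stop(sprintf("polygon '%s' has out-of-bounds vertices", nmp),
             call. = FALSE)
      }
    }
    if (!is.null(seed) &&
        (seed[1] < 0 || seed[1] > nc - 1 || seed[2] < 0 ||
           seed[2] > nr - 1)) {
      stop("seed lies outside the image bounds", call. = FALSE)
    }
  }
  list(seed = seed, polygons = polys)
}

#' Write an ROI coordinate file
#'
#' @param roi list with optional `seed` and `polygons` (named list of
#'   [roi_polygon()]), as returned by [read_roi_file()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi_file <- function(roi, path) {
  out <- list()
  if (!is.null(roi$seed)) out$seed <- as.numeric(roi$seed)
  if (length(roi$polygons)) {
    out$polygons <- lapply(roi$polygons, function(p) {
      list(x = p$x, y = p$y)
    })
  }
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a binary mask as a PNG image
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, target = path)
  invisible(path)
}
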