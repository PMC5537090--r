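#' Radiograph objects
#'
#' A radiograph is a 2-D grid of non-negative integer intensities together
#' with its bit depth, the patient's sex and, when known, chronological age
#' and the reported bone-age class used as the training label.
#'
#' Pixel coordinates are 0-based in the external contract (row-major, origin
#' top-left); internally pixels are stored as a base R integer matrix whose
#' first dimension is the image row.
#'
#' @param pixels integer matrix of intensities, `height x width`.
#' @param bit_depth 8 or 16; all pixels must lie in `[0, 2^bit_depth - 1]`.
#' @param sex `"female"`, `"male"`, or `NA` when unknown.
#' @param chronological_age_years optional non-negative real.
#' @param bone_age_label optional integer bone-age class in 5..18.
#' @param source_id opaque identifier string.
#' @return an object of class `radiograph`.
#' @export
radiograph <- function(pixels, bit_depth = 8L, sex = NA_character_,
                       chronological_age_years = NULL,
                       bone_age_label = NULL, source_id = "") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    baa_stop("baa_geometry_error", "pixels must be a non-empty matrix")
  if (!bit_depth %in% c(8L, 16L))
    baa_stop("baa_format_error", "bit_depth must be 8 or 16")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > max_intensity(bit_depth)))
    baa_stop("baa_format_error",
             sprintf("pixel values must lie in [0, %d]", max_intensity(bit_depth)))
  if (any(abs(pixels - round(pixels)) > 1e-9))
    baa_stop("baa_format_error", "pixel values must be integers")
  storage.mode(pixels) <- "integer"
  if (!is.na(sex)) sex <- match.arg(sex, c("female", "male"))
  if (!is.null(bone_age_label)) {
    bone_age_label <- as.integer(bone_age_label)
    if (bone_age_label < 5L || bone_age_label > 18L)
      baa_stop("baa_out_of_cohort", "bone_age_label must lie in [5, 18]")
  }
  if (!is.null(chronological_age_years) && chronological_age_years < 0)
    baa_stop("baa_domain_error", "chronological age must be non-negative")
  structure(list(
    pixels = pixels, bit_depth = as.integer(bit_depth), sex = sex,
    chronological_age_years = chronological_age_years,
    bone_age_label = bone_age_label, source_id = source_id
  ), class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %dx%d, %d-bit, sex=%s%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              ifelse(is.na(x$sex), "?", x$sex),
              if (!is.null(x$bone_age_label))
                sprintf(", bone age %d y", x$bone_age_label) else "",
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

#' Read a radiograph from disk
#'
#' Supports 8/16-bit grayscale PNG and uncompressed monochrome DICOM
#' (implicit or explicit VR, little endian). For DICOM the photometric
#' interpretation is honored: `MONOCHROME1` images are inverted so that
#' higher stored values always mean brighter pixels.
#'
#' @param path file path.
#' @param ... metadata fields passed on to [radiograph()] (e.g. `sex`).
#' @return a [radiograph()].
#' @export
read_radiograph <- function(path, ...) {
  if (!file.exists(path))
    baa_stop("baa_format_error", sprintf("no such file: %s", path))
  magic <- readBin(path, "raw", n = 132L)
  if (length(magic) >= 8L &&
      identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    return(read_png_radiograph(path, ...))
  }
  if (length(magic) >= 132L &&
      identical(rawToChar(magic[129:132]), "DICM")) {
    return(read_dicom_radiograph(path, ...))
  }
  baa_stop("baa_format_error", "file is neither PNG nor DICOM")
}

read_png_radiograph <- function(path, ...) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!identical(info$color.type, "gray") || length(dim(img)) != 2L)
    baa_stop("baa_format_error", "PNG must be single-channel grayscale")
  depth <- as.integer(info$bit.depth)
  if (!depth %in% c(8L, 16L))
    baa_stop("baa_format_error", "PNG bit depth must be 8 or 16")
  px <- matrix(round(as.numeric(img) * max_intensity(depth)),
               nrow(img), ncol(img))
  radiograph(px, bit_depth = depth, ...)
}

#' Write a radiograph as a grayscale PNG
#'
#' 8-bit images go through `png::writePNG`; 16-bit images are encoded as
#' 16-bit grayscale PNG directly (IHDR/IDAT/IEND with zlib-compressed
#' scanlines) since `png::writePNG` only emits 8 bits per channel.
#'
#' @param r a [radiograph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(r, path) {
  stopifnot(inherits(r, "radiograph"))
  if (r$bit_depth == 8L) {
    png::writePNG(r$pixels / 255, path)
  } else {
    write_png16(r$pixels, path)
  }
  invisible(path)
}

# --- minimal 16-bit grayscale PNG encoder -------------------------------

# 32-bit XOR on doubles via 16-bit halves (values stay < 2^31 per half)
xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        cc <- n
        for (k in 1:8) {
          cc <- if (cc %% 2 == 1) xor32(cc %/% 2, 3988292384) else cc %/% 2
        }
        t[n + 1] <- cc
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  for (x in as.integer(bytes)) {
    idx <- bitwXor(as.integer(crc %% 256), x)
    crc <- xor32(crc %/% 256, tab[idx + 1])
  }
  xor32(crc, 4294967295)
}

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

write_png16 <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  # scanlines: filter byte 0 + big-endian uint16 samples, row by row
  m <- t(pixels)  # row-major order
  hi <- as.raw(m %/% 256L); lo <- as.raw(m %% 256L)
  samp <- as.raw(rbind(hi, lo))  # interleave big-endian byte pairs
  dim(samp) <- NULL
  rows <- matrix(samp, nrow = 2L * w)
  scan <- as.raw(rbind(rep(as.raw(0L), h), rows))
  dim(scan) <- NULL
  idat <- memCompress(scan, type = "gzip")
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
}

# --- minimal DICOM reader (uncompressed monochrome, little endian) ------

read_dicom_radiograph <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 132L)  # preamble + DICM, already validated
  rd_u16 <- function() readBin(con, "integer", size = 2L, endian = "little",
                               signed = FALSE)
  read_u32 <- function() {
    b <- readBin(con, "raw", n = 4L)
    sum(as.integer(b) * c(1, 256, 65536, 16777216))
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  fields <- list()
  transfer <- "1.2.840.10008.1.2.1"
  explicit <- TRUE
  repeat {
    grp_raw <- readBin(con, "raw", n = 2L)
    if (length(grp_raw) < 2L) break
    grp <- sum(as.integer(grp_raw) * c(1, 256))
    ele <- rd_u16()
    meta <- grp == 2L
    exp_here <- meta || explicit
    if (exp_here) {
      vr <- rawToChar(readBin(con, "raw", n = 2L))
      if (vr %in% long_vrs) {
        readBin(con, "raw", n = 2L)
        len <- read_u32()
      } else len <- rd_u16()
    } else {
      vr <- ""
      len <- read_u32()
    }
    if (len >= 4294967295)
      baa_stop("baa_format_error", "undefined-length DICOM elements unsupported")
    val <- readBin(con, "raw", n = len)
    key <- sprintf("%04x,%04x", grp, ele)
    fields[[key]] <- val
    if (key == "0002,0010") {
      transfer <- rawToChar(val[val != as.raw(0)])
      transfer <- sub("\\s+$", "", transfer)
      if (transfer == "1.2.840.10008.1.2") explicit <- FALSE
      else if (transfer != "1.2.840.10008.1.2.1")
        baa_stop("baa_format_error",
                 sprintf("unsupported DICOM transfer syntax %s", transfer))
    }
    if (key == "7fe0,0010") break
  }
  need <- function(key, what) {
    if (is.null(fields[[key]]))
      baa_stop("baa_format_error", sprintf("DICOM missing %s", what))
    fields[[key]]
  }
  as_u16 <- function(v) sum(as.integer(v[1:2]) * c(1, 256))
  rows <- as_u16(need("0028,0010", "Rows"))
  cols <- as_u16(need("0028,0011", "Columns"))
  bits <- as_u16(need("0028,0100", "BitsAllocated"))
  stored <- if (!is.null(fields[["0028,0101"]]))
    as_u16(fields[["0028,0101"]]) else bits
  photometric <- sub("\\s+$", "", rawToChar(need("0028,0004",
                                                 "PhotometricInterpretation")))
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    baa_stop("baa_format_error", "only monochrome DICOM is supported")
  px_raw <- need("7fe0,0010", "PixelData")
  if (bits == 8L) {
    v <- as.integer(px_raw)
    depth <- 8L
  } else if (bits == 16L) {
    v <- readBin(px_raw, "integer", n = length(px_raw) %/% 2L, size = 2L,
                 endian = "little", signed = FALSE)
    depth <- if (stored <= 8L) 8L else 16L
  } else baa_stop("baa_format_error", "BitsAllocated must be 8 or 16")
  if (length(v) < rows * cols)
    baa_stop("baa_format_error", "truncated DICOM pixel data")
  v <- v[seq_len(rows * cols)]
  maxv <- max_intensity(depth)
  v <- clip(v, 0L, maxv)
  if (photometric == "MONOCHROME1") v <- maxv - v
  # DICOM pixel data is row-major
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  radiograph(px, bit_depth = depth, ...)
}
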