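# Minimal DICOM (Explicit VR Little Endian) reader/writer.
#
# Covers the subset of the standard needed for RT Dose, RT Structure Set
# and RT Plan objects: flat elements of the common VRs, nested sequences
# (defined and undefined lengths), and uncompressed 16-bit pixel data.
# Datasets are represented as named lists keyed by "GGGG,EEEE" (uppercase
# hex); each element is list(vr =, value =). Sequence values are lists of
# item datasets.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

UID_RT_DOSE   <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RT_STRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RT_PLAN   <- "1.2.840.10008.5.1.4.1.1.481.5"

.STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                 "ST", "TM", "UI", "UT")
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.tag_key <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

.u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

.u32 <- function(bytes, pos) {
  # as double: lengths can exceed .Machine$integer.max representation issues
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}

.parse_value <- function(vr, bytes) {
  if (vr %in% .STRING_VRS) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    return(strsplit(s, "\\", fixed = TRUE)[[1]])
  }
  switch(vr,
    DS = ,
    IS = {
      s <- rawToChar(bytes[bytes != as.raw(0L)])
      as.numeric(strsplit(trimws(s), "\\", fixed = TRUE)[[1]])
    },
    US = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) / 8L, size = 8L,
                 endian = "little"),
    bytes  # OB/OW/OF/UN: raw
  )
}

# Parse one dataset from `bytes` starting at `pos` (1-based), stopping at
# `end` (exclusive) or at an item-delimitation tag when `stop_at_delim`.
# Returns list(elements = named list, pos = next position).
.parse_dataset <- function(bytes, pos, end, stop_at_delim = FALSE) {
  elements <- list()
  while (pos < end) {
    group <- .u16(bytes, pos)
    element <- .u16(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {
      len <- .u32(bytes, pos)
      pos <- pos + 4L
      if (element == 0xE00D || element == 0xE0DD) {  # item/sequence delimiter
        if (stop_at_delim) return(list(elements = elements, pos = pos))
        next
      }
      stop("unexpected item tag outside a sequence")
    }
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (vr %in% .LONG_VRS) {
      len <- .u32(bytes, pos + 4L)
      pos <- pos + 8L
    } else {
      len <- .u16(bytes, pos + 2L)
      pos <- pos + 4L
    }
    key <- .tag_key(group, element)
    if (vr == "SQ") {
      parsed <- .parse_sequence(bytes, pos, len)
      elements[[key]] <- list(vr = "SQ", value = parsed$items)
      pos <- parsed$pos
    } else if (len == 4294967295) {
      stop("undefined length is only supported for sequences (tag ", key, ")")
    } else {
      value <- if (len > 0) {
        .parse_value(vr, bytes[pos:(pos + len - 1L)])
      } else {
        .parse_value(vr, raw(0))
      }
      elements[[key]] <- list(vr = vr, value = value)
      pos <- pos + len
    }
  }
  list(elements = elements, pos = pos)
}

.parse_sequence <- function(bytes, pos, len) {
  undefined <- (len == 4294967295)
  end <- if (undefined) length(bytes) + 1L else pos + len
  items <- list()
  while (pos < end) {
    group <- .u16(bytes, pos)
    element <- .u16(bytes, pos + 2L)
    ilen <- .u32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break      # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence: expected an item tag")
    }
    if (ilen == 4294967295) {
      parsed <- .parse_dataset(bytes, pos, length(bytes) + 1L,
                               stop_at_delim = TRUE)
    } else {
      parsed <- .parse_dataset(bytes, pos, pos + ilen)
    }
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$pos
  }
  list(items = items, pos = pos)
}

#' Read a DICOM file
#'
#' Parses a DICOM Part-10 file (Explicit VR Little Endian transfer syntax)
#' into a named list of data elements keyed by `"GGGG,EEEE"`.
#'
#' @param path path to a DICOM file.
#' @return an object of class `dicom`: a named element list with the file
#'   meta information in `attr(, "meta")`.
#' @export
dcm_read <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132L ||
      !identical(rawToChar(bytes[129:132]), "DICM")) {
    stop("not a DICOM file: ", path)
  }
  pos <- 133L
  # file meta group (always explicit VR little endian)
  meta <- list()
  repeat {
    if (pos + 3L > length(bytes) || .u16(bytes, pos) != 0x0002) break
    group <- .u16(bytes, pos); element <- .u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .u32(bytes, pos + 8L); hdr <- 12L
    } else {
      len <- .u16(bytes, pos + 6L); hdr <- 8L
    }
    val <- if (len > 0) {
      .parse_value(vr, bytes[(pos + hdr):(pos + hdr + len - 1L)])
    } else .parse_value(vr, raw(0))
    meta[[.tag_key(group, element)]] <- list(vr = vr, value = val)
    pos <- pos + hdr + len
  }
  ts <- meta[["0002,0010"]]$value
  if (!is.null(ts) && !identical(ts, TS_EXPLICIT_LE)) {
    stop("unsupported transfer syntax ", ts, " in ", path,
         " (only Explicit VR Little Endian is supported)")
  }
  ds <- .parse_dataset(bytes, pos, length(bytes) + 1L)$elements
  structure(ds, meta = meta, class = "dicom")
}

#' @rdname dcm_read
#' @param ds a parsed `dicom` object (or any dataset list from it).
#' @param tag element tag as `"GGGG,EEEE"`.
#' @param default value returned when the element is absent.
#' @export
dcm_get <- function(ds, tag, default = NULL) {
  el <- ds[[toupper(tag)]]
  if (is.null(el)) default else el$value
}

# ---- writer ----------------------------------------------------------------

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.fmt_ds <- function(x) {
  # decimal string, max 16 bytes per value
  s <- formatC(x, digits = 10, format = "g", width = 1)
  s <- trimws(s)
  long <- nchar(s) > 16L
  if (any(long)) s[long] <- trimws(formatC(x[long], digits = 8, format = "g"))
  s
}

.enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little")
.enc_u32 <- function(x) {
  x <- as.numeric(x)
  b <- integer(4)
  for (i in 1:4) { b[i] <- x %% 256; x <- x %/% 256 }
  as.raw(b)
}

.enc_value <- function(vr, value) {
  if (vr %in% c("UI")) {
    return(.pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0L)))
  }
  if (vr %in% .STRING_VRS) {
    return(.pad_even(charToRaw(paste(value, collapse = "\\"))))
  }
  switch(vr,
    DS = .pad_even(charToRaw(paste(.fmt_ds(value), collapse = "\\"))),
    IS = .pad_even(charToRaw(paste(as.character(as.integer(value)),
                                   collapse = "\\"))),
    US = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = do.call(c, lapply(value, .enc_u32)),
    FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
    OW = ,
    OB = as.raw(value),
    stop("unsupported VR for writing: ", vr)
  )
}

.enc_element <- function(group, element, vr, value) {
  head <- c(.enc_u16(group), .enc_u16(element), charToRaw(vr))
  if (vr == "SQ") {
    body <- do.call(c, c(list(raw(0)), lapply(value, function(item) {
      content <- .enc_dataset(item)
      c(.enc_u16(0xFFFE), .enc_u16(0xE000), .enc_u32(length(content)), content)
    })))
    return(c(head, as.raw(c(0L, 0L)), .enc_u32(length(body)), body))
  }
  body <- .enc_value(vr, value)
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), .enc_u32(length(body)), body)
  } else {
    c(head, .enc_u16(length(body)), body)
  }
}

# elements: named list keyed "GGGG,EEEE" of list(vr =, value =); written in
# ascending tag order as the standard requires.
.enc_dataset <- function(elements) {
  keys <- names(elements)
  ord <- order(keys)
  chunks <- lapply(keys[ord], function(k) {
    group <- strtoi(substr(k, 1, 4), 16L)
    element <- strtoi(substr(k, 6, 9), 16L)
    .enc_element(group, element, elements[[k]]$vr, elements[[k]]$value)
  })
  do.call(c, c(list(raw(0)), chunks))
}

#' Write a DICOM file
#'
#' Serialises a dataset (as produced for the synthetic phantom bundle) to a
#' DICOM Part-10 file in Explicit VR Little Endian transfer syntax.
#'
#' @param elements named element list keyed `"GGGG,EEEE"`, each element
#'   `list(vr =, value =)`.
#' @param path output file path.
#' @param sop_class_uid,sop_instance_uid media storage identifiers for the
#'   file meta group.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(elements, path, sop_class_uid, sop_instance_uid) {
  meta <- list(
    "0002,0001" = list(vr = "OB", value = as.raw(c(0L, 1L))),
    "0002,0002" = list(vr = "UI", value = sop_class_uid),
    "0002,0003" = list(vr = "UI", value = sop_instance_uid),
    "0002,0010" = list(vr = "UI", value = TS_EXPLICIT_LE),
    "0002,0012" = list(vr = "UI", value = "1.2.826.0.1.3680043.10.1448.1")
  )
  meta_body <- .enc_dataset(meta)
  meta_all <- c(.enc_element(0x0002, 0x0000, "UL", length(meta_body)),
                meta_body)
  out <- c(raw(128L), charToRaw("DICM"), meta_all, .enc_dataset(elements))
  writeBin(out, path)
  invisible(path)
}
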