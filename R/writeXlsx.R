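# Minimal XLSX (ECMA-376 / OOXML spreadsheet) writer.
#
# Writes a workbook of data.frames as an uncompressed ("stored") zip of
# hand-assembled XML parts, using inline strings so no shared-string table
# is needed. Covers exactly what the measurement export requires: numeric,
# logical and character cells with a header row. Readable by Excel,
# LibreOffice and openpyxl.

# CRC-32 (polynomial 0xEDB88320, as used by zip). Table-driven; the crc
# accumulator lives in a signed 32-bit integer (R's bitw* ops treat it as
# unsigned) and is converted to a non-negative double at the end.
.crc32Env <- new.env(parent = emptyenv())

crc32Table <- function() {
  if (is.null(.crc32Env$table)) {
    tab <- integer(256)
    for (b in 0:255) {
      c <- b
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L)
          bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
        else bitwShiftR(c, 1L)
      }
      tab[b + 1L] <- c
    }
    .crc32Env$table <- tab
  }
  .crc32Env$table
}

crc32 <- function(raw) {
  tab <- crc32Table()
  crc <- -1L
  for (byte in as.integer(raw)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, byte), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.double(crc)
}

int2le <- function(x, bytes) {
  # little-endian unsigned integer as raw
  out <- raw(bytes)
  x <- as.double(x)
  for (i in seq_len(bytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# Store named character (XML) entries into a zip file, no compression.
writeStoredZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  sizes <- numeric(length(entries))
  datas <- lapply(entries, charToRaw)
  names <- names(entries)
  pos <- 0
  dosTime <- int2le(0, 2); dosDate <- int2le(33, 2)  # fixed timestamp
  for (i in seq_along(entries)) {
    dat <- datas[[i]]
    nm <- charToRaw(names[i])
    crcs[i] <- crc32(dat)
    sizes[i] <- length(dat)
    offsets[i] <- pos
    hdr <- c(int2le(0x04034b50, 4), int2le(20, 2), int2le(0, 2),
             int2le(0, 2), dosTime, dosDate, int2le(crcs[i], 4),
             int2le(sizes[i], 4), int2le(sizes[i], 4),
             int2le(length(nm), 2), int2le(0, 2), nm)
    writeBin(hdr, con)
    writeBin(dat, con)
    pos <- pos + length(hdr) + length(dat)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    nm <- charToRaw(names[i])
    cd <- c(int2le(0x02014b50, 4), int2le(20, 2), int2le(20, 2),
            int2le(0, 2), int2le(0, 2), dosTime, dosDate,
            int2le(crcs[i], 4), int2le(sizes[i], 4), int2le(sizes[i], 4),
            int2le(length(nm), 2), int2le(0, 2), int2le(0, 2),
            int2le(0, 2), int2le(0, 2), int2le(0, 4),
            int2le(offsets[i], 4), nm)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(int2le(0x06054b50, 4), int2le(0, 2), int2le(0, 2),
            int2le(length(entries), 2), int2le(length(entries), 2),
            int2le(pos - cdStart, 4), int2le(cdStart, 4), int2le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

colRef <- function(j) {
  # 1 -> A, 27 -> AA
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

sheetXml <- function(df, digits = 6) {
  ncol <- length(df)
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_len(ncol), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            colRef(j), xmlEscape(names(df)[j])), character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  if (nrow(df)) {
    cells <- matrix("", nrow(df), ncol)
    for (j in seq_len(ncol)) {
      v <- df[[j]]
      ref <- paste0(colRef(j), seq_len(nrow(df)) + 1L)
      if (is.logical(v)) {
        cells[, j] <- sprintf('<c r="%s" t="b"><v>%d</v></c>', ref,
                              as.integer(v))
      } else if (is.integer(v)) {
        cells[, j] <- ifelse(is.na(v), sprintf('<c r="%s"/>', ref),
                             sprintf('<c r="%s"><v>%d</v></c>', ref, v))
      } else if (is.numeric(v)) {
        val <- sprintf(paste0("%.", digits, "f"), v)
        cells[, j] <- ifelse(is.na(v), sprintf('<c r="%s"/>', ref),
                             sprintf('<c r="%s"><v>%s</v></c>', ref, val))
      } else {
        cells[, j] <- sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                              ref, xmlEscape(as.character(v)))
      }
    }
    for (i in seq_len(nrow(df)))
      rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                              paste(cells[i, ], collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write data frames to an XLSX workbook
#'
#' Self-contained XLSX writer used for the per-video measurement export.
#' Each element of `sheets` becomes one worksheet; columns may be numeric,
#' logical or character. Numbers are serialised with `digits` significant
#' decimal digits.
#'
#' @param sheets named list of data.frames.
#' @param path output `.xlsx` path.
#' @param digits decimal digits for numeric cells.
#' @return Invisibly, `path`.
#' @export
writeXlsx <- function(sheets, path, digits = 6) {
  stopifnot(is.list(sheets), length(sheets) >= 1L,
            !is.null(names(sheets)), all(nzchar(names(sheets))))
  n <- length(sheets)
  sheetEntries <- stats::setNames(
    lapply(sheets, sheetXml, digits = digits),
    sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  sheetTags <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xmlEscape(names(sheets)), seq_len(n), seq_len(n)), collapse = "")
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheetTags, '</sheets></workbook>')
  wbRels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf(paste0(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/',
      'officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>'),
      seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>')
  rootRels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
  contentTypes <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType=',
    '"application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf(paste0(
      '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
      '"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>'),
      seq_len(n)), collapse = ""),
    '</Types>')
  entries <- c(
    stats::setNames(list(contentTypes), "[Content_Types].xml"),
    stats::setNames(list(rootRels), "_rels/.rels"),
    stats::setNames(list(workbook), "xl/workbook.xml"),
    stats::setNames(list(wbRels), "xl/_rels/workbook.xml.rels"),
    sheetEntries)
  writeStoredZip(entries, path)
  invisible(path)
}
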