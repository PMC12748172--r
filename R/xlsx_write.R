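# Minimal xlsx writer (single sheet, inline strings, stored-entry zip).
#
# No xlsx-writing package ships with this environment, so label tables are
# written as a hand-assembled Office Open XML workbook: a zip container with
# uncompressed ("stored") entries and a worksheet using inline strings.
# Deliberately tiny: enough for a rectangular character table, readable by
# readxl and spreadsheet applications.

.u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.u32 <- function(x) as.raw((floor(x / 256^(0:3))) %% 256)

.crc32 <- function(content) {
  hex <- digest::digest(content, algo = "crc32", serialize = FALSE)
  # parse the 8-digit hex as a number without integer overflow
  digits <- strtoi(strsplit(tolower(hex), "")[[1]], 16L)
  Reduce(function(a, b) a * 16 + b, digits, accumulate = FALSE)
}

# write a zip archive with stored (uncompressed) entries
.zip_store <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  central <- raw(0)
  pos <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crc <- .crc32(data)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .u16(20), .u16(0),
                   .u16(0), .u16(0), .u16(0x21), .u32(crc),
                   .u32(length(data)), .u32(length(data)),
                   .u16(length(name)), .u16(0), name)
    offsets[i] <- pos
    writeBin(local_hdr, con)
    writeBin(data, con)
    pos <- pos + length(local_hdr) + length(data)
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)), .u16(20), .u16(20),
                 .u16(0), .u16(0), .u16(0), .u16(0x21), .u32(crc),
                 .u32(length(data)), .u32(length(data)),
                 .u16(length(name)), .u16(0), .u16(0), .u16(0), .u16(0),
                 .u32(0), .u32(offsets[i]), name)
  }
  writeBin(central, con)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .u16(0), .u16(0),
             .u16(length(entries)), .u16(length(entries)),
             .u32(length(central)), .u32(pos), .u16(0)), con)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

# df: data.frame of character columns; header row written first
write_minimal_xlsx <- function(df, path) {
  rows <- rbind(names(df), as.matrix(df))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    cells <- vapply(seq_len(ncol(rows)), function(j) {
      sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              .col_letter(j), i, .xml_escape(rows[i, j]))
    }, character(1))
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, character(1))
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(body, collapse = ""), '</sheetData></worksheet>')
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="labels" sheetId="1" r:id="rId1"/></sheets></workbook>')
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>')
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>')
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ',
    'ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>')
  entries <- list(
    "[Content_Types].xml" = charToRaw(content_types),
    "_rels/.rels" = charToRaw(root_rels),
    "xl/workbook.xml" = charToRaw(workbook),
    "xl/_rels/workbook.xml.rels" = charToRaw(wb_rels),
    "xl/worksheets/sheet1.xml" = charToRaw(sheet))
  .zip_store(path, entries)
}
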