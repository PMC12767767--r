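# Minimal XLSX (SpreadsheetML) writer for the measurement-workbook dialect.
# Writes each data frame as one worksheet; strings go as inline strings, numbers
# as full-precision <v> cells (%.17g round-trips IEEE doubles exactly). Only the
# parts of the format a reader needs are emitted.

.xlsx_col_letter <- function(j) {
  s <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]
    l <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      l <- paste0(LETTERS[r + 1], l)
      n <- (n - 1) %/% 26
    }
    s[i] <- l
  }
  s
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.xlsx_cell <- function(ref, value) {
  if (is.na(value)) return("")
  if (is.numeric(value)) {
    sprintf('<c r="%s"><v>%s</v></c>', ref, sprintf("%.17g", value))
  } else {
    sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
            ref, .xml_escape(as.character(value)))
  }
}

.xlsx_sheet_xml <- function(df) {
  cols <- .xlsx_col_letter(seq_len(ncol(df)))
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_len(ncol(df)), function(j) {
    .xlsx_cell(paste0(cols[j], 1L), names(df)[j])
  }, character(1))
  rows[1L] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_len(ncol(df)), function(j) {
      .xlsx_cell(paste0(cols[j], i + 1L), df[[j]][i])
    }, character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

# sheets: named list of data frames, written in order under their names.
write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L, !is.null(names(sheets)))
  dir <- tempfile("xlsx")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  n <- length(sheets)
  idx <- seq_len(n)

  overrides <- sprintf(paste0(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>'), idx)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(overrides, collapse = ""), '</Types>'),
    file.path(dir, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/',
    '2006/relationships/officeDocument" Target="xl/workbook.xml"/></Relationships>'),
    file.path(dir, "_rels", ".rels"))

  sheet_entries <- sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                           .xml_escape(names(sheets)), idx, idx)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', paste(sheet_entries, collapse = ""), '</sheets></workbook>'),
    file.path(dir, "xl", "workbook.xml"))

  rels <- sprintf(paste0(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/',
    '2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>'), idx, idx)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(rels, collapse = ""), '</Relationships>'),
    file.path(dir, "xl", "_rels", "workbook.xml.rels"))

  for (i in idx) {
    writeLines(.xlsx_sheet_xml(sheets[[i]]),
               file.path(dir, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }

  path <- normalizePath(path, mustWork = FALSE)
  if (file.exists(path)) unlink(path)
  zip::zip(path,
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels",
                     sprintf("xl/worksheets/sheet%d.xml", idx)),
           root = dir, mode = "mirror")
  unlink(dir, recursive = TRUE)
  invisible(path)
}
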