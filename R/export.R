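# Minimal xlsx writer (no xlsx-writing package ships with the stack).
# An xlsx file is a zip of XML parts; sheets use inline strings for text
# and plain numbers otherwise, which readxl reads back losslessly.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

sheet_xml <- function(df) {
  header <- names(df)
  rows <- character(nrow(df) + 1)
  cell <- function(ref, v) {
    if (is.na(v)) return(sprintf('<c r="%s"/>', ref))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && is.numeric(v))
      sprintf('<c r="%s"><v>%s</v></c>', ref,
              format(num, digits = 15, scientific = FALSE))
    else
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
              xml_escape(as.character(v)))
  }
  rows[1] <- paste0('<row r="1">',
                    paste(vapply(seq_along(header), function(j)
                      cell(paste0(col_letter(j), 1), header[j]),
                      character(1)), collapse = ""),
                    "</row>")
  for (i in seq_len(nrow(df))) {
    rows[i + 1] <- paste0(sprintf('<row r="%d">', i + 1),
                          paste(vapply(seq_along(df), function(j)
                            cell(paste0(col_letter(j), i + 1), df[[j]][i]),
                            character(1)), collapse = ""),
                          "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write data frames to a minimal Excel workbook
#'
#' Writes one worksheet per element of `sheets`.  Text cells are stored
#' as inline strings, numeric cells as numbers; the output is readable
#' by standard spreadsheet software and by `readxl`.
#'
#' @param sheets Named list of data frames.
#' @param path Output `.xlsx` path.
#' @return Invisibly, `path`.
#' @export
write_xlsx_workbook <- function(sheets, path) {
  if (is.data.frame(sheets)) sheets <- list(Sheet1 = sheets)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets))))
    abort_input("every sheet needs a name")
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE))
  ns <- length(sheets)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(ns)), collapse = ""),
    "</Types>"), file.path(tmp, "[Content_Types].xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"), file.path(tmp, "_rels", ".rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(ns), seq_len(ns)),
          collapse = ""),
    "</sheets></workbook>"), file.path(tmp, "xl", "workbook.xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(ns), seq_len(ns)), collapse = ""),
    "</Relationships>"), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  for (k in seq_len(ns))
    writeLines(sheet_xml(as.data.frame(sheets[[k]])),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", k)))
  zip::zip(zipfile = path.expand(path), files = list.files(tmp),
           root = tmp, mode = "cherry-pick")
  invisible(path)
}

feature_table <- function(matrix) {
  keep <- colSums(matrix$values != 0) > 0   # drop excluded (all-zero) buckets
  vals <- matrix$values[, keep, drop = FALSE]
  ppm <- matrix$feature_ppm[keep]
  df <- data.frame(Sample = paste0("sample_", seq_len(nrow(vals))),
                   Class = matrix$class_labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(`colnames<-`(vals, sprintf("%.4f", ppm)),
                          check.names = FALSE))
}

#' Export a feature matrix for statistical analysis
#'
#' `"metaboanalyst"` writes a samples-in-rows CSV whose first row is
#' `Sample,Class,<ppm labels>` with ppm labels at 4 decimals in
#' descending order -- directly importable into MetaboAnalyst.
#' `"excel"` writes the same table as the first worksheet of an Excel
#' workbook, plus one worksheet per multiplet analysis supplied.
#' Buckets that are zero in every sample (excluded regions) are dropped.
#'
#' @param matrix A [feature_matrix].
#' @param format `"metaboanalyst"` or `"excel"`.
#' @param path Output file path.
#' @param multiplet_fits Optional named list of data frames (one per
#'   analysed metabolite) appended as extra worksheets of the Excel
#'   workbook.
#' @return Invisibly, `path`.
#' @export
export_statistics <- function(matrix, format = c("metaboanalyst", "excel"),
                              path, multiplet_fits = NULL) {
  format <- match.arg(format)
  if (!inherits(matrix, "feature_matrix"))
    abort_input("matrix must be a feature_matrix")
  if (nrow(matrix$values) == 0 || ncol(matrix$values) == 0)
    abort_input("cannot export an empty matrix")
  df <- feature_table(matrix)
  if (format == "metaboanalyst") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    sheets <- c(list(features = df), multiplet_fits)
    write_xlsx_workbook(sheets, path)
  }
  invisible(path)
}
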