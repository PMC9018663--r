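# NIST-style MSP text format: the interchange format for voltage-resolved
# spectral libraries. One entry per (compound, cone voltage), named
# "<abbr>@<V>V", with machine-readable Comment fields, so files stay valid
# for generic MSP readers that know nothing about multi-channel libraries.

#' MSP entry
#'
#' @param name Entry name, unique within a file (here `"<abbr>@<V>V"`).
#' @param comment_fields Named character vector; must include `Compound`
#'   (abbreviation) and `ConeVoltage` (e.g. `"12V"`).
#' @param mz,intensity Peak list vectors.
#' @return An `msp_entry` list.
#' @export
msp_entry <- function(name, comment_fields, mz, intensity) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  comment_fields <- vapply(comment_fields, as.character, character(1))
  if (!all(c("Compound", "ConeVoltage") %in% names(comment_fields))) {
    stop("comment_fields must include Compound and ConeVoltage")
  }
  structure(
    list(name = name, comment_fields = comment_fields,
         num_peaks = length(mz),
         peaks = data.frame(mz = as.numeric(mz),
                            intensity = as.numeric(intensity))),
    class = "msp_entry"
  )
}

entry_voltage <- function(e) {
  as.integer(sub("V$", "", e$comment_fields[["ConeVoltage"]]))
}

format_peak_num <- function(x) {
  # integers print without decimals; anything else with up to 4 decimals,
  # trailing zeros trimmed -- fixed formatting keeps serialization
  # byte-deterministic
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.4f", x)))
}

#' Write entries to an MSP document
#'
#' NIST dialect: a `Name:` line, a `Comment:` line with `;`-separated
#' `key=value` fields, a `Num Peaks:` line, then one `mz intensity` pair per
#' line, entries separated by a blank line. Serialization is deterministic:
#' the same entries always produce byte-identical output.
#'
#' @param entries List of [msp_entry()].
#' @param path Output file path, or `NULL` to return the text.
#' @param eol Line separator, default `"\n"`.
#' @return The document as a single string, invisibly when writing.
#' @export
write_msp <- function(entries, path = NULL, eol = "\n") {
  nms <- vapply(entries, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0) {
    stop("duplicate entry names: ", paste(dup, collapse = ", "))
  }
  blocks <- vapply(entries, function(e) {
    comment <- paste(names(e$comment_fields), e$comment_fields,
                     sep = "=", collapse = "; ")
    paste0(
      "Name: ", e$name, eol,
      "Comment: ", comment, eol,
      "Num Peaks: ", e$num_peaks, eol,
      paste0(format_peak_num(e$peaks$mz), " ",
             format_peak_num(e$peaks$intensity), eol, collapse = "")
    )
  }, character(1))
  doc <- paste0(blocks, collapse = eol)
  if (is.null(path)) return(doc)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(doc, con, eos = NULL)
  invisible(doc)
}

#' Read an MSP document
#'
#' Tolerant of Windows and Unix line endings and of `;`- or `=`-separated
#' comment fields. `read_msp(write_msp(E))` reproduces `E` field for field.
#'
#' @param path File path, or a single string containing the document when
#'   `text = TRUE`.
#' @param text Logical; treat `path` as document text.
#' @return List of [msp_entry()].
#' @export
read_msp <- function(path, text = FALSE) {
  lines <- if (text) strsplit(path, "\r?\n")[[1]] else readLines(path)
  lines <- sub("\r$", "", lines)
  starts <- grep("^Name:", lines)
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1, length(lines))
  mapply(function(from, to) parse_msp_block(lines[from:to]),
         starts, ends, SIMPLIFY = FALSE)
}

parse_msp_block <- function(block) {
  name <- trimws(sub("^Name:", "", block[1]))
  cmt <- grep("^Comment:", block, value = TRUE)
  fields <- character(0)
  if (length(cmt) > 0) {
    body <- trimws(sub("^Comment:", "", cmt[1]))
    parts <- trimws(strsplit(body, ";")[[1]])
    parts <- parts[nzchar(parts)]
    kv <- regmatches(parts, regexec("^([^=]+?)\\s*=\\s*(.*)$", parts))
    ok <- lengths(kv) == 3
    fields <- vapply(kv[ok], `[`, character(1), 3)
    names(fields) <- vapply(kv[ok], `[`, character(1), 2)
  }
  if (!"ConeVoltage" %in% names(fields)) {
    stop("entry '", name, "': missing ConeVoltage comment field")
  }
  np_line <- grep("^Num Peaks:", block)
  if (length(np_line) == 0) stop("entry '", name, "': missing Num Peaks")
  declared <- as.integer(trimws(sub("^Num Peaks:", "", block[np_line[1]])))
  peak_lines <- block[seq(np_line[1] + 1, length.out = length(block) - np_line[1])]
  peak_lines <- trimws(peak_lines)
  peak_lines <- peak_lines[nzchar(peak_lines)]
  pairs <- strsplit(peak_lines, "[[:space:]]+")
  if (any(lengths(pairs) < 2)) {
    stop("entry '", name, "': malformed peak line")
  }
  mz <- as.numeric(vapply(pairs, `[`, character(1), 1))
  intensity <- as.numeric(vapply(pairs, `[`, character(1), 2))
  if (length(mz) != declared) {
    stop(sprintf("entry '%s': Num Peaks is %d but %d pairs found",
                 name, declared, length(mz)))
  }
  msp_entry(name, fields, mz, intensity)
}
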