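# Plain-text interchange for glycan structure lists.

#' Read a glycan structure list
#'
#' One IUPAC-condensed string per line, UTF-8; `#` starts a comment; an
#' optional tab-separated second column names the structure (defaults to the
#' canonical string).
#'
#' @param path file path.
#' @return Named list of [glycan_structure()].
#' @export
read_glycan_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no glycan strings in ", path)
  parts <- strsplit(lines, "\t")
  structs <- lapply(parts, function(p) parse_iupac(p[1]))
  nm <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2 && nzchar(parts[[i]][2])) parts[[i]][2]
    else write_iupac(structs[[i]])
  }, character(1))
  stats::setNames(structs, make.unique(nm, sep = "#"))
}

#' Write a glycan structure list
#'
#' @param structures named list of [glycan_structure()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_glycan_list <- function(structures, path) {
  lines <- vapply(seq_along(structures), function(i) {
    paste(write_iupac(structures[[i]]), names(structures)[i], sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
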