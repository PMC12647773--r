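# Samples x features relative-abundance container shared by the glycomics and
# metabolomics sides of the pipeline.

#' Construct an abundance table
#'
#' A samples x features matrix of non-negative relative abundances plus the
#' per-sample metadata the longitudinal design needs (individual label and
#' lactation day). Rows are expected to be compositions: percentages summing
#' to 100 (or proportions summing to 1).
#'
#' @param abund numeric matrix, samples in rows, features in columns; row and
#'   column names required. Missing values allowed (imputed downstream).
#' @param individual character/factor of length nrow(abund).
#' @param day numeric lactation day of length nrow(abund).
#' @param normalize if TRUE (default), rows are re-closed to the nominal
#'   total, with a warning for rows whose sum deviated noticeably; if FALSE,
#'   a row deviating by more than `tol` is an error.
#' @param tol maximum accepted closure deviation, in percent of the total
#'   (default 0.5).
#' @return An object of class `abundance_table` with elements `abund`,
#'   `meta` (data.frame: sample_id, individual, day).
#' @export
abundance_table <- function(abund, individual, day, normalize = TRUE, tol = 0.5) {
  stopifnot(is.matrix(abund), is.numeric(abund))
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("abundance matrix needs row (sample) and column (feature) names")
  if (anyDuplicated(rownames(abund)))
    stop("duplicate sample_id: ",
         paste(unique(rownames(abund)[duplicated(rownames(abund))]), collapse = ", "))
  if (any(abund < 0, na.rm = TRUE)) stop("negative abundances are not allowed")
  stopifnot(length(individual) == nrow(abund), length(day) == nrow(abund))
  rs <- rowSums(abund, na.rm = TRUE)
  if (any(rs == 0)) stop("all-zero sample row(s): ",
                         paste(rownames(abund)[rs == 0], collapse = ", "))
  total <- if (stats::median(rs) > 50) 100 else 1
  dev <- 100 * abs(rs - total) / total     # percent deviation from closure
  if (!normalize && any(dev > tol))
    stop("rows do not close to ", total, ": ",
         paste(rownames(abund)[dev > tol], collapse = ", "))
  if (normalize) {
    noticeable <- dev > 0.05
    if (any(noticeable))
      warning("renormalizing ", sum(noticeable),
              " row(s) whose sums deviated from ", total)
    abund <- abund / rs * total
  }
  structure(list(abund = abund,
                 meta = data.frame(sample_id = rownames(abund),
                                   individual = as.character(individual),
                                   day = as.numeric(day),
                                   stringsAsFactors = FALSE)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$abund), " samples x ", ncol(x$abund),
      " features; days: ", paste(sort(unique(x$meta$day)), collapse = ", "),
      "; individuals: ", length(unique(x$meta$individual)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$abund)

#' Read an abundance table from delimited text
#'
#' Expected layout: columns `sample_id`, `individual`, `day`, then one column
#' per feature. Field separator is comma by default with tab auto-detected;
#' missing values may be empty cells or `NA`.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param ... passed to [abundance_table()] (e.g. `normalize`, `tol`).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, sep = NULL, ...) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          comment.char = "", quote = "\"")
  need <- c("sample_id", "individual", "day")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    lines <- which(df$sample_id == dup) + 1L  # +1 for the header line
    stop("duplicate sample_id '", dup, "' on lines ", paste(lines, collapse = " and "))
  }
  feat <- setdiff(names(df), need)
  m <- as.matrix(df[, feat, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  abundance_table(m, df$individual, df$day, ...)
}

#' Write an abundance table as delimited text
#'
#' Metadata columns (`sample_id`, `individual`, `day`) come first, then the
#' features; the result round-trips through [read_abundance_table()].
#'
#' @param x an [abundance_table()].
#' @param path output file.
#' @param sep field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "abundance_table"))
  df <- cbind(x$meta, as.data.frame(x$abund, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
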