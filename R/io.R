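# Readers and writers for the package's external formats: Newick trees,
# headered CSV tables, and ground-truth JSON.

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth < 0) stop("Newick parse error: unmatched ')' at position ", i,
                        call. = FALSE)
  }
  if (depth != 0) {
    stop("Newick parse error: ", depth, " unmatched '(' at end of input",
         call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  tr
}

#' Write a Newick tree
#'
#' Branch lengths are written with 12 significant digits so that
#' write-then-read round-trips preserve them.
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write a data frame or matrix as headered CSV
#'
#' Prepends `#`-prefixed header lines (used to record the seed and
#' tolerance set of a run) above a standard CSV body.
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param header Named character/numeric vector recorded as `# key=value`
#'   lines.
#' @param row_names Write row names as a leading column?
#' @return `path`, invisibly.
#' @export
write_csv_header <- function(x, path, header = NULL, row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", names(header), "=", unname(header)), con)
  }
  if (is.matrix(x)) {
    x <- as.data.frame(x)
    row_names <- TRUE
  }
  write.csv(x, con, row.names = row_names)
  invisible(path)
}

#' Read a headered CSV written by [write_csv_header()]
#'
#' @param path Input path.
#' @param row_names Treat the first column as row names?
#' @return Data frame with attribute `header` (named character vector).
#' @export
read_csv_header <- function(path, row_names = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  header <- NULL
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    parts <- strsplit(kv, "=", fixed = TRUE)
    header <- setNames(vapply(parts, function(p)
      paste(p[-1], collapse = "="), character(1)),
      vapply(parts, `[[`, character(1), 1))
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  df <- read.csv(text = paste(body, collapse = "\n"),
                 row.names = if (row_names) 1 else NULL,
                 check.names = FALSE)
  attr(df, "header") <- header
  df
}

#' Serialize ground truth to JSON
#'
#' @param truth A list (e.g. the `truth` component of a simulation).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
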