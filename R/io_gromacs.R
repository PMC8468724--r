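# ---------------------------------------------------------------------------
# Readers/writers for the GROMACS-style text outputs: XVG time series and
# XPM (C pixmap) existence/contact matrices. Round-tripping a binary matrix
# through write -> read is lossless.
# ---------------------------------------------------------------------------

#' Read an XVG time-series file
#'
#' Lines starting with `#` are comments, lines starting with `@` are plot
#' directives; both are preserved as metadata. Data lines are whitespace-
#' separated numeric columns.
#'
#' @param path file path.
#' @return data.frame of the numeric columns; column names taken from
#'   `@ sN legend` directives when present (first column `time`). Metadata in
#'   `attr(, "comments")` and `attr(, "directives")`.
#' @export
load_xvg <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  directives <- lines[startsWith(lines, "@")]
  data_lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "@") &
                        nzchar(trimws(lines))]
  if (!length(data_lines)) stop("no data rows in XVG file: ", path)
  parts <- strsplit(trimws(data_lines), "[ \t]+")
  ncol <- length(parts[[1]])
  bad <- which(vapply(parts, length, integer(1)) != ncol)
  if (length(bad))
    stop("malformed XVG data at line ", bad[1], " of ", path)
  mat <- matrix(as.numeric(unlist(parts)), ncol = ncol, byrow = TRUE)
  if (any(is.na(mat)))
    stop("non-numeric XVG data in ", path)
  legends <- regmatches(directives,
                        regexec("@\\s*s[0-9]+\\s+legend\\s+\"([^\"]*)\"",
                                directives))
  legends <- vapply(legends[lengths(legends) == 2],
                    function(m) m[2], character(1))
  cn <- c("time", if (length(legends) >= ncol - 1)
    legends[seq_len(ncol - 1)] else paste0("y", seq_len(ncol - 1)))
  df <- as.data.frame(mat)
  names(df) <- cn
  attr(df, "comments") <- comments
  attr(df, "directives") <- directives
  df
}

#' Write an XVG time-series file
#'
#' @param df data.frame; first column is the abscissa (time).
#' @param path output path.
#' @param title,xaxis,yaxis optional plot labels.
#' @export
write_xvg <- function(df, path, title = "", xaxis = "Time (ps)",
                      yaxis = "") {
  hdr <- c("# written by dualscreen",
           sprintf("@    title \"%s\"", title),
           sprintf("@    xaxis  label \"%s\"", xaxis),
           sprintf("@    yaxis  label \"%s\"", yaxis))
  leg <- sprintf("@ s%d legend \"%s\"", seq_len(ncol(df) - 1) - 1,
                 names(df)[-1])
  mat <- as.matrix(df)
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", as.numeric(r)),
                                          collapse = "  "))
  writeLines(c(hdr, leg, body), path)
  invisible(path)
}

.xpm_chars <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                "M", "N", "O", "P", "Q", "R", "S", "T")

#' Write an integer matrix as a GROMACS-style XPM pixmap
#'
#' Level k of the matrix (0-based) is encoded by one character and labelled
#' via the color-map comment, as the GROMACS tools do. Pixel rows are written
#' top-to-bottom with the matrix's last row first, matching the pixmap
#' convention.
#'
#' @param mat integer matrix with values in 0..(n_levels-1).
#' @param path output path.
#' @param labels one label per level (default `"0"`, `"1"`, ...).
#' @param title title comment.
#' @export
write_xpm <- function(mat, path, labels = NULL, title = "matrix") {
  mat <- as.matrix(mat)
  vals <- sort(unique(as.vector(mat)))
  stopifnot(all(vals == round(vals)), min(vals) >= 0)
  n_levels <- max(vals) + 1
  if (n_levels > length(.xpm_chars)) stop("too many levels for XPM writer")
  if (is.null(labels)) labels <- as.character(seq_len(n_levels) - 1)
  stopifnot(length(labels) == n_levels)
  g <- round(seq(255, 0, length.out = n_levels))
  greys <- sprintf("#%02X%02X%02X", g, g, g)
  lines <- c("/* XPM */",
             sprintf("/* title: \"%s\" */", title),
             "static char *matrix_xpm[] = {",
             sprintf("\"%d %d %d 1\",", ncol(mat), nrow(mat), n_levels),
             sprintf("\"%s  c %s /* \"%s\" */\",",
                     .xpm_chars[seq_len(n_levels)], greys, labels))
  px <- apply(mat, 1, function(r) paste(.xpm_chars[r + 1], collapse = ""))
  px <- rev(px)  # top pixel row = last matrix row
  px_lines <- sprintf("\"%s\"%s", px, c(rep(",", length(px) - 1), ""))
  writeLines(c(lines, px_lines, "};"), path)
  invisible(path)
}

#' Read a GROMACS-style XPM pixmap into an integer matrix
#'
#' @param path file path.
#' @return integer matrix (values 0-based by color-map order); level labels
#'   in `attr(, "labels")`, any title comment in `attr(, "title")`.
#' @export
load_xpm <- function(path) {
  lines <- readLines(path)
  title <- sub(".*title: \"([^\"]*)\".*", "\\1",
               grep("title:", lines, value = TRUE)[1])
  hdr_i <- grep("^\"[0-9]+ +[0-9]+ +[0-9]+ +[0-9]+\"?,?", lines)
  if (!length(hdr_i)) stop("malformed XPM: no header line in ", path)
  hdr_i <- hdr_i[1]
  hdr_str <- sub("^\"([^\"]*)\".*", "\\1", lines[hdr_i])
  hdr <- suppressWarnings(as.integer(strsplit(trimws(hdr_str), "[ \t]+")[[1]]))
  if (length(hdr) < 4 || any(is.na(hdr)))
    stop("malformed XPM header at line ", hdr_i, " of ", path)
  w <- hdr[1]; h <- hdr[2]; nc <- hdr[3]; cpp <- hdr[4]
  rest <- lines[(hdr_i + 1):length(lines)]
  quoted <- rest[grepl("^\"", rest)]
  if (length(quoted) < nc + h)
    stop("truncated XPM file (expected ", nc + h, " payload lines): ", path)
  col_lines <- quoted[seq_len(nc)]
  chars <- substr(col_lines, 2, 1 + cpp)
  labels <- vapply(col_lines, function(ln) {
    lb <- sub('.*/\\* "([^"]*)" \\*/.*', "\\1", ln)
    if (identical(lb, ln)) NA_character_ else lb
  }, character(1), USE.NAMES = FALSE)
  labels[is.na(labels)] <- as.character(which(is.na(labels)) - 1)
  px_lines <- quoted[(nc + 1):(nc + h)]
  px <- sub("^\"([^\"]*)\".*", "\\1", px_lines)
  if (any(nchar(px) != w * cpp))
    stop("XPM pixel row width mismatch in ", path)
  lev <- seq_along(chars) - 1L
  names(lev) <- chars
  mat <- matrix(0L, nrow = h, ncol = w)
  for (r in seq_len(h)) {
    cells <- substring(px[r], seq(1, w * cpp, by = cpp),
                       seq(cpp, w * cpp, by = cpp))
    v <- lev[cells]
    if (any(is.na(v)))
      stop("unknown XPM pixel character in row ", r, " of ", path)
    mat[h - r + 1, ] <- v  # undo top-first convention
  }
  attr(mat, "labels") <- unname(labels)
  attr(mat, "title") <- title
  mat
}
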