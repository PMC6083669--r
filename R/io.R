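#' Read an ASCII PLY point cloud
#'
#' Supports PLY 1.0 ASCII files with a single `vertex` element carrying float
#' `x`, `y`, `z` properties, optional `uchar red`, `green`, `blue` and an
#' optional integer `label` property. Binary PLY dialects are rejected rather
#' than silently mis-read; meshes (non-empty `face` elements) are out of
#' scope. Row order is preserved exactly.
#'
#' @param path path to an ASCII PLY file.
#' @param strict if `TRUE`, label values outside the closed vocabulary are
#'   rejected (see [point_cloud()]).
#' @return A [point_cloud()].
#' @seealso [write_ply()], [read_xyz()]
#' @export
read_ply <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop(sprintf("malformed PLY header at line 1: expected 'ply', got '%s'",
                 if (length(lines)) lines[1] else "<empty file>"), call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY header: missing 'end_header'", call. = FALSE)

  props <- character(0)      # vertex property names, in order
  n_vertex <- NA_integer_
  cur_element <- ""
  for (i in 2:(end - 1L)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "comment")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "format") {
      if (length(tok) < 2L || tok[2] != "ascii") {
        stop(sprintf("unsupported PLY dialect at line %d: '%s' (only 'format ascii 1.0')",
                     i, ln), call. = FALSE)
      }
    } else if (tok[1] == "element") {
      if (length(tok) != 3L) {
        stop(sprintf("malformed PLY header at line %d: '%s'", i, ln), call. = FALSE)
      }
      cur_element <- tok[2]
      cnt <- suppressWarnings(as.integer(tok[3]))
      if (is.na(cnt)) {
        stop(sprintf("malformed PLY header at line %d: bad element count '%s'",
                     i, ln), call. = FALSE)
      }
      if (cur_element == "vertex") {
        n_vertex <- cnt
      } else if (cnt > 0L) {
        stop(sprintf("unsupported PLY element '%s' with count %d (only 'vertex')",
                     cur_element, cnt), call. = FALSE)
      }
    } else if (tok[1] == "property") {
      if (length(tok) >= 2L && tok[2] == "list") {
        stop(sprintf("unsupported PLY list property at line %d: '%s'", i, ln),
             call. = FALSE)
      }
      if (length(tok) != 3L) {
        stop(sprintf("malformed PLY header at line %d: '%s'", i, ln), call. = FALSE)
      }
      if (cur_element == "vertex") props <- c(props, tok[3])
    } else {
      stop(sprintf("malformed PLY header at line %d: '%s'", i, ln), call. = FALSE)
    }
  }
  if (is.na(n_vertex)) stop("malformed PLY header: no 'element vertex'", call. = FALSE)
  if (!all(c("x", "y", "z") %in% props)) {
    stop("PLY vertex element must have x, y, z properties", call. = FALSE)
  }

  if (n_vertex == 0L) {
    return(point_cloud(matrix(numeric(0), 0, 3)))
  }
  data_lines <- lines[(end + 1L):length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) < n_vertex) {
    stop(sprintf("PLY data truncated: header declares %d vertices, found %d rows",
                 n_vertex, length(data_lines)), call. = FALSE)
  }
  con <- textConnection(data_lines[seq_len(n_vertex)])
  on.exit(close(con), add = TRUE)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  if (length(vals) != n_vertex * length(props)) {
    stop(sprintf("PLY data malformed: expected %d values (%d x %d), found %d",
                 n_vertex * length(props), n_vertex, length(props), length(vals)),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = n_vertex, ncol = length(props), byrow = TRUE)
  colnames(m) <- props
  colors <- if (all(c("red", "green", "blue") %in% props)) {
    m[, c("red", "green", "blue"), drop = FALSE]
  } else NULL
  labels <- if ("label" %in% props) as.integer(m[, "label"]) else NULL
  point_cloud(m[, c("x", "y", "z"), drop = FALSE],
              colors = colors, labels = labels, strict = strict)
}

#' Write a point cloud as ASCII PLY
#'
#' Emits a single `vertex` element; `red`/`green`/`blue` and `label`
#' properties are written iff the cloud carries them.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param precision significant digits for coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, precision = 6) {
  stopifnot(inherits(cloud, "point_cloud"), precision >= 1)
  n <- n_points(cloud)
  header <- c(
    "ply",
    "format ascii 1.0",
    "comment written by cloudtruth",
    sprintf("element vertex %d", n),
    "property float x",
    "property float y",
    "property float z"
  )
  if (!is.null(cloud$colors)) {
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue")
  }
  if (!is.null(cloud$labels)) header <- c(header, "property int label")
  header <- c(header, "end_header")

  body <- character(0)
  if (n > 0L) {
    fmt <- sprintf("%%.%dg %%.%dg %%.%dg", precision, precision, precision)
    body <- sprintf(fmt, cloud$points[, 1], cloud$points[, 2], cloud$points[, 3])
    if (!is.null(cloud$colors)) {
      body <- paste(body, sprintf("%d %d %d", cloud$colors[, 1],
                                  cloud$colors[, 2], cloud$colors[, 3]))
    }
    if (!is.null(cloud$labels)) body <- paste(body, sprintf("%d", cloud$labels))
  }
  con <- file(path, open = "wb")  # fixed newline convention across platforms
  on.exit(close(con), add = TRUE)
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a whitespace-delimited XYZ point cloud
#'
#' Accepts rows of 3 (`x y z`) or 6 (`x y z r g b`) columns; the 6-column
#' form populates colours. Ragged rows are a format error naming the row.
#'
#' @param path path to the text file.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(point_cloud(matrix(numeric(0), 0, 3)))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  ncol <- nf[1]
  if (!ncol %in% c(3L, 6L)) {
    stop(sprintf("XYZ format error at row 1: expected 3 or 6 columns, found %d", ncol),
         call. = FALSE)
  }
  bad <- which(nf != ncol)
  if (length(bad)) {
    stop(sprintf("XYZ format error at row %d: expected %d columns, found %d",
                 bad[1], ncol, nf[bad[1]]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    row <- ceiling(which(is.na(vals))[1] / ncol)
    stop(sprintf("XYZ format error at row %d: non-numeric value", row), call. = FALSE)
  }
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  point_cloud(m[, 1:3, drop = FALSE],
              colors = if (ncol == 6L) m[, 4:6, drop = FALSE])
}

#' Write a point cloud as XYZ text
#'
#' @param cloud a [point_cloud()]; colours, when present, are written as
#'   columns 4--6. Labels are not representable in this format and dropped.
#' @param path output path.
#' @param precision significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path, precision = 6) {
  stopifnot(inherits(cloud, "point_cloud"))
  fmt <- sprintf("%%.%dg %%.%dg %%.%dg", precision, precision, precision)
  body <- sprintf(fmt, cloud$points[, 1], cloud$points[, 2], cloud$points[, 3])
  if (!is.null(cloud$colors)) {
    body <- paste(body, sprintf("%d %d %d", cloud$colors[, 1],
                                cloud$colors[, 2], cloud$colors[, 3]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(body, con, sep = "\n")
  invisible(path)
}
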