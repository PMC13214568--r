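#' Write / read streamlines in TCK format
#'
#' Minimal MRtrix TCK support: an ASCII header (`mrtrix tracks`,
#' `datatype: Float32LE`, `count`, `file: . <offset>`, `END`) followed by
#' little-endian float32 point triplets in world coordinates, with
#' `(NaN, NaN, NaN)` separating streamlines and `(Inf, Inf, Inf)`
#' terminating the stream.  The per-streamline status table is written
#' separately by [write_streamline_status()].
#'
#' @param ss a `streamline_set` (or a plain list of n x 3 world-point
#'   matrices).
#' @param path output `.tck` path.
#' @return `write_tck()` returns `path` invisibly; `read_tck()` returns a
#'   list of n x 3 point matrices.
#' @export
write_tck <- function(ss, path) {
  polylines <- if (inherits(ss, "streamline_set")) ss$polylines else ss
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(polylines)))
  # compute the data offset: header + "file: . OFFSET" + "END" + newlines
  probe <- function(off) {
    lines <- c(header, sprintf("file: . %d", off), "END")
    sum(nchar(lines, type = "bytes")) + length(lines)  # '\n' per line
  }
  off <- probe(0)
  off <- probe(off); off <- probe(off)                  # fixed point
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, sprintf("file: . %d", off), "END"), con, sep = "\n")
  for (p in polylines) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L,
             endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("read_tck: truncated header")
    if (ln == "END") break
    lines <- c(lines, ln)
  }
  if (!identical(lines[1], "mrtrix tracks"))
    stop("read_tck: not a TCK file")
  file_line <- grep("^file: ", lines, value = TRUE)
  off <- as.integer(sub("^file: \\. ", "", file_line))
  seek(con, off)
  raw_n <- file.size(path) - off
  vals <- readBin(con, "numeric", n = raw_n / 4L, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  ends <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  out <- list()
  start <- 1L
  for (e in ends) {
    if (e > start)
      out[[length(out) + 1L]] <- m[start:(e - 1L), , drop = FALSE]
    if (is.infinite(m[e, 1])) break
    start <- e + 1L
  }
  out
}

#' Write the per-streamline status table
#'
#' TSV keyed by streamline index, with the termination status, point
#' count and seed location of every streamline (retained and discarded).
#'
#' @param ss a `streamline_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_streamline_status <- function(ss, path) {
  stopifnot(inherits(ss, "streamline_set"))
  df <- data.frame(index = seq_along(ss$polylines),
                   status = as.character(ss$status),
                   n_points = vapply(ss$polylines, nrow, integer(1)),
                   seed_x = ss$seed_point[, 1],
                   seed_y = ss$seed_point[, 2],
                   seed_z = ss$seed_point[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
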