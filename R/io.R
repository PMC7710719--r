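#' Read / write contact matrices
#'
#' The package's interchange format is a self-describing dense-tsv dialect:
#' a `#`-prefixed header (resolution, assembly, balanced flag, bin count),
#' a bin table (`chrom start end valid`), a `#matrix` marker, then the dense
#' square matrix, whitespace-separated, one row per line.  Masked entries are
#' written as `NA`.  Values are written with 17 significant digits so a
#' write/read round trip preserves them to better than 1e-9 (bit-identically
#' for integer counts).
#'
#' @param path file path.
#' @param format only `"dense-tsv"` (alias `"tsv"`) is supported.
#' @return `read_matrix` returns a `contact_matrix`; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, format = c("dense-tsv", "tsv", "cooler")) {
  format <- match.arg(format)
  if (format == "cooler")
    stop("cooler (.cool) files are HDF5 containers and are not supported ",
         "by this package; convert to the dense-tsv dialect (see README)")
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get_field <- function(key, default = NULL) {
    ln <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  n <- as.integer(get_field("bins"))
  res <- as.numeric(get_field("resolution"))
  assembly <- get_field("assembly", "unknown")
  balanced <- isTRUE(as.logical(get_field("balanced", "FALSE")))
  mat_at <- grep("^#\\s*matrix", lines)[1]
  if (is.na(n) || is.na(mat_at)) stop("not a dense-tsv contact matrix: ", path)
  bin_lines <- lines[setdiff(seq_len(mat_at - 1), hdr)]
  bins <- utils::read.table(text = bin_lines, header = TRUE,
                            stringsAsFactors = FALSE)
  if (nrow(bins) != n) stop("header declares ", n, " bins but bin table has ",
                            nrow(bins))
  attr(bins, "resolution") <- res
  attr(bins, "assembly") <- assembly
  body <- lines[(mat_at + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vals <- scan(text = body, what = numeric(), na.strings = "NA", quiet = TRUE)
  if (length(vals) != n * n)
    stop("bin table has ", n, " bins but matrix body holds ", length(vals),
         " values (expected ", n * n, ")")
  V <- matrix(vals, nrow = n, byrow = TRUE)
  valid <- bins$valid %||% (rowSums(!is.na(V)) > 0)
  bins$valid <- NULL
  contact_matrix(bins, V, valid = as.logical(valid), balanced = balanced)
}

#' @rdname read_matrix
#' @param m a `contact_matrix`.
#' @export
write_matrix <- function(m, path, format = c("dense-tsv", "tsv", "cooler")) {
  format <- match.arg(format)
  if (format == "cooler")
    stop("cooler output is not supported; use dense-tsv")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# irhic dense-tsv contact matrix",
               paste0("# resolution: ", format(m$resolution, scientific = FALSE)),
               paste0("# assembly: ", m$assembly),
               paste0("# balanced: ", m$balanced),
               paste0("# bins: ", nrow(m$bins))), con)
  bt <- m$bins
  bt$valid <- m$valid
  utils::write.table(format(bt, scientific = FALSE), con, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  writeLines("# matrix", con)
  rows <- apply(m$values, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(rows, con)
  invisible(path)
}

#' Write a per-bin score track as bedGraph
#' @param bins bin table; @param score per-bin numeric (NA rows skipped).
#' @keywords internal
#' @export
write_bedgraph <- function(bins, score, path) {
  keep <- is.finite(score)
  df <- data.frame(bins$chrom[keep], format(bins$start[keep], scientific = FALSE),
                   format(bins$end[keep], scientific = FALSE),
                   formatC(score[keep], digits = 10, format = "g"))
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "score")
  df
}

#' Write boundaries (or any interval set) as BED with score column
#' @keywords internal
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE),
                    format(df$end, scientific = FALSE),
                    df$name %||% ".",
                    formatC(df$score %||% 0, digits = 10, format = "g"))
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write loop anchor pairs as BEDPE (0-based, half-open)
#' @param path file path.
#' @return data.frame with chrom1,start1,end1,chrom2,start2,end2 (+ extras).
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE needs at least 6 columns")
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  df
}

#' @rdname read_bedpe
#' @param df BEDPE-like data.frame.
#' @export
write_bedpe <- function(df, path) {
  out <- df[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  for (k in c("start1", "end1", "start2", "end2"))
    out[[k]] <- format(out[[k]], scientific = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
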