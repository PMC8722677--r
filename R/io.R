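#' Read / write delimited tables
#'
#' UTF-8 CSV/TSV with header; the delimiter is inferred from the file
#' extension (`.tsv` = tab, otherwise comma).
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_table_file` returns a data.frame.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_table_file
#' @export
write_table_file <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED is 0-based half-open on disk; in memory intervals are `GRanges`
#' (1-based closed), so a BED line `chr1 100 200 peak1` becomes the range
#' 101..200. Only the first four columns are used; extra columns
#' (narrowPeak etc.) are ignored on read.
#'
#' @param path file path.
#' @param gr a `GRanges`, optionally named (names become the BED name
#'   column).
#' @return `read_bed` returns a `GRanges` with a `name` metadata column.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(parts, length, integer(1))
  bad <- which(ncol < 3)
  if (length(bad)) stopf("malformed BED line %d: fewer than 3 fields", bad[1])
  chrom <- vapply(parts, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(start0) || anyNA(end0)) stopf("malformed BED line %d: non-numeric coordinates",
                                          which(is.na(start0) | is.na(end0))[1])
  if (any(start0 >= end0)) stopf("invalid BED line %d: start >= end",
                                 which(start0 >= end0)[1])
  name <- ifelse(ncol >= 4, vapply(parts, function(p) if (length(p) >= 4) p[[4]] else "",
                                   character(1)), "")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0), name = name)
  gr
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  name <- if (!is.null(gr$name)) gr$name else if (!is.null(names(gr))) names(gr)
          else sprintf("interval_%d", seq_along(gr))
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), name)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a 10x-style Matrix-Market count triplet
#'
#' `read_mtx` expects `matrix.mtx`, `genes.tsv` and `barcodes.tsv` in one
#' directory (barcodes file may carry a second column of group labels).
#'
#' @param dir directory with the triplet.
#' @param m a `CountMatrix` to write.
#' @return `read_mtx` returns a [count_matrix()].
#' @export
read_mtx <- function(dir) {
  mm <- file.path(dir, "matrix.mtx")
  gf <- file.path(dir, "genes.tsv")
  bf <- file.path(dir, "barcodes.tsv")
  for (f in c(mm, gf, bf)) if (!file.exists(f)) stopf("file not found: %s", f)
  x <- as_csparse(Matrix::readMM(mm))
  genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)
  bc <- utils::read.delim(bf, header = FALSE, stringsAsFactors = FALSE)
  dimnames(x) <- list(genes[[1]], bc[[1]])
  group <- if (ncol(bc) >= 2) bc[[2]] else rep("all", ncol(x))
  count_matrix(x, group)
}

#' @rdname read_mtx
#' @export
write_mtx <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(m$genes, file.path(dir, "genes.tsv"))
  writeLines(paste(m$cells, m$group, sep = "\t"), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write image stacks
#'
#' Multi-page TIFF plus a JSON sidecar (`<stem>.json`) holding
#' `pixel_size_um`, `frame_interval_min` and `wavelength_nm`. Frames are
#' stored in nm OPD scaled by `scale` to fit TIFF float pages losslessly.
#'
#' @param path TIFF path.
#' @param stack a [phase_stack()].
#' @return `read_stack` returns a `PhaseStack`.
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) stopf("the 'tiff' package is required")
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) f * meta$scale)
  phase_stack(frames, meta$pixel_size_um, meta$frame_interval_min,
              meta$wavelength_nm %||% 660)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) stopf("the 'tiff' package is required")
  stopifnot(inherits(stack, "PhaseStack"))
  mx <- max(1e-12, max(vapply(stack$frames, max, numeric(1))))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f / mx, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               wavelength_nm = stack$wavelength_nm, scale = mx)
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write voltage trace sets as wide CSV
#'
#' Wide format: a `time_ms` column plus one column per recording site. The
#' frame rate is recovered from the time column.
#'
#' @param path CSV path.
#' @param traces a [voltage_trace_set()].
#' @param group_label label attached on read.
#' @return `read_traces_csv` returns a `VoltageTraceSet`.
#' @export
read_traces_csv <- function(path, group_label = "") {
  df <- read_table_file(path)
  if (!"time_ms" %in% names(df)) stopf("trace CSV needs a time_ms column")
  dt <- median(diff(df$time_ms))
  m <- as.matrix(df[setdiff(names(df), "time_ms")])
  voltage_trace_set(m, frame_rate_hz = 1000 / dt, group_label = group_label)
}

#' @rdname read_traces_csv
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "VoltageTraceSet"))
  dt <- 1000 / traces$frame_rate_hz
  df <- data.frame(time_ms = (seq_len(nrow(traces$samples)) - 1) * dt)
  df <- cbind(df, as.data.frame(traces$samples))
  write_table_file(df, path)
}
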