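#' Export or re-import a simulated dataset as plain-text files
#'
#' `export_dataset` writes the marker map (`markers.tsv`), one call table
#' per progeny (`calls_<id>.tsv` with columns `chrom`, `pos`, `call`), and
#' one truth BED file per progeny (`truth_<id>.bed`, 0-based half-open:
#' CO breakpoints as 1-bp features named `CO`, converted intervals named
#' `GC:<left>:<right>`).  `read_dataset` reverses the operation; a
#' write/read round trip reproduces the inputs exactly.
#'
#' @param map A [marker_map()].
#' @param calls List of `observed_calls`.
#' @param truths List of `chromatid_truth`, parallel to `calls` (may be
#'   `NULL` when only observed data exist).
#' @param dir Output directory, created if needed.
#' @return `export_dataset` returns `dir` invisibly; `read_dataset` returns
#'   a list with `map`, `calls` and `truths`.
#' @export
export_dataset <- function(map, calls, truths = NULL, dir) {
  stop_if(!is.null(truths) && length(truths) != length(calls),
          "calls and truths must have equal length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_map(map, file.path(dir, "markers.tsv"))
  for (obs in calls) {
    df <- data.frame(chrom = map$chromosome, pos = map$markers$pos,
                     call = obs$calls, stringsAsFactors = FALSE)
    write.table(df, file.path(dir, paste0("calls_", obs$progeny_id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  for (truth in truths) {
    write_truth_bed(truth, map$chromosome,
                    file.path(dir, paste0("truth_", truth$progeny_id, ".bed")))
  }
  invisible(dir)
}

write_truth_bed <- function(truth, chrom, path) {
  co <- truth$co_breakpoints
  gc <- truth$gc_events
  df <- rbind(
    if (length(co)) data.frame(chrom = chrom, start = as.integer(co - 1),
                               end = as.integer(co),
                               name = "CO", stringsAsFactors = FALSE),
    if (nrow(gc)) data.frame(chrom = chrom,
                             start = as.integer(gc$dsb - gc$left - 1),
                             end = as.integer(gc$dsb + gc$right),
                             name = sprintf("GC:%d:%d", gc$left, gc$right),
                             stringsAsFactors = FALSE)
  )
  if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), name = character(0))
  df <- df[order(df$start), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_truth_bed <- function(path, progeny_id) {
  bed <- read_bed(path)
  if (is.null(bed$name)) bed$name <- character(nrow(bed))
  is_co <- bed$name == "CO"
  gcb <- bed[!is_co, , drop = FALSE]
  if (nrow(gcb)) {
    ext <- do.call(rbind, lapply(strsplit(gcb$name, ":", fixed = TRUE),
                                 function(x) as.integer(x[2:3])))
    gc <- data.frame(dsb = gcb$start + 1L + ext[, 1],
                     left = ext[, 1], right = ext[, 2])
  } else {
    gc <- data.frame(dsb = integer(0), left = integer(0), right = integer(0))
  }
  structure(list(progeny_id = progeny_id, start_parent = NA_character_,
                 co_breakpoints = bed$end[is_co], gc_events = gc),
            class = "chromatid_truth")
}

#' @rdname export_dataset
#' @export
read_dataset <- function(dir) {
  map <- read_marker_map(file.path(dir, "markers.tsv"))
  call_files <- sort(list.files(dir, "^calls_.*\\.tsv$", full.names = TRUE))
  ids <- sub("^calls_(.*)\\.tsv$", "\\1", basename(call_files))
  calls <- lapply(seq_along(call_files), function(i) {
    df <- read.delim(call_files[i], stringsAsFactors = FALSE,
                     colClasses = c("character", "integer", "character"))
    stop_if(!identical(df$pos, map$markers$pos),
            "call table does not match the marker map")
    structure(list(progeny_id = ids[i], calls = df$call), class = "observed_calls")
  })
  truth_files <- file.path(dir, paste0("truth_", ids, ".bed"))
  truths <- NULL
  if (all(file.exists(truth_files))) {
    truths <- lapply(seq_along(ids), function(i) read_truth_bed(truth_files[i], ids[i]))
    names(truths) <- ids
  }
  list(map = map, calls = setNames(calls, ids), truths = truths)
}

#' Read or write BED intervals
#'
#' Thin wrappers around `rtracklayer` for 0-based half-open BED files,
#' returning and accepting plain data frames with 1-based inclusive
#' `start`/`end` columns (the package's internal convention) plus optional
#' `name` and `class` columns.
#'
#' @param path File path.
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open for `write_bed`'s file, 1-based inclusive in the data frame)
#'   and optionally `name`.
#' @return `read_bed` returns a data frame with columns `chrom`, `start`,
#'   `end` (where `start` is 0-based, `end` exclusive, as stored) plus
#'   `name` when present.
#' @keywords internal
#' @export
read_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  df <- data.frame(chrom = as.character(gr$seqnames),
                   start = gr$start - 1L,  # back to 0-based
                   end = gr$end,
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  df
}
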