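#' Read and write peak tables
#'
#' Peak tables are UTF-8 delimited text (tab or whitespace) with the header
#' `study_id x y z value stat n1 n2`: one row per peak, coordinates in MNI
#' mm, `stat` either `t` or `d`, `n2 = 0` for one-sample designs. Rows are
#' grouped into [study] objects by `study_id`; malformed rows are rejected
#' with their line number.
#'
#' @param path path to the table.
#' @return `read_peaks`: list of [study] objects (empty for a header-only
#'   file).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop(path, ": empty peak table (no header)")
  required <- c("study_id", "x", "y", "z", "value", "stat", "n1", "n2")
  header <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  if (length(lines) == 1L) return(list())
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(f) != length(header))
      stop(path, ", line ", i, ": expected ", length(header),
           " fields, got ", length(f))
    r <- as.list(f)
    names(r) <- header
    for (col in c("x", "y", "z", "value", "n1", "n2")) {
      v <- suppressWarnings(as.numeric(r[[col]]))
      if (is.na(v))
        stop(path, ", line ", i, ": non-numeric '", col, "': ", r[[col]])
      r[[col]] <- v
    }
    if (!r$stat %in% c("t", "d"))
      stop(path, ", line ", i, ": unknown stat '", r$stat,
           "' (must be 't' or 'd')")
    r$line <- i
    r
  })
  ids <- vapply(rows, `[[`, "", "study_id")
  lapply(split(rows, factor(ids, levels = unique(ids))), function(rr) {
    n1 <- unique(vapply(rr, `[[`, 0, "n1"))
    n2 <- unique(vapply(rr, `[[`, 0, "n2"))
    if (length(n1) > 1L || length(n2) > 1L)
      stop(path, ": study '", rr[[1]]$study_id,
           "' has inconsistent group sizes")
    pks <- lapply(rr, function(r)
      peak(c(r$x, r$y, r$z), r$value, stat = r$stat))
    study(rr[[1]]$study_id, pks, n1, n2)
  })
}

#' @rdname read_peaks
#' @param studies list of [study] objects.
#' @export
write_peaks <- function(path, studies) {
  rows <- c("study_id\tx\ty\tz\tvalue\tstat\tn1\tn2")
  for (st in studies) for (pk in st$peaks) {
    rows <- c(rows, paste(st$study_id, pk$coord_mm[1], pk$coord_mm[2],
                          pk$coord_mm[3], pk$value, pk$stat, st$n1, st$n2,
                          sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
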