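#' Readers and writers for the package's tabular formats
#'
#' Plain-text round-trip formats for every stage: ASV counts (TSV, samples
#' as columns), taxonomy (TSV), rrn lookup (TSV), probe signals (long
#' TSV), forcing and flux series (CSV), season partitions (JSON). Readers
#' validate schema and values and report the offending location; writers
#' emit headers and encode missing values as empty fields.
#'
#' @param x Object to write.
#' @param path File path.
#' @name warmtrait-io
NULL

#' @rdname warmtrait-io
#' @export
write_asv_counts <- function(x, path) readr::write_tsv(x, path)

#' @rdname warmtrait-io
#' @export
read_asv_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(x)[1] != "asv_id")
    stop("ASV table must start with an asv_id column", call. = FALSE)
  for (j in setdiff(names(x), "asv_id")) {
    bad <- which(is.na(x[[j]]) | x[[j]] < 0 | x[[j]] != round(x[[j]]))
    if (length(bad))
      stop(sprintf("invalid count at row %d, column %s", bad[1], j),
           call. = FALSE)
  }
  x
}

#' @rdname warmtrait-io
#' @export
write_taxonomy <- function(x, path) readr::write_tsv(x, path)

#' @rdname warmtrait-io
#' @export
read_taxonomy <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("asv_id", "lineage", "confidence")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("taxonomy table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname warmtrait-io
#' @export
write_rrn_lookup <- function(x, path) readr::write_tsv(x, path)

#' @rdname warmtrait-io
#' @export
read_rrn_lookup <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("taxon", "rank", "copy_number", "parent")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("rrn lookup missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x$copy_number) | x$copy_number <= 0)
  if (length(bad))
    stop("non-positive copy number at row ", bad[1], call. = FALSE)
  x
}

#' @rdname warmtrait-io
#' @export
write_probe_signals <- function(x, path) {
  ann <- attr(x, "annotations")
  readr::write_tsv(tibble::as_tibble(x), path)
  if (!is.null(ann))
    readr::write_tsv(ann, sub("(\\.[^.]+)?$", "_annotations\\1", path,
                              perl = TRUE))
  invisible(path)
}

#' @rdname warmtrait-io
#' @export
read_probe_signals <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("probe", "sample_id", "month", "treatment", "batch", "signal")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("probe table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann_path <- sub("(\\.[^.]+)?$", "_annotations\\1", path, perl = TRUE)
  if (file.exists(ann_path))
    attr(x, "annotations") <- readr::read_tsv(ann_path,
                                              show_col_types = FALSE)
  class(x) <- c("geochip_matrix", class(x))
  x
}

#' @rdname warmtrait-io
#' @export
write_forcing <- function(x, path) readr::write_csv(x, path)

#' @rdname warmtrait-io
#' @export
read_forcing <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("date", "treatment", "temperature", "moisture", "gpp")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("forcing missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (tr in unique(x$treatment)) {
    d <- sort(x$date[x$treatment == tr])
    gap <- which(diff(d) != 1)
    if (length(gap))
      stop("forcing has a missing day after ", d[gap[1]], " (", tr, ")",
           call. = FALSE)
  }
  bad <- which(x$moisture < 0 | x$moisture > 100)
  if (length(bad))
    stop("moisture out of [0, 100] at row ", bad[1], call. = FALSE)
  if (!"doy" %in% names(x)) x$doy <- as.integer(format(x$date, "%j"))
  if (!"month" %in% names(x)) x$month <- as.integer(format(x$date, "%m"))
  class(x) <- c("forcing_series", class(x))
  x
}

#' @rdname warmtrait-io
#' @export
write_fluxes <- function(x, path) readr::write_csv(x, path)

#' @rdname warmtrait-io
#' @export
read_fluxes <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("month", "r_h") %in% names(x)))
    stop("flux table needs month and r_h columns", call. = FALSE)
  bad <- which(x$r_h < 0)
  if (length(bad)) stop("negative r_h at row ", bad[1], call. = FALSE)
  if (all(c("r_s", "r_a") %in% names(x))) {
    res <- x$r_a - (x$r_s - x$r_h)
    bad <- which(abs(res) > 1e-8)
    if (length(bad))
      stop("r_a != r_s - r_h at row ", bad[1], call. = FALSE)
  }
  x
}

#' @rdname warmtrait-io
#' @export
write_partition <- function(x, path) {
  stopifnot(inherits(x, "season_partition"))
  jsonlite::write_json(
    list(months = x$table, rise_interval = x$rise_interval,
         fall_interval = x$fall_interval, rise_at = x$rise_at,
         fall_at = x$fall_at),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname warmtrait-io
#' @export
read_partition <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(table = tibble::as_tibble(j$months),
         rise_interval = j$rise_interval, fall_interval = j$fall_interval,
         rise_at = j$rise_at, fall_at = j$fall_at),
    class = "season_partition")
}
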