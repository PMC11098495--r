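#' Construct and validate a genomic view
#'
#' A view is an ordered set of named, non-overlapping genomic regions that
#' defines the 1D coordinate axis for all per-region analyses (e.g. whole
#' chromosomes, or chromosome arms split at centromeres). Order is meaningful
#' and preserved.
#'
#' @param store A `ContactStore` supplying chromosome names and lengths.
#' @param regions Optional data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (default `chrom:start-end`). When `NULL`, the default
#'   view is one region per chromosome, in store order, named by chromosome.
#' @param centromeres Optional data.frame (`chrom`, `pos`): chromosomes listed
#'   here are split into `<chrom>_p` (before `pos`) and `<chrom>_q` arms.
#' @return data.frame of class `genomic_view` with columns `chrom`, `start`,
#'   `end`, `name`.
#' @examples
#' \dontrun{
#' view <- make_view(store)                       # whole chromosomes
#' arms <- make_view(store, centromeres = data.frame(chrom = "chr1", pos = 3e6))
#' }
#' @export
make_view <- function(store, regions = NULL, centromeres = NULL) {
  chroms <- store$chroms
  if (is.null(regions)) {
    regions <- data.frame(chrom = chroms$name, start = 0,
                          end = chroms$length, name = chroms$name,
                          stringsAsFactors = FALSE)
    if (!is.null(centromeres)) {
      out <- list()
      for (k in seq_len(nrow(regions))) {
        r <- regions[k, ]
        cen <- centromeres$pos[match(r$chrom, centromeres$chrom)]
        if (!is.na(cen)) {
          if (cen <= r$start || cen >= r$end)
            stop("centromere for ", r$chrom, " outside chromosome")
          out[[length(out) + 1L]] <- data.frame(
            chrom = r$chrom, start = c(r$start, cen), end = c(cen, r$end),
            name = paste0(r$chrom, c("_p", "_q")), stringsAsFactors = FALSE)
        } else out[[length(out) + 1L]] <- r
      }
      regions <- do.call(rbind, out)
    }
  } else {
    regions <- as.data.frame(regions)
    if (is.null(regions$name))
      regions$name <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  regions <- regions[c("chrom", "start", "end", "name")]
  rownames(regions) <- NULL
  validate_view(regions, chroms)
  class(regions) <- c("genomic_view", "data.frame")
  regions
}

validate_view <- function(view, chroms = NULL) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(view)))
  if (any(!nzchar(view$name)) || anyDuplicated(view$name))
    stop("view region names must be unique and non-empty")
  if (any(view$end <= view$start)) stop("empty view region")
  if (!is.null(chroms)) {
    m <- match(view$chrom, chroms$name)
    if (anyNA(m)) stop("view chromosome absent from store: ",
                       paste(unique(view$chrom[is.na(m)]), collapse = ", "))
    if (any(view$start < 0) || any(view$end > chroms$length[m]))
      stop("view region outside chromosome bounds")
  }
  for (ch in unique(view$chrom)) {
    v <- view[view$chrom == ch, , drop = FALSE]
    v <- v[order(v$start), , drop = FALSE]
    if (nrow(v) > 1L && any(v$start[-1L] < v$end[-nrow(v)]))
      stop("overlapping view regions on ", ch)
  }
  invisible(TRUE)
}

# 0-based bin ids per view region, as a named list (region order preserved)
view_bins <- function(store, view) {
  out <- lapply(seq_len(nrow(view)), function(k)
    region_bins(store, view$chrom[k], view$start[k], view$end[k]))
  names(out) <- view$name
  out
}

#' Align an interval-valued track to the bins of a store
#'
#' Converts signal given on arbitrary intervals (bedGraph dialect) to one
#' value per bin by coverage-weighted averaging; bins with no overlapping
#' interval get `NA`.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param store A `ContactStore`.
#' @return data.frame (`chrom`, `start`, `end`, `value`), one row per bin in
#'   bin-table order.
#' @export
align_track <- function(track, store) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  bad <- setdiff(unique(track$chrom), store$chroms$name)
  if (length(bad)) stop("track chromosome absent from store: ",
                        paste(bad, collapse = ", "))
  bs <- store$binsize
  chrom_off <- c(0L, cumsum(tabulate(factor(store$bins$chrom,
                                            levels = store$chroms$name))))
  names(chrom_off) <- c(store$chroms$name, "_end")
  num <- den <- numeric(store$nbins)
  for (r in seq_len(nrow(track))) {
    ch <- track$chrom[r]; s <- track$start[r]; e <- track$end[r]
    v <- track$value[r]
    if (is.na(v) || e <= s) next
    clen <- store$chroms$length[match(ch, store$chroms$name)]
    e <- min(e, clen)
    b0 <- floor(s / bs); b1 <- ceiling(e / bs) - 1
    bidx <- chrom_off[[ch]] + (b0:b1) + 1
    ov <- pmin((b0:b1 + 1) * bs, e, clen) - pmax((b0:b1) * bs, s)
    num[bidx] <- num[bidx] + v * ov
    den[bidx] <- den[bidx] + ov
  }
  val <- ifelse(den > 0, num / den, NA_real_)
  data.frame(chrom = store$bins$chrom, start = store$bins$start,
             end = store$bins$end, value = val, stringsAsFactors = FALSE)
}

#' Read / write BED-like and bedGraph-like TSV tables
#'
#' 0-based half-open coordinates throughout (BED convention). Files with a
#' header line are detected by a non-numeric second field; headerless files
#' are assigned the standard column names.
#'
#' @param path File path.
#' @param col_names Names used for headerless files.
#' @return data.frame.
#' @export
read_intervals <- function(path, col_names = c("chrom", "start", "end", "name")) {
  head_lines <- readLines(path, n = 50L)
  first <- head_lines[!startsWith(head_lines, "#")][1L]
  if (is.na(first)) stop("no data lines in ", path)
  f1 <- strsplit(first, "\t")[[1L]]
  has_header <- length(f1) >= 2L && is.na(suppressWarnings(as.numeric(f1[2L])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!has_header) names(df) <- col_names[seq_len(min(ncol(df), length(col_names)))]
  df
}

#' @rdname read_intervals
#' @param df data.frame to write.
#' @param header Write a header line (default TRUE).
#' @param comment Optional comment line(s) written with a leading `#`.
#' @export
write_intervals <- function(df, path, header = TRUE, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}
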