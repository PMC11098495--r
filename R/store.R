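#' @importFrom stats quantile
NULL

#' Open a contact store (cooler-schema file)
#'
#' Opens one resolution of a binned contact matrix stored in the cooler HDF5
#' schema (v3), either a single-resolution `.cool` file or one resolution of a
#' multi-resolution `.mcool` file selected with the URI syntax
#' `path::/resolutions/<binsize>`.
#'
#' The returned handle exposes the chromosome table, the bin table (with the
#' balancing-weight column if present) and lazy, chunked access to the
#' upper-triangular pixel table. Pixels are stored strictly upper-triangular
#' (`bin1_id <= bin2_id`), sorted, without duplicates; coordinates are 0-based,
#' half-open. A missing (`NaN`) weight marks a filtered-out ("bad") bin: any
#' balanced value touching it is missing.
#'
#' @param uri Path to a `.cool` file, or `"path::/resolutions/<N>"` (also
#'   accepted: `"path::resolutions/<N>"`) for an `.mcool`.
#' @return An object of class `ContactStore` with elements `path`, `root`,
#'   `binsize`, `chroms` (data.frame: `name`, `length`), `bins` (data.frame:
#'   `chrom`, `start`, `end`, and `weight` when stored), `nbins`, `nnz`.
#' @seealso [write_cool()], [pixel_chunks()], [fetch_dense()]
#' @export
open_store <- function(uri) {
  parts <- strsplit(uri, "::", fixed = TRUE)[[1L]]
  path <- parts[1L]
  root <- if (length(parts) > 1L) parts[2L] else "/"
  if (!startsWith(root, "/")) root <- paste0("/", root)
  if (!file.exists(path)) stop("file not found: ", path)

  ls0 <- rhdf5::h5ls(path, recursive = 2L)
  top_groups <- ls0$name[ls0$group == "/" & ls0$otype == "H5I_GROUP"]
  if (root == "/" && "resolutions" %in% top_groups && !"pixels" %in% top_groups) {
    avail <- ls0$name[ls0$group == "/resolutions"]
    stop("multi-resolution file: select a resolution with '", path,
         "::/resolutions/<N>'; available: ", paste(avail, collapse = ", "))
  }
  if (root != "/") {
    grp <- sub("^/", "", root)
    have <- paste0(ls0$group, "/", ls0$name)
    have <- sub("^//", "/", have)
    if (!paste0("/", grp) %in% have) {
      avail <- ls0$name[ls0$group == "/resolutions"]
      stop("resolution group '", root, "' not present; available: ",
           if (length(avail)) paste(avail, collapse = ", ") else "(none)")
    }
  }

  rd <- function(name) rhdf5::h5read(path, paste0(root, "/", name), bit64conversion = "double")
  lsr <- rhdf5::h5ls(path)
  dsets <- sub("^//", "/", paste0(lsr$group, "/", lsr$name))
  need <- paste0(sub("/$", "", root), c("/chroms", "/bins", "/pixels", "/indexes"))
  if (!all(need %in% dsets)) {
    stop("not a cooler-schema v3 group: missing ",
         paste(setdiff(need, dsets), collapse = ", "))
  }

  chroms <- data.frame(
    name = as.character(rd("chroms/name")),
    length = as.numeric(rd("chroms/length")),
    stringsAsFactors = FALSE
  )
  bchrom <- rd("bins/chrom")
  # chrom column may be integer codes (0-based, referencing chroms/name),
  # an HDF5 enum read back as factor, or plain strings
  bchrom <- if (is.numeric(bchrom)) chroms$name[as.integer(bchrom) + 1L]
            else as.character(bchrom)
  bins <- data.frame(
    chrom = bchrom,
    start = as.numeric(rd("bins/start")),
    end = as.numeric(rd("bins/end")),
    stringsAsFactors = FALSE
  )
  bin_cols <- lsr$name[sub("^//", "/", lsr$group) == paste0(sub("/$", "", root), "/bins")]
  if ("weight" %in% bin_cols) {
    w <- as.numeric(rd("bins/weight"))
    w[!is.finite(w)] <- NA_real_
    bins$weight <- w
  }
  attrs <- rhdf5::h5readAttributes(path, root)
  binsize <- if (!is.null(attrs[["bin-size"]])) as.numeric(attrs[["bin-size"]]) else
    as.numeric(stats::median(bins$end - bins$start))

  b1o <- as.numeric(rd("indexes/bin1_offset"))
  store <- structure(list(
    uri = uri, path = path, root = sub("/$", "", root),
    binsize = binsize, chroms = chroms, bins = bins,
    nbins = nrow(bins), nnz = b1o[length(b1o)],
    bin1_offset = b1o,
    cache = new.env(parent = emptyenv())
  ), class = "ContactStore")
  validate_store_tables(store$chroms, store$bins, binsize)
  store
}

#' @export
print.ContactStore <- function(x, ...) {
  cat("ContactStore:", x$uri, "\n")
  cat("  binsize:", format(x$binsize, big.mark = ","), "bp\n")
  cat("  chroms: ", nrow(x$chroms), " (", paste(utils::head(x$chroms$name, 4L), collapse = ", "),
      if (nrow(x$chroms) > 4L) ", ..." else "", ")\n", sep = "")
  cat("  bins:", x$nbins, " nnz pixels:", x$nnz,
      if (!is.null(x$bins$weight)) " [balanced]" else "", "\n")
  invisible(x)
}

validate_store_tables <- function(chroms, bins, binsize, pixels = NULL) {
  stopifnot(is.data.frame(chroms), all(c("name", "length") %in% names(chroms)))
  if (anyDuplicated(chroms$name)) stop("duplicate chromosome names")
  # bins must tile each chromosome in fixed steps (last bin may be short)
  for (k in seq_len(nrow(chroms))) {
    b <- bins[bins$chrom == chroms$name[k], , drop = FALSE]
    n_expect <- ceiling(chroms$length[k] / binsize)
    if (nrow(b) != n_expect ||
        any(b$start != (seq_len(nrow(b)) - 1L) * binsize) ||
        any(b$end != pmin(b$start + binsize, chroms$length[k]))) {
      stop("bins do not tile chromosome ", chroms$name[k],
           " in steps of ", binsize)
    }
  }
  if (!identical(unique(bins$chrom), chroms$name))
    stop("bin table chromosome order differs from chromosome table")
  if (!is.null(pixels)) validate_pixels(pixels, nrow(bins))
  invisible(TRUE)
}

validate_pixels <- function(pixels, nbins) {
  stopifnot(all(c("bin1_id", "bin2_id", "count") %in% names(pixels)))
  if (nrow(pixels) == 0L) return(invisible(TRUE))
  if (any(pixels$bin1_id > pixels$bin2_id))
    stop("pixels must be upper-triangular: bin1_id <= bin2_id")
  if (any(pixels$bin1_id < 0L) || any(pixels$bin2_id >= nbins))
    stop("pixel bin ids out of range")
  key <- pixels$bin1_id * nbins + pixels$bin2_id
  if (is.unsorted(key, strictly = TRUE))
    stop("pixels must be sorted by (bin1_id, bin2_id) without duplicates")
  if (any(pixels$count < 0)) stop("negative pixel counts")
  invisible(TRUE)
}

#' Write a contact store to a cooler-schema HDF5 file
#'
#' Writes chromosome, bin and pixel tables as a cooler schema v3 group,
#' readable by [open_store()] and by standard cooler-schema readers. Passing
#' `root = "/resolutions/<N>"` writes one member of a multi-resolution
#' (`.mcool`) layout.
#'
#' @param path Output file path.
#' @param chroms data.frame with `name`, `length`.
#' @param bins data.frame with `chrom`, `start`, `end` and optionally `weight`
#'   (`NA` = bad bin, stored as `NaN`).
#' @param pixels data.frame with `bin1_id`, `bin2_id` (0-based, upper
#'   triangular, sorted, unique) and non-negative integer `count`.
#' @param binsize Bin size in bp.
#' @param root HDF5 group to write into (default `"/"`).
#' @param overwrite Replace an existing file (default TRUE when `root = "/"`).
#' @return The path, invisibly.
#' @export
write_cool <- function(path, chroms, bins, pixels, binsize, root = "/",
                       overwrite = identical(root, "/")) {
  validate_store_tables(chroms, bins, binsize, pixels)
  pixels <- as.data.frame(pixels)[c("bin1_id", "bin2_id", "count")]
  if (overwrite && file.exists(path)) unlink(path)
  if (!file.exists(path)) rhdf5::h5createFile(path)
  root <- sub("/$", "", root)
  if (root != "") {
    segs <- strsplit(sub("^/", "", root), "/")[[1L]]
    acc <- ""
    for (s in segs) {
      acc <- paste0(acc, "/", s)
      if (!rhdf5::H5Lexists(fid <- rhdf5::H5Fopen(path), sub("^/", "", acc))) {
        rhdf5::H5Fclose(fid)
        rhdf5::h5createGroup(path, acc)
      } else rhdf5::H5Fclose(fid)
    }
  }
  g <- function(name) paste0(root, "/", name)
  for (grp in c("chroms", "bins", "pixels", "indexes")) rhdf5::h5createGroup(path, g(grp))

  rhdf5::h5write(chroms$name, path, g("chroms/name"))
  rhdf5::h5write(as.integer(chroms$length), path, g("chroms/length"))

  chrom_code <- match(bins$chrom, chroms$name) - 1L
  rhdf5::h5write(as.integer(chrom_code), path, g("bins/chrom"))
  rhdf5::h5write(as.integer(bins$start), path, g("bins/start"))
  rhdf5::h5write(as.integer(bins$end), path, g("bins/end"))
  if (!is.null(bins$weight)) {
    w <- as.numeric(bins$weight)
    w[is.na(w)] <- NaN
    rhdf5::h5write(w, path, g("bins/weight"))
  }

  rhdf5::h5write(as.integer(pixels$bin1_id), path, g("pixels/bin1_id"))
  rhdf5::h5write(as.integer(pixels$bin2_id), path, g("pixels/bin2_id"))
  rhdf5::h5write(as.integer(pixels$count), path, g("pixels/count"))

  nbins <- nrow(bins)
  chrom_offset <- c(0L, cumsum(as.integer(table(factor(bins$chrom, levels = chroms$name)))))
  # bin1_offset[b+1] = number of pixels with bin1_id < b+1  (CSR row index)
  cnt <- tabulate(pixels$bin1_id + 1L, nbins)
  bin1_offset <- c(0L, cumsum(cnt))
  rhdf5::h5write(as.integer(chrom_offset), path, g("indexes/chrom_offset"))
  rhdf5::h5write(as.integer(bin1_offset), path, g("indexes/bin1_offset"))

  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  loc <- if (root == "") fid else { gid <- rhdf5::H5Gopen(fid, root); on.exit(rhdf5::H5Gclose(gid), add = TRUE); gid }
  wa <- function(what, value) rhdf5::h5writeAttribute(value, loc, what, asScalar = TRUE)
  wa("format", "HDF5::Cooler")
  wa("format-version", 3L)
  wa("bin-type", "fixed")
  wa("bin-size", as.integer(binsize))
  wa("storage-mode", "symmetric-upper")
  wa("nchroms", nrow(chroms))
  wa("nbins", nbins)
  wa("nnz", nrow(pixels))
  wa("sum", sum(as.numeric(pixels$count)))
  wa("generated-by", paste0("hicmaptools-", as.character(utils::packageVersion("hicmaptools"))))
  if (root != "") {
    rhdf5::h5writeAttribute("HDF5::MCOOL", fid, "format", asScalar = TRUE)
    rhdf5::h5writeAttribute(2L, fid, "format-version", asScalar = TRUE)
  }
  invisible(path)
}

#' Read pixels, with optional bin1 range restriction
#'
#' @param store A `ContactStore`.
#' @param bin1_range Optional length-2 vector of 0-based inclusive bin1 ids;
#'   uses the CSR index so only the needed slice is read.
#' @param rows Optional explicit row slice (1-based, inclusive) of the pixel
#'   table, overriding `bin1_range`.
#' @return data.frame with `bin1_id`, `bin2_id`, `count`.
#' @keywords internal
read_pixels <- function(store, bin1_range = NULL, rows = NULL) {
  if (is.null(rows)) {
    if (is.null(bin1_range)) rows <- c(1, store$nnz)
    else rows <- c(store$bin1_offset[bin1_range[1L] + 1L] + 1,
                   store$bin1_offset[bin1_range[2L] + 2L])
  }
  if (rows[2L] < rows[1L])
    return(data.frame(bin1_id = integer(), bin2_id = integer(), count = integer()))
  idx <- list(seq.int(rows[1L], rows[2L]))
  rd <- function(name) as.vector(rhdf5::h5read(store$path, paste0(store$root, "/pixels/", name),
                                               index = idx, bit64conversion = "double"))
  data.frame(bin1_id = as.integer(rd("bin1_id")),
             bin2_id = as.integer(rd("bin2_id")),
             count = as.numeric(rd("count")))
}

#' Iterate over the pixel table in chunks
#'
#' Applies `fun` to successive slices of the pixel table. Every aggregate in
#' the package is chunk-size independent: any `chunk_size` yields the same
#' result as a single pass.
#'
#' @param store A `ContactStore`.
#' @param fun Function taking a pixel data.frame chunk.
#' @param chunk_size Pixels per chunk (default 1e7).
#' @return List of `fun` results, invisibly.
#' @export
pixel_chunks <- function(store, fun, chunk_size = 1e7) {
  out <- list()
  i <- 1
  k <- 1L
  while (i <= store$nnz) {
    j <- min(i + chunk_size - 1, store$nnz)
    out[[k]] <- fun(read_pixels(store, rows = c(i, j)))
    i <- j + 1
    k <- k + 1L
  }
  invisible(out)
}

#' Per-bin weights for balancing
#'
#' @param store A `ContactStore`.
#' @param use_weights `TRUE` (use the stored `weight` column; error if absent),
#'   `FALSE` (unit weights: raw data), or the name of a bin column.
#' @return Numeric vector of length `nbins`; `NA` marks bad bins.
#' @keywords internal
store_weights <- function(store, use_weights = TRUE) {
  if (isFALSE(use_weights)) return(rep(1, store$nbins))
  col <- if (isTRUE(use_weights)) "weight" else use_weights
  w <- store$bins[[col]]
  if (is.null(w)) {
    avail <- setdiff(names(store$bins), c("chrom", "start", "end"))
    stop("weight column '", col, "' not found; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  as.numeric(w)
}

# Full symmetric sparse count matrix (cached). Fixture-scale maps fit easily;
# dense slices for eigendecomposition, dot scoring and snipping are cut from it.
store_sparse <- function(store) {
  if (!is.null(store$cache$sym)) return(store$cache$sym)
  px <- read_pixels(store)
  up <- Matrix::sparseMatrix(i = px$bin1_id + 1L, j = px$bin2_id + 1L,
                             x = px$count, dims = c(store$nbins, store$nbins))
  sym <- up + Matrix::t(up)
  Matrix::diag(sym) <- Matrix::diag(up)
  store$cache$sym <- sym
  sym
}

#' Dense (balanced) matrix slice
#'
#' Materializes the symmetrized contact matrix over two sets of bins.
#'
#' @param store A `ContactStore`.
#' @param bins1,bins2 0-based bin id vectors (rows, columns); `bins2` defaults
#'   to `bins1`.
#' @param use_weights See [store_weights()]; balanced value is
#'   `count * w_i * w_j`, `NA` where either bin is bad.
#' @return Dense numeric matrix.
#' @export
fetch_dense <- function(store, bins1, bins2 = bins1, use_weights = TRUE) {
  M <- as.matrix(store_sparse(store)[bins1 + 1L, bins2 + 1L, drop = FALSE])
  w <- store_weights(store, use_weights)
  M <- M * outer(w[bins1 + 1L], w[bins2 + 1L])
  M
}

#' 0-based bin ids of a region
#'
#' A bin belongs to a region when its start coordinate lies in
#' `[region_start, region_end)`.
#' @param store A `ContactStore`.
#' @param chrom,start,end Region coordinates (bp, 0-based half-open).
#' @return Integer vector of 0-based bin ids.
#' @export
region_bins <- function(store, chrom, start, end) {
  b <- store$bins
  which(b$chrom == chrom & b$start >= start & b$start < end) - 1L
}
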