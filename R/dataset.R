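#' ADT dataset: cells x markers counts with per-cell batch labels
#'
#' The unit of all processing in adtwarp. Counts are non-negative integers
#' with cells as rows and markers as columns. Missing markers are supported
#' only at the (marker, batch) level: within one batch a marker is either
#' fully observed or fully `NA` (see [marker_availability()]).
#'
#' @param counts numeric matrix, cells x markers, non-negative, no `NaN`/`Inf`.
#'   `NA` entries are allowed and mean "marker not profiled for this cell";
#'   they must tile whole (marker, batch) blocks once batches are attached.
#' @param cell_ids unique character vector, one per row. Defaults to rownames.
#' @param marker_names unique character vector, one per column. Defaults to
#'   colnames.
#' @param batch optional factor/character of batch labels, one per cell.
#' @return An object of class `adt_dataset`: a list with elements `counts`
#'   (matrix with dimnames), and `batch` (factor or `NULL`).
#' @examples
#' m <- matrix(c(0, 5, 10, 0, 2, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("c", 1:3), c("CD3", "CD19")))
#' ds <- adt_dataset(m)
#' dim(ds)
#' @export
adt_dataset <- function(counts, cell_ids = rownames(counts),
                        marker_names = colnames(counts), batch = NULL) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(nrow(counts)))
  if (is.null(marker_names)) stop("marker names are required")
  cell_ids <- as.character(cell_ids)
  marker_names <- as.character(marker_names)
  if (nrow(counts) != length(cell_ids))
    stop("length of cell_ids does not match number of rows")
  if (ncol(counts) != length(marker_names))
    stop("length of marker_names does not match number of columns")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", toString(utils::head(unique(cell_ids[duplicated(cell_ids)]), 3)))
  if (anyDuplicated(marker_names))
    stop("duplicate marker names: ",
         toString(unique(marker_names[duplicated(marker_names)])))
  if (ncol(counts) < 1L) stop("at least one marker is required")
  if (!is.numeric(counts)) {
    bad <- which(!is.na(counts) & is.na(suppressWarnings(as.numeric(counts))),
                 arr.ind = TRUE)
    stop("non-numeric count entries, e.g. cell '", cell_ids[bad[1, 1]],
         "', marker '", marker_names[bad[1, 2]], "'")
  }
  nonfinite <- !is.na(counts) & !is.finite(counts)
  if (any(nonfinite)) {
    bad <- which(nonfinite, arr.ind = TRUE)[1, ]
    stop("non-finite count for cell '", cell_ids[bad[1]], "', marker '",
         marker_names[bad[2]], "'")
  }
  neg <- !is.na(counts) & counts < 0
  if (any(neg)) {
    bad <- which(neg, arr.ind = TRUE)[1, ]
    stop("negative count for cell '", cell_ids[bad[1]], "', marker '",
         marker_names[bad[2]], "'")
  }
  dimnames(counts) <- list(cell_ids, marker_names)
  if (!is.null(batch)) {
    if (length(batch) != nrow(counts))
      stop("batch labels must have one entry per cell")
    batch <- droplevels(as.factor(batch))
  }
  structure(list(counts = counts, batch = batch), class = "adt_dataset")
}

#' @export
dim.adt_dataset <- function(x) dim(x$counts)

#' @export
print.adt_dataset <- function(x, ...) {
  cat("adt_dataset:", nrow(x$counts), "cells x", ncol(x$counts), "markers\n")
  if (!is.null(x$batch)) {
    tb <- table(x$batch)
    cat("batches:", paste0(names(tb), " (", tb, ")", collapse = ", "), "\n")
  } else cat("batches: <not attached>\n")
  invisible(x)
}

#' Cell identifiers, marker names and batch labels of a dataset
#' @param ds an [adt_dataset()].
#' @return character vector (or factor for `batch_of_cell`).
#' @export
cell_ids <- function(ds) rownames(ds$counts)

#' @rdname cell_ids
#' @export
marker_names <- function(ds) colnames(ds$counts)

#' @rdname cell_ids
#' @export
batch_of_cell <- function(ds) ds$batch

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an ADT count matrix
#'
#' Dense tables are CSV/TSV with a header row of marker names and the cell id
#' in the first column. Sparse input is Matrix Market coordinate format with
#' `features.tsv` / `barcodes.tsv` sidecars in the common features x barcodes
#' orientation; it is transposed on read so that cells are rows everywhere.
#'
#' @param path path to the dense table or the `.mtx` file.
#' @param format `"auto"` (by extension), `"dense"` or `"mtx"`.
#' @param features,barcodes sidecar paths for MTX input; default to
#'   `features.tsv` / `barcodes.tsv` next to the `.mtx` file.
#' @return An [adt_dataset()] (without batch labels).
#' @export
read_adt_counts <- function(path, format = c("auto", "dense", "mtx"),
                            features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                             check.names = FALSE, colClasses = "character")
    ids <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage <- apply(m, 2, as.numeric))
    storage <- matrix(as.numeric(storage), nrow = nrow(m))
    bad <- which(is.na(storage) & !(is.na(m) | m %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric count for cell '", ids[bad[1, 1]], "', marker '",
           colnames(tab)[-1][bad[1, 2]], "'")
    adt_dataset(storage, cell_ids = ids, marker_names = colnames(tab)[-1])
  } else {
    dir <- dirname(path)
    if (is.null(features)) features <- file.path(dir, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    for (f in c(features, barcodes))
      if (!file.exists(f)) stop("sidecar file not found: ", f)
    mm <- as.matrix(Matrix::readMM(path))
    feats <- utils::read.table(features, header = FALSE, sep = "\t",
                               colClasses = "character")[[1]]
    bcs <- utils::read.table(barcodes, header = FALSE, sep = "\t",
                             colClasses = "character")[[1]]
    if (nrow(mm) != length(feats) || ncol(mm) != length(bcs))
      stop("MTX dimensions do not match sidecar files")
    adt_dataset(t(mm), cell_ids = bcs, marker_names = feats)
  }
}

#' Attach batch labels from a metadata table
#'
#' @param ds an [adt_dataset()].
#' @param meta data frame with a `cell_id` column and one or more candidate
#'   batch columns (e.g. `sample`, `study`).
#' @param batch_key name of the column in `meta` to use as the batch label.
#' @return `ds` with `batch` populated; batches with zero cells are dropped.
#' @export
attach_batches <- function(ds, meta, batch_key) {
  stopifnot(inherits(ds, "adt_dataset"))
  if (!"cell_id" %in% names(meta)) stop("meta must have a 'cell_id' column")
  if (!batch_key %in% names(meta))
    stop("batch_key '", batch_key, "' not found in meta")
  idx <- match(cell_ids(ds), meta$cell_id)
  if (anyNA(idx)) {
    missing <- cell_ids(ds)[is.na(idx)]
    stop("cell ids missing from meta: ", toString(utils::head(missing, 5)),
         if (length(missing) > 5) " ...")
  }
  ds$batch <- droplevels(as.factor(meta[[batch_key]][idx]))
  validate_availability(ds)
  ds
}

#' Marker availability per (marker, batch)
#'
#' A marker is available in a batch unless all of its values in that batch are
#' `NA`. Markers absent from a batch contribute no cells to normalization and
#' receive no warp for that batch.
#'
#' @param ds an [adt_dataset()] with batches attached.
#' @return logical matrix, batches x markers.
#' @export
marker_availability <- function(ds) {
  stopifnot(inherits(ds, "adt_dataset"), !is.null(ds$batch))
  avail <- vapply(levels(ds$batch), function(b) {
    colSums(!is.na(ds$counts[ds$batch == b, , drop = FALSE])) > 0
  }, logical(ncol(ds$counts)))
  t(matrix(avail, ncol(ds$counts), nlevels(ds$batch),
           dimnames = list(marker_names(ds), levels(ds$batch))))
}

# NA entries must tile whole (marker, batch) blocks
validate_availability <- function(ds) {
  if (!anyNA(ds$counts)) return(invisible(TRUE))
  for (b in levels(ds$batch)) {
    block <- ds$counts[ds$batch == b, , drop = FALSE]
    nna <- colSums(is.na(block))
    partial <- nna > 0 & nna < nrow(block)
    if (any(partial))
      stop("marker '", marker_names(ds)[which(partial)[1]], "' is partially ",
           "missing in batch '", b, "'; NA must cover whole (marker, batch) blocks")
  }
  invisible(TRUE)
}

#' Write (and read back) a normalized expression matrix
#'
#' Dense CSV/TSV with the same cell and marker ordering as the dataset; values
#' for (marker, batch) combinations absent per [marker_availability()] are
#' written as the `NA` sentinel, never 0.
#'
#' @param values numeric matrix, same shape as `ds$counts`.
#' @param ds the [adt_dataset()] the values belong to.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_normalized <- function(values, ds, path) {
  stopifnot(inherits(ds, "adt_dataset"))
  values <- as.matrix(values)
  if (!all(dim(values) == dim(ds$counts)))
    stop("values shape ", toString(dim(values)), " does not match dataset ",
         toString(dim(ds$counts)))
  if (nrow(values) == 0) {
    writeLines(paste(c("cell_id", marker_names(ds)),
                     collapse = guess_sep(path)), path)
    return(invisible(path))
  }
  txt <- if (nrow(values) > 0)
    format(values, digits = 15, trim = TRUE, scientific = FALSE)
  else matrix(character(0), 0, ncol(values))
  df <- data.frame(cell_id = cell_ids(ds), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- marker_names(ds)
  utils::write.table(df, path, sep = guess_sep(path), row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a dataset to disk (dense CSV + sparse MTX + metadata)
#'
#' @param ds an [adt_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_adt_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(cell_id = cell_ids(ds), ds$counts, check.names = FALSE)
  utils::write.table(df, file.path(dir, "counts.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE, na = "NA")
  cnt <- ds$counts
  cnt[is.na(cnt)] <- 0
  Matrix::writeMM(Matrix::Matrix(t(cnt), sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(marker_names(ds), file.path(dir, "features.tsv"))
  writeLines(cell_ids(ds), file.path(dir, "barcodes.tsv"))
  if (!is.null(ds$batch))
    utils::write.table(
      data.frame(cell_id = cell_ids(ds), batch = as.character(ds$batch)),
      file.path(dir, "metadata.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
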