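#' Write an event stream as columnar CSV plus JSON header
#'
#' The CSV holds one event per row (`bin_index`, `is_random`, in stream
#' order); the sidecar `<path>.json` records counts, domain, grid shape and
#' provenance.
#'
#' @param stream an `event_stream`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(stream, path) {
  utils::write.csv(data.frame(bin_index = stream$bin_index,
                              is_random = as.integer(stream$is_random)),
                   path, row.names = FALSE)
  jsonlite::write_json(stream_header(stream), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an event stream written by [write_stream_csv()]
#'
#' @param path CSV file path (the `<path>.json` header must sit beside it).
#' @return `event_stream`.
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  event_stream(df$bin_index, as.logical(df$is_random), domain = hdr$domain,
               grid_shape = hdr$grid_shape,
               provenance = as.list(hdr$provenance))
}

stream_header <- function(stream) {
  list(n_true = stream$n_true, n_random = stream$n_random,
       n_events = length(stream$bin_index), domain = stream$domain,
       grid_shape = stream$grid_shape, provenance = stream$provenance,
       binary_layout = "per event: uint32 bin_index (little-endian), uint8 is_random")
}

#' Write an event stream in the compact binary layout
#'
#' Fixed-width little-endian records, 5 bytes per event: an unsigned 32-bit
#' bin index followed by a one-byte random flag. The JSON header goes to
#' `<path>.json` as for the CSV writer.
#'
#' @inheritParams write_stream_csv
#' @return `path`, invisibly.
#' @export
write_stream_bin <- function(stream, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(stream$bin_index)
  raw <- raw(5L * n)
  if (n > 0L) {
    idx_bytes <- writeBin(stream$bin_index, raw(), size = 4L,
                          endian = "little")
    pos <- rep(seq(0L, by = 5L, length.out = n), each = 4L) +
      rep(1:4, times = n)
    raw[pos] <- idx_bytes
    raw[seq(5L, by = 5L, length.out = n)] <-
      as.raw(as.integer(stream$is_random))
  }
  writeBin(raw, con)
  jsonlite::write_json(stream_header(stream), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an event stream written by [write_stream_bin()]
#'
#' @param path binary file path.
#' @return `event_stream`.
#' @export
read_stream_bin <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- hdr$n_events
  raw <- readBin(path, "raw", n = 5L * n)
  idx <- if (n > 0L) {
    pos <- rep(seq(0L, by = 5L, length.out = n), each = 4L) + rep(1:4, n)
    readBin(raw[pos], "integer", n = n, size = 4L, endian = "little")
  } else integer(0)
  isr <- if (n > 0L)
    as.logical(as.integer(raw[seq(5L, by = 5L, length.out = n)]))
  else logical(0)
  event_stream(idx, isr, domain = hdr$domain, grid_shape = hdr$grid_shape,
               provenance = as.list(hdr$provenance))
}

#' Write a volume as NIfTI
#'
#' Writes with an RAS+ affine built from the voxel size.
#'
#' @param vol numeric/integer array (SUV image, label map or mask).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(4, 4, 4)) {
  arr <- array(as.numeric(unclass(vol)), dim(vol))
  ni <- RNifti::asNifti(arr)
  RNifti::pixdim(ni) <- rep_len(voxel_size, length(dim(arr)))
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' Export a phantom as NIfTI volumes plus JSON sidecar
#'
#' Writes `<prefix>_suv.nii.gz`, `<prefix>_labels.nii.gz` and
#' `<prefix>_spec.json`.
#'
#' @param phantom an `activity_phantom`.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
export_phantom <- function(phantom, prefix) {
  vs <- phantom$spec$voxel_size
  p1 <- paste0(prefix, "_suv.nii.gz")
  p2 <- paste0(prefix, "_labels.nii.gz")
  p3 <- paste0(prefix, "_spec.json")
  write_volume_nifti(phantom$suv_map, p1, vs)
  write_volume_nifti(phantom$label_map, p2, vs)
  spec <- phantom$spec
  spec$lesions <- lapply(spec$lesions, function(l)
    list(center = l$center, volume_ml = l$volume_ml, suv = l$suv))
  jsonlite::write_json(unclass(spec), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
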