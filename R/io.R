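#' Read / write BIDS-style event tables
#'
#' Tab-separated, UTF-8, `n/a` sentinel for absent values. Required columns:
#' `onset`, `duration`, `speaker`, `word`; `response`, `response_time`,
#' `missing`, `run` are carried when present. Rows are sorted by onset on
#' read (with a warning if the file was unsorted).
#'
#' @param path file path.
#' @return [read_events()]: an `event_table`; [write_events()]: the path,
#'   invisibly.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          stringsAsFactors = FALSE)
  required <- c("onset", "duration", "speaker", "word")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    vl_error(paste("events file lacks column(s):", paste(miss, collapse = ", ")),
             "voicelight_schema_error")
  }
  if ("run" %in% names(df)) {
    ord <- order(df$run, df$onset)
  } else {
    df$run <- 1L
    ord <- order(df$onset)
  }
  if (is.unsorted(ord)) {
    warning("events not sorted by onset; sorting on read")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  if ("missing" %in% names(df)) df$missing <- as.logical(df$missing)
  structure(df, class = c("event_table", "data.frame"),
            speakers = sort(unique(df$speaker)),
            words = sort(unique(df$word)))
}

#' @param events an `event_table` (or compatible data frame).
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "n/a",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti keeping voxel sizes attached. 3D and 4D images
#' only; gzipped files are handled transparently.
#'
#' @param path file path (.nii or .nii.gz).
#' @return [read_volume()]: numeric array (3D or 4D) with attributes
#'   `voxel_size_mm` and `affine`; [write_volume()]: the path, invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L)) {
    vl_error(paste0("expected a 3D or 4D volume, got ", nd, "D"),
             "voicelight_schema_error")
  }
  pix <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_size_mm") <- pix[1:3]
  attr(arr, "affine") <- unclass(RNifti::xform(img))
  arr
}

#' @param vol 3D or 4D numeric array (logical masks are written as 0/1).
#' @param voxel_size_mm voxel spacing recorded in the header.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path, voxel_size_mm = c(2, 2, 2)) {
  nd <- length(dim(vol))
  if (!nd %in% c(3L, 4L)) {
    vl_error("only 3D or 4D arrays can be written", "voicelight_schema_error")
  }
  storage.mode(vol) <- "double"
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, nd - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that volumes share a grid and affine
#'
#' @param vols list of arrays from [read_volume()].
#' @return TRUE invisibly; co-registration mismatch raises an error.
#' @export
check_coregistered <- function(vols) {
  ref_dim <- dim(vols[[1]])[1:3]
  ref_aff <- attr(vols[[1]], "affine")
  for (v in vols[-1]) {
    same_dim <- all(dim(v)[1:3] == ref_dim)
    same_aff <- is.null(ref_aff) || is.null(attr(v, "affine")) ||
      isTRUE(all.equal(ref_aff, attr(v, "affine"), tolerance = 1e-6))
    if (!same_dim || !same_aff) {
      vl_error("volumes are not co-registered (grid or affine mismatch)",
               "voicelight_coregistration_error")
    }
  }
  invisible(TRUE)
}

# JSON provenance sidecar next to an output file.
write_sidecar <- function(path, info) {
  side <- paste0(tools::file_path_sans_ext(path, compression = TRUE), ".json")
  jsonlite::write_json(info, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}
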