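#' Read and write grayscale images
#'
#' 8-bit grayscale PNG (lossless round trip for integer \[0, 255\] images)
#' or plain CSV matrices (full precision). Color PNGs are collapsed to
#' luminance with a warning. Other extensions are rejected by name.
#'
#' @param path file path ending in `.png` or `.csv`.
#' @param image numeric matrix (or phantom) on the \[0, 255\] scale.
#' @return `read_image()`: numeric matrix in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      warning("color PNG collapsed to luminance")
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    }
    a * 255
  } else if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    stop(sprintf("unsupported image format '.%s' (use .png or .csv)", ext),
         call. = FALSE)
  }
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  u <- as_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(round(clip01(u, 0, 255)) / 255, path)
  } else if (ext == "csv") {
    utils::write.table(u, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop(sprintf("unsupported image format '.%s' (use .png or .csv)", ext),
         call. = FALSE)
  }
  invisible(path)
}

# ---- native array container: JSON manifest + arrays --------------------

#' Serialize k-space data, sampling masks and dictionaries
#'
#' The package's native array container is a JSON object with a manifest
#' (`type`, `shape`, auxiliary metadata) and the array values (complex
#' arrays as separate real/imaginary vectors, column-major). Everything
#' written can be read back to an equal in-memory value.
#'
#' @param kspace,mask,dictionary the object to write.
#' @param path output `.json` path.
#' @return the read functions return `kspace`, `sampling_mask` and
#'   `sparse_dictionary` objects respectively.
#' @name array-io
NULL

#' @rdname array-io
#' @export
write_kspace <- function(kspace, path) {
  v <- as_kspace_values(kspace)
  jsonlite::write_json(list(type = "kspace", shape = dim(v),
                            real = as.vector(Re(v)),
                            imag = as.vector(Im(v))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname array-io
#' @export
read_kspace <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "kspace")) stop("not a kspace container",
                                         call. = FALSE)
  structure(list(values = matrix(complex(real = j$real, imaginary = j$imag),
                                 j$shape[1], j$shape[2])),
            class = "kspace")
}

#' @rdname array-io
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {     # 0/255 visualization; metadata is lost
    png::writePNG(as_mask_matrix(mask) * 1, path)
    return(invisible(path))
  }
  if (!inherits(mask, "sampling_mask"))
    mask <- new_sampling_mask(as_mask_matrix(mask), "custom", NA_real_)
  jsonlite::write_json(list(type = "sampling_mask", shape = dim(mask$mask),
                            trajectory = mask$trajectory,
                            requested_factor = mask$requested_factor,
                            mask = as.integer(mask$mask)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname array-io
#' @export
read_mask <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "sampling_mask")) stop("not a sampling_mask container",
                                                call. = FALSE)
  m <- matrix(as.logical(j$mask), j$shape[1], j$shape[2])
  new_sampling_mask(m, j$trajectory,
                    if (is.null(j$requested_factor)) NA_real_
                    else j$requested_factor)
}

#' @rdname array-io
#' @export
write_dictionary <- function(dictionary, path) {
  D <- as_atoms(dictionary)
  jsonlite::write_json(list(type = "dictionary", shape = dim(D),
                            patch_size = dictionary$patch_size,
                            method = dictionary$method,
                            atoms = as.vector(D)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname array-io
#' @export
read_dictionary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "dictionary")) stop("not a dictionary container",
                                             call. = FALSE)
  structure(list(atoms = matrix(j$atoms, j$shape[1], j$shape[2]),
                 patch_size = j$patch_size, method = j$method),
            class = "sparse_dictionary")
}

# ---- tables ------------------------------------------------------------

cohort_columns <- c("patient_id", "group", "adc", "correct")

#' Read and write diagnostic/benchmark tables
#'
#' CSV with a documented header. `schema = "cohort"` requires columns
#' `patient_id, group, adc, correct` and reports malformed rows with their
#' line numbers; extra columns pass through untouched.
#'
#' @param path CSV path.
#' @param table data.frame to write.
#' @param schema one of "cohort", "none".
#' @return `read_table()` returns a validated data.frame.
#' @export
read_table <- function(path, schema = c("cohort", "none")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)
  if (schema == "cohort") {
    miss <- setdiff(cohort_columns, names(d))
    if (length(miss))
      stop(sprintf("missing column(s) %s; expected header: %s",
                   paste(miss, collapse = ", "),
                   paste(cohort_columns, collapse = ",")), call. = FALSE)
    bad <- which(!is.finite(d$adc) | d$adc <= 0 |
                   !(d$correct %in% c(0, 1)) | is.na(d$group) | d$group == "")
    if (length(bad))
      stop(sprintf("malformed row(s) at line(s): %s",
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    d$group <- factor(d$group)
  }
  d
}

#' @rdname read_table
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read and write run configuration (YAML)
#'
#' YAML mirror of [recon_config()]; unknown keys are rejected.
#'
#' @param path YAML path.
#' @param config a `recon_config`.
#' @return `read_config()` returns a `recon_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(recon_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(recon_config, y)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$reference <- NULL
  yaml::write_yaml(x[!vapply(x, is.null, TRUE)], path)
  invisible(path)
}
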