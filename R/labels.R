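# Text-format plumbing for the detector: YOLO-style label files and YAML
# architecture configs.

#' Read a YOLO-style label file
#'
#' Each line is `class cx cy w h` with coordinates normalised to `[0, 1]`
#' relative to the image size.
#'
#' @param path Label file path.
#' @param image_width,image_height Optional pixel dimensions; when given,
#'   pixel-space `left/top/width/height` columns are added.
#' @return A tibble with columns `class_id`, `cx`, `cy`, `w`, `h` (and pixel
#'   columns when dimensions are supplied).
#' @export
read_yolo_labels <- function(path, image_width = NULL, image_height = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                  w = numeric(), h = numeric())
  } else {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    bad <- which(lengths(parts) != 5L)
    if (length(bad) > 0L) {
      stop_input(sprintf("line %d: expected 5 whitespace-separated fields", bad[1]))
    }
    m <- matrix(as.numeric(unlist(parts)), ncol = 5L, byrow = TRUE)
    if (any(!is.finite(m))) stop_input("non-numeric field in label file")
    out <- tibble(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                  w = m[, 4], h = m[, 5])
  }
  if (!is.null(image_width) && !is.null(image_height)) {
    out <- dplyr::mutate(out,
      width = .data$w * image_width, height = .data$h * image_height,
      left = .data$cx * image_width - .data$width / 2,
      top = .data$cy * image_height - .data$height / 2)
  }
  out
}

#' Write a YOLO-style label file
#'
#' @param labels A tibble with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- sprintf("%d %.10g %.10g %.10g %.10g", as.integer(labels$class_id),
                   labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Write an architecture config as YAML
#'
#' @param cfg An [arch_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arch_config <- function(cfg, path) {
  if (!inherits(cfg, "cellmot_arch_config")) stop_config("`cfg` must be an arch_config()")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read an architecture config from YAML
#'
#' @param path YAML file written by [write_arch_config()].
#' @return An [arch_config()].
#' @export
read_arch_config <- function(path) {
  raw <- yaml::read_yaml(path)
  arch_config(nc = raw$nc, input_size = raw$input_size, variant = raw$variant,
              iema_groups = raw$iema_groups,
              gsconv_dw_kernel = raw$gsconv_dw_kernel)
}
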