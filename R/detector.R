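# Assembly of the nano-scale one-stage detector topology and its variants.
#
# The layer graph is represented as a tibble: one row per layer with the
# module type, input references and a nested parameter-tensor table. The
# graph is used for exact parameter accounting and structural inspection;
# detection inference is an injection contract (see detect()).
#
# Variants:
#   baseline — the reference nano topology.
#   iema     — baseline + one inverted-residual attention block inserted on
#              the small-object (P3) neck branch (64 channels at nano width).
#   gsconv   — baseline with the two neck downsample convolutions on the
#              P4/P5 fusion paths replaced by group-shuffle convolutions.
#   iegs     — both modifications.

#' Architecture configuration
#'
#' @param nc Number of object classes (>= 1).
#' @param input_size Input image side in pixels (default 640). Parameter
#'   counts are invariant to it; it is carried for inference plumbing.
#' @param variant One of `"baseline"`, `"iema"`, `"gsconv"`, `"iegs"`
#'   (`"+iema"`/`"+gsconv"` are accepted aliases).
#' @param iema_groups Group factor of the attention block (default 32).
#' @param gsconv_dw_kernel Depthwise kernel of the group-shuffle convolution
#'   (default 5).
#' @return A `cellmot_arch_config` list, including the named insertion points
#'   the variant touches.
#' @export
arch_config <- function(nc = 14L, input_size = 640L,
                        variant = c("baseline", "iema", "gsconv", "iegs"),
                        iema_groups = 32L, gsconv_dw_kernel = 5L) {
  if (is.character(variant)) variant <- sub("^\\+", "", variant)
  variant <- match.arg(variant)
  structure(list(
    nc = check_count(nc, "nc"),
    input_size = check_count(input_size, "input_size"),
    variant = variant,
    iema_insertion = "neck_p3_c3k2",
    gsconv_replacements = c("neck_p4_down", "neck_p5_down"),
    iema_groups = check_count(iema_groups, "iema_groups"),
    gsconv_dw_kernel = check_count(gsconv_dw_kernel, "gsconv_dw_kernel")
  ), class = "cellmot_arch_config")
}

# ---- module tensor tables for the detector skeleton -------------------------

tt_bottleneck <- function(p, c1, c2, e = 0.5) {
  ch <- floor(c2 * e)
  dplyr::bind_rows(tt_conv_bn(paste0(p, ".cv1"), c1, ch, 3),
                   tt_conv_bn(paste0(p, ".cv2"), ch, c2, 3))
}

tt_c3k <- function(p, c1, c2, n = 2, e = 0.5) {
  ch <- floor(c2 * e)
  out <- dplyr::bind_rows(tt_conv_bn(paste0(p, ".cv1"), c1, ch, 1),
                          tt_conv_bn(paste0(p, ".cv2"), c1, ch, 1),
                          tt_conv_bn(paste0(p, ".cv3"), 2 * ch, c2, 1))
  for (i in seq_len(n)) {
    out <- dplyr::bind_rows(out, tt_bottleneck(paste0(p, ".m", i), ch, ch, e = 1))
  }
  out
}

tt_c3k2 <- function(p, c1, c2, n = 1, use_c3k = FALSE, e = 0.5) {
  ch <- floor(c2 * e)
  out <- dplyr::bind_rows(tt_conv_bn(paste0(p, ".cv1"), c1, 2 * ch, 1),
                          tt_conv_bn(paste0(p, ".cv2"), (2 + n) * ch, c2, 1))
  for (i in seq_len(n)) {
    sub <- if (use_c3k) tt_c3k(paste0(p, ".m", i), ch, ch) else {
      tt_bottleneck(paste0(p, ".m", i), ch, ch)
    }
    out <- dplyr::bind_rows(out, sub)
  }
  out
}

tt_sppf <- function(p, c1, c2) {
  ch <- c1 %/% 2
  dplyr::bind_rows(tt_conv_bn(paste0(p, ".cv1"), c1, ch, 1),
                   tt_conv_bn(paste0(p, ".cv2"), 4 * ch, c2, 1))
}

tt_attention <- function(p, dim, num_heads, attn_ratio = 0.5) {
  key_dim <- floor(dim / num_heads * attn_ratio)
  h <- dim + 2 * key_dim * num_heads
  dplyr::bind_rows(tt_conv_bn(paste0(p, ".qkv"), dim, h, 1),
                   tt_conv_bn(paste0(p, ".proj"), dim, dim, 1),
                   tt_conv_bn(paste0(p, ".pe"), dim, dim, 3, g = dim))
}

tt_psablock <- function(p, c) {
  dplyr::bind_rows(tt_attention(paste0(p, ".attn"), c, max(1, c %/% 64)),
                   tt_conv_bn(paste0(p, ".ffn1"), c, 2 * c, 1),
                   tt_conv_bn(paste0(p, ".ffn2"), 2 * c, c, 1))
}

tt_c2psa <- function(p, c1, c2, n = 1) {
  ch <- floor(c2 * 0.5)
  out <- dplyr::bind_rows(tt_conv_bn(paste0(p, ".cv1"), c1, 2 * ch, 1),
                          tt_conv_bn(paste0(p, ".cv2"), 2 * ch, c1, 1))
  for (i in seq_len(n)) {
    out <- dplyr::bind_rows(out, tt_psablock(paste0(p, ".m", i), ch))
  }
  out
}

tt_detect <- function(p, nc, ch = c(64, 128, 256), reg_max = 16) {
  c2h <- max(16, ch[1] %/% 4, reg_max * 4)
  c3h <- max(ch[1], min(nc, 100))
  out <- NULL
  for (i in seq_along(ch)) {
    x <- ch[i]
    out <- dplyr::bind_rows(
      out,
      tt_conv_bn(sprintf("%s.box%d.0", p, i), x, c2h, 3),
      tt_conv_bn(sprintf("%s.box%d.1", p, i), c2h, c2h, 3),
      tt_conv2d(sprintf("%s.box%d.2", p, i), c2h, 4 * reg_max, 1),
      tt_conv_bn(sprintf("%s.cls%d.0", p, i), x, x, 3, g = x),
      tt_conv_bn(sprintf("%s.cls%d.1", p, i), x, c3h, 1),
      tt_conv_bn(sprintf("%s.cls%d.2", p, i), c3h, c3h, 3, g = c3h),
      tt_conv_bn(sprintf("%s.cls%d.3", p, i), c3h, c3h, 1),
      tt_conv2d(sprintf("%s.cls%d.4", p, i), c3h, nc, 1)
    )
  }
  # distributional box-decoding projection (fixed weights, part of the graph)
  dplyr::bind_rows(out, tt_row(paste0(p, ".dfl.weight"), reg_max))
}

# ---- graph assembly ---------------------------------------------------------

layer_row <- function(idx, name, module, from, c_out, section, tensors) {
  nt <- sum(tensors$n_train)
  nd <- sum(tensors$n_deploy)
  tibble(idx = idx, name = name, module = module, from = list(from),
         c_out = c_out, section = section, tensors = list(tensors),
         n_train = nt, n_deploy = nd)
}

no_params <- function() tt_row(character(0), numeric(0))[0, ]

#' Build the detector layer graph
#'
#' Assembles the nano-scale topology for the requested variant and enumerates
#' every parameter tensor layer by layer.
#'
#' @param cfg An [arch_config()].
#' @return A `cellmot_model`: list with elements `cfg` and `layers` (a tibble
#'   with one row per layer and a nested tensor table).
#' @export
build_model <- function(cfg = arch_config()) {
  if (!inherits(cfg, "cellmot_arch_config")) stop_config("`cfg` must be an arch_config()")
  nc <- cfg$nc
  with_iema <- cfg$variant %in% c("iema", "iegs")
  with_gsconv <- cfg$variant %in% c("gsconv", "iegs")

  L <- list()
  add <- function(...) L[[length(L) + 1L]] <<- layer_row(...)

  add(0L, "stem", "conv", -1L, 16L, "backbone", tt_conv_bn("stem", 3, 16, 3))
  add(1L, "down_p2", "conv", -1L, 32L, "backbone", tt_conv_bn("down_p2", 16, 32, 3))
  add(2L, "stage_p2", "c3k2", -1L, 64L, "backbone", tt_c3k2("stage_p2", 32, 64, e = 0.25))
  add(3L, "down_p3", "conv", -1L, 64L, "backbone", tt_conv_bn("down_p3", 64, 64, 3))
  add(4L, "stage_p3", "c3k2", -1L, 128L, "backbone", tt_c3k2("stage_p3", 64, 128, e = 0.25))
  add(5L, "down_p4", "conv", -1L, 128L, "backbone", tt_conv_bn("down_p4", 128, 128, 3))
  add(6L, "stage_p4", "c3k2", -1L, 128L, "backbone",
      tt_c3k2("stage_p4", 128, 128, use_c3k = TRUE))
  add(7L, "down_p5", "conv", -1L, 256L, "backbone", tt_conv_bn("down_p5", 128, 256, 3))
  add(8L, "stage_p5", "c3k2", -1L, 256L, "backbone",
      tt_c3k2("stage_p5", 256, 256, use_c3k = TRUE))
  add(9L, "sppf", "sppf", -1L, 256L, "backbone", tt_sppf("sppf", 256, 256))
  add(10L, "psa", "c2psa", -1L, 256L, "backbone", tt_c2psa("psa", 256, 256))

  add(11L, "up1", "upsample", -1L, 256L, "neck", no_params())
  add(12L, "cat1", "concat", c(-1L, 6L), 384L, "neck", no_params())
  add(13L, "neck_p4_mid", "c3k2", -1L, 128L, "neck", tt_c3k2("neck_p4_mid", 384, 128))
  add(14L, "up2", "upsample", -1L, 128L, "neck", no_params())
  add(15L, "cat2", "concat", c(-1L, 4L), 256L, "neck", no_params())
  add(16L, "neck_p3_c3k2", "c3k2", -1L, 64L, "neck", tt_c3k2("neck_p3_c3k2", 256, 64))

  if (with_iema) {
    add(NA_integer_, "neck_p3_iema", "iema", -1L, 64L, "neck",
        tt_iema("neck_p3_iema", 64, cfg$iema_groups))
  }

  if (with_gsconv) {
    add(17L, "neck_p4_down", "gsconv", -1L, 64L, "neck",
        tt_gsconv("neck_p4_down", 64, 64, 3, cfg$gsconv_dw_kernel))
  } else {
    add(17L, "neck_p4_down", "conv", -1L, 64L, "neck",
        tt_conv_bn("neck_p4_down", 64, 64, 3))
  }
  add(18L, "cat3", "concat", c(-1L, 13L), 192L, "neck", no_params())
  add(19L, "neck_p4_c3k2", "c3k2", -1L, 128L, "neck", tt_c3k2("neck_p4_c3k2", 192, 128))
  if (with_gsconv) {
    add(20L, "neck_p5_down", "gsconv", -1L, 128L, "neck",
        tt_gsconv("neck_p5_down", 128, 128, 3, cfg$gsconv_dw_kernel))
  } else {
    add(20L, "neck_p5_down", "conv", -1L, 128L, "neck",
        tt_conv_bn("neck_p5_down", 128, 128, 3))
  }
  add(21L, "cat4", "concat", c(-1L, 10L), 384L, "neck", no_params())
  add(22L, "neck_p5_c3k2", "c3k2", -1L, 256L, "neck",
      tt_c3k2("neck_p5_c3k2", 384, 256, use_c3k = TRUE))
  add(23L, "head", "detect", c(16L, 19L, 22L), nc, "head", tt_detect("head", nc))

  structure(list(cfg = cfg, layers = dplyr::bind_rows(L)), class = "cellmot_model")
}

#' Exact parameter count of a detector graph
#'
#' Sums the per-layer tensor enumeration of [build_model()].
#'
#' @param model A `cellmot_model`.
#' @param convention `"deployment"` (each fusable conv+BN pair counted as conv
#'   weights plus one folded per-channel bias — the convention under which
#'   deployed model sizes are reported and the default) or `"training"`
#'   (every trainable scalar, batch-norm affine pairs included).
#' @return A single number.
#' @export
count_parameters <- function(model, convention = c("deployment", "training")) {
  if (!inherits(model, "cellmot_model")) stop_input("`model` must come from build_model()")
  convention <- match.arg(convention)
  col <- if (convention == "deployment") "n_deploy" else "n_train"
  sum(model$layers[[col]])
}

#' @export
print.cellmot_model <- function(x, ...) {
  cat(sprintf("<cellmot_model> variant=%s nc=%d layers=%d params(deployment)=%s\n",
              x$cfg$variant, x$cfg$nc, nrow(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @method tidy cellmot_model
#' @export
tidy.cellmot_model <- function(x, ...) {
  dplyr::select(x$layers, "idx", "name", "module", "section", "c_out",
                "n_train", "n_deploy")
}

#' @method glance cellmot_model
#' @export
glance.cellmot_model <- function(x, ...) {
  tibble(variant = x$cfg$variant, nc = x$cfg$nc, n_layers = nrow(x$layers),
         params_deployment = count_parameters(x, "deployment"),
         params_training = count_parameters(x, "training"))
}

# ---- inference contract -----------------------------------------------------

#' Stub detector backend returning injected detections
#'
#' Builds a backend function for [detect()] that returns pre-specified boxes
#' per frame index, unchanged. Used to drive the tracker with oracle or
#' synthetic detections.
#'
#' @param detections A tibble with columns `frame`, `left`, `top`, `width`,
#'   `height`, `score` and optionally `class_id`.
#' @return A function `(frame, frame_index) -> tibble` usable as `backend`.
#' @export
stub_detector <- function(detections) {
  detections <- as_tibble(detections)
  if (!"class_id" %in% names(detections)) detections$class_id <- 0L
  function(frame, frame_index) {
    dplyr::filter(detections, .data$frame == frame_index)[
      , c("left", "top", "width", "height", "score", "class_id")]
  }
}

#' Run per-frame detection
#'
#' Applies a detection backend to an ordered frame sequence and returns one
#' row per detection in pixel coordinates of the input frame (0-based, boxes
#' as left/top/width/height). Deterministic for a deterministic backend.
#'
#' @param frames A list of frames (matrices or arrays); may be empty. Frames
#'   may also be `NULL` placeholders when the backend only uses the index
#'   (detection-only mode).
#' @param backend A function `(frame, frame_index) -> tibble` with columns
#'   `left`, `top`, `width`, `height`, `score`, `class_id`; see
#'   [stub_detector()].
#' @param cfg An [arch_config()] (carried for class-count validation).
#' @return A tibble with columns `frame`, `left`, `top`, `width`, `height`,
#'   `score`, `class_id`.
#' @export
detect <- function(frames, backend, cfg = arch_config()) {
  if (!is.function(backend)) stop_input("`backend` must be a function")
  empty <- tibble(frame = integer(), left = numeric(), top = numeric(),
                  width = numeric(), height = numeric(), score = numeric(),
                  class_id = integer())
  if (length(frames) == 0L) return(empty)
  out <- purrr::imap(frames, function(fr, i) {
    res <- as_tibble(backend(fr, as.integer(i)))
    if (nrow(res) == 0L) return(empty[0, -1])
    needed <- c("left", "top", "width", "height", "score", "class_id")
    if (!all(needed %in% names(res))) {
      stop_input("backend must return left/top/width/height/score/class_id")
    }
    res <- res[, needed]
    if (any(res$width <= 0 | res$height <= 0)) stop_input("boxes must have positive extent")
    if (any(res$score < 0 | res$score > 1)) stop_input("scores must lie in [0, 1]")
    if (any(res$class_id < 0 | res$class_id >= cfg$nc)) {
      stop_input("class_id out of range for the configured class count")
    }
    res
  })
  dplyr::bind_rows(purrr::map2(out, seq_along(out), function(d, i) {
    dplyr::mutate(d, frame = as.integer(i), .before = 1)
  }))
}
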