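vca_config_defaults <- function() {
  list(
    `start.line_length` = 7L,
    `start.n_directions` = 4L,
    `start.empty_line_proportion_max` = 0.5,
    `grow.d_max` = 2,
    `effective_intensity` = "otsu",
    `binarize.n_bins` = 256L,
    `binarize.manual_threshold` = NA_real_,
    `filter.min_branch_length` = 5,
    `filter.min_ratio` = 3,
    `quantify.diagonal_weighting` = FALSE,
    `io.roi` = NA_character_,
    `io.calibration_mm_per_px` = NA_real_,
    `run.seed` = NA_integer_,
    `run.log_level` = "info")
}

#' Pipeline configuration
#'
#' Flat, namespaced configuration covering every tunable of the pipeline.
#' Unknown keys are rejected and all values are validated before any
#' computation. `effective_intensity` is either a number in `[0, 1]` or the
#' string `"otsu"`; `io.roi` is `"top,left,height,width"` (0-based) or `NA`
#' for the full image.
#'
#' @param ... Named overrides of the defaults, e.g.
#'   `vca_config(\`grow.d_max\` = 3)`.
#' @return A named list of validated settings (class `vca_config`).
#' @export
vca_config <- function(...) {
  cfg <- vca_config_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    vca_stop("all configuration overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    vca_stop(paste0("unknown configuration key(s): ",
                    paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "vca_config")
}

validate_config <- function(cfg) {
  ei <- cfg$effective_intensity
  if (!(identical(ei, "otsu") ||
        (is.numeric(ei) && length(ei) == 1L && !is.na(ei) && ei >= 0 && ei <= 1))) {
    vca_stop("`effective_intensity` must be \"otsu\" or a number in [0, 1]")
  }
  start_point_params(cfg$`start.line_length`, cfg$`start.n_directions`,
                     NULL, cfg$`start.empty_line_proportion_max`)
  growth_params(cfg$`grow.d_max`, NULL)
  filter_params(cfg$`filter.min_branch_length`, cfg$`filter.min_ratio`)
  if (cfg$`binarize.n_bins` < 2) vca_stop("`binarize.n_bins` must be >= 2")
  mt <- cfg$`binarize.manual_threshold`
  if (!is.na(mt) && (mt < 0 || mt > 1)) {
    vca_stop("`binarize.manual_threshold` must be in [0, 1]")
  }
  if (!is.na(cfg$`io.roi`)) parse_roi(cfg$`io.roi`)
  invisible(cfg)
}

parse_roi <- function(spec) {
  parts <- suppressWarnings(as.integer(strsplit(as.character(spec), ",")[[1L]]))
  if (length(parts) != 4L || anyNA(parts)) {
    vca_stop("`io.roi` must be \"top,left,height,width\" (0-based integers)")
  }
  rect_roi(parts[1L], parts[2L], parts[3L], parts[4L])
}

#' Render a configuration as key=value text
#'
#' @param cfg A [vca_config()].
#' @return Character vector of `key=value` lines.
#' @export
config_text <- function(cfg = vca_config()) {
  vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s=%s", k, if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
}

#' Read a configuration file
#'
#' Flat `key=value` lines; `#` starts a comment; blank lines ignored.
#' File values are overridden by `...` (as CLI flags override a file).
#'
#' @param path Path to the file.
#' @param ... Further overrides, applied after the file.
#' @return A [vca_config()].
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) vca_io_stop(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- vca_config_defaults()
  vals <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) vca_stop(sprintf("malformed config line (no '='): %s", ln))
    k <- trimws(substr(ln, 1L, eq - 1L))
    v <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!k %in% names(defaults)) {
      vca_stop(sprintf("unknown configuration key: %s", k))
    }
    proto <- defaults[[k]]
    if (v == "NA" || v == "") {
      vals[[k]] <- proto[NA][1L]  # NA of the key's own type
      next
    }
    vals[[k]] <- if (k == "effective_intensity") {
      if (identical(v, "otsu")) "otsu" else as.numeric(v)
    } else if (is.integer(proto)) {
      as.integer(v)
    } else if (is.numeric(proto)) {
      as.numeric(v)
    } else if (is.logical(proto)) {
      as.logical(v)
    } else {
      v
    }
  }
  do.call(vca_config, c(vals, list(...)))
}

#' Segment a microvascular network in an OCTA angiogram
#'
#' Runs the full improved-VCA pipeline: (optional) crop to the region of
#' interest and grayscale conversion; starting-point detection and
#' gap-tolerant connectivity growth merged over four quarter-turn rotations;
#' Otsu (or manual) binarization restricted to the grown network;
#' Zhang-Suen skeletonization; piece-by-piece branch-graph filtering of
#' noise and artifacts; and length/area/width quantification of the
#' surviving network.
#'
#' A constant image (e.g. all black) has no Otsu threshold; the pipeline
#' returns an empty segmentation with zero length rather than failing.
#'
#' @param img Grayscale matrix in `[0, 1]`, RGB array, or a file path.
#' @param config A [vca_config()].
#' @return A `vca_segmentation` object: stage rasters (`gray`, `network`,
#'   `binary`, `skeleton_raw`, `skeleton`, `mask`), the filtered `graph`,
#'   `components` (per-component decisions), one-row `metrics`, and the
#'   `threshold` actually used.
#' @export
segment_angiogram <- function(img, config = vca_config()) {
  validate_config(config)
  if (is.character(img)) img <- read_image(img)
  img <- to_grayscale(img)
  if (!is.na(config$`io.roi`)) img <- crop_roi(img, parse_roi(config$`io.roi`))
  assert_gray(img)

  thr <- if (!is.na(config$`binarize.manual_threshold`)) {
    config$`binarize.manual_threshold`
  } else if (identical(config$effective_intensity, "otsu")) {
    tryCatch(otsu_threshold(img, config$`binarize.n_bins`),
             octavca_validation_error = function(e) NA_real_)
  } else {
    config$effective_intensity
  }

  empty <- matrix(FALSE, nrow(img), ncol(img))
  if (is.na(thr)) {
    graph <- skeleton_graph(empty)
    out <- list(gray = img, threshold = NA_real_, network = empty,
                binary = empty, skeleton_raw = empty, graph = graph,
                skeleton = empty, mask = empty,
                components = tibble::tibble(),
                metrics = measure_vessels(empty, empty),
                config = config)
    return(structure(out, class = "vca_segmentation"))
  }

  sp <- start_point_params(config$`start.line_length`,
                           config$`start.n_directions`, thr,
                           config$`start.empty_line_proportion_max`)
  gp <- growth_params(config$`grow.d_max`, thr)
  network <- extract_network(img, sp, gp)
  binary <- binarize_network(img, network, thr)
  skeleton_raw <- skeletonize(binary)
  graph_raw <- skeleton_graph(skeleton_raw, warn_nonthin = FALSE)
  fp <- filter_params(config$`filter.min_branch_length`,
                      config$`filter.min_ratio`)
  graph <- filter_pieces(graph_raw, fp)
  mask <- mask_from_graph(graph, binary)
  mm <- config$`io.calibration_mm_per_px`
  metrics <- measure_vessels(graph$skeleton, mask,
                             diagonal_weighted = config$`quantify.diagonal_weighting`,
                             mm_per_px = if (is.na(mm)) NULL else mm)
  structure(list(gray = img, threshold = thr, network = network,
                 binary = binary, skeleton_raw = skeleton_raw, graph = graph,
                 skeleton = graph$skeleton, mask = mask,
                 components = attr(graph, "decisions") %||% tibble::tibble(),
                 metrics = metrics, config = config),
            class = "vca_segmentation")
}

#' @export
print.vca_segmentation <- function(x, ...) {
  cat(sprintf("<vca_segmentation> %dx%d image, threshold %s\n",
              nrow(x$gray), ncol(x$gray),
              if (is.na(x$threshold)) "NA (degenerate image)"
              else format(x$threshold, digits = 4)))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.vca_segmentation <- function(x, ...) {
  tibble::as_tibble(x$components)
}

#' @export
glance.vca_segmentation <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(threshold = x$threshold,
                       n_components_kept = if (nrow(x$components)) {
                         sum(x$components$kept)
                       } else 0L,
                   n_components_removed = if (nrow(x$components)) {
                     sum(!x$components$kept)
                   } else 0L))
}

#' Plot the stages of a segmentation
#'
#' Raster panels of the pipeline stages (gray input, extracted network,
#' binarized network, raw skeleton, filtered skeleton, final mask), the
#' same intermediates a reader checks visually.
#'
#' @param object A [segment_angiogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vca_segmentation <- function(object, ...) {
  stage_levels <- c("input", "network", "binarized", "skeleton",
                    "filtered skeleton", "final mask")
  as_df <- function(m, stage) {
    v <- if (is.logical(m)) m * 1 else m
    tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(v), stage = stage)
  }
  df <- dplyr::bind_rows(
    as_df(object$gray, "input"),
    as_df(object$network, "network"),
    as_df(object$binary, "binarized"),
    as_df(object$skeleton_raw, "skeleton"),
    as_df(object$skeleton, "filtered skeleton"),
    as_df(object$mask, "final mask"))
  df$stage <- factor(df$stage, levels = stage_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
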