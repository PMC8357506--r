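# Frame and configuration I/O.

#' Read a grayscale frame sequence
#'
#' Accepts a directory of PNG/TIFF frames (sorted by file name), a character
#' vector of file paths, or a single multi-page TIFF. RGB frames are
#' converted with the Rec. 601 luma weights.
#'
#' @param path Directory, file path(s), or one multi-page TIFF.
#' @return List of numeric matrices in \[0, 1\].
#' @export
read_frames <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                            ignore.case = TRUE, full.names = TRUE))
    if (length(path) == 0) abort("no PNG/TIFF frames found",
                                 class = "echotrack_io_error")
  }
  frames <- list()
  for (p in path) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      frames[[length(frames) + 1]] <- to_gray(png::readPNG(p))
    } else {
      pages <- tiff::readTIFF(p, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      for (pg in pages) frames[[length(frames) + 1]] <- to_gray(pg)
    }
  }
  frames
}

#' Write a frame as PNG
#'
#' @param frame Numeric matrix; values are clipped to \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  assert_frame(frame)
  png::writePNG(clip01(frame), path)
  invisible(path)
}

# Serialize a track_config tree to/from JSON. Sub-configs are stored as
# plain lists; classes are restored on read.
#' Write a tracking configuration as JSON
#'
#' @param cfg A [track_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "track_config"))
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else if (is.matrix(x)) {
    list(nrow = nrow(x), values = as.numeric(x))
  } else x
}

#' Read a tracking configuration from JSON
#'
#' Missing fields take the package defaults.
#'
#' @param path JSON file written by [write_track_config()] (or hand-edited).
#' @return A [track_config()].
#' @export
read_track_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  # call each constructor with the stored fields so derived values (e.g. the
  # scale ratio k) and validation are re-applied
  rebuild <- function(node, constructor, fields) {
    if (is.null(node)) return(constructor())
    args <- node[intersect(names(node), fields)]
    do.call(constructor, args)
  }
  track_config(
    tolerance = if (!is.null(j$tolerance)) j$tolerance else 20,
    refine_with_lk = if (is.null(j$refine_with_lk)) TRUE
                     else isTRUE(j$refine_with_lk),
    reacquire = if (is.null(j$reacquire)) TRUE else isTRUE(j$reacquire),
    denoise = if (is.null(j$denoise)) TRUE else isTRUE(j$denoise),
    filter = rebuild(j$filter, mean_filter_spec, c("rows", "cols")),
    scale = rebuild(j$scale, scale_space_config,
                    c("sigma0", "scales", "octaves", "contrast_threshold",
                      "edge_ratio", "assumed_blur", "double_input",
                      "abs_response")),
    descriptor = rebuild(j$descriptor, descriptor_config,
                         c("d", "bins", "clamp_value", "normalization")),
    match = rebuild(j$match, match_config,
                    c("ratio_threshold", "search", "bbf_max_checks",
                      "mutual")),
    lk = rebuild(j$lk, lk_config,
                 c("window", "max_iterations", "convergence_tol",
                   "weight_epsilon", "pyramid_levels"))
  )
}
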