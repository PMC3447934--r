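# Manders colocalization of a red (probe) channel against a thresholded
# green (marker) channel, with per-condition group statistics.

#' Manders' M1 coefficient
#'
#' Fraction of total red-channel intensity that lies on pixels whose
#' green-channel intensity is strictly above the threshold:
#' `M1 = sum(red[green > thr]) / sum(red)`. Pixels exactly at the
#' threshold are excluded. M1 lies in `[0, 1]` and is invariant to
#' rescaling the red channel.
#'
#' @param red,green Numeric matrices of identical dimensions, finite and
#'   non-negative.
#' @param threshold Either a number (applied to the green channel) or
#'   `"otsu"` for Otsu's automatic threshold of the green channel.
#' @return M1, a scalar in `[0, 1]`, with the threshold actually used
#'   stored in attribute `"threshold"`.
#' @export
manders_m1 <- function(red, green, threshold = "otsu") {
  check_channel_pair(red, green)
  thr <- resolve_threshold(green, threshold)
  tot <- sum(red)
  if (tot <= 0) stop("total red intensity is zero; M1 undefined", call. = FALSE)
  m1 <- sum(red[green > thr]) / tot
  structure(m1, threshold = thr)
}

#' Manders' M2 coefficient (green over thresholded red)
#'
#' Symmetric counterpart of [manders_m1()]: the fraction of green
#' intensity on pixels where red exceeds the threshold. Provided for
#' completeness; the trafficking pipeline itself only uses M1.
#'
#' @inheritParams manders_m1
#' @param threshold Number or `"otsu"`, applied to the red channel.
#' @export
manders_m2 <- function(red, green, threshold = "otsu") {
  check_channel_pair(red, green)
  thr <- resolve_threshold(red, threshold)
  tot <- sum(green)
  if (tot <= 0) stop("total green intensity is zero; M2 undefined", call. = FALSE)
  structure(sum(green[red > thr]) / tot, threshold = thr)
}

check_channel_pair <- function(red, green) {
  if (!is.matrix(red) || !is.matrix(green)) {
    stop("channels must be numeric matrices", call. = FALSE)
  }
  if (!identical(dim(red), dim(green))) {
    stop("channel dimensions differ", call. = FALSE)
  }
  if (!all(is.finite(red)) || !all(is.finite(green))) {
    stop("non-finite pixel values", call. = FALSE)
  }
  if (any(red < 0) || any(green < 0)) {
    stop("negative pixel values", call. = FALSE)
  }
  invisible(TRUE)
}

resolve_threshold <- function(channel, threshold) {
  if (is.numeric(threshold)) return(as.numeric(threshold))
  if (identical(threshold, "otsu")) return(otsu_threshold(channel))
  stop("`threshold` must be numeric or \"otsu\"", call. = FALSE)
}

#' Otsu threshold of an intensity image
#'
#' Thin wrapper around `EBImage::otsu()` operating on arbitrary-range
#' non-negative matrices (EBImage expects intensities in `[0, 1]`).
#'
#' @param channel Numeric matrix.
#' @param levels Number of histogram levels (default 256).
#' @return Threshold on the original intensity scale.
#' @export
otsu_threshold <- function(channel, levels = 256L) {
  mx <- max(channel)
  if (mx <= 0) return(0)
  mx * EBImage::otsu(EBImage::Image(channel / mx), range = c(0, 1),
                     levels = levels)
}

#' Read / write a single-channel grayscale TIFF
#'
#' `read_channel_tiff()` returns the raw integer sample values (8- or
#' 16-bit); `write_channel_tiff()` writes a numeric matrix as 16-bit
#' grayscale, storing values as-is when they already fit the sample range.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix of pixel values.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  img
}

#' @rdname read_channel_tiff
#' @param channel Numeric matrix of non-negative pixel values; values are
#'   rounded and clipped to the 16-bit range.
#' @export
write_channel_tiff <- function(channel, path) {
  v <- pmin(pmax(round(channel), 0), 65535)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Group colocalization statistics over a time course
#'
#' Computes per-image M1 for red/green image pairs grouped by condition
#' and timepoint, then the per-group mean and standard deviation (the
#' usual presentation for fixed-cell colocalization time courses).
#'
#' @param pairs A data.frame with columns `condition`, `timepoint_min`,
#'   and either (`red_path`, `green_path`) pointing to TIFF files or a
#'   list-column `images` of `list(red =, green =)` matrices.
#' @param threshold Number or `"otsu"` (per image, on the green channel).
#' @return data.frame: `condition`, `timepoint_min`, `n_images`,
#'   `mean_m1`, `sd_m1`; a per-image table is attached as attribute
#'   `"per_image"`. Empty groups are dropped with a warning.
#' @export
coloc_timecourse <- function(pairs, threshold = "otsu") {
  need <- c("condition", "timepoint_min")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` needs columns condition and timepoint_min", call. = FALSE)
  }
  if (!nrow(pairs)) {
    warning("no image pairs supplied")
    return(data.frame(condition = character(0), timepoint_min = numeric(0),
                      n_images = integer(0), mean_m1 = numeric(0),
                      sd_m1 = numeric(0)))
  }
  m1 <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if ("images" %in% names(pairs)) {
      red <- pairs$images[[k]]$red
      green <- pairs$images[[k]]$green
    } else {
      red <- read_channel_tiff(pairs$red_path[k])
      green <- read_channel_tiff(pairs$green_path[k])
    }
    m1[k] <- as.numeric(manders_m1(red, green, threshold))
  }
  per_image <- data.frame(condition = pairs$condition,
                          timepoint_min = pairs$timepoint_min, m1 = m1)
  groups <- unique(per_image[, c("condition", "timepoint_min")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- per_image$condition == groups$condition[g] &
      per_image$timepoint_min == groups$timepoint_min[g]
    v <- m1[sel]
    data.frame(condition = groups$condition[g],
               timepoint_min = groups$timepoint_min[g],
               n_images = length(v), mean_m1 = mean(v),
               sd_m1 = if (length(v) > 1L) stats::sd(v) else 0)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$condition, res$timepoint_min), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "per_image") <- per_image
  res
}
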