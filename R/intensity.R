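#' Mean channel intensity as a percentage of the 8-bit maximum
#'
#' Image Average Intensity of a (green, P2RY12) channel: the sum of all
#' pixel values divided by the number of pixels, normalised by 255 (the
#' maximum an 8-bit pixel can represent) and expressed as a percentage.
#' Because the denominator is the whole image, no cell mask is applied; a
#' mask-restricted variant is available via `mask` for sensitivity
#' analysis. 16-bit images are rescaled to the 8-bit range (divide by
#' 257) with a message so percentages stay comparable.
#'
#' @param img A [field_image()] (typically the p2ry12 channel projection).
#' @param bit_depth Bit depth of `img` pixels (8 or 16).
#' @param mask Optional logical matrix; when supplied, only `TRUE` pixels
#'   enter both the sum and the denominator.
#' @return Percentage in `[0, 100]`, with attribute `n_pixels`.
#' @export
mean_intensity_percent <- function(img, bit_depth = 8, mask = NULL) {
  stopifnot(inherits(img, "field_image"))
  px <- img$pixels
  if (length(px) == 0) abort("empty image")
  if (bit_depth == 16) {
    inform("rescaling 16-bit pixels to 8-bit range (factor 1/257)")
    px <- px / 257
  }
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(px)))
    if (!any(mask)) abort("mask selects no pixels")
    px <- px[mask]
  }
  structure(100 * mean(px) / 255, n_pixels = length(px))
}

#' Summarise intensity records by layer, eye group and day
#'
#' Produces the mean +/- SD tables of channel-intensity percentages per
#' cell of a grouping (default layer x group x day). The SD uses the
#' n - 1 denominator; a group with a single record gets SD 0 and
#' `sd_defined = FALSE`. Grouping cells absent from the data are simply
#' omitted (with a warning listing how many groups were summarised).
#'
#' @param records Tibble with at least `mean_intensity_percent` and the
#'   grouping columns.
#' @param ... Grouping columns (tidy-select); default
#'   `layer, group, day`.
#' @return Tibble with `mean`, `sd`, `n`, `sd_defined` per group.
#' @export
summarize_intensity <- function(records, ...) {
  stopifnot(is.data.frame(records),
            "mean_intensity_percent" %in% names(records))
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    groups <- rlang::quos(.data$layer, .data$group, .data$day)
  }
  out <- records |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      mean = mean(.data$mean_intensity_percent),
      sd = if (dplyr::n() > 1) sd(.data$mean_intensity_percent) else 0,
      n = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(sd_defined = .data$n > 1)
  if (any(!out$sd_defined)) {
    warn("some groups contain a single record; their SD is reported as 0")
  }
  out
}
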