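#' Base-composition analytics for labeled site collections
#'
#' Active and inactive target sites differ systematically in base
#' composition — most prominently, thymine is depleted in active sites at
#' every triplet-internal position. These helpers quantify that signal as
#' plain proportions (no smoothing): mean per-site base counts, mean base
#' counts per triplet-internal position, and a per-position
#' percent-difference matrix between the active subset and the whole
#' collection (the numbers behind a sequence-logo difference plot).
#'
#' @name composition
NULL

filter_class <- function(sites, which) {
  if (which == "all") sites else sites[sites$label == which, ]
}

#' @rdname composition
#' @param sites Labeled site table.
#' @param which `"active"`, `"inactive"` or `"all"`.
#' @return For `mean_base_counts()`, a tibble with columns `base` (G, A,
#'   C, T) and `mean_count` (mean occurrences per 9-bp site; sums to 9).
#' @export
mean_base_counts <- function(sites, which = c("all", "active", "inactive")) {
  which <- match.arg(which)
  sites <- validate_sites(sites)
  sub <- filter_class(sites, which)
  if (nrow(sub) == 0) abort(paste0("no sites in class ", sQuote(which)))
  counts <- encode_base_counts(sub$sequence)
  tibble(base = DNA_BASES, mean_count = unname(colMeans(counts)))
}

#' @rdname composition
#' @return For `positional_mean_counts()`, a tibble with columns
#'   `triplet_pos` (1-3: position within a triplet), `base` and
#'   `mean_count` (each triplet position's four means sum to 3).
#' @export
positional_mean_counts <- function(sites,
                                   which = c("all", "active", "inactive")) {
  which <- match.arg(which)
  sites <- validate_sites(sites)
  sub <- filter_class(sites, which)
  if (nrow(sub) == 0) abort(paste0("no sites in class ", sQuote(which)))
  counts <- colMeans(encode_positional(sub$sequence))
  tibble(
    triplet_pos = rep(1:3, each = 4),
    base = rep(DNA_BASES, 3),
    mean_count = unname(counts)
  )
}

#' @rdname composition
#' @return For `percent_difference_matrix()`, a tibble with columns
#'   `position` (1-9, 5'->3'), `base` and `difference`: 100 times the
#'   frequency of the base at that position among active sites minus its
#'   frequency among all sites. Each position's four differences sum
#'   to 0. Positive values mark bases favored in active sites.
#' @export
percent_difference_matrix <- function(sites) {
  sites <- validate_sites(sites)
  active <- sites[sites$label == "active", ]
  if (nrow(active) == 0) abort("no active sites in the dataset")
  freq <- function(sub) {
    chars <- feature_matrix(sub, "identity")
    vapply(1:9, function(p) {
      as.numeric(table(factor(chars[, p], levels = DNA_BASES))) / nrow(sub)
    }, numeric(4))  # 4 x 9
  }
  d <- 100 * (freq(active) - freq(sites))
  tibble(
    position = rep(1:9, each = 4),
    base = rep(DNA_BASES, 9),
    difference = as.numeric(d)
  )
}

#' Long-format composition report
#'
#' Binds the three composition analyses into one tidy table suitable for
#' TSV export: per-class mean base counts, per-class positional mean
#' counts, and the active-versus-all percent-difference matrix.
#'
#' @param sites Labeled site table with at least one active site.
#' @return A tibble with columns `analysis`, `class`, `position`, `base`,
#'   `value`.
#' @export
composition_report <- function(sites) {
  sites <- validate_sites(sites)
  classes <- intersect(c("active", "inactive"), unique(sites$label))
  totals <- purrr::map_dfr(classes, function(cl) {
    dplyr::mutate(mean_base_counts(sites, cl), analysis = "mean_base_counts",
                  class = cl, position = NA_integer_,
                  value = .data$mean_count, .keep = "none",
                  base = .data$base)
  })
  positional <- purrr::map_dfr(classes, function(cl) {
    dplyr::mutate(positional_mean_counts(sites, cl),
                  analysis = "positional_mean_counts", class = cl,
                  position = .data$triplet_pos, value = .data$mean_count,
                  .keep = "none", base = .data$base)
  })
  pdm <- dplyr::mutate(percent_difference_matrix(sites),
                       analysis = "percent_difference", class = "active",
                       value = .data$difference, .keep = "none",
                       base = .data$base,
                       position = .data$position)
  dplyr::bind_rows(totals, positional, pdm)[
    , c("analysis", "class", "position", "base", "value")]
}

#' Plot the per-position percent-difference matrix
#'
#' @param sites Labeled site table.
#' @return A ggplot bar chart, one panel per site position, differences
#'   in percentage points.
#' @export
plot_composition_difference <- function(sites) {
  pdm <- percent_difference_matrix(sites)
  ggplot2::ggplot(pdm, ggplot2::aes(x = .data$base, y = .data$difference,
                                    fill = .data$base)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~position, nrow = 1) +
    ggplot2::labs(x = NULL, y = "Active minus overall frequency (%)",
                  title = "Position-specific composition difference")
}
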