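#' Enumerate the OPEN-targetable 9-mer space
#'
#' The Cartesian product of the three triplet pools, concatenated 5'->3',
#' in lexicographic order. With the published pool sizes (26/21/23) this
#' is 12,558 distinct sites.
#'
#' @param pools A `zf_pools` object.
#' @return Character vector of distinct 9-mers, lexicographically sorted.
#' @export
enumerate_half_sites <- function(pools) {
  stopifnot(inherits(pools, "zf_pools"))
  grid <- expand.grid(t3 = sort(pools$pos3), t2 = sort(pools$pos2),
                      t1 = sort(pools$pos1), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  paste0(grid$t1, grid$t2, grid$t3)
}

# dam (GATC) and dcm (CCWGG = CCAGG/CCTGG) recognition motifs. The set is
# closed under reverse complement — GATC is self-complementary and
# CCAGG <-> CCTGG — so a forward-strand substring search covers both
# strands.
METHYLATION_MOTIFS <- c("GATC", "CCAGG", "CCTGG")

#' Is a site excluded by dam/dcm methylation?
#'
#' E. coli dam methylates GATC and dcm methylates CCWGG (CCAGG/CCTGG);
#' methylation within a target site blocks selection in the bacterial
#' reporter host, so such sites are not targetable. A site is excluded if
#' it contains any of the three motifs as a forward-strand substring
#' (the motif set is reverse-complement-closed, so one strand suffices).
#'
#' @param seq Character vector of DNA sequences.
#' @return Logical vector.
#' @examples
#' methylation_excluded(c("GGGGATCGG", "GGGGGGGGG"))
#' @export
methylation_excluded <- function(seq) {
  seq <- toupper(as.character(seq))
  Reduce(`|`, lapply(METHYLATION_MOTIFS,
                     function(m) grepl(m, seq, fixed = TRUE)))
}

#' Count ordered ZFN site pairs from a half-site count
#'
#' A full nuclease site is an ordered pair of half-sites (left, right),
#' so `n` usable half-sites yield `n^2` distinct nuclease sites at a
#' fixed spacer length; 12,143 targetable half-sites give 147,452,449
#' nuclease sites.
#'
#' @param n_half_sites Non-negative integer count of usable half-sites.
#' @return `n_half_sites^2` as a double (the counts exceed 32-bit range).
#' @export
zfn_pair_count <- function(n_half_sites) {
  as.numeric(n_half_sites)^2
}

#' Summarize the targetable 9-mer space
#'
#' Enumerates the pool product, removes dam/dcm-excluded sites, and (when
#' a classifier is supplied) counts the sites predicted active at
#' `theta`. ZFN pair counts are ordered-pair counts (squares).
#'
#' @param pools A `zf_pools` object.
#' @param model Optional fitted `zf_nb` classifier.
#' @param theta Classification threshold for the predicted-active count.
#' @return One-row tibble: `n_enumerable`, `n_methylation_excluded`,
#'   `n_targetable`, `n_predicted_active` (`NA` without a model),
#'   `n_zfn_pairs` (targetable half-sites squared), `n_zfn_pairs_active`.
#' @export
summarize_target_space <- function(pools, model = NULL, theta = 0.5) {
  sites <- enumerate_half_sites(pools)
  excluded <- methylation_excluded(sites)
  targetable <- sites[!excluded]
  n_active <- NA_real_
  if (!is.null(model)) {
    stopifnot(inherits(model, "zf_nb"))
    post <- nb_posterior(model, tibble(sequence = targetable))
    n_active <- sum(post >= theta)
  }
  tibble(
    n_enumerable = length(sites),
    n_methylation_excluded = sum(excluded),
    n_targetable = length(targetable),
    n_predicted_active = n_active,
    n_zfn_pairs = zfn_pair_count(length(targetable)),
    n_zfn_pairs_active = if (is.na(n_active)) NA_real_
                         else zfn_pair_count(n_active)
  )
}

#' Scan DNA sequences for candidate ZFN sites
#'
#' A ZFN site is two 9-bp zinc finger half-sites in inverted orientation
#' around a 5-7 bp spacer: in forward-strand coordinates the full site is
#' `left(9) + spacer + right(9)`, and the two zinc finger targets are
#' `reverse_complement(left)` (the array bound on the minus strand) and
#' `right`. This construction is strand-closed, so a single forward-strand
#' scan finds every site. Windows containing `N` are skipped.
#'
#' @param records Tibble from [read_fasta()] (columns `id`, `sequence`),
#'   or any data frame with those columns.
#' @param pools Optional `zf_pools`; when given, both half-sites must lie
#'   in the pool product.
#' @param spacers Spacer lengths to scan, a subset of 5:7.
#' @param model Optional fitted `zf_nb` used to score both half-sites.
#' @param min_confidence Optional integer 0-9; with a model, keep only
#'   hits whose half-sites are both predicted active (posterior >= 0.5)
#'   with confidence at or above this value.
#' @param methylation Where to apply the dam/dcm filter: `"half_site"`
#'   drops hits whose half-sites contain a motif (matching the
#'   context-free pool-space counts); `"window"` additionally searches
#'   the full site including the spacer; `"none"` disables the filter.
#' @return A tibble of hits: `contig`, `start` (1-based position of the
#'   full site's first base), `spacer_length`, `full_site`,
#'   `half_site_1`, `half_site_2`, and with a model `posterior_1`,
#'   `posterior_2`, `confidence_1`, `confidence_2`.
#' @export
scan_zfn_sites <- function(records, pools = NULL, spacers = 5:7,
                           model = NULL, min_confidence = NULL,
                           methylation = c("half_site", "window", "none")) {
  methylation <- match.arg(methylation)
  if (length(spacers) == 0 || !all(spacers %in% 5:7)) {
    abort("`spacers` must be a non-empty subset of 5:7")
  }
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    abort("`records` must have `id` and `sequence` columns")
  }
  pool_set <- if (!is.null(pools)) enumerate_half_sites(pools)

  hits <- purrr::map_dfr(seq_len(nrow(records)), function(r) {
    seq <- toupper(records$sequence[r])
    n <- nchar(seq)
    purrr::map_dfr(sort(as.integer(spacers)), function(s) {
      w <- 18L + s
      if (n < w) return(NULL)
      starts <- seq_len(n - w + 1L)
      win <- substring(seq, starts, starts + w - 1L)
      keep <- !grepl("N", win, fixed = TRUE)
      if (!any(keep)) return(NULL)
      starts <- starts[keep]; win <- win[keep]
      left <- substr(win, 1L, 9L)
      right <- substr(win, 10L + s, w)
      h1 <- reverse_complement(left)
      h2 <- right
      ok <- rep(TRUE, length(win))
      if (!is.null(pool_set)) ok <- ok & h1 %in% pool_set & h2 %in% pool_set
      if (methylation == "half_site") {
        ok <- ok & !methylation_excluded(h1) & !methylation_excluded(h2)
      } else if (methylation == "window") {
        ok <- ok & !methylation_excluded(h1) & !methylation_excluded(h2) &
          !methylation_excluded(win)
      }
      if (!any(ok)) return(NULL)
      tibble(contig = records$id[r], start = starts[ok],
             spacer_length = s, full_site = win[ok],
             half_site_1 = h1[ok], half_site_2 = h2[ok])
    })
  })
  if (nrow(hits) == 0) {
    hits <- tibble(contig = character(), start = integer(),
                   spacer_length = integer(), full_site = character(),
                   half_site_1 = character(), half_site_2 = character())
  }
  if (!is.null(model)) {
    if (nrow(hits) > 0) {
      p1 <- nb_posterior(model, tibble(sequence = hits$half_site_1))
      p2 <- nb_posterior(model, tibble(sequence = hits$half_site_2))
      hits$posterior_1 <- p1
      hits$posterior_2 <- p2
      hits$confidence_1 <- confidence_score(p1)
      hits$confidence_2 <- confidence_score(p2)
      if (!is.null(min_confidence)) {
        keep <- p1 >= 0.5 & p2 >= 0.5 &
          hits$confidence_1 >= min_confidence &
          hits$confidence_2 >= min_confidence
        hits <- hits[keep, ]
      }
    } else {
      hits$posterior_1 <- numeric()
      hits$posterior_2 <- numeric()
      hits$confidence_1 <- integer()
      hits$confidence_2 <- integer()
    }
  }
  hits
}

#' Write a ZFN hit report as TSV
#' @param hits Tibble from [scan_zfn_sites()].
#' @param path Output path.
#' @return The hits, invisibly.
#' @export
write_hit_report <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(hits)
}
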