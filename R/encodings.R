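#' Target-site feature encodings
#'
#' Three encodings of a 9-bp target site feed the classifiers:
#'
#' * **identity** — the nine nucleotide identities, one categorical
#'   attribute per position 5'->3' (`p1`..`p9`).
#' * **base_counts** — four integers: occurrences of G, A, C, T in the
#'   site (`count_G`..`count_T`); they sum to 9.
#' * **positional** — twelve integers: for each triplet-internal position
#'   (1st, 2nd, 3rd base of a triplet), how many of the three triplets
#'   carry each base there (`t1_G`..`t3_T`); each group of four sums to 3.
#'
#' Attribute order is fixed as (G, A, C, T) throughout.
#'
#' @name encodings
NULL

ENCODING_KINDS <- c("identity", "base_counts", "positional")

#' @rdname encodings
#' @param sequence Character vector of validated 9-mers.
#' @return For `encode_identity()`, a tibble with character columns
#'   `p1`..`p9`.
#' @examples
#' encode_identity("GTTGACGGC")
#' encode_base_counts("GTTGACGGC") # 4 G, 1 A, 2 C, 2 T
#' @export
encode_identity <- function(sequence) {
  m <- do.call(rbind, strsplit(as.character(sequence), "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0, 9)
  colnames(m) <- paste0("p", 1:9)
  as_tibble(m)
}

#' @rdname encodings
#' @return For `encode_base_counts()`, a tibble with integer columns
#'   `count_G`, `count_A`, `count_C`, `count_T`.
#' @export
encode_base_counts <- function(sequence) {
  sequence <- as.character(sequence)
  counts <- vapply(DNA_BASES, function(b) {
    nchar(sequence) - nchar(gsub(b, "", sequence, fixed = TRUE))
  }, integer(length(sequence)))
  if (length(sequence) == 1L) counts <- matrix(counts, nrow = 1)
  if (length(sequence) == 0L) counts <- matrix(integer(0), 0, 4)
  colnames(counts) <- paste0("count_", DNA_BASES)
  as_tibble(counts)
}

#' @rdname encodings
#' @return For `encode_positional()`, a tibble with integer columns
#'   `t1_G`..`t1_T`, `t2_G`..`t2_T`, `t3_G`..`t3_T`: base counts at the
#'   1st, 2nd and 3rd position within the three triplet subsites.
#' @export
encode_positional <- function(sequence) {
  sequence <- as.character(sequence)
  n <- length(sequence)
  out <- matrix(0L, nrow = n, ncol = 12,
                dimnames = list(NULL, paste0(
                  rep(paste0("t", 1:3), each = 4), "_", rep(DNA_BASES, 3))))
  if (n > 0) {
    chars <- do.call(rbind, strsplit(sequence, "", fixed = TRUE))
    for (tp in 1:3) {          # position within a triplet
      cols <- chars[, c(tp, tp + 3L, tp + 6L), drop = FALSE]
      for (b in DNA_BASES) {
        out[, paste0("t", tp, "_", b)] <- rowSums(cols == b)
      }
    }
  }
  as_tibble(out)
}

#' Encode a site table for classification
#'
#' Order-preserving: row *i* of the result encodes row *i* of `sites`.
#'
#' @param sites A site table (see [zf_sites()]).
#' @param encoding One of `"identity"`, `"base_counts"`, `"positional"`.
#' @return A tibble of feature columns followed by the `label` column.
#' @export
encode_sites <- function(sites, encoding = c("identity", "base_counts",
                                             "positional")) {
  encoding <- match.arg(encoding)
  sites <- validate_sites(sites)
  feats <- switch(encoding,
    identity = encode_identity(sites$sequence),
    base_counts = encode_base_counts(sites$sequence),
    positional = encode_positional(sites$sequence)
  )
  feats$label <- sites$label
  feats
}

# Per-attribute value domains; count attributes are treated as nominal
# with bounded arity (0..9 for totals, 0..3 for positional counts).
encoding_schema <- function(encoding) {
  switch(encoding,
    identity = list(
      attributes = paste0("p", 1:9),
      domains = rep(list(DNA_BASES), 9)
    ),
    base_counts = list(
      attributes = paste0("count_", DNA_BASES),
      domains = rep(list(as.character(0:9)), 4)
    ),
    positional = list(
      attributes = paste0(rep(paste0("t", 1:3), each = 4), "_",
                          rep(DNA_BASES, 3)),
      domains = rep(list(as.character(0:3)), 12)
    ),
    abort(paste0("unknown encoding kind: ", encoding))
  )
}

# Feature matrix as character values matching the schema domains.
feature_matrix <- function(sites, encoding) {
  feats <- switch(encoding,
    identity = encode_identity(sites$sequence),
    base_counts = encode_base_counts(sites$sequence),
    positional = encode_positional(sites$sequence),
    abort(paste0("unknown encoding kind: ", encoding))
  )
  m <- as.matrix(feats)
  mode(m) <- "character"
  m
}
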