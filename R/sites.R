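#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("G", "A", "C", "T")
SITE_LENGTH <- 9L

#' Construct a tibble of 9-bp zinc finger target sites
#'
#' A *target site* is a 9-bp DNA sequence read 5'->3' on the strand bound by
#' a three-finger zinc finger array; it decomposes into three triplet
#' subsites (positions 1-3, 4-6, 7-9), one per finger. Sites carry an
#' activity label reflecting whether OPEN selection yielded a binding
#' protein for them.
#'
#' @param sequence Character vector of 9-character strings over G/A/C/T.
#' @param label Activity labels: `"active"`, `"inactive"` or `"unknown"`
#'   (case-insensitive). Recycled if length 1.
#' @param id Optional free-text identifiers.
#' @return A tibble with columns `sequence`, `label`, `id`, validated.
#' @examples
#' zf_sites(c("GTTGACGGC", "TTTTTTTTT"), c("active", "inactive"))
#' @export
zf_sites <- function(sequence, label = "unknown", id = NA_character_) {
  sites <- tibble(
    sequence = toupper(as.character(sequence)),
    label = normalize_labels(label),
    id = as.character(id)
  )
  validate_sites(sites)
}

normalize_labels <- function(label) {
  lab <- tolower(trimws(as.character(label)))
  lab[is.na(lab) | lab == ""] <- "unknown"
  bad <- setdiff(unique(lab), c("active", "inactive", "unknown"))
  if (length(bad) > 0) {
    abort(paste0(
      "unknown label token(s): ", paste(sQuote(bad), collapse = ", "),
      "; expected active/inactive/unknown"
    ))
  }
  lab
}

#' Validate a site table
#'
#' Checks the 9-bp G/A/C/T invariant on every sequence and normalizes the
#' label column. Errors name the offending row.
#'
#' @param sites A data frame with at least a `sequence` column.
#' @param require_labels If `TRUE`, require at least one active and one
#'   inactive site (the minimal training contract).
#' @return The validated table as a tibble with columns `sequence`,
#'   `label`, `id`.
#' @export
validate_sites <- function(sites, require_labels = FALSE) {
  if (!is.data.frame(sites) || !"sequence" %in% names(sites)) {
    abort("`sites` must be a data frame with a `sequence` column")
  }
  sites <- as_tibble(sites)
  if (!"label" %in% names(sites)) sites$label <- "unknown"
  if (!"id" %in% names(sites)) sites$id <- NA_character_
  sites <- sites[, c("sequence", "label", "id")]
  sites$sequence <- toupper(as.character(sites$sequence))
  sites$label <- normalize_labels(sites$label)

  len <- nchar(sites$sequence)
  bad_len <- which(len != SITE_LENGTH)
  if (length(bad_len) > 0) {
    abort(sprintf(
      "row %d: sequence length %d ≠ 9", bad_len[1], len[bad_len[1]]
    ))
  }
  bad_chr <- which(!grepl("^[GACT]+$", sites$sequence))
  if (length(bad_chr) > 0) {
    abort(sprintf(
      "row %d: sequence %s contains characters outside {G,A,C,T}",
      bad_chr[1], sQuote(sites$sequence[bad_chr[1]])
    ))
  }
  if (require_labels) {
    if (!all(c("active", "inactive") %in% sites$label)) {
      abort("training data must contain at least one active and one inactive site")
    }
  }
  sites
}

#' Read a site table from delimited text
#'
#' Reads a headered TSV or CSV with a `sequence` column and optional
#' `label` and `id` columns. Labels are normalized case-insensitively to
#' active/inactive/unknown; a missing label column yields all-unknown.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (sniff the header line), `"tsv"` or `"csv"`.
#' @return A validated site tibble (`sequence`, `label`, `id`).
#' @export
read_sites <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", header)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!"sequence" %in% names(raw)) {
    abort(paste0("no `sequence` column in ", path))
  }
  validate_sites(raw)
}

#' Write a site table as TSV
#'
#' Emits a headered TSV (`sequence`, `label`, `id`) that round-trips
#' losslessly through [read_sites()].
#'
#' @param sites Site table (validated on write).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_sites <- function(sites, path) {
  sites <- validate_sites(sites)
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(sites)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorized.
#'
#' @param seq Character vector over A/C/G/T/N (case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' reverse_complement("CCAGG") # "CCTGG"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf(
      "invalid character in sequence %d: %s", which(bad)[1],
      sQuote(seq[which(bad)[1]])
    ))
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Split 9-mers into their three triplet subsites
#' @param seq Character vector of 9-character sequences.
#' @return A character matrix with columns `t1`, `t2`, `t3`.
#' @keywords internal
site_triplets <- function(seq) {
  m <- cbind(
    t1 = substr(seq, 1L, 3L),
    t2 = substr(seq, 4L, 6L),
    t3 = substr(seq, 7L, 9L)
  )
  rownames(m) <- NULL
  m
}
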