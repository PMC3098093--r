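#' Read DNA sequences from a FASTA file
#'
#' Multi-record FASTA; sequences are uppercased, line wrapping removed.
#' Only A/C/G/T/N are accepted: scan candidate windows containing `N` are
#' skipped downstream, anything else is rejected with the record id and
#' offending position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `description`
#'   (the header text after the first whitespace, `NA` if none),
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = TRUE),
    error = function(e) abort(paste0("could not parse FASTA ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(recs) == 0) abort(paste0("no records in FASTA file ", path))
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  for (i in seq_along(seqs)) {
    if (ids[i] == "") abort(sprintf("record %d has an empty id", i))
    if (is.na(seqs[i]) || nchar(seqs[i]) == 0) {
      abort(sprintf("record %s has an empty sequence", sQuote(ids[i])))
    }
    hit <- regexpr("[^ACGTN]", seqs[i])
    if (hit > 0) {
      abort(sprintf(
        "record %s: invalid character %s at position %d",
        sQuote(ids[i]), sQuote(substr(seqs[i], hit, hit)), as.integer(hit)
      ))
    }
  }
  tibble(id = unname(ids), sequence = unname(seqs),
         description = unname(desc))
}
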