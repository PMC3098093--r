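# Shared fixtures built in code; no binary data.

# A small perfectly separable dataset: position 1 determines the class.
toy_separable <- function() {
  zf_sites(
    c("GGGGGGGGG", "GGGGGGGGA", "GGGGGGGAG", "GGGGGAGGG",
      "TTTTTTTTT", "TTTTTTTTC", "TTTTTTCTT", "TTTCTTTTT"),
    c(rep("active", 4), rep("inactive", 4))
  )
}

# The four-site hand-arithmetic dataset used to check posteriors.
toy_hand <- function() {
  zf_sites(
    c("GGGGGGGGG", "GGGGGGGGT", "TTTTTTTTT", "TTTTTTTTG"),
    c("active", "active", "inactive", "inactive")
  )
}

random_9mers <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("G", "A", "C", "T"), 9, replace = TRUE), collapse = "")
  }, character(1))
}

# Independent naive Bayes oracle: direct products of smoothed counts,
# computed with table() arithmetic, no log space, no shared code path.
nb_oracle_posterior <- function(train_sites, query_seq, encoding, alpha) {
  enc <- function(s) {
    feats <- switch(encoding,
      identity = encode_identity(s),
      base_counts = encode_base_counts(s),
      positional = encode_positional(s)
    )
    m <- as.matrix(feats); mode(m) <- "character"; m
  }
  domains <- switch(encoding,
    identity = rep(list(c("G", "A", "C", "T")), 9),
    base_counts = rep(list(as.character(0:9)), 4),
    positional = rep(list(as.character(0:3)), 12)
  )
  xtr <- enc(train_sites$sequence)
  xq <- enc(query_seq)[1, ]
  score <- function(cls) {
    idx <- train_sites$label == cls
    n_c <- sum(idx)
    prior <- (n_c + alpha) / (nrow(train_sites) + 2 * alpha)
    lik <- 1
    for (j in seq_along(xq)) {
      k <- length(domains[[j]])
      cnt <- sum(xtr[idx, j] == xq[j])
      lik <- lik * (cnt + alpha) / (n_c + k * alpha)
    }
    prior * lik
  }
  score("active") / (score("active") + score("inactive"))
}

write_temp_sites <- function(sites, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  readr::write_tsv(sites, path, progress = FALSE)
  path
}
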