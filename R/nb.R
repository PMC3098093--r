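#' Fit a categorical naive Bayes classifier to labeled target sites
#'
#' The classifier assumes attribute independence given the class and
#' models every attribute as nominal: nucleotide identities over
#' \{G,A,C,T\}, total base counts over 0..9, positional base counts over
#' 0..3. Priors and conditionals are Laplace-smoothed with pseudocount
#' `alpha`:
#' \deqn{P(c) = (n_c + \alpha) / (N + 2\alpha)}
#' \deqn{P(v \mid c) = (n_{v,c} + \alpha) / (n_c + k\alpha)}
#' where *k* is the attribute's arity. With `alpha = 0` unobserved values
#' get probability zero; this is allowed but not the default.
#'
#' @param sites Labeled site table; both classes must be present.
#' @param encoding Feature encoding (see [encodings]).
#' @param alpha Pseudocount, default 1 (add-one smoothing).
#' @return An object of class `zf_nb` with elements `priors` (named
#'   numeric, active/inactive), `conditionals` (list per attribute of
#'   value-by-class probability matrices), `schema`, `alpha`, and the
#'   training class counts.
#' @examples
#' train <- zf_sites(c("GGGGGGGGG", "TTTTTTTTT"), c("active", "inactive"))
#' fit <- nb_fit(train)
#' predict(fit, zf_sites("GGGGGGGGT"))
#' @export
nb_fit <- function(sites, encoding = c("identity", "base_counts",
                                       "positional"), alpha = 1) {
  encoding <- match.arg(encoding)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    abort("`alpha` must be a single non-negative number")
  }
  sites <- validate_sites(sites, require_labels = TRUE)
  counts <- nb_count(sites, encoding)
  nb_from_counts(counts, alpha)
}

# keep the raw counts on the fitted object so it can be serialized
# exactly and rebuilt bit-identically

CLASSES <- c("active", "inactive")

# Raw count tables (no smoothing): class totals + per-attribute
# value-by-class counts. LOOCV decrements these directly.
nb_count <- function(sites, encoding) {
  schema <- encoding_schema(encoding)
  x <- feature_matrix(sites, encoding)
  cls <- sites$label
  if (any(cls == "unknown")) abort("training sites must all be labeled")
  n_class <- vapply(CLASSES, function(c) sum(cls == c), numeric(1))
  tables <- vector("list", length(schema$attributes))
  names(tables) <- schema$attributes
  for (j in seq_along(schema$attributes)) {
    dom <- schema$domains[[j]]
    tab <- matrix(0, nrow = length(dom), ncol = 2,
                  dimnames = list(dom, CLASSES))
    for (c in CLASSES) {
      t0 <- table(factor(x[cls == c, j], levels = dom))
      tab[, c] <- as.numeric(t0)
    }
    tables[[j]] <- tab
  }
  list(encoding = encoding, schema = schema, n_class = n_class,
       tables = tables)
}

nb_from_counts <- function(counts, alpha) {
  n_class <- counts$n_class
  priors <- (n_class + alpha) / (sum(n_class) + 2 * alpha)
  conds <- lapply(counts$tables, function(tab) {
    arity <- nrow(tab)
    sweep(tab + alpha, 2, n_class + arity * alpha, "/")
  })
  structure(
    list(priors = priors, conditionals = conds,
         schema = c(list(encoding = counts$encoding), counts$schema),
         alpha = alpha, n_class = n_class, counts = counts),
    class = "zf_nb"
  )
}

#' @export
print.zf_nb <- function(x, ...) {
  cat("<zf_nb> categorical naive Bayes classifier\n",
      "  encoding: ", x$schema$encoding,
      " (", length(x$schema$attributes), " attributes)\n",
      "  alpha: ", x$alpha, "\n",
      "  trained on ", x$n_class[["active"]], " active / ",
      x$n_class[["inactive"]], " inactive sites\n", sep = "")
  invisible(x)
}

#' Posterior probability of the active class
#'
#' Applies Bayes' rule with the fitted priors and conditionals; the
#' product over attributes is accumulated in log space and renormalized,
#' so long feature vectors cannot underflow.
#'
#' @param model A fitted `zf_nb`.
#' @param sites Site table (labels ignored).
#' @return Numeric vector of `P(active | site)` in \[0, 1\].
#' @export
nb_posterior <- function(model, sites) {
  stopifnot(inherits(model, "zf_nb"))
  sites <- validate_sites(sites)
  x <- feature_matrix(sites, model$schema$encoding)
  if (!identical(colnames(x), model$schema$attributes)) {
    abort("feature schema mismatch between model and input")
  }
  n <- nrow(x)
  logp <- matrix(rep(log(model$priors), each = n), nrow = n)
  colnames(logp) <- CLASSES
  for (j in seq_along(model$schema$attributes)) {
    tab <- model$conditionals[[j]]
    idx <- match(x[, j], rownames(tab))
    if (anyNA(idx)) {
      abort(sprintf("attribute %s: value outside the model's domain",
                    model$schema$attributes[j]))
    }
    logp <- logp + log(tab[idx, , drop = FALSE])
  }
  m <- pmax(logp[, 1], logp[, 2])
  pa <- exp(logp[, "active"] - m)
  pi_ <- exp(logp[, "inactive"] - m)
  unname(pa / (pa + pi_))
}

#' Transform a posterior probability into a 0-9 confidence score
#'
#' Sites with posterior >= 0.5 are called active, below 0.5 inactive. On
#' the active side the score increments by 1 for every 0.05 of posterior
#' above 0.5 (so 0.75 -> 5); on the inactive side, for every 0.05 below
#' 0.5 (so 0.25 -> 5). The score is capped at 9. A small epsilon guards
#' exact multiples of 0.05 against floating-point representation.
#'
#' @param posterior Numeric vector of posteriors in \[0, 1\].
#' @return Integer vector of scores in 0..9.
#' @examples
#' confidence_score(c(0.75, 0.25, 0.5, 1))
#' @export
confidence_score <- function(posterior) {
  if (any(is.na(posterior)) || any(posterior < 0 | posterior > 1)) {
    abort("posterior probabilities must lie in [0, 1]")
  }
  dist <- abs(posterior - 0.5)
  as.integer(pmin(9L, floor(dist / 0.05 + 1e-9)))
}

#' Predict activity for candidate target sites
#'
#' @param object A fitted `zf_nb`.
#' @param newdata Site table to classify.
#' @param theta Classification threshold on the active posterior; the
#'   boundary is inclusive (posterior >= `theta` is called active),
#'   default 0.5.
#' @param ... Unused.
#' @return A tibble with columns `sequence`, `id`, `posterior_active`,
#'   `predicted` (active/inactive) and `confidence` (0-9, computed at the
#'   0.5 midpoint regardless of `theta`).
#' @export
predict.zf_nb <- function(object, newdata, theta = 0.5, ...) {
  if (!is.numeric(theta) || theta < 0 || theta > 1) {
    abort("`theta` must lie in [0, 1]")
  }
  newdata <- validate_sites(newdata)
  p <- nb_posterior(object, newdata)
  tibble(
    sequence = newdata$sequence,
    id = newdata$id,
    posterior_active = p,
    predicted = ifelse(p >= theta, "active", "inactive"),
    confidence = confidence_score(p)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the conditional probability tables of a fitted classifier
#'
#' @param x A fitted `zf_nb`.
#' @param ... Unused.
#' @return A tibble with one row per (attribute, value, class):
#'   `attribute`, `value`, `class`, `probability`.
#' @export
tidy.zf_nb <- function(x, ...) {
  purrr::map_dfr(x$schema$attributes, function(a) {
    tab <- x$conditionals[[a]]
    tidyr::expand_grid(attribute = a, value = rownames(tab),
                       class = CLASSES) |>
      dplyr::mutate(probability = as.numeric(tab[cbind(.data$value,
                                                       .data$class)]))
  })
}

#' One-row model summary
#' @param x A fitted `zf_nb`.
#' @param ... Unused.
#' @return Tibble with encoding, alpha, class counts and priors.
#' @export
glance.zf_nb <- function(x, ...) {
  tibble(
    encoding = x$schema$encoding,
    alpha = x$alpha,
    n_active = x$n_class[["active"]],
    n_inactive = x$n_class[["inactive"]],
    prior_active = x$priors[["active"]]
  )
}

#' Serialize a fitted classifier to JSON
#'
#' Plain-text, versioned. The document stores the sufficient statistics
#' (integer class and value counts) plus `alpha`; [read_nb_model()]
#' rebuilds the probability tables through the same smoothing arithmetic
#' as [nb_fit()], so reloaded models reproduce posteriors bit-identically.
#'
#' @param model A fitted `zf_nb`.
#' @param path Output path.
#' @return The model, invisibly.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "zf_nb"))
  doc <- list(
    format = "openzfp-nb",
    version = 1L,
    encoding = model$schema$encoding,
    alpha = model$alpha,
    n_class = as.list(model$n_class),
    value_counts = lapply(model$counts$tables, function(tab) {
      list(values = rownames(tab),
           active = unname(tab[, "active"]),
           inactive = unname(tab[, "inactive"]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(model)
}

#' Load a serialized classifier
#' @param path Path to a JSON file written by [write_nb_model()].
#' @return A `zf_nb` object.
#' @export
read_nb_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "openzfp-nb")) {
    abort(paste0(path, " is not an openzfp naive Bayes model file"))
  }
  schema <- encoding_schema(doc$encoding)
  tables <- lapply(schema$attributes, function(a) {
    entry <- doc$value_counts[[a]]
    tab <- cbind(active = entry$active, inactive = entry$inactive)
    rownames(tab) <- entry$values
    tab
  })
  names(tables) <- schema$attributes
  counts <- list(encoding = doc$encoding, schema = schema,
                 n_class = unlist(doc$n_class)[CLASSES], tables = tables)
  nb_from_counts(counts, doc$alpha)
}
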