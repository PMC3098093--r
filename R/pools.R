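#' Triplet pool configurations
#'
#' OPEN assembles a three-finger array from three pools of pre-selected
#' fingers, one pool per triplet subsite of the 9-bp target. A pool
#' configuration lists, for each of the three positions (position 1 =
#' 5'-most triplet), the DNA triplets for which a finger pool exists. The
#' targetable 9-mer space is the Cartesian product of the three lists.
#'
#' @name zf_pools
NULL

#' Build a pool configuration
#'
#' @param pos1,pos2,pos3 Character vectors of distinct 3-bp triplets over
#'   G/A/C/T for finger positions 1 (5'-most), 2 and 3.
#' @return An object of class `zf_pools`: a named list of the three
#'   validated triplet vectors.
#' @examples
#' zf_pool_config(pos1 = "GGG", pos2 = "GAA", pos3 = "GCC")
#' @export
zf_pool_config <- function(pos1, pos2, pos3) {
  pools <- list(pos1 = toupper(pos1), pos2 = toupper(pos2),
                pos3 = toupper(pos3))
  for (nm in names(pools)) {
    trip <- pools[[nm]]
    if (length(trip) == 0) abort(paste0("pool ", nm, " is empty"))
    n <- nchar(trip)
    if (any(n != 3L)) {
      i <- which(n != 3L)[1]
      abort(sprintf("%s: triplet length %d ≠ 3 (%s)", nm, n[i],
                    sQuote(trip[i])))
    }
    if (any(!grepl("^[GACT]{3}$", trip))) {
      i <- which(!grepl("^[GACT]{3}$", trip))[1]
      abort(sprintf("%s: invalid triplet %s", nm, sQuote(trip[i])))
    }
    if (anyDuplicated(trip)) {
      abort(sprintf("%s: duplicate triplet %s", nm,
                    sQuote(trip[duplicated(trip)][1])))
    }
  }
  structure(pools, class = "zf_pools")
}

#' Read a pool configuration file
#'
#' The on-disk format is YAML with three keys `pos1`, `pos2`, `pos3`,
#' each a list of triplets.
#'
#' @param path Path to the YAML file.
#' @return A `zf_pools` object.
#' @export
read_pool_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- yaml::read_yaml(path)
  missing <- setdiff(c("pos1", "pos2", "pos3"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("pool config lacks key(s): ", paste(missing, collapse = ", ")))
  }
  zf_pool_config(unlist(raw$pos1), unlist(raw$pos2), unlist(raw$pos3))
}

#' Write a pool configuration file
#' @param pools A `zf_pools` object.
#' @param path Output path (YAML).
#' @return The input, invisibly.
#' @export
write_pool_config <- function(pools, path) {
  stopifnot(inherits(pools, "zf_pools"))
  yaml::write_yaml(lapply(unclass(pools), as.list), path)
  invisible(pools)
}

#' The shipped default pool configuration
#'
#' Pool lists of sizes 26, 21 and 23 for finger positions 1, 2 and 3,
#' matching the published pool *sizes* of current OPEN reagents. The pool
#' sizes are real; the triplet *identities* beyond the 16 GNN triplets are
#' provisional placeholders (documented in the shipped file), because the
#' exact TNN/ANN pool memberships have not been published. Supply your own
#' file via [read_pool_config()] for real reagent inventories.
#'
#' @return A `zf_pools` object with list sizes 26/21/23.
#' @export
default_pool_config <- function() {
  read_pool_config(system.file("extdata", "pools_default.yaml",
                               package = "openzfp", mustWork = TRUE))
}

#' @export
print.zf_pools <- function(x, ...) {
  cat("<zf_pools> triplet pools:",
      sprintf("pos%d: %d triplets", 1:3, lengths(x)), sep = "\n  ")
  cat("  targetable 9-mer space:", prod(lengths(x)), "sites\n")
  invisible(x)
}
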