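#' Construct a species (one evolving lineage)
#'
#' A species is one row of a community table: an evolving lineage with an
#' evolvability `k`, a current mean strategy `u`, and a population density
#' `x`.  Extinct species keep their row: density is fixed at 0, the strategy
#' is frozen, and they no longer enter any competition sum.
#'
#' @param id Unique lineage identifier (character).
#' @param k Evolvability: rate constant scaling strategy change per unit
#'   selection gradient (non-negative).
#' @param u Current strategy (trait value).
#' @param x Current population density (non-negative).
#' @param extant Logical; `FALSE` iff `extinction_time` is set.
#' @param parent_id Identifier of the parent lineage, or `NA` for founders.
#' @param birth_time Time at which the lineage appeared.
#' @param extinction_time Time of extinction, or `NA` while extant.
#'
#' @return A one-row `evodyn_community` data frame.
#' @seealso [founder_pair()], [community()]
#' @export
species <- function(id, k, u, x, extant = TRUE, parent_id = NA_character_,
                    birth_time = 0, extinction_time = NA_real_) {
  stopifnot(
    "k must be non-negative" = is.numeric(k) && k >= 0,
    "x must be non-negative" = is.numeric(x) && x >= 0
  )
  if (extant && !is.na(extinction_time))
    stop("an extant species cannot carry an extinction_time", call. = FALSE)
  if (!extant && is.na(extinction_time))
    stop("an extinct species must carry an extinction_time", call. = FALSE)
  out <- data.frame(
    id = as.character(id), k = k, u = u, x = x, extant = extant,
    parent_id = as.character(parent_id), birth_time = birth_time,
    extinction_time = extinction_time, stringsAsFactors = FALSE
  )
  class(out) <- c("evodyn_community", "data.frame")
  out
}

#' Combine species into a community
#'
#' @param ... One-row communities from [species()] (or whole communities).
#' @return An `evodyn_community` data frame, one row per lineage.
#' @export
community <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(out$id)) stop("species ids must be unique", call. = FALSE)
  class(out) <- c("evodyn_community", "data.frame")
  out
}

#' Standard two-founder community
#'
#' The canonical experiment of the package: one fast- and one slow-evolving
#' species, identical in every respect except evolvability, starting at the
#' same strategy and density.
#'
#' @param u0 Initial strategy shared by both founders.
#' @param x0 Initial density per founder (default 10).
#' @param k_fast,k_slow Evolvabilities of the two founders (defaults 0.5 and
#'   0.2).
#' @return An `evodyn_community` with rows `fast_0` and `slow_0`.
#' @examples
#' founder_pair(u0 = 0.5)
#' @export
founder_pair <- function(u0, x0 = 10, k_fast = 0.5, k_slow = 0.2) {
  community(
    species("fast_0", k = k_fast, u = u0, x = x0),
    species("slow_0", k = k_slow, u = u0, x = x0)
  )
}

#' Extant subset of a community
#' @param comm An `evodyn_community`.
#' @return The extant rows.
#' @export
extant_community <- function(comm) {
  comm[comm$extant, , drop = FALSE]
}

check_community <- function(comm) {
  if (!is.data.frame(comm))
    stop("`community` must be a data frame (see species())", call. = FALSE)
  need <- c("id", "k", "u", "x", "extant")
  miss <- setdiff(need, names(comm))
  if (length(miss))
    stop("community is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  comm
}

#' @export
print.evodyn_community <- function(x, ...) {
  cat(sprintf("community of %d species (%d extant)\n", nrow(x), sum(x$extant)))
  print.data.frame(x, ...)
  invisible(x)
}
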