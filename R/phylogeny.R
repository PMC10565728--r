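#' Lineage tree of a radiation run
#'
#' Nodes are lineages: the founders of each G-function plus every daughter
#' species created at a branching point.  A speciation event turns the
#' parent's branch into an internal node whose two children are the
#' continuing parent lineage and the daughter.
#'
#' @param nodes Data frame with columns `id`, `parent_id` (`NA` for
#'   founders), `birth_time`, `extinction_time` (`NA` while extant), `k`,
#'   `u_final`.
#' @param t_end Horizon at which extant branches are cut.
#' @return An object of class `evodyn_phylogeny`.
#' @export
phylogeny <- function(nodes, t_end) {
  need <- c("id", "parent_id", "birth_time", "extinction_time", "k", "u_final")
  miss <- setdiff(need, names(nodes))
  if (length(miss))
    stop("phylogeny nodes missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent_id[i]
    if (!is.na(p)) {
      j <- match(p, nodes$id)
      if (is.na(j)) stop("unknown parent id: ", p, call. = FALSE)
      if (nodes$birth_time[j] > nodes$birth_time[i])
        stop("parent ", p, " born after child ", nodes$id[i], call. = FALSE)
    }
  }
  structure(list(nodes = nodes, t_end = t_end), class = "evodyn_phylogeny")
}

#' @export
print.evodyn_phylogeny <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("phylogeny: %d lineages (%d founders, %d speciations), t_end = %g\n",
              nrow(n), sum(is.na(n$parent_id)), sum(!is.na(n$parent_id)), x$t_end))
  print.data.frame(n, ...)
  invisible(x)
}

#' Newick serialisation of a radiation phylogeny
#'
#' Branch lengths are in simulation time units (`end - birth` per segment,
#' where `end` is the next speciation on that lineage, its extinction time,
#' or `t_end`).  Internal node labels are lineage ids; the founders of the
#' two G-functions are joined under a zero-length `root`.  Ends with `";"`.
#'
#' @param phy An `evodyn_phylogeny`.
#' @return A single Newick string.
#' @examples
#' ph <- phylogeny(data.frame(
#'   id = c("fast_0", "slow_0"), parent_id = NA_character_,
#'   birth_time = 0, extinction_time = NA_real_, k = c(0.5, 0.2),
#'   u_final = c(-1.7, 1.3)), t_end = 100)
#' as_newick(ph)
#' @export
as_newick <- function(phy) {
  stopifnot(inherits(phy, "evodyn_phylogeny"))
  nodes <- phy$nodes
  t_end <- phy$t_end
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE)

  clade <- function(id, start) {
    kids <- nodes[!is.na(nodes$parent_id) & nodes$parent_id == id &
                    nodes$birth_time > start, , drop = FALSE]
    kids <- kids[order(kids$birth_time), , drop = FALSE]
    if (!nrow(kids)) {
      end <- nodes$extinction_time[match(id, nodes$id)]
      if (is.na(end)) end <- t_end
      return(paste0(id, ":", fmt(end - start)))
    }
    tb <- kids$birth_time[1]
    paste0("(", clade(id, tb), ",", clade(kids$id[1], tb), ")",
           id, ":", fmt(tb - start))
  }

  founders <- nodes$id[is.na(nodes$parent_id)]
  sub <- vapply(founders, function(f)
    clade(f, nodes$birth_time[match(f, nodes$id)]), character(1))
  paste0("(", paste(sub, collapse = ","), ")root:0;")
}

#' Write a phylogeny to a Newick file
#' @param phy An `evodyn_phylogeny`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(phy, path) {
  writeLines(as_newick(phy), path)
  invisible(path)
}
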