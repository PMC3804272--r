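#' Node distances (nd) of every leaf on a rooted FSF tree
#'
#' For each leaf a, the raw node distance is the number of internal nodes
#' strictly between the root and a (both endpoints excluded); nd is the raw
#' distance divided by its maximum over all leaves, so a leaf attached
#' directly to the root (the most ancestral structure) has nd = 0 and the
#' deepest leaf has nd = 1. nd is a topology-only statistic: branch lengths
#' are ignored.
#'
#' @param tree A rooted `ape::phylo` tree with unique leaf labels
#'   (FSF ids).
#' @return Named numeric vector of nd values in `[0, 1]`, one per leaf.
#' @examples
#' tr <- ape::read.tree(text = "((((L5,L4)i3,L3)i2,L2)i1,L1)r;")
#' node_distances(tr)  # L1 = 0, L2 = 1/3, L5 = 1
#' @export
node_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  raw <- vapply(seq_len(ntip), function(tip) {
    d <- 0L
    node <- parent[tip]
    while (node != root) {
      d <- d + 1L
      node <- parent[node]
    }
    d
  }, integer(1))
  if (max(raw) == 0L) stop("degenerate tree: nd undefined")
  stats::setNames(raw / max(raw), tree$tip.label)
}

#' Geological age of an FSF from its node distance
#'
#' Linear molecular clock for fold superfamilies:
#' `t = -3.831 * nd + 3.628`, in billions of years (Gy). The clock can
#' return a (slightly) negative age for the youngest structures; the raw
#' value is returned with a warning rather than clamped.
#'
#' @param nd Numeric vector of node distances in `[0, 1]`.
#' @return Ages in Gy.
#' @examples
#' clock_age(0)    # 3.628 Gy
#' clock_age(0.2)  # 2.8618 Gy
#' @export
clock_age <- function(nd) {
  if (any(nd < 0 | nd > 1)) stop("nd must lie in [0, 1]")
  t <- -3.831 * nd + 3.628
  if (any(t < 0)) warning("clock returned negative age(s) for nd near 1")
  t
}

#' Age stratum of an FSF
#'
#' Ancient FSFs emerged before the onset of massive domain loss
#' (nd in \[0, 0.2\]); recent FSFs emerged after the "big bang" of domain
#' combination (nd in \[0.6, 1\]); everything else is `"neither"`. Both
#' bins are closed.
#'
#' @param nd Numeric vector of node distances in `[0, 1]`.
#' @return Character vector in `{"ancient", "recent", "neither"}`.
#' @export
age_bin <- function(nd) {
  if (any(nd < 0 | nd > 1)) stop("nd must lie in [0, 1]")
  ifelse(nd <= 0.2, "ancient", ifelse(nd >= 0.6, "recent", "neither"))
}

#' FSF age table from a rooted tree
#'
#' Convenience wrapper combining [node_distances()], [clock_age()] and
#' [age_bin()].
#'
#' @param tree Rooted `ape::phylo` tree with FSF ids as leaf labels.
#' @return Data frame with `fsf_id`, `nd`, `age_gy`, `stratum`.
#' @export
fsf_age_table <- function(tree) {
  nd <- node_distances(tree)
  data.frame(fsf_id = names(nd), nd = unname(nd),
             age_gy = suppressWarnings(clock_age(unname(nd))),
             stratum = age_bin(unname(nd)),
             stringsAsFactors = FALSE)
}

#' Read a precomputed FSF age table
#'
#' Alternative to providing a tree: a TSV with columns `fsf_id` and `nd`
#' (additional columns ignored); ages and strata are recomputed.
#'
#' @param path Path to the TSV file.
#' @return Data frame as in [fsf_age_table()].
#' @export
read_fsf_age_table <- function(path) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("fsf_id", "nd") %in% names(tab)))
  data.frame(fsf_id = as.character(tab$fsf_id), nd = as.numeric(tab$nd),
             age_gy = suppressWarnings(clock_age(as.numeric(tab$nd))),
             stratum = age_bin(as.numeric(tab$nd)),
             stringsAsFactors = FALSE)
}

#' Cumulative accumulation curves of FSF repertoires over nd
#'
#' For each repertoire class (shared between the species, specific to A,
#' specific to B), counts how many FSFs have appeared by each node distance
#' — the cumulative accumulation of domain structures over evolutionary
#' time.
#'
#' @param age_table Data frame with `fsf_id`, `nd` (see [fsf_age_table()]).
#' @param venn Venn decomposition from [compare_repertoires()].
#' @return Data frame with `class` (`shared`, `only_a`, `only_b`), `nd`
#'   (distinct breakpoints, ascending) and `cumulative` counts.
#' @export
cumulative_accumulation <- function(age_table, venn) {
  all_ids <- unlist(venn, use.names = FALSE)
  missing <- setdiff(all_ids, age_table$fsf_id)
  if (length(missing) > 0L)
    stop("no nd for FSF id(s): ", paste(missing, collapse = ", "))
  rows <- lapply(names(venn), function(cls) {
    ids <- venn[[cls]]
    if (length(ids) == 0L)
      return(data.frame(class = character(), nd = numeric(),
                        cumulative = integer(), stringsAsFactors = FALSE))
    nd <- sort(age_table$nd[match(ids, age_table$fsf_id)])
    brk <- unique(nd)
    data.frame(class = cls, nd = brk,
               cumulative = vapply(brk, function(x) sum(nd <= x), integer(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
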