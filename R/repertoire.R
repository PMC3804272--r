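#' Build the FSF repertoire of a species
#'
#' @param assignments Long-format assignment table.
#' @param species Species label.
#' @return List with `species` and `fsf` (sorted unique FSF ids).
#' @export
build_repertoire <- function(assignments, species = "") {
  list(species = species, fsf = sort(unique(assignments$fsf_id)))
}

#' Compare two FSF repertoires (Venn decomposition)
#'
#' @param a,b Repertoires from [build_repertoire()] (or plain character
#'   vectors of FSF ids).
#' @return List with `shared`, `only_a`, `only_b` (sorted FSF id vectors).
#' @export
compare_repertoires <- function(a, b) {
  fa <- if (is.list(a)) a$fsf else unique(a)
  fb <- if (is.list(b)) b$fsf else unique(b)
  list(shared = sort(intersect(fa, fb)),
       only_a = sort(setdiff(fa, fb)),
       only_b = sort(setdiff(fb, fa)))
}

#' Proteome and domain-coverage summary statistics
#'
#' Per-species summary in the style of a proteome census table: sequence
#' counts and lengths (in residues), the fraction of residues inside FSF
#' domain regions (as opposed to intervening sequence), domain-region sizes,
#' and FSF repertoire counts.
#'
#' @param records Proteome data frame.
#' @param assignments Its assignment table.
#' @param other Optional: the other species' repertoire (or FSF id vector),
#'   needed to count species-specific FSFs; `NA` when absent.
#' @return One-row data frame with columns `n_sequences`,
#'   `n_with_assignment`, `pct_with_assignment`, `mean_length`, `sd_length`,
#'   `min_length`, `max_length`, `fraction_in_fsf`, `mean_fsf_residues`,
#'   `min_fsf_residues`, `max_fsf_residues`, `total_fsfs`, `specific_fsfs`.
#' @export
proteome_summary <- function(records, assignments, other = NULL) {
  lens <- nchar(records$sequence)
  with_assign <- records$seq_id %in% assignments$seq_id
  # residues inside FSF regions, overlaps collapsed per sequence
  fsf_res <- vapply(records$seq_id, function(id) {
    a <- assignments[assignments$seq_id == id, , drop = FALSE]
    if (nrow(a) == 0L) return(0L)
    m <- merge_intervals(a[, c("start", "end")])
    sum(m[, 2L] - m[, 1L] + 1L)
  }, integer(1))
  dom <- fsf_res[with_assign]
  specific <- if (is.null(other)) NA_integer_ else
    length(compare_repertoires(build_repertoire(assignments), other)$only_a)
  data.frame(
    n_sequences = nrow(records),
    n_with_assignment = sum(with_assign),
    pct_with_assignment = if (nrow(records)) 100 * mean(with_assign) else NA_real_,
    mean_length = mean(lens), sd_length = stats::sd(lens),
    min_length = min(lens), max_length = max(lens),
    fraction_in_fsf = if (sum(lens)) sum(fsf_res) / sum(lens) else 0,
    mean_fsf_residues = if (length(dom)) mean(dom) else NA_real_,
    min_fsf_residues = if (length(dom)) min(dom) else NA_integer_,
    max_fsf_residues = if (length(dom)) max(dom) else NA_integer_,
    total_fsfs = length(unique(assignments$fsf_id)),
    specific_fsfs = specific
  )
}

#' Tally FSFs by functional category
#'
#' @param fsf_set Character vector of FSF ids.
#' @param category_map Data frame with columns `fsf_id`, `category`
#'   (may cover only part of `fsf_set`).
#' @return Named integer vector of counts per category; ids without a
#'   mapping are counted under `"unknown"`. Empty input gives an empty
#'   vector.
#' @export
tally_functions <- function(fsf_set, category_map) {
  fsf_set <- unique(fsf_set)
  if (length(fsf_set) == 0L) return(integer(0))
  cat <- category_map$category[match(fsf_set, category_map$fsf_id)]
  cat[is.na(cat)] <- "unknown"
  table_out <- table(cat)
  stats::setNames(as.integer(table_out), names(table_out))
}
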