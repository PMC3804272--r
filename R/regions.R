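#' Merge intervals into a minimal disjoint set
#'
#' Merges overlapping and adjacent 1-based inclusive intervals. Adjacent
#' means touching on the residue grid: `(1,2)` and `(3,4)` merge to `(1,4)`.
#'
#' @param intervals Two-column matrix or data frame of `start`, `end`
#'   (1-based inclusive), or an empty object.
#' @return Two-column integer matrix (`start`, `end`) of disjoint sorted
#'   intervals covering the same residues.
#' @examples
#' merge_intervals(rbind(c(3, 7), c(5, 10)))  # -> (3, 10)
#' @export
merge_intervals <- function(intervals) {
  m <- as.matrix(intervals)
  if (length(m) == 0L || nrow(m) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  storage.mode(m) <- "integer"
  stopifnot(ncol(m) == 2L, all(m[, 1L] <= m[, 2L]), all(m[, 1L] >= 1L))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- nrow(out)
    if (m[i, 1L] <= out[last, 2L] + 1L) {
      out[last, 2L] <- max(out[last, 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Partition a sequence into structural contexts
#'
#' Splits one protein sequence into the five analysis contexts: the whole
#' sequence, all domain residues, residues of shared-FSF domains, residues
#' of species-specific-FSF domains, and intervening (non-domain) residues.
#' A residue covered by both a shared-FSF and a specific-FSF assignment is
#' counted as shared (shared wins), keeping the three region classes
#' disjoint; every residue belongs to exactly one of
#' shared / specific / intervening.
#'
#' @param record One-row data frame (or list) with `seq_id` and `sequence`.
#' @param assignments Long-format assignment rows for this sequence
#'   (may be empty).
#' @param shared_fsf Character vector of FSF ids shared by the two species.
#' @return A list with `seq_id`, `contexts` (named character vector of
#'   concatenated subsequences for `whole`, `domain_all`, `domain_shared`,
#'   `domain_specific`, `intervening`) and `counts` (residue counts per
#'   context, ambiguity letters included).
#' @export
partition_sequence <- function(record, assignments, shared_fsf) {
  seq <- record$sequence
  n <- nchar(seq)
  if (nrow(assignments) > 0L) {
    if (!all(assignments$seq_id == record$seq_id))
      stop("assignments reference a different seq_id")
    if (any(assignments$end > n))
      stop("assignment exceeds sequence length for ", record$seq_id)
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  shared_mask <- logical(n)
  specific_mask <- logical(n)
  for (i in seq_len(nrow(assignments))) {
    idx <- assignments$start[i]:assignments$end[i]
    if (assignments$fsf_id[i] %in% shared_fsf) shared_mask[idx] <- TRUE
    else specific_mask[idx] <- TRUE
  }
  specific_mask <- specific_mask & !shared_mask   # shared wins
  domain_mask <- shared_mask | specific_mask
  ctx <- c(
    whole           = seq,
    domain_all      = paste(res[domain_mask], collapse = ""),
    domain_shared   = paste(res[shared_mask], collapse = ""),
    domain_specific = paste(res[specific_mask], collapse = ""),
    intervening     = paste(res[!domain_mask], collapse = "")
  )
  list(seq_id = record$seq_id, contexts = ctx, counts = nchar(ctx))
}

#' Partition every sequence of a proteome
#'
#' @param records Proteome data frame (`seq_id`, `sequence`).
#' @param assignments Long-format assignment table for this proteome.
#'   Assignments whose `seq_id` is absent from `records` are dropped with a
#'   warning.
#' @param shared_fsf Character vector of shared FSF ids.
#' @return Named list of per-sequence partitions (see [partition_sequence()]).
#' @export
partition_proteome <- function(records, assignments, shared_fsf) {
  unknown <- setdiff(unique(assignments$seq_id), records$seq_id)
  if (length(unknown) > 0L) {
    warning("dropping assignments for unknown seq_id(s): ",
            paste(unknown, collapse = ", "))
    assignments <- assignments[!assignments$seq_id %in% unknown, , drop = FALSE]
  }
  by_seq <- split(assignments, factor(assignments$seq_id, levels = records$seq_id))
  out <- lapply(seq_len(nrow(records)), function(i) {
    partition_sequence(records[i, ], by_seq[[records$seq_id[i]]], shared_fsf)
  })
  names(out) <- records$seq_id
  out
}

#' Export partitions as a BED-like table
#'
#' Writes one row per maximal run of residues in a context, with 0-based
#' half-open coordinates (BED convention).
#'
#' @param partitions Result of [partition_proteome()].
#' @param records The proteome the partitions came from.
#' @param assignments Its assignment table.
#' @param shared_fsf Shared FSF ids.
#' @return Data frame with `seq_id`, `start`, `end` (0-based half-open),
#'   `context` in `{domain_shared, domain_specific, intervening}`.
#' @export
partition_table <- function(partitions, records, assignments, shared_fsf) {
  rows <- lapply(records$seq_id, function(id) {
    rec <- records[records$seq_id == id, ]
    a <- assignments[assignments$seq_id == id, , drop = FALSE]
    n <- nchar(rec$sequence)
    lab <- rep("intervening", n)
    for (i in seq_len(nrow(a))) {
      idx <- a$start[i]:a$end[i]
      is_shared <- a$fsf_id[i] %in% shared_fsf
      lab[idx] <- ifelse(lab[idx] == "domain_shared" | is_shared,
                         "domain_shared", "domain_specific")
    }
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths        # 0-based half-open
    data.frame(seq_id = id, start = starts, end = ends,
               context = r$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
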