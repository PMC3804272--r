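#' FSF multiset of a sequence's assignments
#'
#' One FSF id per assignment (repeats kept), so a sequence with two copies
#' of the same FSF contributes it twice.
#'
#' @param assignments Long-format assignment rows for one sequence.
#' @return Character vector (possibly with repeats), sorted.
#' @export
fsf_multiset <- function(assignments) {
  if (nrow(assignments) == 0L) return(character(0))
  sort(unname(vapply(split(assignments, assignments$assignment),
                     function(a) a$fsf_id[1L], character(1))))
}

#' Classify a homologous pair by its FSF assignments
#'
#' The five categories of homologous sequence pairs:
#' 1. neither sequence has FSF assignments;
#' 2. assignments in one sequence but not the other;
#' 3. extra FSF assignments in one of the sequences (one multiset strictly
#'    contains the other; an extra repeat of a shared FSF counts as extra);
#' 4. different FSF assignments with no containment either way;
#' 5. identical assignments (equal FSF multisets).
#'
#' Comparison is at the level of FSF id multisets, not interval
#' coordinates. The category is symmetric in the two sequences.
#'
#' @param fsf_a,fsf_b FSF multisets (character vectors, see
#'   [fsf_multiset()]) or assignment data frames for the two sequences.
#' @return Integer in 1..5.
#' @export
classify_pair <- function(fsf_a, fsf_b) {
  if (is.data.frame(fsf_a)) fsf_a <- fsf_multiset(fsf_a)
  if (is.data.frame(fsf_b)) fsf_b <- fsf_multiset(fsf_b)
  na <- length(fsf_a); nb <- length(fsf_b)
  if (na == 0L && nb == 0L) return(1L)
  if (na == 0L || nb == 0L) return(2L)
  ta <- table(fsf_a); tb <- table(fsf_b)
  if (identical(sort(fsf_a), sort(fsf_b))) return(5L)
  a_in_b <- all(names(ta) %in% names(tb)) && all(ta <= tb[names(ta)])
  b_in_a <- all(names(tb) %in% names(ta)) && all(tb <= ta[names(tb)])
  if (a_in_b || b_in_a) return(3L)
  4L
}

#' Classify every homologous pair
#'
#' @param pairs Data frame with `id_a`, `id_b`.
#' @param assign_a,assign_b Assignment tables of species A and B.
#' @return `pairs` with an integer `category` column added.
#' @export
classify_pairs <- function(pairs, assign_a, assign_b) {
  by_a <- split(assign_a, assign_a$seq_id)
  by_b <- split(assign_b, assign_b$seq_id)
  empty <- assign_a[0L, , drop = FALSE]
  pairs$category <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- by_a[[pairs$id_a[i]]]; if (is.null(a)) a <- empty
    b <- by_b[[pairs$id_b[i]]]; if (is.null(b)) b <- empty
    classify_pair(a, b)
  }, integer(1))
  pairs
}

#' Per-sequence composition of one FSF's domain regions
#'
#' Computes the relative abundance of each repeat of the FSF on the
#' sequence separately (concatenating the segments of a split domain),
#' then averages over repeats — repeat averaging, not residue pooling, so
#' each repeat contributes equally regardless of its length.
#'
#' @param record One-row data frame (or list) with `seq_id`, `sequence`.
#' @param assignments Assignment rows for this sequence restricted to one
#'   `fsf_id`.
#' @return Named composition vector, or `NULL` when every repeat is empty
#'   after ambiguity filtering (observation dropped).
#' @examples
#' rec <- data.frame(seq_id = "s", sequence = "RRXRD")
#' asn <- data.frame(seq_id = "s", fsf_id = "f", assignment = c(1, 2),
#'                   start = c(1, 4), end = c(2, 5))
#' per_sequence_fsf_composition(rec, asn)  # mean of (R:1) and (R:.5, D:.5)
#' @export
per_sequence_fsf_composition <- function(record, assignments) {
  stopifnot(nrow(assignments) >= 1L,
            length(unique(assignments$fsf_id)) == 1L)
  if (any(assignments$end > nchar(record$sequence)))
    stop("assignment exceeds sequence length for ", record$seq_id)
  reps <- lapply(split(assignments, assignments$assignment), function(a) {
    segs <- substring(record$sequence, a$start, a$end)
    relative_abundance(paste(segs, collapse = ""))
  })
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) == 0L) return(NULL)
  colMeans(do.call(rbind, reps))
}

#' Matched-FSF observations from category-5 homologous pairs
#'
#' For every homologous pair with identical FSF assignments and every
#' distinct FSF on it, records the repeat-averaged composition of that
#' FSF's regions in each species and their difference.
#'
#' @param pairs Data frame of category-5 pairs (`id_a`, `id_b`; a
#'   `category` column, if present, must be all 5).
#' @param records_a,records_b Proteomes of species A and B.
#' @param assign_a,assign_b Their assignment tables.
#' @return List with `fsf_id` (character, one per observation), `pair`
#'   (pair label `id_a|id_b`), `comp_a`, `comp_b`, `diff` (matrices with 20
#'   columns); attribute `n_fsf` gives the number of distinct FSFs.
#' @export
matched_fsf_dataset <- function(pairs, records_a, records_b,
                                assign_a, assign_b) {
  if (!is.null(pairs$category) && any(pairs$category != 5L))
    stop("matched_fsf_dataset requires category-5 pairs only")
  by_a <- split(assign_a, assign_a$seq_id)
  by_b <- split(assign_b, assign_b$seq_id)
  fsf_ids <- character(0); pair_ids <- character(0)
  comp_a <- list(); comp_b <- list()
  for (i in seq_len(nrow(pairs))) {
    ia <- pairs$id_a[i]; ib <- pairs$id_b[i]
    aa <- by_a[[ia]]; bb <- by_b[[ib]]
    if (is.null(aa) || is.null(bb) ||
        !identical(sort(unique(aa$fsf_id)), sort(unique(bb$fsf_id))) ||
        classify_pair(aa, bb) != 5L)
      stop("pair ", ia, "|", ib, " is not category 5")
    rec_a <- records_a[records_a$seq_id == ia, ]
    rec_b <- records_b[records_b$seq_id == ib, ]
    for (f in unique(aa$fsf_id)) {
      ca <- per_sequence_fsf_composition(rec_a, aa[aa$fsf_id == f, ])
      cb <- per_sequence_fsf_composition(rec_b, bb[bb$fsf_id == f, ])
      if (is.null(ca) || is.null(cb)) next
      fsf_ids <- c(fsf_ids, f)
      pair_ids <- c(pair_ids, paste(ia, ib, sep = "|"))
      comp_a[[length(comp_a) + 1L]] <- ca
      comp_b[[length(comp_b) + 1L]] <- cb
    }
  }
  ca <- do.call(rbind, comp_a)
  cb <- do.call(rbind, comp_b)
  if (is.null(ca)) {
    ca <- cb <- matrix(numeric(), ncol = 20L,
                       dimnames = list(NULL, AMINO_ACIDS))
  }
  out <- list(fsf_id = fsf_ids, pair = pair_ids,
              comp_a = ca, comp_b = cb, diff = ca - cb)
  attr(out, "n_fsf") <- length(unique(fsf_ids))
  out
}

#' Compare species composition over matched FSFs
#'
#' Observations sharing an FSF are first averaged within the FSF (over
#' pairs), giving one composition per FSF per species; the two per-FSF
#' composition sets are then compared with the Welch two-sample t-test
#' (default). Alternatively (`method = "paired"`) a one-sample t-test on
#' the per-FSF mean differences is available. An age filter restricts the
#' analysis to FSFs whose nd falls in a stratum.
#'
#' @param observations Result of [matched_fsf_dataset()].
#' @param ref Barophily reference.
#' @param age_table Optional data frame with `fsf_id`, `nd` (see
#'   [fsf_age_table()]); required when `stratum` is given.
#' @param stratum Optional: `"ancient"` (nd in \[0, 0.2\]) or `"recent"`
#'   (nd in \[0.6, 1\]).
#' @param method `"welch"` (default) or `"paired"`.
#' @return A [compare_groups()]-style data frame (for `"paired"`, `maa_b`,
#'   `sd_b`, `sem_b` describe the differences' distribution is not reported;
#'   columns `t`, `df`, `p` come from the one-sample test on per-FSF
#'   differences). Attribute `n_fsf` gives the number of FSFs used.
#' @export
matched_comparison <- function(observations, ref = load_barophily_reference(),
                               age_table = NULL, stratum = NULL,
                               method = c("welch", "paired")) {
  method <- match.arg(method)
  keep <- rep(TRUE, length(observations$fsf_id))
  if (!is.null(stratum)) {
    if (is.null(age_table)) stop("age_table required for stratified analysis")
    missing <- setdiff(unique(observations$fsf_id), age_table$fsf_id)
    if (length(missing) > 0L)
      stop("no nd for FSF id(s): ", paste(missing, collapse = ", "))
    nd <- age_table$nd[match(observations$fsf_id, age_table$fsf_id)]
    keep <- age_bin(nd) == stratum
  }
  if (!any(keep)) stop("empty stratum: no matched FSFs with nd in range")
  fsf <- factor(observations$fsf_id[keep])
  mean_by_fsf <- function(m) {
    rowsum(m[keep, , drop = FALSE], fsf) / as.vector(table(fsf))
  }
  ma <- mean_by_fsf(observations$comp_a)
  mb <- mean_by_fsf(observations$comp_b)
  if (nrow(ma) < 2L)
    stop("need at least two matched FSFs after filtering")
  out <- if (method == "welch") {
    compare_groups(ma, mb, ref)
  } else {
    .paired_comparison(ma, mb, ref)
  }
  attr(out, "n_fsf") <- nrow(ma)
  out
}

# one-sample t-test on per-FSF mean differences
.paired_comparison <- function(ma, mb, ref) {
  ord <- aa_report_order(ref)
  d <- ma[, ord, drop = FALSE] - mb[, ord, drop = FALSE]
  tests <- vapply(ord, function(aa) {
    x <- d[, aa]
    if (stats::sd(x) == 0) {
      if (isTRUE(all.equal(mean(x), 0))) return(c(t = 0, df = length(x) - 1, p = 1))
      stop("degenerate paired comparison for ", aa)
    }
    fit <- stats::t.test(x)
    c(t = unname(fit$statistic), df = unname(fit$parameter), p = fit$p.value)
  }, numeric(3))
  refx <- ref[match(ord, ref$aa), ]
  n <- nrow(d)
  data.frame(
    aa = ord, name = refx$name, class = refx$class, rank = refx$rank,
    maa_a = unname(colMeans(ma[, ord, drop = FALSE])),
    maa_b = unname(colMeans(mb[, ord, drop = FALSE])),
    diff = unname(colMeans(d)),
    sd_a = unname(apply(ma[, ord, drop = FALSE], 2, stats::sd)),
    sd_b = unname(apply(mb[, ord, drop = FALSE], 2, stats::sd)),
    sem_a = unname(apply(ma[, ord, drop = FALSE], 2, stats::sd)) / sqrt(n),
    sem_b = unname(apply(mb[, ord, drop = FALSE], 2, stats::sd)) / sqrt(n),
    t = tests["t", ], df = tests["df", ], p = tests["p", ],
    stars = significance_stars(tests["p", ]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
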