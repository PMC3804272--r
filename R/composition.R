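#' Relative amino-acid abundance of a subsequence
#'
#' Counts of each standard amino acid divided by the number of standard
#' residues in the subsequence. Ambiguity letters (X, B, Z, U) are excluded
#' from both numerator and denominator, so the 20 abundances sum to 1
#' whenever at least one standard residue is present.
#'
#' @param subsequence Character scalar (possibly empty).
#' @return Named numeric vector over [AMINO_ACIDS], or `NULL` when the
#'   subsequence has no standard residue ("no observation": the sequence is
#'   skipped for that context).
#' @examples
#' relative_abundance("RRKD")  # R 0.5, K 0.25, D 0.25
#' @export
relative_abundance <- function(subsequence) {
  letters <- strsplit(subsequence, "", fixed = TRUE)[[1]]
  counts <- tabulate(factor(letters, levels = AMINO_ACIDS), nbins = 20L)
  total <- sum(counts)
  if (total == 0L) return(NULL)
  stats::setNames(counts / total, AMINO_ACIDS)
}

#' Composition matrix for a set of subsequences
#'
#' Applies [relative_abundance()] to each subsequence and stacks the results,
#' dropping subsequences with no standard residue.
#'
#' @param subsequences Character vector; names (if any) become row names.
#' @return Numeric matrix with 20 columns, one row per retained subsequence.
#' @export
composition_matrix <- function(subsequences) {
  vecs <- lapply(subsequences, relative_abundance)
  keep <- !vapply(vecs, is.null, logical(1))
  m <- do.call(rbind, vecs[keep])
  if (is.null(m)) m <- matrix(numeric(), ncol = 20L,
                              dimnames = list(NULL, AMINO_ACIDS))
  if (!is.null(names(subsequences))) rownames(m) <- names(subsequences)[keep]
  m
}

#' Mean relative amino-acid abundance (MAA) of a group
#'
#' Unweighted arithmetic mean of composition vectors over all observations
#' in a group, one value per amino acid.
#'
#' @param vectors Numeric matrix (rows = observations) or list of
#'   composition vectors.
#' @return Named numeric vector over [AMINO_ACIDS].
#' @export
group_mean <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(vectors) || nrow(vectors) == 0L) stop("empty group")
  colMeans(vectors)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. When both samples have zero variance:
#' equal means give `t = 0, p = 1`; unequal means are a degenerate
#' comparison and raise an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Named numeric vector `c(t, df, p)`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t needs at least two observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(c(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("degenerate comparison: both variances zero with unequal means")
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  c(t = unname(fit$statistic), df = unname(fit$parameter), p = fit$p.value)
}

#' Significance stars for a p-value
#'
#' The star tiers used throughout the report tables:
#' `*` p < 0.1, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#' (Note there is no 0.05 tier.)
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cut_at <- c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1)
  stars <- c("****", "***", "**", "*", "")
  stars[findInterval(p, cut_at, rightmost.closed = TRUE)]
}

#' Compare amino-acid composition between two groups of observations
#'
#' For each amino acid, computes the group MAAs, their difference
#' (species A minus species B, so with A the barophile a positive value
#' indicates a barophile-tilted usage), a Welch two-sample t-test across
#' the two observation sets, star annotation, and the barophily class.
#'
#' @param obs_a,obs_b Composition matrices (rows = observations); each must
#'   have at least two rows.
#' @param ref Barophily reference (see [load_barophily_reference()]).
#' @return Data frame, one row per amino acid in report order, with columns
#'   `aa`, `name`, `class`, `rank`, `maa_a`, `maa_b`, `diff`, `sd_a`,
#'   `sd_b`, `sem_a`, `sem_b`, `t`, `df`, `p`, `stars`; attributes `n_a`,
#'   `n_b` give the group sizes.
#' @export
compare_groups <- function(obs_a, obs_b, ref = load_barophily_reference()) {
  if (is.list(obs_a) && !is.matrix(obs_a)) obs_a <- do.call(rbind, obs_a)
  if (is.list(obs_b) && !is.matrix(obs_b)) obs_b <- do.call(rbind, obs_b)
  if (nrow(obs_a) < 2L || nrow(obs_b) < 2L)
    stop("each group needs at least two observations")
  ord <- aa_report_order(ref)
  tests <- vapply(ord, function(aa) welch_t(obs_a[, aa], obs_b[, aa]),
                  numeric(3))
  maa_a <- colMeans(obs_a)[ord]
  maa_b <- colMeans(obs_b)[ord]
  sd_a <- apply(obs_a[, ord, drop = FALSE], 2, stats::sd)
  sd_b <- apply(obs_b[, ord, drop = FALSE], 2, stats::sd)
  refx <- ref[match(ord, ref$aa), ]
  out <- data.frame(
    aa = ord, name = refx$name, class = refx$class, rank = refx$rank,
    maa_a = unname(maa_a), maa_b = unname(maa_b),
    diff = unname(maa_a - maa_b),
    sd_a = unname(sd_a), sd_b = unname(sd_b),
    sem_a = unname(sd_a / sqrt(nrow(obs_a))),
    sem_b = unname(sd_b / sqrt(nrow(obs_b))),
    t = tests["t", ], df = tests["df", ], p = tests["p", ],
    stars = significance_stars(tests["p", ]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_a") <- nrow(obs_a)
  attr(out, "n_b") <- nrow(obs_b)
  out
}

#' Preference-summary grid across contexts
#'
#' Summarises a set of group comparisons (one per structural/age context)
#' into the per-amino-acid preference grid: a cell holds `"B"` when the
#' barophile uses the amino acid significantly more (`diff > 0`,
#' `p < alpha`), `"N"` when the nonbarophile does, and is blank otherwise.
#' An amino acid is flagged consistent when at least `min_congruent`
#' contexts carry a letter congruent with its barophily class and no
#' context carries an incongruent letter (class-I amino acids are never
#' flagged).
#'
#' @param comparisons Named list of [compare_groups()] results; canonical
#'   context names are `complete`, `shared_fsf`, `specific_fsf`,
#'   `homologous_all`, `homologous_ancient`, `homologous_recent`.
#' @param ref Barophily reference.
#' @param alpha Significance threshold for a letter (default 0.1, the
#'   outermost star tier).
#' @param min_congruent Minimum congruent contexts for the consistency flag.
#' @return Data frame with `aa`, `name`, `class`, `rank`, one letter column
#'   per context, and logical `consistent`.
#' @export
preference_summary <- function(comparisons, ref = load_barophily_reference(),
                               alpha = 0.1, min_congruent = 4L) {
  stopifnot(length(comparisons) > 0L, !is.null(names(comparisons)))
  ord <- aa_report_order(ref)
  refx <- ref[match(ord, ref$aa), ]
  letters <- sapply(comparisons, function(cmp) {
    cmp <- cmp[match(ord, cmp$aa), ]
    ifelse(cmp$p < alpha & cmp$diff > 0, "B",
           ifelse(cmp$p < alpha & cmp$diff < 0, "N", ""))
  })
  letters <- matrix(letters, nrow = length(ord),
                    dimnames = list(ord, names(comparisons)))
  congruent <- rowSums(letters == matrix(refx$class, length(ord),
                                         ncol(letters)))
  incongruent <- rowSums(letters != "" &
                         letters != matrix(refx$class, length(ord),
                                           ncol(letters)))
  consistent <- refx$class %in% c("B", "N") &
    congruent >= min_congruent & incongruent == 0L
  out <- data.frame(aa = ord, name = refx$name, class = refx$class,
                    rank = refx$rank, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(letters, stringsAsFactors = FALSE))
  out$consistent <- consistent
  rownames(out) <- NULL
  out
}
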