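#' Run the full comparative composition analysis
#'
#' End-to-end orchestration over a bundle (from [simulate_proteome_pair()],
#' [read_bundle()], or assembled by hand from the readers): proteome
#' summaries, FSF repertoire Venn decomposition and function tallies,
#' per-context MAA comparisons (whole sequence, intervening regions,
#' shared-FSF regions, specific-FSF regions), homolog-pair classification,
#' matched-FSF comparisons (all / ancient / recent strata), the
#' preference-summary grid, cumulative accumulation curves, and a run log
#' with the per-stage observation counts.
#'
#' Statistical unit: for the sequence contexts, one composition vector per
#' sequence per context (sequences with no residue in a context are
#' skipped), Welch two-sample t-test across species. For matched-FSF
#' comparisons, one repeat-averaged composition per FSF per pair, averaged
#' within FSF, Welch test across the per-FSF species means.
#'
#' @param bundle List with `records_a`, `records_b` (species A = the
#'   barophile), `assignments_a`, `assignments_b`, `pairs`, and `age_table`
#'   (optional; without it the age-stratified comparisons and accumulation
#'   curves are skipped).
#' @param ref Barophily reference.
#' @param alpha Significance threshold for preference letters.
#' @param category_map Optional FSF function-category map (data frame
#'   `fsf_id`, `category`) for the repertoire tallies.
#' @param out_dir Optional directory: when given, every result table is
#'   written as TSV plus a YAML manifest (see [write_report()]).
#' @return List of class `barocomp_report` with elements `summary_a`,
#'   `summary_b`, `venn`, `venn_counts`, `tally_a`, `tally_b`,
#'   `pair_categories`, `comparisons` (named list: `complete`,
#'   `intervening`, `shared_fsf`, `specific_fsf`, `homologous_all`,
#'   `homologous_ancient`, `homologous_recent`), `preference`,
#'   `accumulation`, `log`.
#' @export
run_analysis <- function(bundle, ref = load_barophily_reference(),
                         alpha = 0.1, category_map = NULL, out_dir = NULL) {
  need <- c("records_a", "records_b", "assignments_a", "assignments_b", "pairs")
  if (!all(need %in% names(bundle)))
    stop("bundle must contain: ", paste(need, collapse = ", "))

  rep_a <- build_repertoire(bundle$assignments_a, "species_a")
  rep_b <- build_repertoire(bundle$assignments_b, "species_b")
  venn <- compare_repertoires(rep_a, rep_b)

  summary_a <- proteome_summary(bundle$records_a, bundle$assignments_a, rep_b)
  summary_b <- proteome_summary(bundle$records_b, bundle$assignments_b, rep_a)

  tally_a <- tally_b <- NULL
  if (!is.null(category_map)) {
    tally_a <- tally_functions(venn$only_a, category_map)
    tally_b <- tally_functions(venn$only_b, category_map)
  }

  part_a <- partition_proteome(bundle$records_a, bundle$assignments_a, venn$shared)
  part_b <- partition_proteome(bundle$records_b, bundle$assignments_b, venn$shared)
  ctx_matrix <- function(parts, ctx)
    composition_matrix(vapply(parts, function(p) p$contexts[[ctx]], character(1)))
  ctx_map <- c(complete = "whole", intervening = "intervening",
               shared_fsf = "domain_shared", specific_fsf = "domain_specific")
  comparisons <- list()
  counts <- list()
  for (nm in names(ctx_map)) {
    ma <- ctx_matrix(part_a, ctx_map[[nm]])
    mb <- ctx_matrix(part_b, ctx_map[[nm]])
    counts[[nm]] <- c(n_a = nrow(ma), n_b = nrow(mb))
    comparisons[[nm]] <- if (nrow(ma) >= 2L && nrow(mb) >= 2L)
      compare_groups(ma, mb, ref) else NULL
    if (is.null(comparisons[[nm]]))
      warning("context '", nm, "' has fewer than two observations per species")
  }

  pairs_cat <- classify_pairs(bundle$pairs, bundle$assignments_a,
                              bundle$assignments_b)
  cat_counts <- vapply(1:5, function(k) sum(pairs_cat$category == k), integer(1))
  names(cat_counts) <- paste0("cat", 1:5)

  matched <- matched_fsf_dataset(pairs_cat[pairs_cat$category == 5L, ],
                                 bundle$records_a, bundle$records_b,
                                 bundle$assignments_a, bundle$assignments_b)
  comparisons$homologous_all <-
    if (attr(matched, "n_fsf") >= 2L) matched_comparison(matched, ref) else NULL
  strat_n <- c(ancient = NA_integer_, recent = NA_integer_)
  for (s in c("ancient", "recent")) {
    nm <- paste0("homologous_", s)
    comparisons[[nm]] <- NULL
    if (!is.null(bundle$age_table)) {
      nd <- bundle$age_table$nd[match(unique(matched$fsf_id),
                                      bundle$age_table$fsf_id)]
      strat_n[[s]] <- sum(age_bin(nd[!is.na(nd)]) == s)
      if (strat_n[[s]] >= 2L)
        comparisons[[nm]] <- matched_comparison(matched, ref,
                                                bundle$age_table, s)
      else
        warning("stratum '", s, "' has fewer than two matched FSFs; skipped")
    }
  }

  pref_contexts <- comparisons[intersect(
    c("complete", "shared_fsf", "specific_fsf", "homologous_all",
      "homologous_ancient", "homologous_recent"), names(comparisons))]
  pref_contexts <- pref_contexts[!vapply(pref_contexts, is.null, logical(1))]
  preference <- preference_summary(pref_contexts, ref, alpha)

  accumulation <- NULL
  if (!is.null(bundle$age_table))
    accumulation <- cumulative_accumulation(bundle$age_table, venn)

  log <- list(
    package_version = as.character(utils::packageVersion("barocomp")),
    seed = if (!is.null(bundle$config)) bundle$config$seed else NA,
    alpha = alpha,
    n_sequences = c(a = nrow(bundle$records_a), b = nrow(bundle$records_b)),
    n_fsf = c(a = length(rep_a$fsf), b = length(rep_b$fsf),
              shared = length(venn$shared)),
    context_observations = counts,
    pair_categories = as.list(cat_counts),
    n_matched_fsf = attr(matched, "n_fsf"),
    strata_fsf = as.list(strat_n)
  )

  report <- structure(list(
    summary_a = summary_a, summary_b = summary_b,
    venn = venn,
    venn_counts = c(shared = length(venn$shared),
                    only_a = length(venn$only_a),
                    only_b = length(venn$only_b)),
    tally_a = tally_a, tally_b = tally_b,
    pair_categories = cat_counts,
    matched = matched,
    comparisons = comparisons,
    preference = preference,
    accumulation = accumulation,
    log = log
  ), class = "barocomp_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle as TSV tables plus a YAML manifest
#'
#' @param report A `barocomp_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  wt <- function(x, f) utils::write.table(x, fp(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(cbind(species = c("a", "b"), rbind(report$summary_a, report$summary_b)),
     "proteome_summary.tsv")
  venn_df <- data.frame(
    class = rep(names(report$venn), lengths(report$venn)),
    fsf_id = unlist(report$venn, use.names = FALSE))
  wt(venn_df, "venn.tsv")
  for (nm in names(report$comparisons))
    if (!is.null(report$comparisons[[nm]]))
      wt(report$comparisons[[nm]], paste0("comparison_", nm, ".tsv"))
  wt(report$preference, "preference_summary.tsv")
  if (!is.null(report$accumulation)) wt(report$accumulation, "accumulation.tsv")
  yaml::write_yaml(report$log, fp("run_manifest.yaml"))
  invisible(dir)
}

#' @export
print.barocomp_report <- function(x, ...) {
  cat("barocomp report\n")
  cat("  sequences: a =", x$log$n_sequences[["a"]],
      ", b =", x$log$n_sequences[["b"]], "\n")
  cat("  FSFs: a =", x$log$n_fsf[["a"]], ", b =", x$log$n_fsf[["b"]],
      ", shared =", x$log$n_fsf[["shared"]], "\n")
  cat("  homolog pairs by category:",
      paste(names(x$pair_categories), x$pair_categories, collapse = ", "), "\n")
  cat("  matched FSFs:", x$log$n_matched_fsf, "\n")
  flagged <- x$preference$aa[x$preference$consistent]
  cat("  consistently preferred:",
      if (length(flagged)) paste(flagged, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
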