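#' Read a proteome FASTA file
#'
#' Reads protein sequences and returns one row per record. The sequence
#' identifier is the header token up to the first whitespace; sequences are
#' uppercased. Besides the 20 standard residues, the ambiguity letters
#' X, B, Z and U are accepted (they are kept in the sequence but excluded
#' from all composition counts downstream).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `seq_id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 some description", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(ids == "")) stop("empty sequence id in FASTA header")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  bad <- vapply(seqs, function(s) {
    letters <- strsplit(s, "", fixed = TRUE)[[1]]
    any(!letters %in% c(AMINO_ACIDS, .AMBIGUOUS))
  }, logical(1))
  if (any(bad))
    stop("non-amino-acid letters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  data.frame(seq_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a proteome to FASTA
#'
#' @param records Data frame with `seq_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", records$seq_id)
  out[c(FALSE, TRUE)] <- records$sequence
  writeLines(out, path)
  invisible(path)
}

#' Read a domain-assignment table
#'
#' Parses a TSV with columns `seq_id`, `fsf_id`, `regions`, one row per
#' domain assignment. `regions` encodes 1-based inclusive residue intervals
#' as `"start-end"`, with multiple comma-separated segments for
#' discontinuous (split) domains, e.g. `"3-57,90-140"`. Segments of one
#' assignment are sorted and must not overlap. Whether a `seq_id` exists in
#' the proteome is checked at join time, not here.
#'
#' @param path Path to the TSV file (header required).
#' @return A long-format data frame with one row per segment and columns
#'   `seq_id`, `fsf_id`, `assignment` (integer identifying the source row,
#'   so repeats of the same FSF on a sequence stay distinguishable),
#'   `start`, `end` (1-based inclusive).
#' @export
read_domain_assignments <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("seq_id", "fsf_id", "regions")
  if (!all(need %in% names(tab)))
    stop("assignment table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L)
    return(data.frame(seq_id = character(), fsf_id = character(),
                      assignment = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    iv <- .parse_regions(tab$regions[i], where = paste0("row ", i))
    data.frame(seq_id = tab$seq_id[i], fsf_id = tab$fsf_id[i],
               assignment = i, start = iv[, 1L], end = iv[, 2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parsed)
  rownames(out) <- NULL
  out
}

# "3-57,90-140" -> matrix of sorted, validated segments
.parse_regions <- function(regions, where = "") {
  segs <- strsplit(regions, ",", fixed = TRUE)[[1]]
  if (length(segs) == 0L) stop("empty region string (", where, ")")
  m <- t(vapply(segs, function(s) {
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed segment '", s, "' (", where, ")")
    as.integer(parts)
  }, integer(2)))
  if (any(is.na(m))) stop("non-integer coordinates (", where, ")")
  if (any(m[, 1L] < 1L)) stop("coordinates must be >= 1 (", where, ")")
  if (any(m[, 1L] > m[, 2L]))
    stop("inverted interval (start > end) in '", regions, "' (", where, ")")
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L]))
    stop("overlapping segments within one assignment: '", regions, "' (", where, ")")
  m
}

#' Write a domain-assignment table
#'
#' Inverse of [read_domain_assignments()]: regroups the long format into one
#' row per assignment with a comma-separated region string.
#'
#' @param assignments Long-format assignment data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_assignments <- function(assignments, path) {
  if (nrow(assignments) == 0L) {
    writeLines("seq_id\tfsf_id\tregions", path)
    return(invisible(path))
  }
  key <- factor(assignments$assignment, levels = unique(assignments$assignment))
  rows <- lapply(split(assignments, key), function(a) {
    a <- a[order(a$start), , drop = FALSE]
    c(a$seq_id[1L], a$fsf_id[1L], paste(a$start, a$end, sep = "-", collapse = ","))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("seq_id", "fsf_id", "regions")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homologous-pair table
#'
#' TSV with two columns, `id_a` (barophile) and `id_b` (nonbarophile). Each
#' sequence id may appear in at most one pair.
#'
#' @param path Path to the TSV file (header required).
#' @return Data frame with columns `id_a`, `id_b`.
#' @export
read_homolog_pairs <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("id_a", "id_b") %in% names(tab)))
    stop("homolog-pair table must have columns id_a, id_b")
  tab <- tab[, c("id_a", "id_b")]
  if (anyDuplicated(tab$id_a) || anyDuplicated(tab$id_b))
    stop("a sequence id appears in more than one homolog pair")
  tab
}

#' Write a homologous-pair table
#' @param pairs Data frame with `id_a`, `id_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homolog_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Barophily reference: class and rank of the 20 amino acids
#'
#' The packaged reference classifying each amino acid as barophilic (B;
#' preferentially substituted into the barophile: Arg, Ser, Val, Asp, Gly),
#' nonbarophilic (N: Asn, Lys, Pro, Ile, Thr, Gln, Tyr) or indifferent (I),
#' with the integer barophily rank (BR; 20 = most barophilic, 1 = least;
#' no rank for class I).
#'
#' @return Data frame with columns `aa` (one-letter code), `name`
#'   (three-letter code), `class` (`"B"`, `"N"` or `"I"`) and `rank`
#'   (integer or `NA`).
#' @examples
#' ref <- load_barophily_reference()
#' ref[ref$aa == "R", ]  # Arg: class B, rank 20
#' @export
load_barophily_reference <- function() {
  path <- system.file("extdata", "barophily_reference.tsv",
                      package = "barocomp", mustWork = TRUE)
  ref <- utils::read.delim(path, colClasses = c("character", "character",
                                                "character", "integer"))
  stopifnot(nrow(ref) == 20L, setequal(ref$aa, AMINO_ACIDS),
            sum(ref$class == "B") == 5L, sum(ref$class == "N") == 7L,
            sum(ref$class == "I") == 8L,
            setequal(ref$rank[ref$class == "B"], 16:20),
            setequal(ref$rank[ref$class == "N"], 1:7),
            all(is.na(ref$rank[ref$class == "I"])))
  ref
}

#' Canonical report ordering of amino acids
#'
#' Orders amino acids by barophily rank, descending (most barophilic first),
#' then unranked (class-I) amino acids alphabetically.
#'
#' @param ref Barophily reference, see [load_barophily_reference()].
#' @return Character vector of the 20 one-letter codes in report order.
#' @export
aa_report_order <- function(ref = load_barophily_reference()) {
  ranked <- ref[!is.na(ref$rank), ]
  c(ranked$aa[order(-ranked$rank)], sort(ref$aa[is.na(ref$rank)]))
}
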