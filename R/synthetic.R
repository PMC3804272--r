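# Synthetic proteome pairs with planted barophily biases.
#
# The generator emulates the statistical structure the pipeline consumes:
# two species' proteomes built from homologous pairs that share a domain
# architecture, with domain-region residues drawn from class-tilted
# frequencies (barophile up-weights class-B amino acids, nonbarophile
# mirrored) and intervening-region residues drawn from the untilted
# background in both species. Tilting can be modulated per age stratum of
# the domain's FSF, so age-stratified recovery is testable.

# run code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic proteome-pair generator with
#' validation. Defaults emulate a desk-scale version of a two-species
#' archaeal comparison: 300 homologous pairs, 120 fold superfamilies of
#' which 80% are shared, domain regions of mean length 200 residues,
#' uniform background frequencies, and a planted bias of `delta = 0.2`.
#'
#' @param n_pairs Number of homologous sequence pairs.
#' @param n_fsf Number of FSFs (leaves of the simulated tree).
#' @param shared_fraction Fraction of FSFs present in both species; the
#'   remainder is split evenly into the two species-specific pools.
#' @param domain_length,intervening_length Named numeric vectors
#'   `c(mean, sd, min)` of the segment-length distributions (Gaussian,
#'   rounded, truncated at `min`).
#' @param background Named numeric vector of background amino-acid
#'   frequencies over [AMINO_ACIDS]; must sum to 1.
#' @param delta Planted bias in `[0, 1)`: in domain regions the barophile
#'   draws class-B amino acids with weight `1 + delta_eff` and class-N with
#'   `1 - delta_eff` (renormalised); the nonbarophile is mirrored.
#' @param bias_by_stratum Named multipliers (`ancient`, `neither`,
#'   `recent`) applied to `delta` according to the age stratum of the
#'   domain's FSF (`delta_eff = delta * multiplier`).
#' @param category_rates Named rates (`cat1`..`cat4`) at which homologous
#'   pairs are generated in the four non-identical assignment categories;
#'   the remainder is category 5 (identical assignments).
#' @param domains_per_pair Integer vector to draw the number of domains of
#'   a pair's architecture from (uniformly).
#' @param n_specific_extra Unpaired sequences per species carrying
#'   species-specific FSF domains (these populate the specific-FSF
#'   context; homologous pairs use shared FSFs only).
#' @param seed Integer seed; all randomness in the generator derives from
#'   it through a single stream in fixed draw order.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 300L, n_fsf = 120L, shared_fraction = 0.8,
                       domain_length = c(mean = 200, sd = 40, min = 30),
                       intervening_length = c(mean = 40, sd = 15, min = 1),
                       background = stats::setNames(rep(0.05, 20), AMINO_ACIDS),
                       delta = 0.2,
                       bias_by_stratum = c(ancient = 1, neither = 1, recent = 1),
                       category_rates = c(cat1 = 0.02, cat2 = 0.02,
                                          cat3 = 0.02, cat4 = 0.02),
                       domains_per_pair = 1:3,
                       n_specific_extra = 40L,
                       seed = 1L) {
  stopifnot(n_pairs >= 2L, n_fsf >= 4L,
            shared_fraction > 0, shared_fraction < 1,
            all(c("mean", "sd", "min") %in% names(domain_length)),
            all(c("mean", "sd", "min") %in% names(intervening_length)),
            setequal(names(background), AMINO_ACIDS),
            abs(sum(background) - 1) < 1e-9, all(background > 0),
            delta >= 0, delta < 1,
            setequal(names(bias_by_stratum), c("ancient", "neither", "recent")),
            all(abs(bias_by_stratum * delta) < 1),
            all(category_rates >= 0), sum(category_rates) < 1,
            setequal(names(category_rates), paste0("cat", 1:4)),
            all(domains_per_pair >= 1L), n_specific_extra >= 0L)
  background <- background[AMINO_ACIDS]
  structure(list(n_pairs = as.integer(n_pairs), n_fsf = as.integer(n_fsf),
                 shared_fraction = shared_fraction,
                 domain_length = domain_length,
                 intervening_length = intervening_length,
                 background = background, delta = delta,
                 bias_by_stratum = bias_by_stratum,
                 category_rates = category_rates,
                 domains_per_pair = as.integer(domains_per_pair),
                 n_specific_extra = as.integer(n_specific_extra),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# species-tilted residue frequencies; species "A" is the barophile
.tilted_freq <- function(background, ref, delta_eff, species = c("A", "B")) {
  species <- match.arg(species)
  cls <- ref$class[match(names(background), ref$aa)]
  up <- if (species == "A") "B" else "N"
  dn <- if (species == "A") "N" else "B"
  w <- ifelse(cls == up, 1 + delta_eff, ifelse(cls == dn, 1 - delta_eff, 1))
  p <- background * w
  p / sum(p)
}

#' Analytic expected MAA difference under the generator
#'
#' Closed-form expectation of the per-residue composition difference
#' (barophile minus nonbarophile) planted by the generator:
#' `E[diff(aa)] = p(aa) * (w_A / Z_A - w_B / Z_B)` where `w` is the class
#' tilt (`1 + delta_eff` for the up-weighted class, `1 - delta_eff` for the
#' down-weighted one, 1 for class I) and `Z` the resulting normaliser.
#' Exactly zero in the intervening context. Note that for class-I amino
#' acids the expectation is small but not exactly zero whenever the total
#' background mass of the B and N classes differs (the normalisers then
#' differ between species).
#'
#' @param config A [sim_config()].
#' @param aa One-letter amino-acid code.
#' @param context `"domain"` or `"intervening"`.
#' @param stratum Age stratum of the domain's FSF (selects the
#'   `bias_by_stratum` multiplier; default `"neither"`).
#' @param ref Barophily reference.
#' @return Expected MAA difference (a number).
#' @export
expected_maa_difference <- function(config, aa,
                                    context = c("domain", "intervening"),
                                    stratum = "neither",
                                    ref = load_barophily_reference()) {
  context <- match.arg(context)
  stopifnot(aa %in% AMINO_ACIDS)
  if (context == "intervening") return(0)
  delta_eff <- config$delta * config$bias_by_stratum[[stratum]]
  pa <- .tilted_freq(config$background, ref, delta_eff, "A")
  pb <- .tilted_freq(config$background, ref, delta_eff, "B")
  unname(pa[aa] - pb[aa])
}

# grow a rooted binary tree by sequential random attachment to a uniformly
# chosen edge; the first leaf stays attached to the root (the basal, most
# ancestral structure), guaranteeing a leaf at nd = 0
.grow_tree <- function(n) {
  stopifnot(n >= 2L)
  parent <- c(NA_integer_, 1L, 1L)   # 1 = root; 2, 3 = leaves
  children <- list(c(2L, 3L))
  is_leaf <- c(FALSE, TRUE, TRUE)
  protected <- 2L
  while (sum(is_leaf) < n) {
    cand <- setdiff(which(!is.na(parent)), protected)
    v <- cand[sample.int(length(cand), 1L)]
    u <- length(parent) + 1L           # new internal node splitting edge above v
    w <- u + 1L                        # new leaf
    pv <- parent[v]
    children[[pv]][children[[pv]] == v] <- u
    parent[c(u, w)] <- c(pv, u)
    parent[v] <- u
    children[[u]] <- c(v, w)
    is_leaf[c(u, w)] <- c(FALSE, TRUE)
  }
  labels <- integer(length(parent))
  labels[which(is_leaf)] <- seq_len(sum(is_leaf))
  name_of <- function(node) sprintf("fsf_%03d", labels[node])
  deparse_nwk <- function(node) {
    if (is_leaf[node]) return(name_of(node))
    paste0("(", paste(vapply(children[[node]], deparse_nwk, character(1)),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(deparse_nwk(1L), ";"))
}

#' Simulate a rooted binary FSF tree
#'
#' Sequential random attachment: starting from a two-leaf tree, each new
#' leaf is inserted on a uniformly chosen edge. One root-attached leaf is
#' kept basal throughout, so the tree always has a most-ancestral FSF at
#' node distance 0; normalisation of [node_distances()] puts the deepest
#' leaf at 1. Leaf labels are `fsf_001 .. fsf_<n>` in creation order.
#'
#' @param n_fsf Number of leaves (>= 2).
#' @param seed Integer seed; the same seed reproduces the tree exactly.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_fsf, seed = 1L) {
  if (n_fsf < 2L) stop("n_fsf must be >= 2")
  .with_seed(seed, .grow_tree(n_fsf))
}

# one sequence: alternating intervening / domain segments.
# arch: character vector of fsf ids (ordered); returns list(sequence, rows)
.build_sequence <- function(arch, species, cfg, ref, delta_by_fsf) {
  dl <- cfg$domain_length; il <- cfg$intervening_length
  k <- length(arch)
  if (k == 0L) {
    len <- max(30L, as.integer(round(stats::rnorm(1, dl[["mean"]], dl[["sd"]]))))
    seqc <- paste(sample(AMINO_ACIDS, len, TRUE, cfg$background), collapse = "")
    return(list(sequence = seqc, fsf = character(0),
                start = integer(0), end = integer(0)))
  }
  ilen <- pmax(as.integer(il[["min"]]),
               as.integer(round(stats::rnorm(k + 1L, il[["mean"]], il[["sd"]]))))
  dlen <- pmax(as.integer(dl[["min"]]),
               as.integer(round(stats::rnorm(k, dl[["mean"]], dl[["sd"]]))))
  segs <- character(2L * k + 1L)
  starts <- integer(k); ends <- integer(k)
  pos <- 0L
  for (j in seq_len(k)) {
    segs[2L * j - 1L] <- paste(sample(AMINO_ACIDS, ilen[j], TRUE,
                                      cfg$background), collapse = "")
    pos <- pos + ilen[j]
    pf <- .tilted_freq(cfg$background, ref, delta_by_fsf[[arch[j]]], species)
    segs[2L * j] <- paste(sample(AMINO_ACIDS, dlen[j], TRUE, pf), collapse = "")
    starts[j] <- pos + 1L
    pos <- pos + dlen[j]
    ends[j] <- pos
  }
  segs[2L * k + 1L] <- paste(sample(AMINO_ACIDS, ilen[k + 1L], TRUE,
                                    cfg$background), collapse = "")
  list(sequence = paste(segs, collapse = ""), fsf = arch,
       start = starts, end = ends)
}

#' Simulate a proteome pair with planted composition biases
#'
#' Generates two species' proteomes from homologous pairs sharing domain
#' architectures drawn from the shared FSF pool, plus unpaired per-species
#' sequences carrying species-specific FSFs. Domain-region residues are
#' drawn from class-tilted frequencies (see [sim_config()]); intervening
#' residues from the untilted background in both species. A small
#' configurable fraction of pairs is generated in homolog categories 1-4
#' (no / one-sided / extra / different assignments); the rest have
#' identical assignments (category 5). Species-specific FSFs never enter
#' homologous pairs.
#'
#' @param config A [sim_config()].
#' @return List with `records_a`, `records_b` (proteome data frames;
#'   species A is the barophile), `assignments_a`, `assignments_b`
#'   (long-format tables), `pairs` (with the generating `category_truth`),
#'   `tree` (`ape::phylo`), `age_table`, and `truth` (list: `fsf` table
#'   with per-FSF nd, stratum, pool and effective delta; `expected` table
#'   of analytic MAA differences per amino acid, context and stratum).
#'   Identical seeds give identical bundles.
#' @export
simulate_proteome_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ref <- load_barophily_reference()
  .with_seed(config$seed, {
    tree <- .grow_tree(config$n_fsf)
    age <- fsf_age_table(tree)
    delta_by_fsf <- as.list(stats::setNames(
      config$delta * unname(config$bias_by_stratum[age$stratum]), age$fsf_id))
    perm <- sample(age$fsf_id)
    n_shared <- max(2L, round(config$shared_fraction * config$n_fsf))
    if (n_shared > config$n_fsf - 2L) n_shared <- config$n_fsf - 2L
    shared <- perm[seq_len(n_shared)]
    rest <- perm[-seq_len(n_shared)]
    specific_a <- rest[seq_along(rest) %% 2L == 1L]
    specific_b <- rest[seq_along(rest) %% 2L == 0L]

    probs <- c(config$category_rates, cat5 = 1 - sum(config$category_rates))
    categories <- sample(1:5, config$n_pairs, TRUE, probs)

    recs_a <- vector("list", config$n_pairs)
    recs_b <- vector("list", config$n_pairs)
    asn_a <- list(); asn_b <- list()
    for (i in seq_len(config$n_pairs)) {
      k <- config$domains_per_pair[sample.int(length(config$domains_per_pair), 1L)]
      arch <- sample(shared, k, replace = TRUE)
      arch_a <- arch_b <- arch
      cat_i <- categories[i]
      if (cat_i == 1L) {
        arch_a <- arch_b <- character(0)
      } else if (cat_i == 2L) {
        if (sample.int(2L, 1L) == 1L) arch_a <- character(0)
        else arch_b <- character(0)
      } else if (cat_i == 3L) {
        extra <- sample(shared, 1L)
        if (sample.int(2L, 1L) == 1L) arch_a <- c(arch, extra)
        else arch_b <- c(arch, extra)
      } else if (cat_i == 4L) {
        arch_b <- sample(setdiff(shared, arch), k, replace = TRUE)
      }
      sa <- .build_sequence(arch_a, "A", config, ref, delta_by_fsf)
      sb <- .build_sequence(arch_b, "B", config, ref, delta_by_fsf)
      recs_a[[i]] <- c(sprintf("a_%04d", i), sa$sequence)
      recs_b[[i]] <- c(sprintf("b_%04d", i), sb$sequence)
      if (length(sa$fsf))
        asn_a[[length(asn_a) + 1L]] <-
          data.frame(seq_id = sprintf("a_%04d", i), fsf_id = sa$fsf,
                     start = sa$start, end = sa$end, stringsAsFactors = FALSE)
      if (length(sb$fsf))
        asn_b[[length(asn_b) + 1L]] <-
          data.frame(seq_id = sprintf("b_%04d", i), fsf_id = sb$fsf,
                     start = sb$start, end = sb$end, stringsAsFactors = FALSE)
    }
    # unpaired sequences with species-specific domains
    xa <- vector("list", config$n_specific_extra)
    xb <- vector("list", config$n_specific_extra)
    for (i in seq_len(config$n_specific_extra)) {
      ka <- sample.int(2L, 1L)
      sa <- .build_sequence(sample(specific_a, ka, replace = TRUE),
                            "A", config, ref, delta_by_fsf)
      sb <- .build_sequence(sample(specific_b, ka, replace = TRUE),
                            "B", config, ref, delta_by_fsf)
      xa[[i]] <- c(sprintf("a_x%03d", i), sa$sequence)
      xb[[i]] <- c(sprintf("b_x%03d", i), sb$sequence)
      asn_a[[length(asn_a) + 1L]] <-
        data.frame(seq_id = sprintf("a_x%03d", i), fsf_id = sa$fsf,
                   start = sa$start, end = sa$end, stringsAsFactors = FALSE)
      asn_b[[length(asn_b) + 1L]] <-
        data.frame(seq_id = sprintf("b_x%03d", i), fsf_id = sb$fsf,
                   start = sb$start, end = sb$end, stringsAsFactors = FALSE)
    }
    to_records <- function(rec_list) {
      recs <- do.call(rbind, rec_list)
      data.frame(seq_id = recs[, 1L], sequence = recs[, 2L],
                 stringsAsFactors = FALSE)
    }
    to_assignments <- function(asn_list) {
      asn <- if (length(asn_list)) do.call(rbind, asn_list) else
        data.frame(seq_id = character(), fsf_id = character(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE)
      asn$assignment <- seq_len(nrow(asn))
      asn[, c("seq_id", "fsf_id", "assignment", "start", "end")]
    }
    a <- list(records = to_records(c(recs_a, xa)),
              assignments = to_assignments(asn_a))
    b <- list(records = to_records(c(recs_b, xb)),
              assignments = to_assignments(asn_b))

    pairs <- data.frame(id_a = sprintf("a_%04d", seq_len(config$n_pairs)),
                        id_b = sprintf("b_%04d", seq_len(config$n_pairs)),
                        category_truth = categories,
                        stringsAsFactors = FALSE)
    pool <- rep("shared", config$n_fsf)
    names(pool) <- age$fsf_id
    pool[specific_a] <- "specific_a"
    pool[specific_b] <- "specific_b"
    truth_fsf <- data.frame(fsf_id = age$fsf_id, nd = age$nd,
                            stratum = age$stratum,
                            pool = unname(pool[age$fsf_id]),
                            delta_eff = unlist(delta_by_fsf[age$fsf_id]),
                            stringsAsFactors = FALSE)
    grid <- expand.grid(aa = AMINO_ACIDS,
                        stratum = c("ancient", "neither", "recent"),
                        stringsAsFactors = FALSE)
    expected <- rbind(
      data.frame(aa = grid$aa, context = "domain", stratum = grid$stratum,
                 expected_diff = mapply(function(aa, s)
                   expected_maa_difference(config, aa, "domain", s, ref),
                   grid$aa, grid$stratum),
                 stringsAsFactors = FALSE),
      data.frame(aa = AMINO_ACIDS, context = "intervening", stratum = NA,
                 expected_diff = 0, stringsAsFactors = FALSE))
    rownames(expected) <- NULL
    list(records_a = a$records, records_b = b$records,
         assignments_a = a$assignments, assignments_b = b$assignments,
         pairs = pairs, tree = tree, age_table = age,
         truth = list(fsf = truth_fsf, expected = expected),
         config = config)
  })
}

#' Write a simulated bundle to disk
#'
#' Serialises a [simulate_proteome_pair()] result in exactly the plain-text
#' formats the readers consume: two FASTA proteomes, two assignment TSVs,
#' the homolog-pair TSV, the Newick tree, the nd age table, the truth
#' tables and a YAML echo of the configuration.
#'
#' @param sim Result of [simulate_proteome_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(sim$records_a, fp("proteome_a.fasta"))
  write_fasta(sim$records_b, fp("proteome_b.fasta"))
  write_domain_assignments(sim$assignments_a, fp("assignments_a.tsv"))
  write_domain_assignments(sim$assignments_b, fp("assignments_b.tsv"))
  write_homolog_pairs(sim$pairs, fp("homolog_pairs.tsv"))
  ape::write.tree(sim$tree, fp("tree.nwk"))
  utils::write.table(sim$age_table, fp("age_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$fsf, fp("truth_fsf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$expected, fp("truth_expected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$background <- as.list(cfg$background)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Read an analysis bundle from disk
#'
#' Loads the files written by [write_bundle()] (or equivalently formatted
#' real data) back into the in-memory structure [run_analysis()] consumes.
#' The age table is recomputed from `tree.nwk` when present, otherwise read
#' from `age_table.tsv`.
#'
#' @param dir Bundle directory.
#' @return List with `records_a`, `records_b`, `assignments_a`,
#'   `assignments_b`, `pairs`, `age_table` (and `tree` when available).
#' @export
read_bundle <- function(dir) {
  fp <- function(x) file.path(dir, x)
  out <- list(
    records_a = read_fasta(fp("proteome_a.fasta")),
    records_b = read_fasta(fp("proteome_b.fasta")),
    assignments_a = read_domain_assignments(fp("assignments_a.tsv")),
    assignments_b = read_domain_assignments(fp("assignments_b.tsv")),
    pairs = read_homolog_pairs(fp("homolog_pairs.tsv"))
  )
  if (file.exists(fp("tree.nwk"))) {
    out$tree <- ape::read.tree(fp("tree.nwk"))
    out$age_table <- fsf_age_table(out$tree)
  } else if (file.exists(fp("age_table.tsv"))) {
    out$age_table <- read_fsf_age_table(fp("age_table.tsv"))
  }
  out
}
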