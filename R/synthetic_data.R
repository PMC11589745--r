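#' Configuration for the synthetic-data generators
#'
#' One config object drives every generator so that a single integer seed
#' reproduces all fixtures byte-identically (R's default Mersenne-Twister
#' RNG; each generator calls `set.seed(seed + offset)` internally, so
#' fixtures are independent of call order).
#'
#' Defaults emulate the study conditions the downstream rules assume:
#' eleven major taxon groups with Excavata as the recipient lineage,
#' three-stage libraries of five million mapped reads, negative binomial
#' counts with dispersion 0.05 (typical RNA-seq biological noise for a
#' well-behaved library), gene lengths 500-3000 bp, baseline expression
#' 100-1000 RPKM (log-uniform), planted stage effects of 2-4 log2 units,
#' and background branch supports of 75-100 so the planted key branch is
#' the one the 60% rule interrogates.
#'
#' @param seed Integer seed governing all draws.
#' @param taxmap A [taxon_group_map()].
#' @param n_genes Number of genes/queries to simulate.
#' @param hgt_fraction Fraction of genes planted as transfers, in [0, 1].
#' @param support_mean,support_spread Mean and SD of the planted key-branch
#'   support (0-100 scale); spread 0 plants the mean exactly.
#' @param support_dist `"normal"` (default; rounded, clamped to [0, 100])
#'   or `"uniform"` (discrete uniform on 0..100, ignoring mean/spread) for
#'   the planted key-branch support.
#' @param background_support_range Integer range for non-key branch
#'   supports.
#' @param nb_dispersion Negative binomial dispersion (variance
#'   `mu + d*mu^2`); 0 gives Poisson counts.
#' @param library_sizes Named positive numbers, `c(gro=, agg=, germ=)`.
#' @param gene_length_range Gene length interval in bp.
#' @param baseline_rpkm_range Baseline (growth-stage) expression interval,
#'   drawn log-uniformly.
#' @param effect_range Magnitude interval for planted log2 stage effects.
#' @param stage_class_probs Named probabilities over planted stage classes
#'   `null`, `aggup`, `aggdn`, `germup`, `germdn`, `aggspec` (must sum
#'   to 1).
#' @param e_screen,e_tree Screening and tree-tier e-value cut-offs the hit
#'   generator realizes classes against.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       taxmap = taxon_group_map(),
                       n_genes = 100L,
                       hgt_fraction = 0.5,
                       support_mean = 100,
                       support_spread = 0,
                       support_dist = c("normal", "uniform"),
                       background_support_range = c(75L, 100L),
                       nb_dispersion = 0.05,
                       library_sizes = c(gro = 5e6, agg = 5e6, germ = 5e6),
                       gene_length_range = c(500L, 3000L),
                       baseline_rpkm_range = c(100, 1000),
                       effect_range = c(2, 4),
                       stage_class_probs = c(null = 0.6, aggup = 0.08,
                                             aggdn = 0.08, germup = 0.08,
                                             germdn = 0.08, aggspec = 0.08),
                       e_screen = 1e-10,
                       e_tree = 1e-35) {
  stopifnot(inherits(taxmap, "taxon_group_map"))
  support_dist <- match.arg(support_dist)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (hgt_fraction < 0 || hgt_fraction > 1)
    stop("hgt_fraction must be in [0, 1]")
  if (n_genes < 0) stop("n_genes must be non-negative")
  if (support_mean < 0 || support_mean > 100 || support_spread < 0)
    stop("support model must have mean in [0, 100] and spread >= 0")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (!all(c("gro", "agg", "germ") %in% names(library_sizes)))
    stop("library_sizes must name gro, agg and germ")
  if (any(gene_length_range <= 0)) stop("gene lengths must be positive")
  cls <- c("null", "aggup", "aggdn", "germup", "germdn", "aggspec")
  if (!all(cls %in% names(stage_class_probs)) ||
      any(stage_class_probs < 0) ||
      abs(sum(stage_class_probs) - 1) > 1e-8)
    stop("stage_class_probs must be non-negative over ",
         paste(cls, collapse = "/"), " and sum to 1")
  structure(list(seed = seed, taxmap = taxmap, n_genes = as.integer(n_genes),
                 hgt_fraction = hgt_fraction, support_mean = support_mean,
                 support_spread = support_spread, support_dist = support_dist,
                 background_support_range = background_support_range,
                 nb_dispersion = nb_dispersion,
                 library_sizes = library_sizes,
                 gene_length_range = gene_length_range,
                 baseline_rpkm_range = baseline_rpkm_range,
                 effect_range = effect_range,
                 stage_class_probs = stage_class_probs[cls],
                 e_screen = e_screen, e_tree = e_tree),
            class = "sim_config")
}

draw_support <- function(n, mean, spread, dist = "normal") {
  if (dist == "uniform") return(sample(0:100, n, replace = TRUE))
  if (spread == 0) return(rep(round(mean), n))
  pmin(100L, pmax(0L, round(stats::rnorm(n, mean, spread))))
}

draw_background_support <- function(n, range) {
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

clade_newick <- function(labels, supports) {
  # caterpillar clade over labels with one support per internal node
  if (length(labels) == 1L) return(labels)
  s <- labels[1L]
  k <- 1L
  for (i in 2L:length(labels)) {
    s <- sprintf("(%s,%s)%d", s, labels[i], supports[k])
    k <- k + 1L
  }
  s
}

group_leaf_labels <- function(group, n, idx) {
  sprintf("%s|%s_sp%d|%s_t%d_%d", group, group, seq_len(n), group, idx,
          seq_len(n))
}

#' Simulate one gene tree with planted origin
#'
#' Builds a support-annotated Newick gene tree in which the query leaves
#' (species field `query`, taxon group = the recipient) attach inside
#' either the recipient group's clade (`origin = "vertical"`) or the named
#' donor group's clade (`origin = "hgt"`), with an all-donor-group sister
#' of `n_sister` leaves. The branch the HGT caller reads (the branch
#' subtending the query clade for families, or the query+sister ancestor
#' for a singleton query) carries a support drawn from the configured
#' (mean, spread); all other internal branches draw from the background
#' range.
#'
#' @param config A [sim_config()].
#' @param origin `"vertical"` or `"hgt"`.
#' @param donor Donor group name, required for `origin = "hgt"`; must be a
#'   non-recipient group.
#' @param n_query Number of query leaves (>=1); >=2 plants a monophyletic
#'   family.
#' @param n_sister Leaves in the sister subclade, default 2.
#' @param n_per_group Leaves per non-target group clade, default 3.
#' @param tree_index Integer tag making leaf ids unique across trees and
#'   decorrelating RNG streams for batches.
#' @return List: `newick` (string), `truth` (one-row data frame:
#'   `tree_id`, `origin`, `donor_group`, `n_query`, `key_support`).
#' @export
simulate_gene_tree <- function(config, origin = c("vertical", "hgt"),
                               donor = NULL, n_query = 1L, n_sister = 2L,
                               n_per_group = 3L, tree_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  origin <- match.arg(origin)
  taxmap <- config$taxmap
  if (length(taxmap$groups) < 2L) stop("need at least 2 taxon groups")
  if (origin == "hgt") {
    if (is.null(donor)) stop("origin = \"hgt\" requires a donor group")
    if (!donor %in% taxmap$groups)
      stop("unknown donor group: ", donor)
    if (donor == taxmap$recipient)
      stop("donor group must differ from the recipient")
    target <- donor
  } else {
    target <- taxmap$recipient
    donor <- NA_character_
  }
  set.seed(as.integer((config$seed + 7919 * tree_index) %% .Machine$integer.max))
  key_support <- draw_support(1L, config$support_mean, config$support_spread,
                              config$support_dist %||% "normal")
  qlab <- sprintf("%s|query|q%d_%d", taxmap$recipient, tree_index,
                  seq_len(n_query))
  bg <- function(n) draw_background_support(n, config$background_support_range)
  sis_lab <- group_leaf_labels(target, n_sister, tree_index)
  sister <- clade_newick(sis_lab, bg(max(0L, n_sister - 1L)))
  if (n_query == 1L) {
    # key support on the query+sister ancestor (terminal branches carry none)
    core <- sprintf("(%s,%s)%d", qlab, sister, key_support)
  } else {
    qclade <- sprintf("(%s)%d",
                      paste(qlab, collapse = ","), key_support)
    core <- sprintf("(%s,%s)%d", qclade, sister, bg(1L))
  }
  rest_lab <- group_leaf_labels(target, n_per_group, tree_index + 100000L)
  target_clade <- sprintf("(%s,%s)%d", core,
                          clade_newick(rest_lab, bg(n_per_group - 1L)),
                          bg(1L))
  others <- setdiff(taxmap$groups, target)
  if (origin == "hgt") others <- setdiff(others, taxmap$recipient)
  other_clades <- vapply(others, function(g) {
    lab <- group_leaf_labels(g, n_per_group, tree_index)
    clade_newick(lab, bg(n_per_group - 1L))
  }, "")
  # caterpillar over group clades; prokaryote groups placed last so they
  # end up basal and usable as outgroups
  prok <- prokaryote_groups(taxmap)
  ord <- c(setdiff(others, prok), intersect(others, prok))
  sub <- target_clade
  for (g in setdiff(ord, prok))
    sub <- sprintf("(%s,%s)%d", sub, other_clades[g], bg(1L))
  prok_here <- intersect(ord, prok)
  if (length(prok_here)) {
    out <- other_clades[prok_here[1L]]
    if (length(prok_here) > 1L)
      for (g in prok_here[-1L])
        out <- sprintf("(%s,%s)%d", out, other_clades[g], bg(1L))
    newick <- sprintf("(%s,%s);", sub, out)
  } else {
    newick <- sprintf("%s;", sub)
  }
  truth <- data.frame(tree_id = sprintf("tree%d", tree_index),
                      origin = origin, donor_group = donor,
                      n_query = as.integer(n_query),
                      key_support = key_support,
                      stringsAsFactors = FALSE)
  list(newick = newick, truth = truth)
}

#' Simulate a batch of gene trees with planted vertical/HGT origins
#'
#' Plants `hgt_fraction` of the trees as transfers from donors sampled
#' uniformly among non-recipient groups, the rest as vertical descent.
#'
#' @param config A [sim_config()]; `n_genes` trees are produced.
#' @param n_query Query leaves per tree (recycled), default 1.
#' @return List: `newicks` (character vector), `truth` (data frame).
#' @export
simulate_gene_trees <- function(config, n_query = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L)
    return(list(newicks = character(),
                truth = data.frame(tree_id = character(), origin = character(),
                                   donor_group = character(),
                                   n_query = integer(),
                                   key_support = integer(),
                                   stringsAsFactors = FALSE)))
  set.seed(config$seed)
  is_hgt <- seq_len(n) <= round(n * config$hgt_fraction)
  donors_pool <- setdiff(config$taxmap$groups, config$taxmap$recipient)
  donors <- sample(donors_pool, n, replace = TRUE)
  n_query <- rep_len(as.integer(n_query), n)
  res <- lapply(seq_len(n), function(i) {
    simulate_gene_tree(config,
                       origin = if (is_hgt[i]) "hgt" else "vertical",
                       donor = if (is_hgt[i]) donors[i] else NULL,
                       n_query = n_query[i], tree_index = i)
  })
  list(newicks = vapply(res, `[[`, "", "newick"),
       truth = do.call(rbind, lapply(res, `[[`, "truth")))
}

rlogunif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate taxonomy-partitioned hit tables with planted patterns
#'
#' Emits a 13-column tabular hit table (BLAST outfmt-6 dialect plus
#' `subject_group`) whose per-group best e-values realize a planted
#' hit-pattern class per query: `none` (no rows; the query is novel),
#' `excavateOnly` (hits only in the recipient group), `uniHit` (exactly
#' one non-recipient group) or `multiHit` (several). multiHit queries draw
#' 2 or more eukaryote groups with hits below the tree-tier cut-off, so
#' some but not all satisfy the phylogenetic candidate rule; the truth
#' table records which.
#'
#' @param config A [sim_config()].
#' @param class_mixture Named non-negative proportions over
#'   `none`, `excavateOnly`, `uniHit`, `multiHit`; must sum to 1.
#' @return List: `hits` (data frame in [load_hit_table()] layout),
#'   `truth` (`query_id`, `class`, `hit_groups`, `is_novel`,
#'   `is_candidate`), `novelty` (`gene_id`, `is_novel`).
#' @export
simulate_hit_profiles <- function(config,
                                  class_mixture = c(none = 0.25,
                                                    excavateOnly = 0.25,
                                                    uniHit = 0.25,
                                                    multiHit = 0.25)) {
  stopifnot(inherits(config, "sim_config"))
  cls <- c("none", "excavateOnly", "uniHit", "multiHit")
  if (!all(cls %in% names(class_mixture)))
    stop("class_mixture must name ", paste(cls, collapse = ", "))
  class_mixture <- class_mixture[cls]
  if (any(class_mixture < 0)) stop("class proportions must be non-negative")
  if (abs(sum(class_mixture) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  taxmap <- config$taxmap
  n <- config$n_genes
  set.seed(config$seed + 1L)
  qid <- sprintf("gene%05d", seq_len(n))
  classes <- if (n) sample(cls, n, replace = TRUE, prob = class_mixture)
             else character()
  nonrec <- setdiff(taxmap$groups, taxmap$recipient)
  euk_nonrec <- nonrec[taxmap$eukaryote[nonrec]]
  rows <- vector("list", n)
  hit_groups <- character(n)
  is_candidate <- logical(n)
  log_screen <- log10(config$e_screen)   # -10
  log_tree <- log10(config$e_tree)       # -35
  strong_e <- function(k) 10^stats::runif(k, log_tree - 25, log_tree - 1)
  weak_e <- function(k) 10^stats::runif(k, log_tree + 1, log_screen - 1)
  mkrows <- function(q, groups, evalues) {
    k <- length(groups)
    if (k == 0L) return(NULL)
    len <- sample(100:600, k, replace = TRUE)
    data.frame(query_id = q,
               subject_id = sprintf("%s_subj%d", groups,
                                    sample(1:9999, k, replace = TRUE)),
               subject_group = groups,
               evalue = evalues,
               bitscore = round(pmax(50, 80 - 2 * log10(evalues + 1e-300)) +
                                  stats::runif(k, 0, 5), 1),
               pident = round(stats::runif(k, 30, 95), 1),
               length = len, mismatch = sample(0:50, k, replace = TRUE),
               gapopen = sample(0:5, k, replace = TRUE),
               qstart = 1L, qend = len, sstart = 1L, send = len,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "none") { hit_groups[i] <- ""; next }
    if (cl == "excavateOnly") {
      rows[[i]] <- mkrows(qid[i], taxmap$recipient, weak_e(1L))
      hit_groups[i] <- ""
      next
    }
    if (cl == "uniHit") {
      g <- sample(nonrec, 1L)
      gs <- g
      ev <- weak_e(1L)
      if (stats::runif(1) < 0.5) {   # recipient hit allowed, but weaker
        gs <- c(g, taxmap$recipient)
        ev <- c(ev, min(ev) * 10)
      }
      rows[[i]] <- mkrows(qid[i], gs, ev)
      hit_groups[i] <- g
      next
    }
    # multiHit: k_strong eukaryote groups below e_tree, plus optional weak
    k_strong <- sample(2:min(5L, length(euk_nonrec)), 1L)
    gs <- sample(euk_nonrec, k_strong)
    ev <- strong_e(k_strong)
    if (stats::runif(1) < 0.5 && "Bacteria" %in% nonrec) {
      gs <- c(gs, "Bacteria"); ev <- c(ev, strong_e(1L))
    }
    if (stats::runif(1) < 0.3) {
      extra <- setdiff(nonrec, gs)
      if (length(extra)) { gs <- c(gs, sample(extra, 1L)); ev <- c(ev, weak_e(1L)) }
    }
    rows[[i]] <- mkrows(qid[i], gs, ev)
    hit_groups[i] <- paste(sort(gs), collapse = ",")
    is_candidate[i] <- k_strong >= 3L
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(hits))
    hits <- data.frame(query_id = character(), subject_id = character(),
                       pident = numeric(), length = integer(),
                       mismatch = integer(), gapopen = integer(),
                       qstart = integer(), qend = integer(),
                       sstart = integer(), send = integer(),
                       evalue = numeric(), bitscore = numeric(),
                       subject_group = character(),
                       stringsAsFactors = FALSE)
  # positional outfmt-6 layout with the taxon group as 13th column
  hits <- hits[, c("query_id", "subject_id", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                   "bitscore", "subject_group")]
  rownames(hits) <- NULL
  truth <- data.frame(query_id = qid, class = classes,
                      hit_groups = hit_groups,
                      is_novel = classes == "none",
                      is_candidate = is_candidate,
                      stringsAsFactors = FALSE)
  list(hits = hits, truth = truth,
       novelty = data.frame(gene_id = qid, is_novel = truth$is_novel,
                            stringsAsFactors = FALSE))
}

#' Simulate a three-stage count matrix with planted stage effects
#'
#' Counts are negative binomial (Gamma-Poisson; shared dispersion) with
#' mean `baseline_rpkm * 2^effect * len_bp * library_size / 1e9` per stage:
#' growth carries the baseline, aggregation applies the planted
#' growth-to-aggregation effect, germination additionally applies the
#' aggregation-to-germination effect. Planted classes set the effect signs:
#' `aggup` (+e, 0), `aggdn` (-e, 0), `germup` (0, +e), `germdn` (0, -e),
#' `aggspec` (+e, -e), `null` (0, 0), with magnitudes drawn from the
#' configured effect range.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (data frame `gene_id`, `len_bp`, `gro`, `agg`,
#'   `germ`), `truth` (`gene_id`, `class`, `effect_agg`, `effect_germ`,
#'   `baseline_rpkm`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L)
    return(list(counts = data.frame(gene_id = character(), len_bp = integer(),
                                    gro = integer(), agg = integer(),
                                    germ = integer(), stringsAsFactors = FALSE),
                truth = data.frame(gene_id = character(), class = character(),
                                   effect_agg = numeric(),
                                   effect_germ = numeric(),
                                   baseline_rpkm = numeric(),
                                   stringsAsFactors = FALSE)))
  set.seed(config$seed + 2L)
  gid <- sprintf("gene%05d", seq_len(n))
  len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                n, replace = TRUE)
  base <- rlogunif(n, config$baseline_rpkm_range[1],
                   config$baseline_rpkm_range[2])
  cls <- sample(names(config$stage_class_probs), n, replace = TRUE,
                prob = config$stage_class_probs)
  e1 <- stats::runif(n, config$effect_range[1], config$effect_range[2])
  e2 <- stats::runif(n, config$effect_range[1], config$effect_range[2])
  eff_agg <- ifelse(cls == "aggup", e1, ifelse(cls == "aggdn", -e1,
                    ifelse(cls == "aggspec", e1, 0)))
  eff_germ <- ifelse(cls == "germup", e2, ifelse(cls == "germdn", -e2,
                     ifelse(cls == "aggspec", -e2, 0)))
  N <- config$library_sizes
  mu_gro <- base * len * N[["gro"]] / 1e9
  mu_agg <- base * 2^eff_agg * len * N[["agg"]] / 1e9
  mu_germ <- base * 2^(eff_agg + eff_germ) * len * N[["germ"]] / 1e9
  draw <- function(mu) {
    if (config$nb_dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  counts <- data.frame(gene_id = gid, len_bp = len,
                       gro = draw(mu_gro), agg = draw(mu_agg),
                       germ = draw(mu_germ), stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gid, class = cls, effect_agg = eff_agg,
                      effect_germ = eff_germ, baseline_rpkm = base,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Synthetic orthology-group table realizing set marginals
#'
#' Builds an OG membership table (gene, OG id, taxon) in which a declared
#' number of the focal set's genes belong to OGs, spread over a declared
#' number of OGs, with per-taxon sharing and uniqueness counts realized
#' exactly. Useful both as a generator of fixtures with controllable
#' uniqueness fractions and for reconstructing published set summaries
#' from their printed marginals.
#'
#' @param genes Character vector, the focal gene set.
#' @param n_in_ogs How many of `genes` belong to OGs (<= length(genes)).
#' @param n_ogs Number of distinct OGs those members occupy
#'   (<= n_in_ogs).
#' @param shared Named integer vector: number of OGs also containing each
#'   partner taxon (one partner per OG); `sum(shared) <= n_ogs`, the
#'   remainder are unique to the focal taxon.
#' @param focal_taxon Taxon label for the focal genes, default `"Ako"`.
#' @param og_prefix OG id prefix, default `"OG"`.
#' @param seed Optional seed for the member-to-OG allocation.
#' @return Data frame `gene_id`, `og_id`, `taxon`.
#' @export
simulate_og_table <- function(genes, n_in_ogs, n_ogs,
                              shared = c(Ngr = 0L, Disc = 0L),
                              focal_taxon = "Ako", og_prefix = "OG",
                              seed = NULL) {
  genes <- as.character(genes)
  if (n_in_ogs > length(genes)) stop("n_in_ogs exceeds the set size")
  if (n_ogs > n_in_ogs) stop("more OGs than member genes")
  if (sum(shared) > n_ogs) stop("shared OG counts exceed n_ogs")
  if (!is.null(seed)) set.seed(seed)
  if (n_ogs == 0L)
    return(data.frame(gene_id = character(), og_id = character(),
                      taxon = character(), stringsAsFactors = FALSE))
  members <- genes[seq_len(n_in_ogs)]
  ogs <- sprintf("%s%05d", og_prefix, seq_len(n_ogs))
  # every OG gets one member; extras spread round-robin
  og_of <- c(ogs, rep(ogs, length.out = n_in_ogs - n_ogs))
  out <- data.frame(gene_id = members, og_id = og_of, taxon = focal_taxon,
                    stringsAsFactors = FALSE)
  k <- 0L
  for (tx in names(shared)) {
    ns <- shared[[tx]]
    if (ns == 0L) next
    og_share <- ogs[(k + 1L):(k + ns)]
    out <- rbind(out,
                 data.frame(gene_id = sprintf("%s_g%05d", tx, seq_len(ns)),
                            og_id = og_share, taxon = tx,
                            stringsAsFactors = FALSE))
    k <- k + ns
  }
  rownames(out) <- NULL
  out
}

#' Synthetic annotation table with controllable novelty
#'
#' @param genes Character vector of gene ids.
#' @param n_novel Exact number of genes flagged novel (no database hit
#'   anywhere); the first `n_novel` unless `shuffle = TRUE`.
#' @param categories Functional-category vocabulary to draw from.
#' @param category_probs Optional sampling weights over `categories`.
#' @param shuffle Randomize which genes are novel (uses current RNG state).
#' @return Data frame `gene_id`, `category`, `is_novel`, `tm_count`,
#'   `has_sp`.
#' @export
simulate_annotations <- function(genes, n_novel = 0L,
                                 categories = c("signaling", "translation",
                                                "protein_fold_sort_degrade",
                                                "DNA_RR", "CHO_chemistry",
                                                "lipid_chemistry",
                                                "cell_cycle", "cytoskeleton",
                                                "extracell_secrete",
                                                "other"),
                                 category_probs = NULL, shuffle = FALSE) {
  genes <- as.character(genes)
  n <- length(genes)
  if (n_novel > n) stop("n_novel exceeds the set size")
  novel <- rep(FALSE, n)
  novel[seq_len(n_novel)] <- TRUE
  if (shuffle) novel <- sample(novel)
  data.frame(gene_id = genes,
             category = if (n) sample(categories, n, replace = TRUE,
                                      prob = category_probs)
                        else character(),
             is_novel = novel,
             tm_count = if (n) stats::rpois(n, 0.5) else integer(),
             has_sp = if (n) stats::runif(n) < 0.15 else logical(),
             stringsAsFactors = FALSE)
}
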