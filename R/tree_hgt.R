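#' Parse a support-annotated gene tree
#'
#' Reads a Newick gene tree in the common ML dialect where internal node
#' labels carry branch supports on a 0-100 scale (e.g. ultrafast bootstrap
#' percentages). Leaf labels are decomposed with a configurable scheme,
#' by default `GROUP|SPECIES|ID` split on `|`; leaves whose species field
#' equals `query_species` are flagged as query (recipient-proteome) leaves.
#' Supports given as fractions in [0, 1] are rescaled to 0-100 with a
#' warning.
#'
#' @param newick Newick text (single tree) or a `phylo` object.
#' @param query_species Species field value identifying query leaves,
#'   default `"query"`.
#' @param sep Field separator in leaf labels, default `"|"`.
#' @return An object of class `gene_tree`: list with `phy` (ape `phylo`),
#'   `leaves` (data frame `label`, `group`, `species`, `id`, `is_query`)
#'   and `supports` (numeric per internal node, `NA` where absent).
#' @export
parse_gene_tree <- function(newick, query_species = "query", sep = "|") {
  phy <- if (inherits(newick, "phylo")) newick else {
    out <- tryCatch(ape::read.tree(text = newick),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out)) stop("unparseable Newick text")
    out
  }
  if (is.null(phy) || ape::Ntip(phy) < 3L)
    stop("gene tree must have at least 3 leaves")
  parts <- strsplit(phy$tip.label, sep, fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 1L)) stop("empty leaf label")
  group <- vapply(parts, `[`, "", 1L)
  species <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  id <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else p[length(p)], "")
  if (any(!nzchar(group)))
    stop("leaf without a taxon group: ",
         phy$tip.label[which(!nzchar(group))[1L]])
  supports <- parse_supports(phy)
  structure(list(phy = phy,
                 leaves = data.frame(label = phy$tip.label, group = group,
                                     species = species, id = id,
                                     is_query = !is.na(species) &
                                       species == query_species,
                                     stringsAsFactors = FALSE),
                 supports = supports),
            class = "gene_tree")
}

parse_supports <- function(phy) {
  lab <- phy$node.label
  if (is.null(lab)) return(rep(NA_real_, phy$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  ok <- !is.na(sup)
  if (any(ok) && all(sup[ok] >= 0) && all(sup[ok] <= 1) && any(sup[ok] > 0)) {
    warning("branch supports look like fractions in [0,1]; rescaling to 0-100")
    sup <- sup * 100
  }
  if (any(ok & (sup < 0 | sup > 100)))
    stop("branch support outside [0, 100]")
  sup
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", ape::Ntip(x$phy), "leaves,",
      sum(x$leaves$is_query), "query leaf/leaves,",
      length(unique(x$leaves$group)), "taxon groups\n")
  invisible(x)
}

# tip-index sets descending from each node (1..Ntip tips, then internals)
node_tip_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in ape::postorder(phy)) {         # child edges before parent edges
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Test monophyly of a leaf set
#'
#' A leaf set is monophyletic when some branch (bipartition) of the tree
#' separates exactly that set from all remaining leaves; this bipartition
#' semantics is rooting-independent. Singleton sets are monophyletic by
#' convention. When the separating branch carries a support annotation it is
#' returned alongside the verdict.
#'
#' @param gtree A `gene_tree` (or ape `phylo`).
#' @param leaves Character vector of leaf labels (non-empty subset).
#' @return List `monophyletic` (logical) and `support` (numeric or `NA`).
#' @export
is_monophyletic_set <- function(gtree, leaves) {
  phy <- if (inherits(gtree, "gene_tree")) gtree$phy else gtree
  sup <- if (inherits(gtree, "gene_tree")) gtree$supports
         else rep(NA_real_, phy$Nnode)
  leaves <- unique(as.character(leaves))
  if (length(leaves) == 0L) stop("empty leaf set")
  idx <- match(leaves, phy$tip.label)
  if (anyNA(idx)) stop("unknown leaf id: ", leaves[which(is.na(idx))[1L]])
  ntip <- ape::Ntip(phy)
  if (length(idx) == 1L)
    return(list(monophyletic = TRUE, support = NA_real_))
  if (length(idx) == ntip)
    return(list(monophyletic = TRUE, support = NA_real_))
  target <- sort(idx)
  sets <- node_tip_sets(phy)
  root <- ntip + 1L
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    s <- sets[[nd]]
    if (length(s) == length(target) && all(sort(s) == target))
      return(list(monophyletic = TRUE, support = sup[nd - ntip]))
  }
  # unrooted bipartition: the complement side of a branch also forms a clade
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    if (nd == root) next
    s <- sets[[nd]]
    if (length(s) == ntip - length(target) && !any(s %in% target))
      return(list(monophyletic = TRUE, support = sup[nd - ntip]))
  }
  list(monophyletic = FALSE, support = NA_real_)
}

prokaryote_groups <- function(taxmap) taxmap$groups[!taxmap$eukaryote]

#' Root a gene tree for sister-clade orientation
#'
#' Rooting strategy chain: `"outgroup"` roots on the prokaryote
#' (non-eukaryote-group) leaves when they form a bipartition clade disjoint
#' from the query leaves; failing that, on a single prokaryote group's
#' clade (largest, ties broken lexicographically); failing that the chain
#' falls through to `"midpoint"` (requires branch lengths) and finally to a
#' deterministic `"farthest-leaf"` rooting on the non-query leaf
#' topologically farthest from the query MRCA (lexicographic tie-break).
#' The strategy actually used is recorded in the result. Monophyly verdicts
#' use bipartition semantics and are unaffected by rooting; only sister
#' orientation depends on it.
#'
#' @param gtree A `gene_tree`.
#' @param taxmap A [taxon_group_map()] (used to find prokaryote outgroups).
#' @param strategy `"outgroup"` (default, with fallbacks), `"midpoint"`, or
#'   `"farthest-leaf"`.
#' @return A `gene_tree` with rooted `phy`; attribute `rooting` records the
#'   strategy used.
#' @export
root_gene_tree <- function(gtree, taxmap = taxon_group_map(),
                           strategy = c("outgroup", "midpoint",
                                        "farthest-leaf")) {
  stopifnot(inherits(gtree, "gene_tree"))
  strategy <- match.arg(strategy)
  phy <- gtree$phy
  qlab <- gtree$leaves$label[gtree$leaves$is_query]
  used <- NULL
  rooted <- NULL
  try_outgroup <- function(out_labels) {
    if (length(out_labels) == 0L || length(out_labels) >= ape::Ntip(phy) ||
        any(out_labels %in% qlab))
      return(NULL)
    mono <- is_monophyletic_set(gtree, out_labels)
    if (!mono$monophyletic) return(NULL)
    tryCatch(ape::root(phy, outgroup = out_labels, resolve.root = TRUE,
                       edgelabel = TRUE),
             error = function(e) NULL)
  }
  if (strategy == "outgroup") {
    prok <- prokaryote_groups(taxmap)
    all_prok <- gtree$leaves$label[gtree$leaves$group %in% prok]
    rooted <- try_outgroup(all_prok)
    if (!is.null(rooted)) used <- "outgroup"
    if (is.null(rooted)) {
      # per-group attempts, largest clade first then lexicographic
      sizes <- vapply(prok, function(g)
        sum(gtree$leaves$group == g), 0L)
      for (g in prok[order(-sizes, prok)]) {
        rooted <- try_outgroup(gtree$leaves$label[gtree$leaves$group == g])
        if (!is.null(rooted)) { used <- paste0("outgroup:", g); break }
      }
    }
  }
  if (is.null(rooted) && strategy %in% c("outgroup", "midpoint")) {
    if (!is.null(phy$edge.length)) {
      rooted <- tryCatch(phangorn::midpoint(phy, node.labels = "support"),
                         error = function(e) NULL)
      if (!is.null(rooted)) used <- "midpoint"
    } else if (strategy == "midpoint") {
      warning("midpoint rooting requires branch lengths; falling back")
    }
  }
  if (is.null(rooted)) {
    rooted <- farthest_leaf_root(phy, qlab)
    used <- "farthest-leaf"
  }
  out <- gtree
  out$phy <- rooted
  out$supports <- parse_supports(rooted)
  attr(out, "rooting") <- used
  out
}

# topological distances from every tip to the query MRCA; root on the
# farthest non-query tip (lexicographic tie-break)
farthest_leaf_root <- function(phy, qlab) {
  ntip <- ape::Ntip(phy)
  qidx <- match(qlab, phy$tip.label)
  non_query <- setdiff(seq_len(ntip), qidx)
  if (length(non_query) == 0L) stop("tree has only query leaves")
  if (length(qidx) == 0L) {
    pick <- non_query[order(phy$tip.label[non_query])][1L]
  } else {
    anc <- if (length(qidx) == 1L) qidx else ape::getMRCA(phy, qidx)
    dd <- ape::dist.nodes(unit_lengths(phy))[anc, non_query]
    pick <- non_query[order(-dd, phy$tip.label[non_query])][1L]
  }
  ape::root(phy, outgroup = phy$tip.label[pick], resolve.root = TRUE,
            edgelabel = TRUE)
}

unit_lengths <- function(phy) { phy$edge.length <- rep(1, nrow(phy$edge)); phy }

#' Find the sister lineage of the query leaves
#'
#' In a rooted gene tree, the smallest clade containing all query leaves is
#' located; its sibling subtree(s) form the sister set (at a polytomy all
#' sibling subtrees are returned jointly). The key support is the one on
#' the branch subtending the smallest query-containing clade; for a single
#' query leaf that branch is terminal and never annotated, so the support
#' on the branch subtending the query+sister ancestor is used instead.
#'
#' @param gtree A `gene_tree`, rooted (e.g. by [root_gene_tree()]); unrooted
#'   input is rooted on the fly with the default strategy chain.
#' @param taxmap A [taxon_group_map()], used only if rooting is needed.
#' @return List: `status` (`"ok"` or `"unresolved"`), `sister` (leaf
#'   labels), `sister_groups` (their taxon groups), `support` (numeric or
#'   `NA`), `query` (query leaf labels).
#' @export
find_sister <- function(gtree, taxmap = taxon_group_map()) {
  stopifnot(inherits(gtree, "gene_tree"))
  if (!ape::is.rooted(gtree$phy)) gtree <- root_gene_tree(gtree, taxmap)
  phy <- gtree$phy
  sup <- gtree$supports
  ntip <- ape::Ntip(phy)
  qidx <- which(gtree$leaves$is_query)
  if (length(qidx) == 0L) stop("tree has no query leaves")
  unresolved <- list(status = "unresolved", sister = character(),
                     sister_groups = character(), support = NA_real_,
                     query = gtree$leaves$label[qidx])
  mrca <- if (length(qidx) == 1L) qidx else ape::getMRCA(phy, qidx)
  root <- ntip + 1L
  if (mrca == root) return(unresolved)     # smallest containing clade = tree
  parent <- phy$edge[match(mrca, phy$edge[, 2L]), 1L]
  sets <- node_tip_sets(phy)
  sibs <- setdiff(phy$edge[phy$edge[, 1L] == parent, 2L], mrca)
  sister_idx <- sort(unlist(sets[sibs]))
  support <- if (mrca > ntip) sup[mrca - ntip]
             else if (parent > ntip) sup[parent - ntip] else NA_real_
  list(status = "ok",
       sister = phy$tip.label[sister_idx],
       sister_groups = gtree$leaves$group[sister_idx],
       support = support,
       query = gtree$leaves$label[qidx])
}

#' Call horizontal transfer from a gene tree
#'
#' Combines sister identification, donor-group assignment and a support
#' threshold into a per-tree HGT verdict. The donor is the taxon group
#' holding a strict majority (>50%) of the sister leaves; an all-one-group
#' sister is flagged `donor_uniform`. The call is `supported` when a donor
#' exists, it differs from the recipient group, and the key branch support
#' is at least `support_min` (default 60, the conventional ultrafast
#' bootstrap threshold); `unsupported` when the support is below threshold
#' or absent (a polytomy cannot certify the grouping) or the sister is
#' recipient-dominated; `unresolved` when no sister exists or no group
#' holds a majority. Family topology of the query leaves (singleton / mono
#' / mixed) is reported alongside.
#'
#' @param gtree A `gene_tree`.
#' @param taxmap A [taxon_group_map()].
#' @param support_min Integer in [0, 100], default 60.
#' @return One-row data frame: `status`, `key_support`, `donor_group`,
#'   `donor_uniform`, `family_topology`, `n_query`, `rooting`.
#' @export
call_hgt <- function(gtree, taxmap = taxon_group_map(), support_min = 60) {
  stopifnot(inherits(gtree, "gene_tree"),
            support_min >= 0, support_min <= 100)
  if (!ape::is.rooted(gtree$phy)) gtree <- root_gene_tree(gtree, taxmap)
  fam <- classify_family(gtree)
  sis <- find_sister(gtree, taxmap)
  res <- data.frame(status = "unresolved", key_support = NA_real_,
                    donor_group = NA_character_, donor_uniform = NA,
                    family_topology = fam, n_query = length(sis$query),
                    rooting = attr(gtree, "rooting") %||% "as-given",
                    stringsAsFactors = FALSE)
  if (sis$status == "unresolved") return(res)
  tab <- table(sis$sister_groups)
  maj <- names(tab)[which.max(tab)]
  res$key_support <- sis$support
  if (max(tab) * 2L <= length(sis$sister_groups)) {
    # no strict majority: refuse to invent a donor
    return(res)
  }
  res$donor_group <- maj
  res$donor_uniform <- length(tab) == 1L
  if (maj == taxmap$recipient) {
    res$status <- "unsupported"      # vertical signal: sister is recipient
  } else if (!is.na(sis$support) && sis$support >= support_min) {
    res$status <- "supported"
  } else {
    res$status <- "unsupported"      # below threshold or support absent
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify the query family topology
#'
#' `singleton` for a single query leaf, `mono` when the query leaves are
#' monophyletic (bipartition semantics, so the verdict is
#' rooting-independent), `mixed` otherwise. A monophyletic family indicates
#' a single transfer followed by duplication; a mixed family indicates
#' multiple independent transfers or a blend of horizontal and vertical
#' transmission.
#'
#' @param gtree A `gene_tree` with its query leaves flagged.
#' @return `"singleton"`, `"mono"` or `"mixed"`.
#' @export
classify_family <- function(gtree) {
  stopifnot(inherits(gtree, "gene_tree"))
  qlab <- gtree$leaves$label[gtree$leaves$is_query]
  if (length(qlab) == 0L) stop("tree has no query leaves")
  if (length(qlab) == 1L) return("singleton")
  if (is_monophyletic_set(gtree, qlab)$monophyletic) "mono" else "mixed"
}

#' Call HGT over a batch of gene trees
#'
#' @param newicks Character vector of Newick strings (one tree each).
#' @param taxmap A [taxon_group_map()].
#' @param support_min Support threshold, default 60.
#' @param query_species Species field marking query leaves.
#' @param ids Optional tree/gene ids for the output rows.
#' @return Data frame, one row per tree, as [call_hgt()] plus `tree_id`.
#' @export
call_hgt_batch <- function(newicks, taxmap = taxon_group_map(),
                           support_min = 60, query_species = "query",
                           ids = NULL) {
  if (is.null(ids)) ids <- paste0("tree", seq_along(newicks))
  rows <- lapply(seq_along(newicks), function(i) {
    gt <- parse_gene_tree(newicks[i], query_species = query_species)
    cbind(tree_id = ids[i],
          call_hgt(gt, taxmap, support_min = support_min))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Donor-taxonomy summary of supported HGT calls
#'
#' Tabulates supported calls by donor group, split by family topology
#' (the single-transfer vs multiple-transfer panels of a donor profile).
#'
#' @param calls Data frame from [call_hgt_batch()].
#' @return Data frame `donor_group`, `family_topology`, `n`.
#' @export
summarize_donors <- function(calls) {
  sup <- calls[calls$status == "supported", , drop = FALSE]
  if (!nrow(sup))
    return(data.frame(donor_group = character(),
                      family_topology = character(), n = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = sup$status),
                          by = list(donor_group = sup$donor_group,
                                    family_topology = sup$family_topology),
                          FUN = length)
  agg[order(-agg$n, agg$donor_group), c("donor_group", "family_topology", "n")]
}
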