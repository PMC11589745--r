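# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# --- tree oracles (bitmask bipartition enumeration, <= 31 leaves) ---------

# all non-trivial bipartitions of a phylo as tip-index bitmasks
oracle_bipartitions <- function(phy) {
  ntip <- ape::Ntip(phy)
  pp <- ape::prop.part(phy)           # clades of the (arbitrarily) rooted tree
  masks <- vapply(pp, function(tips) sum(bitwShiftL(1L, tips - 1L)), 0)
  unique(masks)
}

oracle_mask <- function(tips_idx) sum(bitwShiftL(1L, tips_idx - 1L))

# bipartition-semantics monophyly: the set or its complement is a clade side
oracle_monophyletic <- function(phy, tips_idx) {
  ntip <- ape::Ntip(phy)
  if (length(tips_idx) <= 1L || length(tips_idx) == ntip) return(TRUE)
  full <- oracle_mask(seq_len(ntip))
  m <- oracle_mask(tips_idx)
  bips <- oracle_bipartitions(phy)
  any(bips == m | bips == bitwXor(full, m))
}

# rooted smallest-superset-clade sister search: enumerate every clade
# (internal node tip sets plus single tips), take the minimal one containing
# all queries, then the minimal proper superset; sister = set difference
oracle_sister <- function(phy, query_idx) {
  ntip <- ape::Ntip(phy)
  pp <- ape::prop.part(phy)
  clades <- c(as.list(seq_len(ntip)), lapply(pp, as.integer))
  contains <- vapply(clades, function(cl) all(query_idx %in% cl), TRUE)
  sizes <- lengths(clades)
  cand <- which(contains)
  minimal <- cand[which.min(sizes[cand])]
  if (sizes[minimal] == ntip) return(NULL)          # unresolved
  base <- clades[[minimal]]
  sup <- which(contains & sizes > sizes[minimal])
  sup <- sup[vapply(sup, function(i) all(base %in% clades[[i]]), TRUE)]
  parent <- sup[which.min(sizes[sup])]
  sort(setdiff(clades[[parent]], base))
}

# --- screening oracle (naive per-query re-scan of the raw table) ----------

oracle_pattern <- function(hits, qid, taxmap) {
  h <- hits[hits$query_id == qid, , drop = FALSE]
  gs <- unique(h$subject_group)
  nonrec <- setdiff(gs, taxmap$recipient)
  if (length(gs) == 0L) "noHit"
  else if (length(nonrec) == 0L) "recipientOnly"
  else if (length(nonrec) == 1L) "uniHit"
  else "multiHit"
}

oracle_candidate <- function(hits, qid, taxmap, is_novel,
                             e_tree = 1e-35, min_euk = 3L) {
  if (is_novel) return(FALSE)
  h <- hits[hits$query_id == qid, , drop = FALSE]
  if (nrow(h) == 0L) return(FALSE)
  nonrec <- h[h$subject_group != taxmap$recipient, , drop = FALSE]
  if (nrow(nonrec) == 0L) return(FALSE)
  euk_groups <- unique(h$subject_group[h$evalue < e_tree &
                                         taxmap$eukaryote[h$subject_group]])
  length(euk_groups) >= min_euk
}

# --- posterior fold-change oracle (Monte-Carlo) ---------------------------

oracle_log2fc <- function(c1, c2, n1, n2, credibility = 0.99, nsim = 2e5) {
  r1 <- stats::rgamma(nsim, c1 + 0.5, rate = n1)
  r2 <- stats::rgamma(nsim, c2 + 0.5, rate = n2)
  lr <- log2(r2 / r1)
  p <- (1 - credibility) / 2
  q <- unname(stats::quantile(lr, c(p, 1 - p)))
  if (q[1] <= 0 && q[2] >= 0) 0 else if (q[1] > 0) q[1] else q[2]
}

# random leaf-labeled tree in the package's label scheme
random_gene_tree_newick <- function(n, n_query = 1L, seed = NULL,
                                    groups = c("A", "B", "C")) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n)
  g <- sample(groups, n, replace = TRUE)
  lab <- sprintf("%s|sp%d|t%d", g, seq_len(n), seq_len(n))
  qi <- sample.int(n, n_query)
  lab[qi] <- sprintf("%s|query|q%d", g[qi], seq_along(qi))
  phy$tip.label <- lab
  ape::write.tree(phy)
}
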