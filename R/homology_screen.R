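#' Taxon group map for taxonomy-partitioned homology screening
#'
#' Declares the major taxon groups against which a proteome was searched,
#' which of them is the recipient lineage (the query's own major group; hits
#' there never count as transfer evidence), and which groups are eukaryotic.
#' The defaults mirror a typical partition used for excavate amoebae:
#' per-group databases for Metazoa, Fungi, Viridiplantae, Bacteria, Archaea,
#' Amoebozoa, Stramenopila, Rhizaria, Alveolata, Rhodophyta and Excavata,
#' with Excavata (Discoba + Metamonada) as the recipient.
#'
#' @param groups Character vector of unique group names.
#' @param recipient Single group name, the recipient lineage.
#' @param eukaryote Named logical vector (one entry per group) flagging
#'   eukaryotic groups, or `NULL` to flag everything except groups named
#'   `"Bacteria"`/`"Archaea"` as eukaryotic.
#' @return An object of class `taxon_group_map`.
#' @export
taxon_group_map <- function(groups = c("Metazoa", "Fungi", "Viridiplantae",
                                       "Bacteria", "Archaea", "Amoebozoa",
                                       "Stramenopila", "Rhizaria", "Alveolata",
                                       "Rhodophyta", "Excavata"),
                            recipient = "Excavata",
                            eukaryote = NULL) {
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("taxon group names must be unique")
  if (length(recipient) != 1L || !recipient %in% groups)
    stop("recipient group must be one of the declared groups")
  if (is.null(eukaryote)) {
    eukaryote <- !groups %in% c("Bacteria", "Archaea")
    names(eukaryote) <- groups
  } else {
    if (is.null(names(eukaryote)) || !all(groups %in% names(eukaryote)))
      stop("'eukaryote' must be a named logical covering every group")
    eukaryote <- as.logical(eukaryote[groups])
    names(eukaryote) <- groups
  }
  structure(list(groups = groups, recipient = recipient,
                 eukaryote = eukaryote),
            class = "taxon_group_map")
}

#' @export
print.taxon_group_map <- function(x, ...) {
  cat("Taxon group map:", length(x$groups), "groups; recipient =",
      x$recipient, "\n")
  cat("  eukaryote:", paste(x$groups[x$eukaryote], collapse = ", "), "\n")
  cat("  prokaryote:", paste(x$groups[!x$eukaryote], collapse = ", "), "\n")
  invisible(x)
}

.blast6_cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Load a tabular homology hit table
#'
#' Reads a BLAST-style 12-column tabular file (outfmt-6 dialect: qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore), optionally carrying a 13th `subject_group` column.
#' When the table has no group column, a subject-to-group map must be
#' supplied. Hits weaker than the screening cut-off are dropped on load.
#'
#' @param path Path to a TSV hit table (comment lines starting `#` ignored).
#' @param taxmap A [taxon_group_map()].
#' @param e_screen Per-database screening e-value cut-off; hits with
#'   `evalue > e_screen` are excluded. Default `1e-10`.
#' @param group_map Optional data frame with columns `subject_id`,
#'   `subject_group`, required when the table lacks a group column.
#' @return Data frame of hit records (`query_id`, `subject_id`,
#'   `subject_group`, `evalue`, `bitscore`, plus the remaining tabular
#'   columns).
#' @export
load_hit_table <- function(path, taxmap, e_screen = 1e-10, group_map = NULL) {
  stopifnot(inherits(taxmap, "taxon_group_map"))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(!nfield %in% c(12L, 13L))
  if (length(bad))
    stop(sprintf("malformed hit table row at line %d: expected 12 or 13 fields, got %d",
                 lineno[bad[1]], nfield[bad[1]]))
  if (length(unique(nfield)) > 1L)
    stop("hit table mixes 12- and 13-field rows")
  mat <- do.call(rbind, parts)
  hits <- data.frame(query_id = mat[, 1], subject_id = mat[, 2],
                     pident = as.numeric(mat[, 3]),
                     length = as.integer(mat[, 4]),
                     mismatch = as.integer(mat[, 5]),
                     gapopen = as.integer(mat[, 6]),
                     qstart = as.integer(mat[, 7]), qend = as.integer(mat[, 8]),
                     sstart = as.integer(mat[, 9]), send = as.integer(mat[, 10]),
                     evalue = as.numeric(mat[, 11]),
                     bitscore = as.numeric(mat[, 12]),
                     stringsAsFactors = FALSE)
  badnum <- which(is.na(hits$evalue) | is.na(hits$bitscore))
  if (length(badnum))
    stop(sprintf("malformed numeric field at line %d", lineno[badnum[1]]))
  if (ncol(mat) == 13L) {
    hits$subject_group <- mat[, 13]
  } else {
    if (is.null(group_map))
      stop("hit table has no subject_group column and no group_map was supplied")
    idx <- match(hits$subject_id, group_map$subject_id)
    if (anyNA(idx))
      stop("subjects missing from group_map: ",
           paste(utils::head(unique(hits$subject_id[is.na(idx)]), 5), collapse = ", "))
    hits$subject_group <- group_map$subject_group[idx]
  }
  unknown <- setdiff(unique(hits$subject_group), taxmap$groups)
  if (length(unknown))
    stop("unknown taxon group(s) in hit table: ", paste(unknown, collapse = ", "))
  if (any(hits$evalue < 0)) stop("negative e-value in hit table")
  hits <- hits[hits$evalue <= e_screen, , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "subject_id", "subject_group", "evalue", "bitscore",
           setdiff(names(hits), c("query_id", "subject_id", "subject_group",
                                  "evalue", "bitscore")))]
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_group = character(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

#' Build per-query taxonomic hit profiles
#'
#' Collapses a hit table to one row per query: the smallest e-value per taxon
#' group and the group of the globally best non-recipient hit. Ties on
#' e-value are broken by higher bitscore, then by lexicographic group name,
#' so profiles are deterministic. An e-value of exactly 0 sorts below any
#' positive e-value.
#'
#' @param hits Hit-record data frame as returned by [load_hit_table()]
#'   (minimally `query_id`, `subject_group`, `evalue`, `bitscore`).
#' @param taxmap A [taxon_group_map()].
#' @param query_ids Optional character vector of all query ids, so queries
#'   without any hit still get a (all-`NA`) profile row.
#' @return Data frame with one row per query: `query_id`, one
#'   `best_<group>` column per group (best e-value, `NA` if no hit),
#'   `top_hit_group` (`NA` if no non-recipient hit) and `n_hit_groups`.
#' @export
build_profiles <- function(hits, taxmap, query_ids = NULL) {
  stopifnot(inherits(taxmap, "taxon_group_map"))
  unknown <- setdiff(unique(hits$subject_group), taxmap$groups)
  if (length(unknown))
    stop("hits reference groups outside the taxon map: ",
         paste(unknown, collapse = ", "))
  qids <- unique(c(if (!is.null(query_ids)) as.character(query_ids),
                   hits$query_id))
  groups <- taxmap$groups
  best <- matrix(NA_real_, nrow = length(qids), ncol = length(groups),
                 dimnames = list(qids, groups))
  top <- rep(NA_character_, length(qids))
  if (nrow(hits)) {
    # deterministic best-hit order: evalue asc, bitscore desc, group asc
    ord <- order(hits$query_id, hits$evalue, -hits$bitscore,
                 hits$subject_group, method = "radix")
    h <- hits[ord, , drop = FALSE]
    ij <- cbind(match(h$query_id, qids), match(h$subject_group, groups))
    # first occurrence per (query, group) is the per-group best
    first <- !duplicated(ij)
    best[ij[first, , drop = FALSE]] <- h$evalue[first]
    # first non-recipient record per query is the top hit
    nr <- h$subject_group != taxmap$recipient
    hn <- h[nr, , drop = FALSE]
    firstq <- !duplicated(hn$query_id)
    top[match(hn$query_id[firstq], qids)] <- hn$subject_group[firstq]
  }
  out <- data.frame(query_id = qids, stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("best_", g)]] <- best[, g]
  out$top_hit_group <- top
  out$n_hit_groups <- rowSums(!is.na(best))
  rownames(out) <- NULL
  out
}

profile_best_matrix <- function(profiles, taxmap) {
  cols <- paste0("best_", taxmap$groups)
  miss <- setdiff(cols, names(profiles))
  if (length(miss)) stop("profile table lacks columns: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(profiles[, cols, drop = FALSE])
  colnames(m) <- taxmap$groups
  m
}

#' Classify a query's taxonomic hit pattern
#'
#' Assigns each profile one of four mutually exclusive, exhaustive labels:
#' `noHit` (no group with a hit), `recipientOnly` (hits only in the
#' recipient group), `uniHit` (exactly one non-recipient group with a hit)
#' or `multiHit` (two or more non-recipient groups). For `uniHit` and
#' `multiHit` the non-recipient hit groups are reported.
#'
#' @param profiles Profile table from [build_profiles()].
#' @param taxmap A [taxon_group_map()].
#' @return Data frame `query_id`, `pattern`, `hit_groups` (comma-joined
#'   non-recipient groups with hits, `""` if none),
#'   `n_nonrecipient_groups`.
#' @export
classify_pattern <- function(profiles, taxmap) {
  stopifnot(inherits(taxmap, "taxon_group_map"))
  m <- profile_best_matrix(profiles, taxmap)
  hitg <- !is.na(m)
  nonrec <- taxmap$groups != taxmap$recipient
  n_nonrec <- rowSums(hitg[, nonrec, drop = FALSE])
  any_rec <- hitg[, !nonrec, drop = FALSE]
  any_rec <- if (ncol(any_rec)) rowSums(any_rec) > 0 else rep(FALSE, nrow(m))
  pattern <- ifelse(n_nonrec >= 2, "multiHit",
                    ifelse(n_nonrec == 1, "uniHit",
                           ifelse(any_rec, "recipientOnly", "noHit")))
  nr_groups <- taxmap$groups[nonrec]
  hg <- apply(hitg[, nonrec, drop = FALSE], 1L,
              function(z) paste(nr_groups[z], collapse = ","))
  data.frame(query_id = profiles$query_id, pattern = pattern,
             hit_groups = hg, n_nonrecipient_groups = n_nonrec,
             stringsAsFactors = FALSE)
}

#' Select phylogenetic HGT candidates
#'
#' A query becomes a tree-building candidate when it is not novel (it has
#' database support somewhere), its globally best non-recipient hit exists,
#' and hits stronger than the tree-tier cut-off (`evalue < e_tree`) cover at
#' least `min_euk_groups` major eukaryote groups. Defaults follow the
#' two-tier screen used for excavate amoebae: `e_tree = 1e-35` on top of a
#' per-database screen at `1e-10`, with three or more eukaryote groups
#' required.
#'
#' @param profiles Profile table from [build_profiles()].
#' @param novelty Data frame with columns `gene_id` (or `query_id`) and
#'   logical `is_novel`; novelty is caller-supplied, the package never
#'   queries external databases.
#' @param taxmap A [taxon_group_map()].
#' @param e_tree Tree-tier e-value cut-off (strict `<`), default `1e-35`.
#' @param min_euk_groups Minimum number of eukaryote groups with a hit below
#'   `e_tree`, default 3.
#' @return Character vector of selected query ids (in profile order).
#' @export
select_phylo_candidates <- function(profiles, novelty, taxmap,
                                    e_tree = 1e-35, min_euk_groups = 3L) {
  stopifnot(inherits(taxmap, "taxon_group_map"), min_euk_groups >= 1)
  idcol <- if ("gene_id" %in% names(novelty)) "gene_id" else "query_id"
  idx <- match(profiles$query_id, novelty[[idcol]])
  if (anyNA(idx))
    stop("novelty flags missing for: ",
         paste(utils::head(profiles$query_id[is.na(idx)], 5), collapse = ", "))
  is_novel <- as.logical(novelty$is_novel[idx])
  m <- profile_best_matrix(profiles, taxmap)
  euk <- taxmap$eukaryote
  n_euk_strong <- rowSums(!is.na(m[, euk, drop = FALSE]) &
                            m[, euk, drop = FALSE] < e_tree)
  sel <- !is_novel & !is.na(profiles$top_hit_group) &
    n_euk_strong >= min_euk_groups
  profiles$query_id[sel]
}
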