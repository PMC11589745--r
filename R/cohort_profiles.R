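#' Round-half-up percentage
#'
#' Percentages are reported to one decimal with round-half-up (not the
#' IEEE banker's rounding of base `round()`), matching how comparative
#' tables conventionally print them.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimals, default 1.
#' @return Numeric percentage; `NA` when the denominator is 0.
#' @export
pct_round <- function(numerator, denominator, digits = 1L) {
  ifelse(denominator == 0, NA_real_,
         floor(100 * numerator / denominator * 10^digits + 0.5) / 10^digits)
}

#' Novelty fraction of a gene set
#'
#' Count and percentage of genes flagged novel (no database hit anywhere)
#' within a set.
#'
#' @param genes Character vector of gene ids.
#' @param annotations Data frame with `gene_id` and logical `is_novel`.
#' @return List: `n_total`, `n_novel`, `pct_novel` (`NA` for an empty set).
#' @export
novelty_fraction <- function(genes, annotations) {
  genes <- unique(as.character(genes))
  idx <- match(genes, annotations$gene_id)
  if (anyNA(idx))
    stop("annotations missing for: ",
         paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  n_novel <- sum(annotations$is_novel[idx])
  list(n_total = length(genes), n_novel = n_novel,
       pct_novel = pct_round(n_novel, length(genes)))
}

#' Orthology-group summary of a gene set
#'
#' From an OG membership table (`gene_id`, `og_id`, `taxon`), computes for
#' a focal gene set: how many members belong to any OG, how many distinct
#' OGs those touch, how many of the touched OGs are shared with each
#' reference taxon (the OG also contains that taxon's genes) and how many
#' are unique to the focal taxon (no other taxon present in the OG).
#' Absence of a taxon from an OG in the table is treated as absence.
#'
#' @param genes Character vector, the focal set.
#' @param og_table Data frame `gene_id`, `og_id`, `taxon`.
#' @param focal_taxon Taxon label of the focal genes, default `"Ako"`.
#' @param reference_taxa Taxa to report sharing against; default all
#'   non-focal taxa present in the table. Unknown taxa are an error.
#' @return List: `n_total`, `n_in_ogs`, `n_ogs`, `n_ogs_shared` (named
#'   integer), `n_ogs_unique`, `pct_in_ogs`, `pct_ogs_unique`.
#' @export
og_summary <- function(genes, og_table, focal_taxon = "Ako",
                       reference_taxa = NULL) {
  genes <- unique(as.character(genes))
  taxa_in_table <- unique(og_table$taxon)
  if (is.null(reference_taxa))
    reference_taxa <- setdiff(taxa_in_table, focal_taxon)
  unknown <- setdiff(reference_taxa, taxa_in_table)
  if (length(unknown))
    stop("reference taxa absent from the OG table: ",
         paste(unknown, collapse = ", "))
  focal_rows <- og_table[og_table$taxon == focal_taxon &
                           og_table$gene_id %in% genes, , drop = FALSE]
  member_genes <- unique(focal_rows$gene_id)
  ogs <- unique(focal_rows$og_id)
  shared <- vapply(reference_taxa, function(tx) {
    tx_ogs <- unique(og_table$og_id[og_table$taxon == tx])
    sum(ogs %in% tx_ogs)
  }, 0L)
  other_ogs <- unique(og_table$og_id[og_table$taxon != focal_taxon])
  n_unique <- sum(!ogs %in% other_ogs)
  list(n_total = length(genes),
       n_in_ogs = length(member_genes),
       n_ogs = length(ogs),
       n_ogs_shared = shared,
       n_ogs_unique = n_unique,
       pct_in_ogs = pct_round(length(member_genes), length(genes)),
       pct_ogs_unique = pct_round(n_unique, length(ogs)))
}

#' Functional-category profile of a gene set
#'
#' Per-category counts over a set, after deduplication of multi-category
#' assignments (a gene annotated several times keeps its first-listed
#' category; a warning reports how many were collapsed). Optionally the
#' set is first restricted to genes actively expressed at a stage
#' (strict `RPKM > floor`).
#'
#' @param genes Character vector of gene ids.
#' @param annotations Data frame `gene_id`, `category` (a gene may appear
#'   on several rows).
#' @param expr Optional table from [stage_expression()], required when
#'   `active_stage` is given.
#' @param active_stage Optional one of `"gro"`, `"agg"`, `"germ"`.
#' @param rpkm_floor Active-expression floor used with `active_stage`,
#'   default 10.
#' @return Named integer vector of counts per category (all categories in
#'   the annotation vocabulary, zero-filled); sums to the number of
#'   (retained) genes.
#' @export
category_profile <- function(genes, annotations, expr = NULL,
                             active_stage = NULL, rpkm_floor = 10) {
  genes <- unique(as.character(genes))
  if (!is.null(active_stage)) {
    active_stage <- match.arg(active_stage, c("gro", "agg", "germ"))
    if (is.null(expr)) stop("active filtering needs an expression table")
    col <- paste0("rpkm_", active_stage)
    active <- expr$gene_id[expr[[col]] > rpkm_floor]
    genes <- genes[genes %in% active]
  }
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  dup <- duplicated(ann$gene_id)
  if (any(dup)) {
    warning(sum(dup), " multi-category assignment(s) collapsed to the ",
            "first-listed category")
    ann <- ann[!dup, , drop = FALSE]
  }
  missing <- setdiff(genes, ann$gene_id)
  if (length(missing))
    stop("annotations missing for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  vocab <- unique(annotations$category)
  counts <- table(factor(ann$category, levels = vocab))
  out <- as.integer(counts)
  names(out) <- vocab
  out
}

#' Strong-response totals for the aggregation transition
#'
#' Number of genes substantially up- or down-regulated between growth and
#' aggregation, their total, and that total as a percentage of the
#' declared proteome.
#'
#' @param classification Table from [classify_stage()].
#' @param proteome_size Total predicted proteins, used as the percentage
#'   base; default the number of classified genes.
#' @return List: `n_up`, `n_dn`, `total`, `pct_of_proteome`.
#' @export
strong_response_total <- function(classification,
                                  proteome_size = nrow(classification)) {
  n_up <- sum(classification$aggup)
  n_dn <- sum(classification$aggdn)
  list(n_up = n_up, n_dn = n_dn, total = n_up + n_dn,
       pct_of_proteome = pct_round(n_up + n_dn, proteome_size))
}

#' Combined per-set summary report
#'
#' A table-shaped report over named gene sets: totals, novelty, OG
#' membership/sharing/uniqueness — the layout used for comparing
#' developmental response sets against the full proteome.
#'
#' @param sets Named list of character vectors (gene sets).
#' @param annotations Annotation table with `gene_id`, `is_novel`.
#' @param og_table OG membership table (`gene_id`, `og_id`, `taxon`).
#' @param focal_taxon Focal taxon label in `og_table`, default `"Ako"`.
#' @param reference_taxa Passed to [og_summary()].
#' @return Data frame with one row per set.
#' @export
set_summary_report <- function(sets, annotations, og_table,
                               focal_taxon = "Ako", reference_taxa = NULL) {
  rows <- lapply(names(sets), function(nm) {
    nv <- novelty_fraction(sets[[nm]], annotations)
    og <- og_summary(sets[[nm]], og_table, focal_taxon = focal_taxon,
                     reference_taxa = reference_taxa)
    row <- data.frame(set = nm, n_total = nv$n_total, n_novel = nv$n_novel,
                      pct_novel = nv$pct_novel, n_in_ogs = og$n_in_ogs,
                      n_ogs = og$n_ogs, n_ogs_unique = og$n_ogs_unique,
                      pct_in_ogs = og$pct_in_ogs,
                      pct_ogs_unique = og$pct_ogs_unique,
                      stringsAsFactors = FALSE)
    for (tx in names(og$n_ogs_shared))
      row[[paste0("n_ogs_shared_", tx)]] <- og$n_ogs_shared[[tx]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
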