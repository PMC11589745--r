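#' Reads per kilobase per million (RPKM)
#'
#' Length- and depth-corrected expression:
#' `1e9 * count / (len_bp * library_size)`. No pseudo-count enters here;
#' RPKM is kept exact and shrinkage lives only in the fold-change prior.
#'
#' @param count Non-negative read count (vectorized).
#' @param len_bp Gene length in bp, positive.
#' @param library_size Total mapped reads in the library, positive.
#' @return Non-negative numeric.
#' @export
rpkm <- function(count, len_bp, library_size) {
  if (any(len_bp <= 0)) stop("len_bp must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  1e9 * count / (len_bp * library_size)
}

#' Conservative single-replicate posterior log2 fold change
#'
#' With one library per condition, a point log2 ratio of counts is badly
#' anti-conservative. This estimator places independent Gamma posteriors on
#' the per-library Poisson rates, `rate_i ~ Gamma(c_i + 1/2, N_i)`
#' (Jeffreys-style prior; `c_i` = count, `N_i` = library size), and takes
#' the central credible interval of `log2(rate_2 / rate_1)`. The returned
#' value is 0 when the interval contains 0, otherwise the interval endpoint
#' nearer 0 (keeping its sign) — the smallest fold change clearly supported
#' by the data. Quantiles are analytic: for independent gammas
#' `G2/G1 = B/(1-B)` with `B ~ Beta(a2, a1)`, so the interval comes from
#' `stats::qbeta` and the estimator is fully deterministic.
#'
#' Both counts 0 gives 0 (an uninformative comparison; flagged in the
#' `"uninformative"` attribute). The estimator shrinks: its magnitude never
#' exceeds the naive pseudo-counted ratio
#' `log2(((c2+1/2)/N2) / ((c1+1/2)/N1))`, and it converges to the true
#' log2 ratio as counts grow.
#'
#' @param c1,c2 Non-negative counts in conditions 1 and 2 (vectorized).
#' @param n1,n2 Positive library sizes.
#' @param credibility Central credible mass in (0, 1), default 0.99.
#' @return Numeric vector of signed log2 fold changes (condition 2 over
#'   condition 1), with attribute `uninformative` (logical vector, TRUE
#'   where both counts were 0).
#' @export
conservative_log2fc <- function(c1, c2, n1, n2, credibility = 0.99) {
  if (any(c1 < 0) || any(c2 < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  if (length(credibility) != 1L || credibility <= 0 || credibility >= 1)
    stop("credibility must be a single value in (0, 1)")
  k <- max(length(c1), length(c2), length(n1), length(n2))
  c1 <- rep_len(c1, k); c2 <- rep_len(c2, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  a1 <- c1 + 0.5
  a2 <- c2 + 0.5
  p <- (1 - credibility) / 2
  # log2(rate2/rate1) = log2(n1/n2) + log2(B/(1-B)), B ~ Beta(a2, a1);
  # the transform is monotone so quantiles map through directly
  blo <- stats::qbeta(p, a2, a1)
  bhi <- stats::qbeta(1 - p, a2, a1)
  shift <- log2(n1 / n2)
  lo <- shift + log2(blo) - log2(1 - blo)
  hi <- shift + log2(bhi) - log2(1 - bhi)
  est <- ifelse(lo <= 0 & hi >= 0, 0, ifelse(lo > 0, lo, hi))
  attr(est, "uninformative") <- c1 == 0 & c2 == 0
  est
}

#' Thresholds defining substantial differential expression (SDE)
#'
#' Joint expression-level and fold-change criteria: a stage response
#' requires `|DE_log2| >= de_min` plus active expression
#' (`RPKM >= rpkm_floor`) in the condition-appropriate stage; the
#' aggregation-specific label additionally requires a two-fold rise into
#' aggregation and a two-fold fall into germination
#' (`aggspec_de`, in log2 units).
#'
#' @param de_min Minimum |log2 fold change| for an up/down call, default 0.9.
#' @param rpkm_floor Active-expression floor in RPKM, default 10.
#' @param aggspec_de Log2 threshold for aggregation-specific genes,
#'   default 1 (two-fold); must be `>= de_min`.
#' @param credibility Credible mass for [conservative_log2fc()], default 0.99.
#' @return Object of class `sde_thresholds`.
#' @export
sde_thresholds <- function(de_min = 0.9, rpkm_floor = 10, aggspec_de = 1,
                           credibility = 0.99) {
  stopifnot(de_min > 0, rpkm_floor > 0, aggspec_de > 0,
            credibility > 0, credibility < 1)
  if (aggspec_de < de_min) stop("aggspec_de must be >= de_min")
  structure(list(de_min = de_min, rpkm_floor = rpkm_floor,
                 aggspec_de = aggspec_de, credibility = credibility),
            class = "sde_thresholds")
}

#' Per-gene stage expression table for a three-stage life cycle
#'
#' From a count table over the growth (`gro`), aggregation (`agg`) and
#' germination (`germ`) stages, computes per-stage RPKM and the two
#' conservative fold changes: `de_agg` (growth to aggregation) and
#' `de_germ` (aggregation to germination).
#'
#' @param counts Data frame with columns `gene_id`, `len_bp`, `gro`, `agg`,
#'   `germ`.
#' @param library_sizes Named numeric `c(gro=, agg=, germ=)`; by default the
#'   column sums of the count table.
#' @param thresholds An [sde_thresholds()] (its `credibility` feeds the
#'   fold-change estimator).
#' @return Data frame: `gene_id`, `len_bp`, counts, `rpkm_gro`, `rpkm_agg`,
#'   `rpkm_germ`, `de_agg`, `de_germ`.
#' @export
stage_expression <- function(counts, library_sizes = NULL,
                             thresholds = sde_thresholds()) {
  need <- c("gene_id", "len_bp", "gro", "agg", "germ")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "))
  stages <- c("gro", "agg", "germ")
  if (nrow(counts) == 0L) {
    out <- counts[, need, drop = FALSE]
    for (s in stages) out[[paste0("rpkm_", s)]] <- numeric(0)
    out$de_agg <- numeric(0)
    out$de_germ <- numeric(0)
    return(out)
  }
  if (is.null(library_sizes))
    library_sizes <- vapply(counts[stages], sum, 0)
  library_sizes <- library_sizes[stages]
  if (any(is.na(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be positive for gro, agg and germ",
         " (empty count tables need an explicit override)")
  out <- counts[, need, drop = FALSE]
  for (s in stages)
    out[[paste0("rpkm_", s)]] <- rpkm(counts[[s]], counts$len_bp,
                                      library_sizes[[s]])
  out$de_agg <- as.numeric(conservative_log2fc(
    counts$gro, counts$agg, library_sizes[["gro"]], library_sizes[["agg"]],
    credibility = thresholds$credibility))
  out$de_germ <- as.numeric(conservative_log2fc(
    counts$agg, counts$germ, library_sizes[["agg"]], library_sizes[["germ"]],
    credibility = thresholds$credibility))
  attr(out, "library_sizes") <- library_sizes
  out
}

#' Stage-response set classification
#'
#' Applies the SDE rules to a stage expression table. `Aggup`/`Aggdn` mark
#' substantial increase/decrease from growth to aggregation, requiring
#' active expression (RPKM at or above the floor) in the stage where the
#' gene is up (aggregation for Aggup, growth for Aggdn); `Germup`/`Germdn`
#' are the symmetric calls on the aggregation-to-germination transition.
#' `AggSpec` (aggregation-specific) genes are Aggup and Germdn with at
#' least `aggspec_de` magnitude on both transitions, so
#' `AggSpec => Aggup & Germdn` holds by construction. `active_gro/agg/germ`
#' flag strict `RPKM > rpkm_floor` expression per stage.
#'
#' @param expr Table from [stage_expression()].
#' @param thresholds An [sde_thresholds()].
#' @return Data frame: `gene_id`, logical `aggup`, `aggdn`, `germup`,
#'   `germdn`, `aggspec`, `active_gro`, `active_agg`, `active_germ`.
#' @export
classify_stage <- function(expr, thresholds = sde_thresholds()) {
  stopifnot(inherits(thresholds, "sde_thresholds"))
  t <- thresholds
  aggup <- expr$de_agg >= t$de_min & expr$rpkm_agg >= t$rpkm_floor
  aggdn <- expr$de_agg <= -t$de_min & expr$rpkm_gro >= t$rpkm_floor
  germup <- expr$de_germ >= t$de_min & expr$rpkm_germ >= t$rpkm_floor
  germdn <- expr$de_germ <= -t$de_min & expr$rpkm_agg >= t$rpkm_floor
  aggspec <- aggup & germdn & expr$de_agg >= t$aggspec_de &
    expr$de_germ <= -t$aggspec_de
  data.frame(gene_id = expr$gene_id,
             aggup = aggup, aggdn = aggdn,
             germup = germup, germdn = germdn, aggspec = aggspec,
             active_gro = expr$rpkm_gro > t$rpkm_floor,
             active_agg = expr$rpkm_agg > t$rpkm_floor,
             active_germ = expr$rpkm_germ > t$rpkm_floor,
             stringsAsFactors = FALSE)
}

#' Average differential expression across replicates
#'
#' For designs with replicate fold-change estimates per gene (as in the
#' two-replicate dictyostelid comparison), returns the per-gene mean DE.
#' In `strict` mode the replicate gene sets must be identical; `lenient`
#' mode intersects them with a warning. Set sizes classified from the
#' consensus DE are bounded by the per-replicate extremes.
#'
#' @param replicates List of data frames, each with `gene_id` and `de`.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return Data frame `gene_id`, `de` (mean across replicates), plus one
#'   `de_r<i>` column per replicate.
#' @export
average_replicates <- function(replicates, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(length(replicates) >= 1L)
  ids <- lapply(replicates, function(r) as.character(r$gene_id))
  common <- Reduce(intersect, ids)
  if (mode == "strict") {
    same <- all(vapply(ids, function(x) setequal(x, common), TRUE))
    if (!same) stop("replicate gene sets differ (use mode = \"lenient\")")
  } else if (!all(vapply(ids, function(x) setequal(x, common), TRUE))) {
    warning("replicate gene sets differ; intersecting")
  }
  out <- data.frame(gene_id = common, stringsAsFactors = FALSE)
  demat <- vapply(replicates,
                  function(r) r$de[match(common, r$gene_id)],
                  numeric(length(common)))
  demat <- matrix(demat, nrow = length(common))
  out$de <- rowMeans(demat)
  for (i in seq_along(replicates)) out[[paste0("de_r", i)]] <- demat[, i]
  out
}
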