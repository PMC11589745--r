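#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list) and
#' assembles the typed objects the stages need: a [taxon_group_map()], an
#' [sde_thresholds()] and a [sim_config()]. Flags passed through `...`
#' override config values (e.g. `seed`, `out_dir`).
#'
#' @param config Path to a YAML file, or a named list.
#' @param ... Scalar overrides applied on top of the file values.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(config, ...) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  over <- list(...)
  cfg[names(over)] <- over
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$support_min <- cfg$support_min %||% 60
  cfg$query_species <- cfg$query_species %||% "query"
  taxmap <- if (is.null(cfg$taxon_groups)) {
    taxon_group_map(recipient = cfg$recipient %||% "Excavata")
  } else {
    taxon_group_map(groups = unlist(cfg$taxon_groups),
                    recipient = cfg$recipient %||% "Excavata")
  }
  thr <- sde_thresholds(de_min = cfg$de_min %||% 0.9,
                        rpkm_floor = cfg$rpkm_floor %||% 10,
                        aggspec_de = cfg$aggspec_de %||% 1,
                        credibility = cfg$credibility %||% 0.99)
  libs <- cfg$library_sizes
  libs <- if (is.null(libs)) c(gro = 5e6, agg = 5e6, germ = 5e6)
          else vapply(unlist(libs)[c("gro", "agg", "germ")],
                      function(x) as.numeric(x), 0)
  sim <- sim_config(seed = cfg$seed, taxmap = taxmap,
                    n_genes = cfg$n_genes %||% 200L,
                    hgt_fraction = cfg$hgt_fraction %||% 0.5,
                    support_mean = cfg$support_mean %||% 100,
                    support_spread = cfg$support_spread %||% 0,
                    nb_dispersion = cfg$nb_dispersion %||% 0.05,
                    library_sizes = libs,
                    e_screen = cfg$e_screen %||% 1e-10,
                    e_tree = cfg$e_tree %||% 1e-35)
  structure(list(raw = cfg, seed = cfg$seed, out_dir = cfg$out_dir,
                 taxmap = taxmap, thresholds = thr, sim = sim,
                 support_min = cfg$support_min,
                 e_screen = cfg$e_screen %||% 1e-10,
                 e_tree = cfg$e_tree %||% 1e-35,
                 min_euk_groups = cfg$min_euk_groups %||% 3L,
                 query_species = cfg$query_species),
            class = "pipeline_config")
}

config_hash <- function(pcfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  raw <- pcfg$raw
  raw$out_dir <- NULL                  # paths must not perturb the hash
  writeLines(yaml::as.yaml(raw[order(names(raw))]), tf)
  unname(tools::md5sum(tf))
}

stage_header <- function(pcfg) {
  sprintf("# aggdev seed=%d config=%s", pcfg$seed, config_hash(pcfg))
}

write_stage_tsv <- function(df, path, pcfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(pcfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis end to end on synthetic inputs:
#' `simulate` writes ground-truthed fixtures (gene trees, hit table,
#' counts, annotations, OG table); `screen` classifies hit patterns and
#' selects phylogenetic candidates; `treecall` calls HGT per tree and
#' summarizes donors; `de` computes RPKM, conservative fold changes and
#' the stage classification; `profile` writes the per-set summary report;
#' `all` runs the full chain and writes a run manifest with the seed,
#' config hash and per-file checksums. No stage mutates its inputs, and
#' reruns with an identical config are byte-identical.
#'
#' @param stage One of `"simulate"`, `"screen"`, `"treecall"`, `"de"`,
#'   `"profile"`, `"all"`.
#' @param config A `pipeline_config` (or path/list accepted by
#'   [pipeline_config()]).
#' @param out_dir Output directory (created if needed); overrides the
#'   config value.
#' @return Invisibly, a character vector of the files written.
#' @export
run_stage <- function(stage = c("all", "simulate", "screen", "treecall",
                                "de", "profile"),
                      config, out_dir = NULL) {
  stage <- match.arg(stage)
  pcfg <- if (inherits(config, "pipeline_config")) config
          else pipeline_config(config)
  dir <- out_dir %||% pcfg$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pathof <- function(f) file.path(dir, f)
  need <- function(f) {
    p <- pathof(f)
    if (!file.exists(p)) stop("missing input for stage '", stage, "': ", p)
    p
  }
  written <- character()
  emit <- function(df, f) {
    write_stage_tsv(df, pathof(f), pcfg)
    written <<- c(written, f)
  }

  do_simulate <- function() {
    trees <- simulate_gene_trees(pcfg$sim)
    writeLines(c(stage_header(pcfg), trees$newicks), pathof("trees.nwk"))
    written <<- c(written, "trees.nwk")
    emit(trees$truth, "tree_truth.tsv")
    hp <- simulate_hit_profiles(pcfg$sim)
    # hit tables are positional (outfmt-6 dialect): header comment only
    con <- file(pathof("hits.tsv"), "w")
    writeLines(stage_header(pcfg), con)
    utils::write.table(hp$hits, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    written <<- c(written, "hits.tsv")
    emit(hp$truth, "hit_truth.tsv")
    emit(hp$novelty, "novelty.tsv")
    cn <- simulate_counts(pcfg$sim)
    emit(cn$counts, "counts.tsv")
    emit(cn$truth, "count_truth.tsv")
    set.seed(pcfg$seed + 3L)
    ann <- simulate_annotations(cn$counts$gene_id,
                                n_novel = round(0.3 * nrow(cn$counts)),
                                shuffle = TRUE)
    emit(ann, "annotations.tsv")
    og <- simulate_og_table(cn$counts$gene_id,
                            n_in_ogs = floor(0.43 * nrow(cn$counts)),
                            n_ogs = floor(0.2 * nrow(cn$counts)),
                            shared = c(Ngr = floor(0.03 * nrow(cn$counts)),
                                       Disc = floor(0.04 * nrow(cn$counts))),
                            seed = pcfg$seed + 4L)
    emit(og, "ogs.tsv")
  }

  do_screen <- function() {
    hits <- load_hit_table(need("hits.tsv"), pcfg$taxmap,
                           e_screen = pcfg$e_screen)
    novelty <- read_stage_tsv(need("novelty.tsv"))
    profiles <- build_profiles(hits, pcfg$taxmap,
                               query_ids = novelty$gene_id)
    emit(profiles, "profiles.tsv")
    emit(classify_pattern(profiles, pcfg$taxmap), "patterns.tsv")
    cand <- select_phylo_candidates(profiles, novelty, pcfg$taxmap,
                                    e_tree = pcfg$e_tree,
                                    min_euk_groups = pcfg$min_euk_groups)
    writeLines(c(stage_header(pcfg), cand), pathof("candidates.txt"))
    written <<- c(written, "candidates.txt")
  }

  do_treecall <- function() {
    lines <- readLines(need("trees.nwk"))
    newicks <- lines[!grepl("^#", lines) & nzchar(lines)]
    calls <- call_hgt_batch(newicks, pcfg$taxmap,
                            support_min = pcfg$support_min,
                            query_species = pcfg$query_species)
    emit(calls, "hgt_calls.tsv")
    emit(summarize_donors(calls), "donor_summary.tsv")
  }

  do_de <- function() {
    counts <- read_stage_tsv(need("counts.tsv"))
    expr <- stage_expression(counts, thresholds = pcfg$thresholds)
    cls <- classify_stage(expr, pcfg$thresholds)
    emit(cbind(expr, cls[, setdiff(names(cls), "gene_id")]),
         "expression.tsv")
  }

  do_profile <- function() {
    expr <- read_stage_tsv(need("expression.tsv"))
    ann <- read_stage_tsv(need("annotations.tsv"))
    og <- read_stage_tsv(need("ogs.tsv"))
    sets <- list(aggup = expr$gene_id[expr$aggup],
                 aggdn = expr$gene_id[expr$aggdn],
                 germup = expr$gene_id[expr$germup],
                 germdn = expr$gene_id[expr$germdn],
                 proteome = expr$gene_id)
    emit(set_summary_report(sets, ann, og), "set_summary.tsv")
  }

  steps <- switch(stage,
                  simulate = list(do_simulate),
                  screen = list(do_screen),
                  treecall = list(do_treecall),
                  de = list(do_de),
                  profile = list(do_profile),
                  all = list(do_simulate, do_screen, do_treecall, do_de,
                             do_profile))
  for (f in steps) f()
  if (stage == "all") {
    files <- sort(written)
    sums <- tools::md5sum(file.path(dir, files))
    manifest <- list(seed = pcfg$seed, config = config_hash(pcfg),
                     package_version = as.character(
                       utils::packageVersion("aggdev")),
                     stages = c("simulate", "screen", "treecall", "de",
                                "profile"),
                     files = as.list(stats::setNames(unname(sums), files)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, "manifest.json")
  }
  invisible(file.path(dir, written))
}
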