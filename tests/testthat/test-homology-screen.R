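tm <- taxon_group_map()

write_hits <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

hit_row <- function(q, group, evalue, bitscore = 100, subject = NULL) {
  data.frame(query_id = q,
             subject_id = subject %||% paste0(group, "_s1"),
             pident = 50, length = 200, mismatch = 10, gapopen = 1,
             qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
             evalue = evalue, bitscore = bitscore, subject_group = group,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hit-table loading screens, validates and reports line numbers", {
  p <- write_hits(rbind(hit_row("q1", "Bacteria", 1e-50),
                        hit_row("q1", "Fungi", 1e-9),
                        hit_row("q2", "Metazoa", 1e-20)))
  hits <- load_hit_table(p, tm, e_screen = 1e-10)
  expect_equal(nrow(hits), 2L)                 # the 1e-9 row is out
  expect_false("Fungi" %in% hits$subject_group)

  empty <- write_hits(hit_row("q", "Fungi", 1)[0, ])
  expect_equal(nrow(load_hit_table(empty, tm)), 0L)

  bad <- tempfile(); writeLines(c("a\tb\tc"), bad)
  expect_error(load_hit_table(bad, tm), "line 1")
  badgroup <- write_hits(hit_row("q1", "Klingon", 1e-30))
  expect_error(load_hit_table(badgroup, tm), "unknown taxon group")
})

test_that("a 12-column table resolves groups through a subject map", {
  df <- hit_row("q1", "Bacteria", 1e-40, subject = "WP_001")
  p <- write_hits(df[, setdiff(names(df), "subject_group")])
  expect_error(load_hit_table(p, tm), "group_map")
  gm <- data.frame(subject_id = "WP_001", subject_group = "Bacteria")
  hits <- load_hit_table(p, tm, group_map = gm)
  expect_equal(hits$subject_group, "Bacteria")
})

test_that("profiles take per-group minima with deterministic tie-breaks", {
  hits <- rbind(hit_row("q1", "Bacteria", 1e-50),
                hit_row("q1", "Bacteria", 1e-30),
                hit_row("q1", "Fungi", 1e-20))
  pr <- build_profiles(hits, tm)
  expect_equal(pr$best_Bacteria, 1e-50)
  expect_equal(pr$best_Fungi, 1e-20)
  expect_equal(pr$top_hit_group, "Bacteria")

  # ties: same e-value, bitscore decides; then lexicographic group
  hits2 <- rbind(hit_row("q1", "Fungi", 1e-30, bitscore = 200),
                 hit_row("q1", "Metazoa", 1e-30, bitscore = 300))
  expect_equal(build_profiles(hits2, tm)$top_hit_group, "Metazoa")
  hits3 <- rbind(hit_row("q1", "Metazoa", 1e-30, bitscore = 200),
                 hit_row("q1", "Fungi", 1e-30, bitscore = 200))
  expect_equal(build_profiles(hits3, tm)$top_hit_group, "Fungi")
  # e-value 0 beats any positive e-value
  hits4 <- rbind(hit_row("q1", "Rhizaria", 0, bitscore = 10),
                 hit_row("q1", "Fungi", 1e-300, bitscore = 999))
  expect_equal(build_profiles(hits4, tm)$top_hit_group, "Rhizaria")
  # recipient-only queries have no top hit
  pr5 <- build_profiles(hit_row("q1", "Excavata", 1e-60), tm)
  expect_true(is.na(pr5$top_hit_group))
})

test_that("profiles match a brute-force group-by-group minimum", {
  set.seed(4242)
  n <- 1000L
  hits <- hit_row("x", "Fungi", 1)[rep(1, n), ]
  hits$query_id <- sprintf("q%d", sample(1:80, n, replace = TRUE))
  hits$subject_group <- sample(tm$groups, n, replace = TRUE)
  hits$evalue <- 10^runif(n, -120, -10)
  hits$bitscore <- runif(n, 50, 500)
  pr <- build_profiles(hits, tm)
  for (q in sample(unique(hits$query_id), 20)) {
    h <- hits[hits$query_id == q, ]
    row <- pr[pr$query_id == q, ]
    for (g in tm$groups) {
      ev <- h$evalue[h$subject_group == g]
      expect_equal(row[[paste0("best_", g)]],
                   if (length(ev)) min(ev) else NA_real_)
    }
    nr <- h[h$subject_group != tm$recipient, ]
    expect_equal(row$top_hit_group,
                 if (nrow(nr)) nr$subject_group[order(nr$evalue, -nr$bitscore,
                                                      nr$subject_group)][1]
                 else NA_character_)
  }
})

test_that("pattern labels partition queries and match definitions", {
  hits <- rbind(hit_row("uni", "Bacteria", 1e-50),
                hit_row("multi", "Fungi", 1e-40),
                hit_row("multi", "Stramenopila", 1e-42),
                hit_row("reconly", "Excavata", 1e-60))
  pr <- build_profiles(hits, tm, query_ids = c("uni", "multi", "reconly",
                                               "nohit"))
  cl <- classify_pattern(pr, tm)
  got <- setNames(cl$pattern, cl$query_id)
  expect_equal(got[["uni"]], "uniHit")
  expect_equal(got[["multi"]], "multiHit")
  expect_equal(got[["reconly"]], "recipientOnly")
  expect_equal(got[["nohit"]], "noHit")
  expect_equal(cl$hit_groups[cl$query_id == "uni"], "Bacteria")
  # partition: every query gets exactly one of the four labels
  expect_true(all(cl$pattern %in% c("noHit", "recipientOnly", "uniHit",
                                    "multiHit")))
})

test_that("pattern calls and candidate selection agree with naive re-scans", {
  cfg <- sim_config(seed = 77, n_genes = 400)
  hp <- simulate_hit_profiles(cfg)
  pr <- build_profiles(hp$hits, tm, query_ids = hp$truth$query_id)
  cl <- classify_pattern(pr, tm)
  for (i in seq(1, 400, by = 7)) {
    q <- hp$truth$query_id[i]
    expect_equal(cl$pattern[cl$query_id == q],
                 oracle_pattern(hp$hits, q, tm), info = q)
  }
  # planted-class confusion matrix is diagonal (excavateOnly = recipientOnly)
  map <- c(none = "noHit", excavateOnly = "recipientOnly",
           uniHit = "uniHit", multiHit = "multiHit")
  expect_equal(unname(map[hp$truth$class]),
               cl$pattern[match(hp$truth$query_id, cl$query_id)])

  cand <- select_phylo_candidates(pr, hp$novelty, tm)
  brute <- hp$truth$query_id[vapply(seq_len(nrow(hp$truth)), function(i)
    oracle_candidate(hp$hits, hp$truth$query_id[i], tm,
                     hp$truth$is_novel[i]), TRUE)]
  expect_setequal(cand, brute)
  expect_setequal(cand, hp$truth$query_id[hp$truth$is_candidate])
})

test_that("tightening the tree-tier cut-off never grows the candidate set", {
  cfg <- sim_config(seed = 78, n_genes = 300)
  hp <- simulate_hit_profiles(cfg)
  pr <- build_profiles(hp$hits, tm, query_ids = hp$truth$query_id)
  sweep <- 10^(-seq(20, 50, by = 5))
  sets <- lapply(sweep, function(e)
    select_phylo_candidates(pr, hp$novelty, tm, e_tree = e))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})
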