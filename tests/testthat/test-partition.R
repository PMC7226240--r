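# Fixture reproducing the published identification arithmetic: disjoint
# SDS (388) and urea (266) cement sets whose union is 654; 13 tick and 49
# host proteins shared between sialome and cementome; 1936 tick and 61
# host sialome proteins; 68 tick-only and 250 host-only cementome
# proteins (tick cementome total 81).
published_partition_fixture <- function() {
  tick_shared <- sprintf("TS%04d", 1:13)
  host_shared <- sprintf("HS%04d", 1:49)
  tick_sial_only <- sprintf("TO%04d", 1:1923)   # 1936 total tick sialome
  host_sial_only <- sprintf("HO%04d", 1:12)     # 61 total host sialome
  tick_cem_only <- sprintf("TC%04d", 1:68)
  host_cem_only <- sprintf("HC%04d", 1:250)
  cement_all <- c(tick_shared, host_shared, tick_cem_only, host_cem_only)
  stopifnot(length(cement_all) == 380)
  # split the 380 cementome accessions into disjoint SDS/urea sets and pad
  # both with extraction-specific accessions to reach 388 and 266
  sds <- c(cement_all[1:200], sprintf("XS%04d", 1:188))
  urea <- c(cement_all[201:380], sprintf("XU%04d", 1:86))
  stopifnot(length(sds) == 388, length(urea) == 266)
  accs <- c(tick_shared, host_shared, tick_sial_only, host_sial_only,
            tick_cem_only, host_cem_only,
            sprintf("XS%04d", 1:188), sprintf("XU%04d", 1:86))
  origin <- c(rep("tick", 13), rep("host", 49), rep("tick", 1923),
              rep("host", 12), rep("tick", 68), rep("host", 250),
              rep("host", 188 + 86))
  list(
    identifications = list(
      salivary_gland.native = c(tick_shared, host_shared, tick_sial_only,
                                host_sial_only),
      cement.SDS = sds,
      cement.urea = urea
    ),
    annotation = data.frame(accession = accs, origin = origin,
                            stringsAsFactors = FALSE)
  )
}

test_that("partition reproduces the published worked arithmetic", {
  fx <- published_partition_fixture()
  p <- build_partition(fx$identifications, fx$annotation)
  counts <- p$counts
  tick <- counts[counts$origin == "tick", ]
  host <- counts[counts$origin == "host", ]
  expect_equal(tick$shared, 13)
  expect_equal(host$shared, 49)
  expect_equal(tick$shared + host$shared, 62)
  expect_equal(tick$cementome_total, 81)   # 13 shared + 68 cement-only
  expect_equal(tick$sialome_total, 1936)
  expect_equal(host$sialome_total, 61)
  expect_equal(p$extraction_counts[["SDS"]], 388)
  expect_equal(p$extraction_counts[["urea"]], 266)
  expect_equal(p$extraction_counts[["union"]], 654)
})

test_that("partition counts are invariant to ordering and duplication", {
  fx <- published_partition_fixture()
  shuffled <- lapply(fx$identifications, function(s) {
    set.seed(1)
    c(sample(s), s[1:5])  # reorder and duplicate a few
  })
  p1 <- build_partition(fx$identifications, fx$annotation)
  p2 <- build_partition(shuffled, fx$annotation)
  expect_equal(p2$counts, p1$counts)
  expect_equal(p2$extraction_counts, p1$extraction_counts)
})

test_that("partition handles empty input and rejects unannotated accessions", {
  ann <- data.frame(accession = "p1", origin = "tick")
  p <- build_partition(list(salivary_gland.native = character(0),
                            cement.SDS = character(0)), ann)
  expect_true(all(p$counts[, -1] == 0))
  expect_error(
    build_partition(list(cement.SDS = c("p1", "mystery")), ann),
    "mystery")
})

test_that("membership totals are additive per origin", {
  ds <- generate_dataset(synthetic_config(n_proteins = 120, seed = 21))
  v <- ds$quant$values
  key <- paste(ds$quant$runs$tissue, ds$quant$runs$extraction, sep = ".")
  idents <- lapply(split(seq_len(ncol(v)), key), function(j) {
    rownames(v)[rowSums(v[, j, drop = FALSE]) > 0]
  })
  p <- build_partition(idents, ds$annotation)
  counts <- p$counts
  expect_equal(counts$cementome_total, counts$shared + counts$cementome_only)
  expect_equal(counts$sialome_total, counts$shared + counts$sialome_only)
  # union per origin
  union_total <- counts$sialome_only + counts$cementome_only + counts$shared
  tab <- table(ds$truth$origin)
  expect_equal(setNames(union_total, counts$origin),
               c(tick = unname(tab["tick"]), host = unname(tab["host"]))[counts$origin])
  # membership labels round-trip against ground truth
  mem <- partition_membership(p)
  tr <- ds$truth$membership[match(mem$accession, ds$truth$protein)]
  expect_equal(mem$membership, tr)
})

test_that("GO process shares sum to 1 and bucket into top-n plus Other", {
  ann <- data.frame(accession = sprintf("p%02d", 1:12),
                    stringsAsFactors = FALSE)
  ann$origin <- "tick"
  ann$go_terms <- lapply(1:12, function(i) paste0("proc", i))
  s <- go_process_shares(ann, ann$accession)
  expect_equal(sum(s$share), 1)
  expect_true(all(s$share >= 0))
  b <- top_n_with_other(s, n = 10)
  expect_equal(nrow(b), 11)
  expect_equal(b$share[b$process == "Other"], 2 / 12, tolerance = 1e-12)
  # single process: share 1
  ann1 <- data.frame(accession = "a", origin = "tick")
  ann1$go_terms <- list("only_process")
  s1 <- go_process_shares(ann1, "a")
  expect_equal(s1$share, 1)
  # no annotations: empty table
  ann0 <- data.frame(accession = "a", origin = "tick")
  ann0$go_terms <- list(character(0))
  expect_equal(nrow(go_process_shares(ann0, "a")), 0)
})

test_that("key-protein selection flags behave at the boundaries", {
  # 3 proteins: one shared, one top of its category, one in a big GO process
  assignments <- data.frame(
    protein = c("a", "b", "c"),
    pattern = "up/up/up",
    category = c("feeding", "feeding", "feeding"),
    untestable = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(accession = c("a", "b", "c"),
                    origin = "tick", stringsAsFactors = FALSE)
  ann$go_terms <- list("big", "big", "small")
  idents <- list(salivary_gland.native = c("a"),
                 cement.SDS = c("a", "b", "c"))
  p <- build_partition(idents, ann)
  runs <- data.frame(run_id = paste0("r", 1:3), tissue = "cement",
                     extraction = "SDS", time = c("T1", "T2", "T3"),
                     bio_rep = 1, tech_rep = 1)
  q <- quant_matrix(matrix(c(9, 9, 9, 5, 5, 5, 1, 1, 1), nrow = 3,
                           byrow = TRUE,
                           dimnames = list(c("a", "b", "c"), runs$run_id)),
                    runs)
  cent <- c(a = 0, b = 10, c = 1)
  s <- select_key_proteins(assignments, p, ann, centrality = cent, quant = q)
  expect_equal(s$shared_sialome_cementome, c(TRUE, FALSE, FALSE))
  expect_equal(s$top2_in_profile_category, c(TRUE, TRUE, FALSE))
  # shares: big = 2/3 > 0.04, small = 1/3 > 0.04 too; tighten threshold
  s2 <- select_key_proteins(assignments, p, ann, centrality = cent,
                            quant = q, go_share_threshold = 0.5)
  expect_equal(s2$go_process_share_gt_threshold, c(TRUE, TRUE, FALSE))
  expect_equal(s$criteria_met, rowSums(s[, 2:5]))
  # extremes: all flags on / off via thresholds
  all_on <- select_key_proteins(assignments, p, ann, centrality = cent,
                                quant = q, top_k = 3,
                                go_share_threshold = 0,
                                centrality_quantile = 0)
  expect_true(all(all_on$go_process_share_gt_threshold))
  expect_true(all(all_on$top2_in_profile_category))
  # missing centrality: criterion skipped with a warning, not FALSE
  expect_warning(
    sk <- select_key_proteins(assignments, p, ann, centrality = NULL,
                              quant = q),
    "centrality")
  expect_true(all(is.na(sk$high_network_centrality)))
  expect_match(sk$skipped[1], "high_network_centrality")
})
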