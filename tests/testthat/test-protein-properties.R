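test_that("amino-acid composition handles plain, mixed and ambiguous input", {
  comp <- aa_composition("GGGG")
  expect_equal(comp[["G"]], 100)
  expect_equal(sum(comp), 100)
  comp2 <- aa_composition("GA")
  expect_equal(comp2[["G"]], 50)
  expect_equal(comp2[["A"]], 50)
  # X excluded from the denominator, counted as ambiguous
  comp3 <- aa_composition("GAXX")
  expect_equal(comp3[["G"]], 50)
  expect_equal(attr(comp3, "n_ambiguous"), 2)
  expect_error(aa_composition(""), "empty")
  expect_error(aa_composition("G1G"), "non-residue")
})

test_that("GRAVY matches the Kyte-Doolittle table and is reversal-invariant", {
  expect_equal(gravy("GGGG"), -0.4)
  expect_equal(gravy("IIII"), 4.5)
  expect_equal(gravy("GI"), 2.05)
  s <- "MKVLAWGGGHHIEDD"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gravy(rev_s), gravy(s))
  expect_warning(g <- gravy("GXG"), "ambiguous")
  expect_equal(g, -0.4)
})

test_that("isoelectric point brackets, orders and converges", {
  seqs <- c("ACDEFGHIKLMNPQRSTVWY", "KKKKKK", "DDDDDD", "GGGG")
  for (s in seqs) {
    # net charge positive at pH 0, negative at pH 14
    chars <- strsplit(s, "")[[1]]
    counts <- table(factor(chars, levels = c(cementome:::AA_STANDARD, "X")))
    counts <- setNames(as.numeric(counts), names(counts))
    f <- function(ph) cementome:::protein_charge_at_ph(
      counts, chars[1], chars[length(chars)], ph)
    expect_gt(f(0), 0)
    expect_lt(f(14), 0)
    # bisection result agrees with a dense grid scan of the charge curve
    pi_hat <- isoelectric_point(s)
    grid <- seq(0, 14, by = 1e-3)
    crossing <- grid[which.min(abs(vapply(grid, f, 0)))]
    expect_lt(abs(pi_hat - crossing), 2e-3)
  }
  expect_gt(isoelectric_point("KKKKKK"), isoelectric_point("DDDDDD"))
})

test_that("instability index follows the DIWV dipeptide sum and is ordered", {
  # homo-dipeptide: II = 10 * DIWV(xx) / 2
  diwv <- cementome:::DIWV
  for (aa in c("A", "L", "P", "W")) {
    s <- paste0(aa, aa)
    expect_equal(as.numeric(instability_index(s)),
                 10 * diwv[aa, aa] / 2)
  }
  # order dependence: reversal changes the index in general
  s <- "MWPLAK"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_false(isTRUE(all.equal(as.numeric(instability_index(s)),
                                as.numeric(instability_index(rev_s)))))
  # stability call at the conventional threshold of 40:
  # poly-A dipeptides weigh 1 each (II = 7.5), Gly-Gly weighs 13.34
  # (II = 100 for GGGG)
  expect_true(attr(instability_index("AAAA"), "stable"))
  expect_false(attr(instability_index("GGGG"), "stable"))
  expect_equal(as.numeric(instability_index("GGGG")),
               10 / 4 * 3 * diwv["G", "G"])
  expect_error(instability_index("G"), "2 residues")
})

test_that("aliphatic index matches its defining formula", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("GGGG"), 0)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("IILL"), 390)
  # mixed: 50% A + 50% V
  expect_equal(aliphatic_index("AV"), 50 + 2.9 * 50)
})

test_that("atomic composition does condensation arithmetic", {
  g <- atomic_composition("G")
  expect_equal(g$counts, c(C = 2, H = 5, N = 1, O = 2, S = 0))
  gg <- atomic_composition("GG")
  expect_equal(gg$counts, c(C = 4, H = 8, N = 2, O = 3, S = 0))
  expect_equal(sum(gg$percent), 100)
  # backbone nitrogens: N count >= length for any sequence
  set.seed(9)
  for (i in 1:5) {
    s <- paste(sample(cementome:::AA_STANDARD, 30, replace = TRUE),
               collapse = "")
    expect_gte(atomic_composition(s)$counts[["N"]], 30)
  }
})

test_that("calculators agree with the independent reference implementation", {
  panel <- read.delim(test_path("reference-panel.tsv"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(panel), 20)
  for (i in seq_len(nrow(panel))) {
    s <- panel$sequence[i]
    expect_lt(abs(gravy(s) - panel$gravy[i]), 1e-3)
    expect_lt(abs(isoelectric_point(s) - panel$pi[i]), 1e-3)
    expect_lt(abs(as.numeric(instability_index(s)) - panel$instability[i]),
              1e-3)
    expect_lt(abs(aliphatic_index(s) - panel$aliphatic[i]), 1e-3)
  }
})

test_that("ratio screen flags both tails with inclusive boundaries", {
  a <- c(G = 30, A = 10, V = 5, L = 4, Y = 2)
  b <- c(G = 20, A = 10, V = 10, L = 6, Y = 0)
  r <- ratio_screen(a, b)
  got <- setNames(r$flagged, r$residue)
  expect_true(got[["G"]])            # 1.5 exactly: boundary inclusive
  expect_false(got[["A"]])           # ratio 1.0
  expect_true(got[["V"]])            # 0.5 exactly
  expect_false(got[["L"]])           # 0.667: inside the band
  expect_true(is.infinite(r$ratio[r$residue == "Y"]))
  expect_true(got[["Y"]])
})

test_that("group summaries subsample reproducibly and separate Gly classes", {
  ds <- generate_dataset(synthetic_config(n_proteins = 120, seed = 31,
                                          gly_rich_fraction = 0.6))
  groups <- ifelse(ds$truth$seq_class == "gly_rich", "tick_cement", "host_cement")
  s1 <- group_property_summary(ds$sequences, groups, seed = 7)
  s2 <- group_property_summary(ds$sequences, groups, seed = 7)
  expect_identical(s1, s2)
  expect_gt(s1$aa_percent["tick_cement", "G"],
            s1$aa_percent["host_cement", "G"])
  expect_gt(s1$aa_percent["tick_cement", "G"], 25)
  # single-protein group equals that protein's own profile
  one <- group_property_summary(ds$sequences[1], groups[1])
  expect_equal(one$profiles$gravy, gravy(ds$sequences[[1]]))
  # subsample caps group size deterministically
  big <- group_property_summary(ds$sequences, groups,
                                subsample = c(tick_cement = 10), seed = 3)
  expect_equal(big$profiles$n[big$profiles$group == "tick_cement"], 10)
})
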