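# KLS construction, evidence augmentation, final scores, per-site filter,
# kinase-substrate and pathway aggregation.

test_that("scoring constants behave exactly as defined", {
  expect_equal(base_kls(1.0, -3), 3)
  expect_equal(base_kls(0, 5), 0)
  expect_equal(base_kls(0.8, 2.5), 2)

  expect_equal(add_psp_evidence(2.0, in_vitro = 1), 2.5)
  expect_equal(add_psp_evidence(2.0, in_vitro = 1, in_vivo = 1), 3.0)
  expect_equal(add_psp_evidence(2.0), 2.0)

  expect_equal(add_biogrid(0, 1), 0.5)
  expect_equal(add_biogrid(0, 3), 0.75)
  expect_equal(add_biogrid(1.2, 0), 1.2)
  expect_error(add_biogrid(1, -1), class = "phosnet_validation_error")

  expect_equal(final_interaction_score(2.5, 2), 5)
  expect_equal(final_interaction_score(2.5, 0), 0)
  expect_equal(final_interaction_score(2.5, -2),
               -final_interaction_score(2.5, 2))
})

test_that("the full KLS chain reproduces the hand-computed spreadsheet", {
  fx <- spreadsheet_fixture()
  got <- interaction_scores(fx$top_scores, fx$activities, fx$regulated,
                            fx$evidence, fx$interactions, run_config())
  expect_equal(nrow(got), nrow(fx$expected))
  key <- paste(got$site, got$kinase)
  ekey <- paste(fx$expected$site, fx$expected$kinase)
  expect_setequal(key, ekey)
  expect_equal(got$final_score[match(ekey, key)], fx$expected$final_score)
  # increments decompose exactly: psp in {0, .5, 1}, biogrid in [0, 1)
  expect_true(all(got$psp_increment %in% c(0, 0.5, 1)))
  expect_true(all(got$biogrid_increment >= 0 & got$biogrid_increment < 1))
  expect_equal(got$augmented_kls,
               got$base_kls + got$psp_increment + got$biogrid_increment)
  # sign of final score matches the regulation score
  expect_equal(sign(got$final_score[got$augmented_kls > 0]),
               sign(got$regulation_score[got$augmented_kls > 0]))
})

test_that("site-level evidence takes precedence over protein-level", {
  fx <- spreadsheet_fixture()
  got <- interaction_scores(fx$top_scores, fx$activities, fx$regulated,
                            fx$evidence, fx$interactions, run_config())
  # K1-A has both: site record (s1, both levels) and protein record (in vitro)
  expect_equal(got$psp_increment[got$site == "s1" & got$kinase == "K1"], 1.0)
  expect_equal(got$psp_increment[got$site == "s2" & got$kinase == "K1"], 0.5)
})

test_that("pairs with evidence strictly outrank identical pairs without", {
  base <- data.frame(site = c("sA", "sB"), protein = c("PA", "PB"),
                     kinase = "K1", raw = 1, percentile = 80)
  act <- data.frame(kinase = "K1", activity = 2)
  reg <- data.frame(site = c("sA", "sB"), protein = c("PA", "PB"),
                    position = c(10L, 10L), comparison = "cmb",
                    direction = "up", regulation_score = c(1.5, 1.5))
  ev <- data.frame(kinase = "K1", protein = "PA", position = NA,
                   in_vitro = 1L, in_vivo = 1L)
  got <- interaction_scores(base, act, reg, ev, NULL, run_config())
  expect_gt(got$final_score[got$protein == "PA"],
            got$final_score[got$protein == "PB"])
})

test_that("per-site top-k filter ranks by |final| with documented
           tie-breaks", {
  sc <- data.frame(site = "s1", kinase = sprintf("K%02d", 1:10),
                   augmented_kls = 1:10 / 10,
                   final_score = c(5, -4, 3, -2.5, 2, 1, 0.5, 0.4, 0.3, 0.2))
  top <- filter_top_per_site(sc, 3)
  expect_equal(top$kinase, c("K01", "K02", "K03"))
  # |final| tie at rank 3 (K03 vs K04): higher augmented KLS wins
  sc$final_score[4] <- -3
  sc$augmented_kls[4] <- 0.9
  top <- filter_top_per_site(sc, 3)
  expect_equal(top$kinase[3], "K04")
  expect_equal(nrow(filter_top_per_site(sc[1:2, ], 3)), 2L)
})

test_that("kinase-substrate scores are signed sums over retained sites", {
  fx <- spreadsheet_fixture()
  got <- interaction_scores(fx$top_scores, fx$activities, fx$regulated,
                            fx$evidence, fx$interactions, run_config())
  ks <- kinase_substrate_scores(got)
  key <- paste(ks$kinase, ks$protein)
  ekey <- paste(fx$expected_ks$kinase, fx$expected_ks$protein)
  expect_setequal(key, ekey)
  expect_equal(ks$score[match(ekey, key)], fx$expected_ks$score)
  # pair with no retained site absent (K3 was dropped on s1, s3, s4)
  expect_false("K3 B" %in% key)
  expect_false("K3 C" %in% key)
})

test_that("pathway interaction scores follow the sum x fraction rule", {
  fx <- spreadsheet_fixture()
  got <- interaction_scores(fx$top_scores, fx$activities, fx$regulated,
                            fx$evidence, fx$interactions, run_config())
  expect_message(
    pw <- pathway_interaction_scores(fx$gene_sets, got, fx$detected,
                                     run_config()),
    "no detected member")
  expect_setequal(pw$pathway, fx$expected_pathways$pathway)
  expect_equal(pw$pathway_score[match(fx$expected_pathways$pathway,
                                      pw$pathway)],
               fx$expected_pathways$pathway_score)
  # invariant to member duplication and ordering
  shuffled <- lapply(fx$gene_sets, function(s) rep(rev(s), 2))
  pw2 <- suppressMessages(
    pathway_interaction_scores(shuffled, got, fx$detected, run_config()))
  expect_equal(pw2$pathway_score, pw$pathway_score)
  # percent convention rescales by exactly 100
  pw3 <- suppressMessages(pathway_interaction_scores(
    fx$gene_sets, got, fx$detected,
    run_config(pathway_fraction_scale = "percent")))
  expect_equal(pw3$pathway_score, pw$pathway_score * 100)
})

test_that("network carries weights, directions and essentiality flags", {
  fx <- spreadsheet_fixture()
  got <- interaction_scores(fx$top_scores, fx$activities, fx$regulated,
                            fx$evidence, fx$interactions, run_config())
  ks <- kinase_substrate_scores(got)
  dep <- data.frame(gene = c("A", "B", "C", "D"),
                    chronos = c(-0.7, 0.2, -0.5, 0.4))
  g <- build_network(ks, dep, run_config())
  expect_equal(igraph::vcount(g), 4L + 4L)
  expect_equal(igraph::ecount(g), nrow(ks))
  expect_true(igraph::V(g)["A"]$essential)
  expect_true(igraph::V(g)["C"]$essential)
  expect_false(igraph::V(g)["B"]$essential)
  ed <- igraph::as_data_frame(g)
  expect_equal(ed$direction, ifelse(ed$weight >= 0, "up", "down"))
})
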