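# Consensus matchers, PSSM scoring, percentile ranking, top-k filter.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

test_that("ROCK matcher follows the basic-residue consensus", {
  expect_true(match_rock_motif(winmake(m2 = "R", a0 = "S")))   # bXpS
  expect_true(match_rock_motif(winmake(m3 = "K", a0 = "T")))   # bXXpT
  expect_false(match_rock_motif(winmake(a0 = "S")))            # nothing basic
  expect_false(match_rock_motif(winmake(m2 = "H", a0 = "S")))  # H not ROCK-basic
  expect_message(v <- match_rock_motif(winmake(m2 = "R", a0 = "Y")),
                 "Y acceptor")
  expect_false(v)
  # pads never match
  expect_false(match_rock_motif(paste0("___", "_", "_", "S", "AAAA")))
})

test_that("AMPK matcher distinguishes strict and relaxed consensus", {
  w <- "VRKGASAAAL"  # phi at -5, basic at -4/-3, phi at +4
  expect_true(match_ampk_motif(w, strict = TRUE))
  w2 <- "GRKGASAAAL"  # phi at -5 lost
  expect_false(match_ampk_motif(w2, strict = TRUE))
  expect_true(match_ampk_motif(w2, strict = FALSE))  # phi at +4, basic at -3
  allA <- winmake()
  expect_false(match_ampk_motif(allA, strict = TRUE))
  expect_false(match_ampk_motif(allA, strict = FALSE))
})

test_that("matchers agree with a position-by-position rule oracle on all
           20^4 constrained windows", {
  hydro <- c("M", "L", "I", "F", "V"); basic3 <- c("R", "K", "H")
  grid <- expand.grid(m5 = AA, m4 = AA, m3 = AA, p4 = AA,
                      stringsAsFactors = FALSE)
  w <- paste0(grid$m5, grid$m4, grid$m3, "AA", "S", "AAA", grid$p4)
  strict_oracle <- grid$m5 %in% hydro & grid$m4 %in% basic3 &
    grid$m3 %in% basic3 & grid$p4 %in% hydro
  relaxed_oracle <- (grid$m5 %in% hydro | grid$p4 %in% hydro) &
    grid$m3 %in% basic3
  expect_identical(match_ampk_motif(w, strict = TRUE), strict_oracle)
  expect_identical(match_ampk_motif(w, strict = FALSE), relaxed_oracle)

  grid2 <- expand.grid(m3 = AA, m2 = AA, stringsAsFactors = FALSE)
  w2 <- paste0("AA", grid2$m3, grid2$m2, "A", "T", "AAAA")
  rock_oracle <- grid2$m2 %in% c("R", "K") | grid2$m3 %in% c("R", "K")
  expect_identical(match_rock_motif(w2), rock_oracle)
})

test_that("raw score is the hand-summed log-odds over non-padded positions", {
  m <- toy_pssm(list(list("-3", "R", 1.5), list("-1", "A", 0.5),
                     list("2", "K", -0.7)))
  model <- kinase_model("T1", pssm = m)
  w <- winmake(m3 = "R", m1 = "A", p2 = "K")
  expect_equal(score_windows(w, model), 1.5 + 0.5 - 0.7)
  # padding removes a contribution
  w_pad <- paste0("__", "R", "AA", "S", "AK", "AA")
  expect_equal(score_windows(w_pad, model), 1.5 + 0.5 - 0.7)
  m2 <- toy_pssm(list(list("-5", "A", 0.8), list("-3", "R", 1.5)))
  model2 <- kinase_model("T2", pssm = m2)
  expect_lt(score_windows(paste0("__RAASAAAA", ""), model2),
            score_windows("AARAASAAAA", model2))
  # acceptor preference enters as log2(pref / 0.5)
  model3 <- kinase_model("T3", pssm = toy_pssm(),
                         acceptor_pref = c(S = 0.8, T = 0.2))
  expect_equal(score_windows(winmake(a0 = "S"), model3), log2(0.8 / 0.5))
  expect_equal(score_windows(winmake(a0 = "T"), model3), log2(0.2 / 0.5))
  expect_error(score_windows(winmake(a0 = "Y"), model3),
               class = "phosnet_validation_error")
})

test_that("empirical percentile uses the midpoint rule and is monotone", {
  bg <- c(1, 2, 2, 3)
  expect_equal(empirical_percentile(0, bg), 0)
  expect_equal(empirical_percentile(1, bg), 12.5)
  expect_equal(empirical_percentile(2, bg), 50)     # 1 below + half of 2 ties
  expect_equal(empirical_percentile(4, bg), 100)
  x <- sort(rnorm(50))
  p <- empirical_percentile(x, rnorm(200))
  expect_true(all(diff(p) >= 0))
  expect_equal(empirical_percentile(c(1.5, 1.5), bg),
               rep(empirical_percentile(1.5, bg), 2))
})

test_that("a window matching the model's best residues tops an alien
           background", {
  m <- toy_pssm(list(list("-3", "R", 2), list("-2", "K", 2), list("1", "L", 2)))
  model <- kinase_model("T1", pssm = m)
  best <- winmake(m3 = "R", m2 = "K", p1 = "L")
  others <- replicate(50, winmake(m3 = "D", m2 = "D", p1 = "D"))
  model <- set_background(model, windows = others)
  res <- score_site(best, model)
  expect_equal(res$percentile, 100)
  expect_equal(res$raw, 6)
})

test_that("top_kinases_for_site retains k kinases with documented
           tie-breaks", {
  scores <- data.frame(site = "s1", protein = "P",
                       kinase = sprintf("K%02d", 1:10),
                       raw = c(10:2, 2.5),
                       percentile = c(100, 90, 80, 70, 60, 50, 40, 30, 20, 20))
  top <- top_kinases_for_site(scores, k = 25)
  expect_equal(nrow(top), 10L)  # min rule
  top3 <- top_kinases_for_site(scores, k = 3)
  expect_equal(top3$kinase, c("K01", "K02", "K03"))
  # K09 and K10 tie at percentile 20; K10 has higher raw (2.5 > 2)
  top9 <- top_kinases_for_site(scores, k = 9)
  expect_true("K10" %in% top9$kinase)
  expect_false("K09" %in% top9$kinase)
  # full tie resolved lexicographically
  tie <- data.frame(site = "s1", protein = "P", kinase = c("KB", "KA"),
                    raw = c(1, 1), percentile = c(50, 50))
  expect_equal(top_kinases_for_site(tie, k = 1)$kinase, "KA")
  expect_equal(nrow(top_kinases_for_site(scores[0, ], k = 3)), 0L)
})

test_that("score_phosphosites percentile-ranks against the dataset-internal
           background and drops tyrosine sites", {
  lib <- generate_kinase_library(3, seed = 2)
  df <- data.frame(protein = c("P1", "P2", "P3"),
                   position = c(1L, 2L, 3L) * 10L,
                   residue = c("S", "T", "Y"),
                   window = c("VRKGASAAAL", "AAAAATAAAA", "AAAAAYAAAA"),
                   comparison = "c", log2fc = 0, adj_p = 0.5)
  sites <- validate_phosphosite_table(df)
  expect_message(sc <- score_phosphosites(sites, lib), "tyrosine")
  expect_equal(nrow(sc), 2L * 3L)
  expect_true(all(sc$percentile >= 0 & sc$percentile <= 100))
  # AMPK-consensus window outranks the plain window for the AMPK-like model
  am <- sc[sc$kinase == "AMPK_SYN", ]
  expect_gt(am$percentile[am$site == "P1_S10"],
            am$percentile[am$site == "P2_T20"])
})
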