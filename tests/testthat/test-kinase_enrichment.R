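# Contingency construction, one-sided Fisher, BH, frequency factors and
# relative kinase activities.

test_that("contingency tables count membership in foreground and background", {
  fg <- sprintf("f%02d", 1:10)
  bg <- sprintf("b%02d", 1:90)
  members <- c(fg[1:4], bg[1:9])
  tab <- build_contingency(members, fg, bg)
  expect_equal(unname(tab), matrix(c(4, 6, 9, 81), 2, byrow = TRUE))
  # kinase in no set
  tab0 <- build_contingency(character(0), fg, bg)
  expect_equal(unname(tab0), matrix(c(0, 10, 0, 90), 2, byrow = TRUE))
  expect_error(build_contingency(members, fg, character(0)),
               class = "phosnet_validation_error")
  expect_error(build_contingency(members, fg, fg[1]),
               class = "phosnet_validation_error")
})

test_that("one-sided Fisher equals exhaustive hypergeometric enumeration", {
  # zero foreground hits: the upper tail covers the whole support
  expect_equal(fisher_one_sided(matrix(c(0, 7, 3, 12), 2, byrow = TRUE)), 1)
  # perfect separation: 1 / C(10, 5)
  expect_equal(fisher_one_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               1 / choose(10, 5))
  expect_equal(fisher_one_sided(matrix(c(2, 8, 2, 88), 2, byrow = TRUE)),
               oracle_hyper_upper(2, m = 4, n = 96, k = 10))
  expect_error(fisher_one_sided(matrix(c(-1, 2, 3, 4), 2)),
               class = "phosnet_validation_error")
})

test_that("Fisher matches the enumeration oracle across a dense grid of
           small tables", {
  set.seed(42)
  for (total in c(4, 9, 17, 30, 45, 60)) {
    for (rep in 1:40) {
      k <- sample1(1:(total - 1))            # foreground size
      m <- sample1(0:total)                  # total hits
      x <- sample1(max(0, k + m - total):min(k, m))
      tab <- matrix(c(x, k - x, m - x, total - k - (m - x)), 2, byrow = TRUE)
      expect_equal(fisher_one_sided(tab),
                   oracle_hyper_upper(x, m, total - m, k), tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches hand-stepped values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "phosnet_validation_error")
})

test_that("frequency factor is the log2 rate ratio with Haldane handling", {
  tab <- matrix(c(4, 6, 9, 81), 2, byrow = TRUE)   # 0.4 vs 0.1
  expect_equal(frequency_factor(tab), 2)
  expect_equal(frequency_factor(matrix(c(5, 5, 50, 50), 2, byrow = TRUE)), 0)
  zf <- frequency_factor(matrix(c(3, 7, 0, 90), 2, byrow = TRUE))
  expect_true(is.finite(zf))
  expect_equal(zf, log2((3.5 / 11) / (0.5 / 91)))
})

enrich_fixture <- function() {
  # 6 sites; kinase KA is in the top sets of the 3 up sites only
  called <- data.frame(
    site = paste0("s", 1:6), protein = paste0("P", 1:6),
    comparison = "cmb",
    direction = c("up", "up", "up", "down", "ns", "ns"))
  top <- rbind(
    data.frame(site = paste0("s", 1:3), protein = paste0("P", 1:3),
               kinase = "KA", raw = 1, percentile = 99),
    data.frame(site = paste0("s", c(1, 4, 5, 6)),
               protein = paste0("P", c(1, 4, 5, 6)),
               kinase = "KB", raw = 1, percentile = 80))
  list(called = called, top = top)
}

test_that("kinase_enrichment assembles counts, p and BH family correctly", {
  fx <- enrich_fixture()
  enr <- kinase_enrichment(fx$top, fx$called)
  expect_equal(nrow(enr), 4L)  # 2 kinases x 2 directions
  ka_up <- enr[enr$kinase == "KA" & enr$direction == "up", ]
  expect_equal(ka_up$fg_hits, 3L)
  expect_equal(ka_up$fg_size, 3L)
  expect_equal(ka_up$bg_hits, 0L)
  expect_equal(ka_up$p, oracle_hyper_upper(3, 3, 3, 3))
  testable_p <- enr$p[enr$testable]
  expect_equal(enr$adj_p[enr$testable], oracle_bh(testable_p))
})

test_that("directions with empty foreground are untestable and excluded
           from the BH family", {
  fx <- enrich_fixture()
  fx$called$direction[fx$called$direction == "down"] <- "ns"
  enr <- kinase_enrichment(fx$top, fx$called)
  expect_false(any(enr$testable[enr$direction == "down"]))
  expect_true(all(is.na(enr$adj_p[enr$direction == "down"])))
  expect_equal(enr$adj_p[enr$testable],
               oracle_bh(enr$p[enr$testable]))
})

test_that("relative activity picks the most significant direction with the
           documented signs", {
  enr <- data.frame(
    kinase = rep(c("KA", "KB", "KC"), each = 2),
    comparison = "cmb",
    direction = rep(c("up", "down"), 3),
    fg_hits = 1L, fg_size = 10L, bg_hits = 1L, bg_size = 90L,
    frequency_factor = c(3, 0.5, 0.2, 2, 1, 1),
    p = c(0.001, 0.5, 0.9, 0.01, 0.5, 0.5),
    testable = TRUE)
  enr$adj_p <- c(0.006, 0.6, 0.95, 0.03, 0.6, 0.6)
  act <- relative_kinase_activity(enr, run_config())
  # KA: up direction, smallest adj p of family -> weight 1 -> activity 3
  expect_equal(act$activity[act$kinase == "KA"], 3)
  expect_equal(act$direction[act$kinase == "KB"], "down")
  expect_lt(act$activity[act$kinase == "KB"], 0)
  # KC ties across directions: |ff| equal -> up preferred
  expect_equal(act$direction[act$kinase == "KC"], "up")
  # kinase with the largest adj p in its chosen direction gets weight 0
  worst <- act$kinase[which.max(act$adj_p)]
  expect_equal(act$activity[act$kinase == worst], 0)
})

test_that("activity is invariant under site relabeling", {
  fx <- enrich_fixture()
  act1 <- relative_kinase_activity(kinase_enrichment(fx$top, fx$called))
  perm <- sample(nrow(fx$called))
  act2 <- relative_kinase_activity(
    kinase_enrichment(fx$top[sample(nrow(fx$top)), ], fx$called[perm, ]))
  expect_equal(act1, act2)
})
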