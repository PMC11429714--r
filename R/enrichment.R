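# Kinase-motif enrichment: contingency construction, one-sided Fisher exact
# tests, BH correction, log2 frequency factors, and signed relative kinase
# activities.

#' Build the 2x2 contingency table for one kinase
#'
#' Foreground = sites called in one direction for a comparison; background =
#' all other quantified sites of the comparison. A site is a "hit" when the
#' kinase is present in the site's retained top-k kinase set.
#'
#' @param member_sites sites (keys) whose top-k set contains the kinase
#' @param foreground foreground site keys (must be disjoint from background)
#' @param background background site keys (non-foreground quantified sites;
#'   must be non-empty)
#' @return 2x2 integer matrix `[[fg_hits, fg_miss], [bg_hits, bg_miss]]`
#' @export
build_contingency <- function(member_sites, foreground, background) {
  if (length(background) == 0) {
    pn_stop("empty background: foreground cannot be all quantified sites",
            "phosnet_validation_error")
  }
  if (length(intersect(foreground, background)) > 0) {
    pn_stop("foreground and background sets must be disjoint",
            "phosnet_validation_error")
  }
  fg_hits <- sum(foreground %in% member_sites)
  bg_hits <- sum(background %in% member_sites)
  matrix(c(fg_hits, length(foreground) - fg_hits,
           bg_hits, length(background) - bg_hits),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("fg", "bg"), c("hit", "miss")))
}

#' One-sided Fisher exact test (over-representation)
#'
#' Upper-tail hypergeometric probability of observing at least the foreground
#' hit count: `P(X >= fg_hits)` with `X ~ Hypergeom(hits_total, misses_total,
#' fg_size)`.
#'
#' @param table 2x2 nonnegative integer matrix as from [build_contingency()]
#' @return the one-sided p-value
#' @export
fisher_one_sided <- function(table) {
  if (any(table < 0) || any(table != round(table))) {
    pn_stop("contingency table must hold nonnegative integers",
            "phosnet_validation_error")
  }
  fg_hits <- table[1, 1]
  fg_size <- sum(table[1, ])
  hits <- sum(table[, 1])
  total <- sum(table)
  stats::phyper(fg_hits - 1, m = hits, n = total - hits, k = fg_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; adjusted p is in
#' `[p, 1]`.
#'
#' @param pvalues numeric vector in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    pn_stop("p-values must lie in [0, 1]", "phosnet_validation_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Log2 frequency factor
#'
#' `log2((fg_hits/fg_size) / (bg_hits/bg_size))`, with a Haldane-style +0.5
#' added to all four cells when any cell is zero so the ratio stays finite.
#'
#' @param table 2x2 matrix as from [build_contingency()]
#' @return the log2 frequency factor (finite)
#' @export
frequency_factor <- function(table) {
  if (any(table == 0)) table <- table + 0.5
  fg_rate <- table[1, 1] / sum(table[1, ])
  bg_rate <- table[2, 1] / sum(table[2, ])
  log2(fg_rate / bg_rate)
}

#' Kinase-motif enrichment for one comparison
#'
#' For every kinase and each direction (up, down): builds the contingency
#' table of top-k-membership among called sites versus the remaining
#' quantified sites, computes the one-sided Fisher p and log2 frequency
#' factor, and BH-adjusts p-values over the family of all kinases x both
#' directions of the comparison. Directions with an empty foreground are
#' flagged untestable and excluded from the BH family.
#'
#' @param top_scores retained site x kinase table from
#'   [top_kinases_for_site()]
#' @param called sites data.frame with a `direction` column (from
#'   [call_differential()]), restricted to one comparison
#' @return data.frame with one row per kinase x direction: counts, frequency
#'   factor, `p`, `adj_p`, `testable`
#' @export
kinase_enrichment <- function(top_scores, called) {
  cmp <- unique(called$comparison)
  if (length(cmp) != 1) {
    pn_stop("kinase_enrichment expects sites of a single comparison",
            "phosnet_validation_error")
  }
  scored_sites <- unique(top_scores$site)
  called <- called[called$site %in% scored_sites, ]
  kinases <- sort(unique(top_scores$kinase))
  members <- split(top_scores$site, top_scores$kinase)

  rows <- list()
  for (dir in c("up", "down")) {
    fg <- called$site[called$direction == dir]
    bg <- called$site[called$direction != dir]
    testable <- length(fg) > 0 && length(bg) > 0
    for (kin in kinases) {
      if (testable) {
        tab <- build_contingency(members[[kin]], fg, bg)
        rows[[length(rows) + 1]] <- data.frame(
          kinase = kin, comparison = cmp, direction = dir,
          fg_hits = tab[1, 1], fg_size = sum(tab[1, ]),
          bg_hits = tab[2, 1], bg_size = sum(tab[2, ]),
          frequency_factor = frequency_factor(tab),
          p = fisher_one_sided(tab), testable = TRUE,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          kinase = kin, comparison = cmp, direction = dir,
          fg_hits = 0L, fg_size = length(fg),
          bg_hits = 0L, bg_size = length(bg),
          frequency_factor = NA_real_, p = NA_real_, testable = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$adj_p <- NA_real_
  res$adj_p[res$testable] <- bh_adjust(res$p[res$testable])
  rownames(res) <- NULL
  res
}

#' Signed relative kinase activity
#'
#' For each kinase, the most significant enrichment direction is chosen
#' (smaller adjusted p; ties by larger |frequency factor|, then up before
#' down). The activity is the product of the min-max normalized significance
#' (over the chosen adjusted p-values of all kinases of the comparison) and
#' the chosen direction's frequency factor, with a positive sign for up and a
#' negative sign for down (the frequency factor's own sign is preserved
#' within the direction). Kinases untestable in both directions are omitted
#' with a message.
#'
#' @param enrichment result of [kinase_enrichment()]
#' @param config a [run_config()] (for the significance transform)
#' @return data.frame with `kinase`, `comparison`, `direction`,
#'   `frequency_factor`, `adj_p`, `activity`
#' @export
relative_kinase_activity <- function(enrichment, config = run_config()) {
  test <- enrichment[enrichment$testable, ]
  dropped <- setdiff(unique(enrichment$kinase), unique(test$kinase))
  if (length(dropped) > 0) {
    message(sprintf("relative_kinase_activity: omitting %d untestable kinase(s)",
                    length(dropped)))
  }
  if (nrow(test) == 0) {
    return(data.frame(kinase = character(0), comparison = character(0),
                      direction = character(0), frequency_factor = numeric(0),
                      adj_p = numeric(0), activity = numeric(0)))
  }
  pick <- lapply(split(test, test$kinase), function(d) {
    ord <- order(d$adj_p, -abs(d$frequency_factor),
                 match(d$direction, c("up", "down")))
    d[ord[1], ]
  })
  chosen <- do.call(rbind, pick)
  w <- significance_weight(chosen$adj_p, config$significance_transform)
  sign_dir <- ifelse(chosen$direction == "up", 1, -1)
  res <- data.frame(kinase = chosen$kinase, comparison = chosen$comparison,
                    direction = chosen$direction,
                    frequency_factor = chosen$frequency_factor,
                    adj_p = chosen$adj_p,
                    activity = sign_dir * w * chosen$frequency_factor,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$kinase), ]
}
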