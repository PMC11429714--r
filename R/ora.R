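# Gene-set overrepresentation analysis (one-tailed hypergeometric, BH) and
# gene-dependency partitioning.

#' One-tailed hypergeometric overrepresentation analysis
#'
#' For every gene set: `bg_hits` = members present in the background,
#' `fg_hits` = members present in the foreground. Sets with fewer than
#' `min_bg` background members are skipped and excluded from the BH family.
#' The p-value is the upper-tail hypergeometric probability
#' `P(X >= fg_hits)` of drawing `fg_hits` set members in `|foreground|`
#' draws from the background; the enrichment ratio is
#' `(fg_hits/|fg|) / (bg_hits/|bg|)`.
#'
#' The foreground must be a subset of the background (the background is the
#' universe, e.g. all detected phosphoproteins).
#'
#' @param foreground character vector of genes of interest
#' @param background character vector, the universe (contains `foreground`)
#' @param gene_sets named list of character vectors (see [read_gmt()])
#' @param min_bg minimum background representation for a set to be tested
#' @return data.frame with one row per tested set: `gene_set`, `fg_hits`,
#'   `fg_size`, `bg_hits`, `bg_size`, `enrichment_ratio`, `p`, `adj_p`;
#'   skipped sets are reported in the `"skipped"` attribute
#' @export
hypergeom_ora <- function(foreground, background, gene_sets, min_bg = 3L) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    pn_stop("foreground must be a subset of the background",
            "phosnet_validation_error")
  }
  n_bg <- length(background)
  n_fg <- length(foreground)
  rows <- list()
  skipped <- character(0)
  for (name in names(gene_sets)) {
    members <- unique(gene_sets[[name]])
    bg_hits <- sum(members %in% background)
    if (bg_hits < min_bg) {
      skipped <- c(skipped, name)
      next
    }
    fg_hits <- sum(members %in% foreground)
    p <- stats::phyper(fg_hits - 1, m = bg_hits, n = n_bg - bg_hits,
                       k = n_fg, lower.tail = FALSE)
    ratio <- if (n_fg == 0) 0 else (fg_hits / n_fg) / (bg_hits / n_bg)
    rows[[length(rows) + 1]] <- data.frame(
      gene_set = name, fg_hits = fg_hits, fg_size = n_fg,
      bg_hits = bg_hits, bg_size = n_bg, enrichment_ratio = ratio,
      p = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    res <- data.frame(gene_set = character(0), fg_hits = integer(0),
                      fg_size = integer(0), bg_hits = integer(0),
                      bg_size = integer(0), enrichment_ratio = numeric(0),
                      p = numeric(0), adj_p = numeric(0))
  } else {
    res <- do.call(rbind, rows)
    res$adj_p <- bh_adjust(res$p)
    rownames(res) <- NULL
  }
  attr(res, "skipped") <- skipped
  res
}

#' Classify gene dependency
#'
#' A gene is `essential` iff its Chronos score is at or below the threshold
#' (boundary inclusive), else `non-essential`.
#'
#' @param score numeric Chronos score(s), finite
#' @param threshold essentiality cutoff (default -0.5)
#' @return character vector in \{"essential", "non-essential"\}
#' @examples
#' classify_dependency(c(-0.6, -0.5, 0.1))
#' @export
classify_dependency <- function(score, threshold = -0.5) {
  if (any(!is.finite(score))) {
    pn_stop("dependency scores must be finite", "phosnet_validation_error")
  }
  ifelse(score <= threshold, "essential", "non-essential")
}

#' Select co-regulated phosphoproteins
#'
#' A co-regulated phosphoprotein carries at least one up- and at least one
#' down-regulated phosphosite in the same treatment comparison.
#'
#' @param called sites data.frame with a `direction` column, one comparison
#' @param class `"co-regulated"` (default), `"up-only"` or `"down-only"`
#' @return character vector of protein identifiers
#' @export
select_phosphoproteins <- function(called,
                                   class = c("co-regulated", "up-only",
                                             "down-only")) {
  class <- match.arg(class)
  up <- unique(called$protein[called$direction == "up"])
  down <- unique(called$protein[called$direction == "down"])
  switch(class,
         "co-regulated" = intersect(up, down),
         "up-only" = setdiff(up, down),
         "down-only" = setdiff(down, up))
}

#' Dependency-partitioned overrepresentation analysis
#'
#' Splits a foreground of phosphoproteins into essential (Chronos <=
#' threshold) and non-essential subsets and runs [hypergeom_ora()] for each
#' against the background of all detected phosphoproteins, BH-adjusting
#' within each family. Genes without a dependency score are excluded from
#' both foregrounds (with a message).
#'
#' @param phosphoproteins foreground proteins (e.g. co-regulated
#'   phosphoproteins from [select_phosphoproteins()])
#' @param dependency dependency data.frame (see [read_dependency_table()])
#' @param gene_sets named list of pathways
#' @param background all detected phosphoproteins
#' @param config a [run_config()]
#' @return list with elements `essential` and `non_essential`, each an ORA
#'   data.frame
#' @export
dependency_partition_ora <- function(phosphoproteins, dependency, gene_sets,
                                     background, config = run_config()) {
  idx <- match(phosphoproteins, dependency$gene)
  unresolved <- phosphoproteins[is.na(idx)]
  if (length(unresolved) > 0) {
    message(sprintf("dependency_partition_ora: %d gene(s) without dependency score dropped",
                    length(unresolved)))
  }
  resolved <- phosphoproteins[!is.na(idx)]
  scores <- dependency$chronos[idx[!is.na(idx)]]
  cls <- classify_dependency(scores, config$chronos_essential_max)
  list(
    essential = hypergeom_ora(resolved[cls == "essential"], background,
                              gene_sets, config$min_background),
    non_essential = hypergeom_ora(resolved[cls == "non-essential"], background,
                                  gene_sets, config$min_background)
  )
}
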