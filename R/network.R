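# Kinase-substrate interaction scoring: KLS construction, curated-evidence
# augmentation, final interaction scores, per-site top-k filtering,
# kinase-substrate and pathway aggregation, and network assembly.

#' Base kinase library score (KLS)
#'
#' `KLS = percentile x |activity|`, with the kinase-phosphosite percentile
#' rescaled from 0-100 to 0-1 so the two factors share scale. Always >= 0.
#'
#' @param percentile kinase-phosphosite percentile on the 0-1 scale
#' @param activity signed relative kinase activity
#' @return the base KLS
#' @examples
#' base_kls(1.0, -3)  # 3
#' @export
base_kls <- function(percentile, activity) {
  percentile * abs(activity)
}

#' Add curated kinase-substrate evidence to a KLS
#'
#' Adds 0.5 per level of evidence (in vitro and in vivo) reported for the
#' kinase-substrate pair; an absent record adds nothing.
#'
#' @param kls numeric KLS value(s)
#' @param in_vitro,in_vivo 0/1 evidence flags (vectors recycled as usual)
#' @return augmented KLS
#' @examples
#' add_psp_evidence(2.0, in_vitro = 1, in_vivo = 0)  # 2.5
#' @export
add_psp_evidence <- function(kls, in_vitro = 0, in_vivo = 0) {
  kls + 0.5 * (in_vitro > 0) + 0.5 * (in_vivo > 0)
}

#' Add the interaction reference-count score to a KLS
#'
#' Adds `n / (n + 1)` where `n` is the number of references reporting the
#' kinase-substrate interaction (`n = 0`, no interaction record, adds 0).
#'
#' @param kls numeric KLS value(s)
#' @param n_refs nonnegative integer reference count(s)
#' @return augmented KLS
#' @examples
#' add_biogrid(2.5, 3)  # 3.25
#' @export
add_biogrid <- function(kls, n_refs) {
  if (any(n_refs < 0)) {
    pn_stop("reference counts must be >= 0", "phosnet_validation_error")
  }
  kls + n_refs / (n_refs + 1)
}

#' Final kinase-phosphosite interaction score
#'
#' The product of the augmented KLS and the site's signed relative
#' differential-regulation score; it carries the regulation score's sign.
#'
#' @param augmented_kls augmented KLS value(s)
#' @param regulation_score signed regulation score(s) from
#'   [regulation_scores()]
#' @return signed final interaction score
#' @export
final_interaction_score <- function(augmented_kls, regulation_score) {
  augmented_kls * regulation_score
}

#' Per-site kinase interaction scores
#'
#' Assembles, for every differentially expressed phosphosite of a comparison,
#' the full scoring chain over its retained top-k kinases:
#' `base KLS -> + evidence increments -> + reference-count increment ->
#' x regulation score`, then keeps the top `k` kinases per site ranked by
#' |final score| (ties by augmented KLS, then kinase name).
#'
#' Evidence resolution prefers a site-level record (matching protein and
#' position) over a protein-level record (position `NA`); reference counts
#' are matched at the kinase-protein level.
#'
#' @param top_scores retained site x kinase table from
#'   [top_kinases_for_site()] (percentiles on the 0-100 scale)
#' @param activities result of [relative_kinase_activity()] for the same
#'   comparison
#' @param regulated sites data.frame with `direction` and `regulation_score`
#'   (from [regulation_scores()]), restricted to one comparison
#' @param evidence curated evidence data.frame (see [read_evidence_table()]),
#'   or `NULL`
#' @param interactions reference-count data.frame (see
#'   [read_interaction_table()]), or `NULL`
#' @param config a [run_config()]
#' @return data.frame with one row per retained kinase x site: `site`,
#'   `protein`, `position`, `kinase`, `comparison`, `direction`, `percentile`
#'   (0-1), `base_kls`, `psp_increment`, `biogrid_increment`, `augmented_kls`,
#'   `regulation_score`, `final_score`
#' @export
interaction_scores <- function(top_scores, activities, regulated,
                               evidence = NULL, interactions = NULL,
                               config = run_config()) {
  cmp <- unique(regulated$comparison)
  if (length(cmp) != 1) {
    pn_stop("interaction_scores expects sites of a single comparison",
            "phosnet_validation_error")
  }
  de <- regulated[regulated$direction %in% c("up", "down"), ]
  if (nrow(de) == 0) {
    return(empty_interaction_scores())
  }
  cand <- merge(top_scores,
                de[, c("site", "position", "direction", "regulation_score")],
                by = "site")
  cand <- merge(cand, activities[, c("kinase", "activity")], by = "kinase")
  if (nrow(cand) == 0) {
    return(empty_interaction_scores())
  }
  cand$comparison <- cmp
  cand$percentile <- cand$percentile / 100   # rescale for products
  cand$base_kls <- base_kls(cand$percentile, cand$activity)

  cand$psp_increment <- psp_increment_for(cand, evidence)
  nref <- biogrid_refs_for(cand, interactions)
  cand$biogrid_increment <- nref / (nref + 1)
  cand$augmented_kls <- cand$base_kls + cand$psp_increment + cand$biogrid_increment
  cand$final_score <- final_interaction_score(cand$augmented_kls,
                                              cand$regulation_score)

  filter_top_per_site(cand, config$top_interactions_per_site)
}

empty_interaction_scores <- function() {
  data.frame(site = character(0), protein = character(0),
             position = integer(0), kinase = character(0),
             comparison = character(0), direction = character(0),
             percentile = numeric(0), base_kls = numeric(0),
             psp_increment = numeric(0), biogrid_increment = numeric(0),
             augmented_kls = numeric(0), regulation_score = numeric(0),
             final_score = numeric(0))
}

# Per-row PSP evidence increment, preferring site-level over protein-level
# records.
psp_increment_for <- function(cand, evidence) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(rep(0, nrow(cand)))
  }
  ev <- evidence
  ev$increment <- 0.5 * (ev$in_vitro > 0) + 0.5 * (ev$in_vivo > 0)
  site_ev <- ev[!is.na(ev$position), ]
  prot_ev <- ev[is.na(ev$position), ]
  inc <- rep(0, nrow(cand))
  if (nrow(prot_ev) > 0) {
    key <- paste(cand$kinase, cand$protein, sep = "\r")
    pkey <- paste(prot_ev$kinase, prot_ev$protein, sep = "\r")
    idx <- match(key, pkey)
    inc[!is.na(idx)] <- prot_ev$increment[idx[!is.na(idx)]]
  }
  if (nrow(site_ev) > 0) {
    key <- paste(cand$kinase, cand$protein, cand$position, sep = "\r")
    skey <- paste(site_ev$kinase, site_ev$protein, site_ev$position, sep = "\r")
    idx <- match(key, skey)
    inc[!is.na(idx)] <- site_ev$increment[idx[!is.na(idx)]]
  }
  inc
}

biogrid_refs_for <- function(cand, interactions) {
  if (is.null(interactions) || nrow(interactions) == 0) {
    return(rep(0L, nrow(cand)))
  }
  key <- paste(cand$kinase, cand$protein, sep = "\r")
  ikey <- paste(interactions$kinase, interactions$protein, sep = "\r")
  idx <- match(key, ikey)
  ifelse(is.na(idx), 0L, interactions$n_refs[idx])
}

#' Retain the top-k interaction scores per phosphosite
#'
#' Ranks by |final score|; ties are broken by augmented KLS, then kinase
#' name. At most `k` kinases are retained per site.
#'
#' @param scores interaction-score data.frame (needs `site`, `kinase`,
#'   `final_score`, `augmented_kls`)
#' @param k maximum kinases per site (default 3)
#' @return the retained subset
#' @export
filter_top_per_site <- function(scores, k = 3L) {
  if (k < 1) pn_stop("k must be >= 1", "phosnet_validation_error")
  if (nrow(scores) == 0) return(scores)
  ord <- order(scores$site, -abs(scores$final_score),
               -scores$augmented_kls, scores$kinase)
  sorted <- scores[ord, ]
  keep <- ave(seq_len(nrow(sorted)), sorted$site, FUN = seq_along) <= k
  res <- sorted[keep, ]
  rownames(res) <- NULL
  res
}

#' Kinase-substrate interaction scores
#'
#' The final kinase interaction score for a kinase-substrate pair is the sum
#' of the (site-filtered) final interaction scores over the substrate's
#' phosphosites. Pairs with no retained site are absent from the output.
#'
#' @param scores site-filtered interaction scores from [interaction_scores()]
#' @return data.frame with `kinase`, `protein`, `comparison`, `score`,
#'   `n_sites`
#' @export
kinase_substrate_scores <- function(scores) {
  if (nrow(scores) == 0) {
    return(data.frame(kinase = character(0), protein = character(0),
                      comparison = character(0), score = numeric(0),
                      n_sites = integer(0)))
  }
  agg <- aggregate(final_score ~ kinase + protein + comparison, data = scores,
                   FUN = sum)
  cnt <- aggregate(final_score ~ kinase + protein + comparison, data = scores,
                   FUN = length)
  names(agg)[4] <- "score"
  agg$n_sites <- cnt$final_score
  agg[order(agg$kinase, agg$protein), ]
}

#' Pathway interaction scores
#'
#' For every pathway: the product of (a) the sum over member phosphoproteins
#' of their interaction-score sums and (b) the fraction of member
#' phosphoproteins that carry at least one interaction score. Membership is
#' restricted to detected phosphoproteins; a pathway with no detected member
#' is omitted with a message. The fraction is on the 0-1 scale by default
#' (`pathway_fraction_scale = "percent"` multiplies by 100). Duplicate
#' members and member order do not affect the score.
#'
#' @param gene_sets named list of pathways (character vectors of proteins)
#' @param scores site-filtered interaction scores from [interaction_scores()]
#' @param detected_proteins character vector of all detected phosphoproteins
#' @param config a [run_config()]
#' @return data.frame with `pathway`, `n_members`, `n_scored`, `score_sum`,
#'   `fraction_scored`, `pathway_score`
#' @export
pathway_interaction_scores <- function(gene_sets, scores, detected_proteins,
                                       config = run_config()) {
  protein_sum <- if (nrow(scores) > 0) {
    tapply(scores$final_score, scores$protein, sum)
  } else {
    numeric(0)
  }
  scale <- if (config$pathway_fraction_scale == "percent") 100 else 1
  rows <- list()
  for (name in names(gene_sets)) {
    members <- intersect(unique(gene_sets[[name]]), detected_proteins)
    if (length(members) == 0) {
      message(sprintf("pathway_interaction_scores: '%s' has no detected member; omitted",
                      name))
      next
    }
    scored <- intersect(members, names(protein_sum))
    frac <- length(scored) / length(members)
    ssum <- sum(protein_sum[scored])
    rows[[length(rows) + 1]] <- data.frame(
      pathway = name, n_members = length(members), n_scored = length(scored),
      score_sum = ssum, fraction_scored = frac,
      pathway_score = ssum * frac * scale, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(pathway = character(0), n_members = integer(0),
                      n_scored = integer(0), score_sum = numeric(0),
                      fraction_scored = numeric(0), pathway_score = numeric(0)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Build the kinase-substrate network
#'
#' Assembles a directed bipartite graph with kinase and substrate nodes and
#' one edge per kinase-substrate score. Edge attributes: `weight` (the
#' kinase-substrate interaction score), `direction` (up/down by score sign),
#' `n_sites`. Substrate nodes carry their Chronos score and an `essential`
#' flag (score <= `chronos_essential_max`).
#'
#' @param ks_scores result of [kinase_substrate_scores()]
#' @param dependency optional dependency data.frame (see
#'   [read_dependency_table()])
#' @param config a [run_config()]
#' @return an `igraph` object
#' @export
build_network <- function(ks_scores, dependency = NULL,
                          config = run_config()) {
  kinases <- unique(ks_scores$kinase)
  substrates <- setdiff(unique(ks_scores$protein), kinases)
  nodes <- data.frame(name = c(kinases, substrates),
                      type = c(rep("kinase", length(kinases)),
                               rep("substrate", length(substrates))),
                      stringsAsFactors = FALSE)
  nodes$chronos <- NA_real_
  nodes$essential <- FALSE
  if (!is.null(dependency)) {
    idx <- match(nodes$name, dependency$gene)
    nodes$chronos <- dependency$chronos[idx]
    nodes$essential <- !is.na(nodes$chronos) &
      nodes$chronos <= config$chronos_essential_max
  }
  edges <- data.frame(from = ks_scores$kinase, to = ks_scores$protein,
                      weight = ks_scores$score,
                      direction = ifelse(ks_scores$score >= 0, "up", "down"),
                      n_sites = ks_scores$n_sites, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}
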