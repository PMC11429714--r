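# Differential calling and the signed phosphosite differential-regulation
# score that enters the final interaction score.

#' Call differentially regulated phosphosites
#'
#' A site is called `up` if log2FC >= `log2fc_min` and adjusted p <=
#' `adjp_max`; `down` if log2FC <= -`log2fc_min` and adjusted p <=
#' `adjp_max`; otherwise `ns`. Boundary values are inclusive.
#'
#' @param sites phosphosite data.frame (long format; see
#'   [read_phosphosite_table()])
#' @param config a [run_config()]
#' @return `sites` with a `direction` column in \{"up", "down", "ns"\}
#' @examples
#' df <- data.frame(protein = "P1", position = 10, residue = "S",
#'                  window = "AAAAASAAAA", comparison = "cmb",
#'                  log2fc = c(1.5, -2, 0), adj_p = c(0.05, 0.2, 0.5))
#' call_differential(validate_phosphosite_table(df), run_config())$direction
#' @export
call_differential <- function(sites, config = run_config()) {
  sig <- sites$adj_p <= config$adjp_max
  sites$direction <- ifelse(sig & sites$log2fc >= config$log2fc_min, "up",
                     ifelse(sig & sites$log2fc <= -config$log2fc_min, "down",
                            "ns"))
  sites
}

#' Min-max normalize to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant input maps to all zeros (documented
#' degenerate rule).
#'
#' @param values non-empty finite numeric vector
#' @return numeric vector in \[0, 1\]
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) {
    pn_stop("minmax_normalize: empty input", "phosnet_validation_error")
  }
  if (any(!is.finite(values))) {
    pn_stop("minmax_normalize: non-finite input", "phosnet_validation_error")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

# Significance weight used in regulation and activity scores: a value in
# [0, 1] that is largest for the most significant adjusted p of the family.
significance_weight <- function(adj_p, transform = "neglog10") {
  p <- adj_p
  if (any(p == 0)) {
    warning("adjusted p-value of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  switch(transform,
         neglog10 = minmax_normalize(-log10(p)),
         one_minus_p = minmax_normalize(1 - p),
         pn_stop("unknown significance transform", "phosnet_config_error"))
}

#' Relative phosphosite differential-regulation score
#'
#' The signed regulation score of a site is the product of its min-max
#' normalized significance and its log2 fold change, computed per treatment
#' comparison over all quantified sites of that comparison. The significance
#' weight is the min-max of -log10(adjusted p) by default (so the most
#' significant site of a comparison gets weight 1 and the least significant
#' weight 0); set `significance_transform = "one_minus_p"` in the config for
#' the alternative reading.
#'
#' Sites keep their score regardless of call direction; `ns` sites are
#' excluded later when scores feed enrichment foregrounds and interaction
#' scoring.
#'
#' @param sites phosphosite data.frame
#' @param config a [run_config()]
#' @return `sites` with `direction` (via [call_differential()]) and
#'   `regulation_score` columns
#' @export
regulation_scores <- function(sites, config = run_config()) {
  sites <- call_differential(sites, config)
  sites$regulation_score <- NA_real_
  for (cmp in unique(sites$comparison)) {
    idx <- sites$comparison == cmp
    w <- significance_weight(sites$adj_p[idx], config$significance_transform)
    sites$regulation_score[idx] <- w * sites$log2fc[idx]
  }
  sites
}
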