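# Motif scoring: consensus matchers, PSSM scoring, percentile ranking,
# and the per-site top-k kinase filter.

#' Construct a kinase motif model
#'
#' A kinase motif model holds a position-specific scoring matrix (PSSM) of
#' log2-odds scores over window positions -5..+4 and the 20-residue alphabet,
#' an acceptor preference over \{S, T\}, and (optionally) a sorted background
#' score sample used for percentile ranking.
#'
#' Position 0 is the phospho-acceptor; its PSSM row is kept for format
#' completeness but scoring uses the acceptor preference instead (as
#' log2(pref / 0.5), i.e. log-odds against an even S/T split), so an
#' indifferent kinase contributes 0 at the acceptor.
#'
#' @param kinase kinase name
#' @param motif_class motif class annotation (free text; not computed here)
#' @param pssm 10 x 20 numeric matrix, rownames `-5..4`, colnames the
#'   amino-acid alphabet, finite entries
#' @param acceptor_pref named numeric `c(S=, T=)` summing to 1
#' @param background optional numeric vector of background raw scores; stored
#'   sorted
#' @return object of class `kinase_model`
#' @export
kinase_model <- function(kinase, motif_class = "unassigned", pssm,
                         acceptor_pref = c(S = 0.5, T = 0.5),
                         background = NULL) {
  if (!is.matrix(pssm) || !identical(dim(pssm), c(10L, 20L))) {
    pn_stop("pssm must be a 10 x 20 matrix (positions -5..4 x residues)",
            "phosnet_validation_error")
  }
  if (!all(is.finite(pssm))) {
    pn_stop("pssm entries must be finite", "phosnet_validation_error")
  }
  if (is.null(colnames(pssm))) colnames(pssm) <- AA_ALPHABET
  if (!identical(colnames(pssm), AA_ALPHABET)) {
    pssm <- pssm[, AA_ALPHABET]
  }
  rownames(pssm) <- as.character(WINDOW_POSITIONS)
  ap <- acceptor_pref[c("S", "T")]
  if (any(is.na(ap)) || any(ap < 0) || abs(sum(ap) - 1) > 1e-8) {
    pn_stop("acceptor_pref must be c(S=, T=) probabilities summing to 1",
            "phosnet_validation_error")
  }
  if (!is.null(background)) {
    background <- sort(as.numeric(background))
    if (length(background) == 0) {
      pn_stop("background sample must be non-empty", "phosnet_validation_error")
    }
  }
  structure(list(kinase = kinase, motif_class = motif_class, pssm = pssm,
                 acceptor_pref = ap, background = background),
            class = "kinase_model")
}

#' @export
print.kinase_model <- function(x, ...) {
  cat(sprintf("kinase_model '%s' (class %s), acceptor pref S=%.2f T=%.2f, %s\n",
              x$kinase, x$motif_class, x$acceptor_pref["S"],
              x$acceptor_pref["T"],
              if (is.null(x$background)) "no background" else
                sprintf("background n=%d", length(x$background))))
  invisible(x)
}

# Window helpers ---------------------------------------------------------------

#' Decompose windows into residue characters
#' @noRd
window_chars <- function(windows) {
  bad <- nchar(windows) != WINDOW_LENGTH
  if (any(bad)) {
    pn_stop(sprintf("window(s) not %d characters long", WINDOW_LENGTH),
            "phosnet_validation_error")
  }
  mat <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                ncol = WINDOW_LENGTH, byrow = TRUE)
  allowed <- c(AA_ALPHABET, PAD_CHAR)
  if (!all(mat %in% allowed)) {
    pn_stop("window contains characters outside the amino-acid alphabet",
            "phosnet_validation_error")
  }
  mat
}

#' Residue at a window position
#'
#' @param windows character vector of 10-character windows
#' @param pos integer position in -5..+4
#' @return character vector of residues (may be the pad character `"_"`)
#' @export
window_residue <- function(windows, pos) {
  idx <- match(as.integer(pos), WINDOW_POSITIONS)
  if (is.na(idx)) {
    pn_stop("position must be in -5..+4", "phosnet_validation_error")
  }
  substr(windows, idx, idx)
}

# Consensus matchers -----------------------------------------------------------

HYDROPHOBIC <- c("M", "L", "I", "F", "V")   # phi
BASIC_AMPK  <- c("R", "K", "H")             # beta (AMPK convention)
BASIC_ROCK  <- c("R", "K")                  # beta (ROCK convention)

#' Match the ROCK consensus motif
#'
#' ROCK1/2 substrates carry a basic residue just upstream of the acceptor:
#' `bXpS/T` (basic at -2) or `bXXpS/T` (basic at -3), with basic = R or K and
#' the acceptor a phospho-serine/threonine. Padded positions never match, and
#' a tyrosine acceptor returns `FALSE` (the motif requires pS/T).
#'
#' @param window character vector of 10-character windows (acceptor at
#'   position 0)
#' @return logical vector
#' @examples
#' match_rock_motif("AAARASAAAA")  # R at -2 -> TRUE
#' @export
match_rock_motif <- function(window) {
  acceptor <- window_residue(window, 0)
  st <- acceptor %in% c("S", "T")
  if (any(acceptor == "Y")) {
    message(sprintf("match_rock_motif: %d window(s) with Y acceptor -> FALSE",
                    sum(acceptor == "Y")))
  }
  hit <- window_residue(window, -2) %in% BASIC_ROCK |
         window_residue(window, -3) %in% BASIC_ROCK
  st & hit
}

#' Match the AMPK consensus motif
#'
#' The AMPK consensus is `phi-beta-beta-X-X-pS/T-X-X-X-phi` (hydrophobic phi =
#' M/L/I/F/V at -5 and +4; basic beta = R/K/H at -4 and -3). In strict mode
#' all four constrained positions must match. In relaxed mode — covering the
#' common motif variants — a hydrophobic residue at -5 *or* +4 plus a basic
#' residue at -3 suffices.
#'
#' @param window character vector of 10-character windows
#' @param strict require the full consensus (default `TRUE`)
#' @return logical vector
#' @examples
#' match_ampk_motif("VRKGASAAAL")            # strict consensus
#' match_ampk_motif("GRKGASAAAL", strict = FALSE)
#' @export
match_ampk_motif <- function(window, strict = TRUE) {
  acceptor <- window_residue(window, 0)
  st <- acceptor %in% c("S", "T")
  m5 <- window_residue(window, -5) %in% HYDROPHOBIC
  m4 <- window_residue(window, -4) %in% BASIC_AMPK
  m3 <- window_residue(window, -3) %in% BASIC_AMPK
  p4 <- window_residue(window, 4) %in% HYDROPHOBIC
  if (strict) {
    st & m5 & m4 & m3 & p4
  } else {
    st & (m5 | p4) & m3
  }
}

# PSSM scoring -----------------------------------------------------------------

#' Score windows against a kinase motif model
#'
#' The raw score is the additive log2-odds over non-padded flanking positions
#' plus the acceptor-preference log-odds `log2(pref[acceptor] / 0.5)`.
#' Padded positions contribute nothing (so a terminus-padded window scores the
#' sum of its observed positions only).
#'
#' @param windows character vector of 10-character windows; acceptors must be
#'   S or T
#' @param model a [kinase_model()]
#' @return numeric vector of raw scores
#' @export
score_windows <- function(windows, model) {
  chars <- window_chars(windows)
  acceptor <- chars[, ACCEPTOR_INDEX]
  if (!all(acceptor %in% c("S", "T"))) {
    pn_stop("acceptor residue must be S or T for PSSM scoring",
            "phosnet_validation_error")
  }
  flank_idx <- setdiff(seq_len(WINDOW_LENGTH), ACCEPTOR_INDEX)
  res_idx <- match(chars[, flank_idx, drop = FALSE], AA_ALPHABET)  # NA = pad
  pos_idx <- matrix(rep(flank_idx, each = nrow(chars)), nrow = nrow(chars))
  contrib <- matrix(0, nrow = nrow(chars), ncol = length(flank_idx))
  ok <- !is.na(res_idx)
  contrib[ok] <- model$pssm[cbind(pos_idx[ok], res_idx[ok])]
  raw <- rowSums(contrib) + log2(model$acceptor_pref[acceptor] / 0.5)
  unname(raw)
}

#' Score one phosphosite window against a model
#'
#' Single-site convenience around [score_windows()]; returns the raw score and
#' its percentile within the model's background sample (midpoint rule for
#' ties, 0-100 scale). The model must carry a background sample.
#'
#' @param window one 10-character window
#' @param model a [kinase_model()] with a non-`NULL` background
#' @return a list with `kinase`, `raw`, `percentile`
#' @export
score_site <- function(window, model) {
  raw <- score_windows(window, model)
  if (is.null(model$background)) {
    pn_stop("model has no background sample; use set_background() first",
            "phosnet_validation_error")
  }
  list(kinase = model$kinase, raw = raw,
       percentile = empirical_percentile(raw, model$background))
}

#' Empirical percentile with midpoint tie rule
#'
#' `100 * (#\{background < x\} + 0.5 * #\{background == x\}) / n`. Monotone in
#' `x`; equal scores map to equal percentiles.
#'
#' @param x numeric vector of scores
#' @param background sorted (or unsorted) numeric background sample
#' @return percentiles on the 0-100 scale
#' @export
empirical_percentile <- function(x, background) {
  if (length(background) == 0) {
    pn_stop("empty background sample", "phosnet_validation_error")
  }
  bg <- sort(background)
  n <- length(bg)
  le <- findInterval(x, bg)                   # #{bg <= x}
  lt <- findInterval(x, bg, left.open = TRUE) # #{bg <  x}
  100 * (lt + 0.5 * (le - lt)) / n
}

#' Attach a background score sample to a model
#'
#' The default background is self-referential: the model's scores over all
#' windows of the analyzed dataset. An external reference sample can be
#' supplied instead.
#'
#' @param model a [kinase_model()]
#' @param windows dataset windows to score as background (ignored if `scores`
#'   given)
#' @param scores optional pre-computed numeric background sample
#' @return the model with its `background` set
#' @export
set_background <- function(model, windows = NULL, scores = NULL) {
  if (is.null(scores)) {
    if (is.null(windows)) {
      pn_stop("set_background needs windows or scores",
              "phosnet_validation_error")
    }
    scores <- score_windows(windows, model)
  }
  model$background <- sort(as.numeric(scores))
  model
}

#' Score all phosphosites against a kinase library
#'
#' Scores every unique site window against every model, percentile-ranks each
#' kinase's scores within that kinase's background (by default the scores over
#' all dataset windows — the self-referential background), and returns the
#' long site x kinase score table.
#'
#' Sites with a tyrosine acceptor are dropped with a message (the library
#' models serine/threonine kinases).
#'
#' @param sites phosphosite data.frame (see [read_phosphosite_table()]); only
#'   unique (site, window) pairs are used
#' @param library named list of [kinase_model()] objects
#' @param background optional named list mapping kinase name to an external
#'   background score sample
#' @return data.frame with columns `site`, `protein`, `kinase`, `raw`,
#'   `percentile`
#' @export
score_phosphosites <- function(sites, library, background = NULL) {
  uniq <- sites[!duplicated(sites$site), c("site", "protein", "window", "residue")]
  y <- uniq$residue == "Y"
  if (any(y)) {
    message(sprintf("score_phosphosites: dropping %d tyrosine site(s)", sum(y)))
    uniq <- uniq[!y, ]
  }
  if (nrow(uniq) == 0) {
    pn_stop("no S/T phosphosites to score", "phosnet_validation_error")
  }
  out <- lapply(library, function(model) {
    raw <- score_windows(uniq$window, model)
    bg <- if (!is.null(background)) background[[model$kinase]] else raw
    data.frame(site = uniq$site, protein = uniq$protein,
               kinase = model$kinase, raw = raw,
               percentile = empirical_percentile(raw, bg),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain the top-k kinases per phosphosite
#'
#' Keeps, for every site, the `k` kinases with the highest percentile; ties at
#' the boundary are broken by raw score, then lexicographic kinase name. With
#' fewer than `k` kinases all are kept.
#'
#' @param scores data.frame from [score_phosphosites()]
#' @param k number of kinases to retain per site (default 25)
#' @return the retained subset of `scores`
#' @export
top_kinases_for_site <- function(scores, k = 25L) {
  if (k < 1) pn_stop("k must be >= 1", "phosnet_validation_error")
  if (nrow(scores) == 0) return(scores)
  ord <- order(scores$site,
               -scores$percentile,
               -scores$raw,
               scores$kinase)
  sorted <- scores[ord, ]
  keep <- ave(seq_len(nrow(sorted)), sorted$site, FUN = seq_along) <= k
  res <- sorted[keep, ]
  rownames(res) <- NULL
  res
}
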