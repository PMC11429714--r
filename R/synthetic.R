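# Synthetic-data generation with planted ground truth: kinase PSSM library,
# phosphoproteome with planted active kinases and motif-true substrates, and
# annotation tables (evidence, interactions, gene sets, dependency scores).
# Every downstream stage is validated by recovering what was planted.

#' Synthetic ground truth
#'
#' Describes the conditions of a simulated experiment: which kinases are
#' active (up/down), how many sites and proteins are generated, the effect
#' size and noise of regulated sites, and how many proteins are co-regulated
#' (receiving one up- and one down-regulated site each, from an up- and a
#' down-active kinase).
#'
#' @param active_kinases_up,active_kinases_down disjoint character vectors of
#'   kinase names
#' @param n_sites,n_proteins,n_kinases integers
#' @param effect_size mean |log2FC| of regulated sites; must be at least
#'   `config$log2fc_min` so planted sites are callable
#' @param noise_sd standard deviation of log2FC noise
#' @param fraction_regulated fraction of sites planted as regulated, in
#'   \[0, 1) (0 gives a pure null experiment)
#' @param n_coregulated number of proteins planted with both an up- and a
#'   down-regulated site (0 when either active set is empty)
#' @param config a [run_config()] (for the callability check)
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(active_kinases_up, active_kinases_down,
                            n_sites = 2000L, n_proteins = 800L,
                            n_kinases = 50L, effect_size = 3,
                            noise_sd = 0.3, fraction_regulated = 0.12,
                            n_coregulated = 30L, config = run_config()) {
  if (length(intersect(active_kinases_up, active_kinases_down)) > 0) {
    pn_stop("up- and down-active kinase sets must be disjoint",
            "phosnet_parameter_error")
  }
  if (fraction_regulated < 0 || fraction_regulated >= 1) {
    pn_stop("fraction_regulated must be in [0, 1)", "phosnet_parameter_error")
  }
  n_active <- length(active_kinases_up) + length(active_kinases_down)
  if (fraction_regulated > 0 && n_active == 0) {
    pn_stop("regulated fraction > 0 requires at least one active kinase",
            "phosnet_parameter_error")
  }
  if (fraction_regulated > 0 && effect_size < config$log2fc_min) {
    pn_stop("effect_size below log2fc_min: planted sites would not be callable",
            "phosnet_parameter_error")
  }
  if (length(active_kinases_up) == 0 || length(active_kinases_down) == 0) {
    n_coregulated <- 0L
  }
  structure(list(active_kinases_up = active_kinases_up,
                 active_kinases_down = active_kinases_down,
                 n_sites = as.integer(n_sites),
                 n_proteins = as.integer(n_proteins),
                 n_kinases = as.integer(n_kinases),
                 effect_size = effect_size, noise_sd = noise_sd,
                 fraction_regulated = fraction_regulated,
                 n_coregulated = as.integer(n_coregulated),
                 planted_substrates = NULL, coregulated_proteins = character(0)),
            class = "synthetic_truth")
}

#' Generate a synthetic kinase PSSM library
#'
#' Each kinase receives a 10 x 20 log2-odds matrix that is near-uniform
#' (Normal(0, 0.1) noise) except for 2-3 strongly preferred (position,
#' residue) pairs with log-odds in \[5, 7\] (comparable to the strong
#' favorite-residue preferences of peptide-array-derived matrices). Two
#' kinases carry literal
#' consensus preferences: `"AMPK_SYN"` (hydrophobic M/L/I/F/V at -5 and +4,
#' basic R/K/H at -4 and -3) and `"ROCK_SYN"` (basic R/K at -2 and -3).
#' Preferred (position, residue) cells are disjoint across the generated
#' kinases (drawn without replacement from the position x residue pool, with
#' the consensus cells reserved), so each planted motif identifies exactly
#' one kinase; in addition, every kinase's background noise is zeroed at the
#' other kinases' signature cells, so a planted window shifts only the score
#' of its owning kinase. Real kinomes have overlapping specificities, which
#' this generator deliberately does not emulate. Acceptor preferences are
#' mild, drawn uniformly in \[0.45, 0.55\] for S.
#'
#' @param n_kinases number of kinases (>= 2)
#' @param seed integer seed; the same seed yields identical matrices
#' @return named list of [kinase_model()] objects
#' @export
generate_kinase_library <- function(n_kinases, seed = 1L) {
  if (n_kinases < 2) {
    pn_stop("n_kinases must be >= 2", "phosnet_parameter_error")
  }
  set.seed(seed)
  names <- c("AMPK_SYN", "ROCK_SYN",
             if (n_kinases > 2) sprintf("KIN%03d", seq_len(n_kinases - 2)))
  noise_pssm <- function() {
    m <- matrix(rnorm(200, 0, 0.1), nrow = 10,
                dimnames = list(as.character(WINDOW_POSITIONS), AA_ALPHABET))
    m["0", ] <- 0
    m
  }
  flank_rows <- setdiff(as.character(WINDOW_POSITIONS), "0")
  # pool of assignable (position, residue) cells; consensus cells reserved
  pool <- expand.grid(row = flank_rows, col = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  reserved <- rbind(
    expand.grid(row = c("-5", "4"), col = HYDROPHOBIC,
                stringsAsFactors = FALSE),
    expand.grid(row = c("-4", "-3"), col = BASIC_AMPK,
                stringsAsFactors = FALSE),
    expand.grid(row = c("-2", "-3"), col = BASIC_ROCK,
                stringsAsFactors = FALSE))
  pool <- pool[!paste(pool$row, pool$col) %in%
                 paste(reserved$row, reserved$col), ]
  pool <- pool[sample(nrow(pool)), ]
  if (3 * (n_kinases - 2) > nrow(pool)) {
    # more kinases than disjoint cells: recycle (motifs then overlap)
    pool <- pool[rep_len(seq_len(nrow(pool)), 3 * n_kinases), ]
  }
  pool_next <- 1L
  models <- vector("list", n_kinases)
  for (i in seq_len(n_kinases)) {
    m <- noise_pssm()
    if (names[i] == "AMPK_SYN") {
      m["-5", HYDROPHOBIC] <- 3.5
      m["4", HYDROPHOBIC] <- 3.5
      m["-4", BASIC_AMPK] <- 3.5
      m["-3", BASIC_AMPK] <- 3.5
      cls <- "CAMK"
    } else if (names[i] == "ROCK_SYN") {
      m["-2", BASIC_ROCK] <- 3.5
      m["-3", BASIC_ROCK] <- 3.5
      cls <- "AGC"
    } else {
      n_pref <- sample(2:3, 1)
      cells <- pool[pool_next:(pool_next + n_pref - 1L), ]
      pool_next <- pool_next + n_pref
      for (j in seq_len(n_pref)) {
        m[cells$row[j], cells$col[j]] <- runif(1, 5, 7)
      }
      cls <- "unassigned"
    }
    pref_s <- runif(1, 0.45, 0.55)
    models[[i]] <- kinase_model(names[i], cls, m,
                                acceptor_pref = c(S = pref_s, T = 1 - pref_s))
  }
  names(models) <- names
  # Zero every model's background noise at the other kinases' signature
  # cells (and at the reserved consensus cells): a planted window then
  # shifts only its owning kinase's score, which keeps single-kinase
  # recovery identifiable.
  signature_cells <- unique(rbind(
    reserved,
    do.call(rbind, lapply(models, function(mod) {
      idx <- which(mod$pssm > 1, arr.ind = TRUE)
      data.frame(row = rownames(mod$pssm)[idx[, 1]],
                 col = colnames(mod$pssm)[idx[, 2]],
                 stringsAsFactors = FALSE)
    }))))
  for (i in seq_along(models)) {
    cells <- as.matrix(signature_cells)
    vals <- models[[i]]$pssm[cells]
    vals[vals <= 1] <- 0          # keep own strong preferences
    models[[i]]$pssm[cells] <- vals
  }
  models
}

# Sample windows from a kinase model: flanking residues per-position
# categorical with probability proportional to 2^log-odds, acceptor from the
# acceptor preference.
sample_windows_from_model <- function(model, n) {
  flank <- matrix("", nrow = n, ncol = WINDOW_LENGTH)
  for (j in seq_len(WINDOW_LENGTH)) {
    if (j == ACCEPTOR_INDEX) {
      flank[, j] <- sample(c("S", "T"), n, replace = TRUE,
                           prob = model$acceptor_pref)
    } else {
      pr <- 2^model$pssm[j, ]
      flank[, j] <- sample(AA_ALPHABET, n, replace = TRUE, prob = pr / sum(pr))
    }
  }
  apply(flank, 1, paste, collapse = "")
}

sample_null_windows <- function(n) {
  flank <- matrix(sample(AA_ALPHABET, n * WINDOW_LENGTH, replace = TRUE),
                  nrow = n)
  flank[, ACCEPTOR_INDEX] <- sample(c("S", "T"), n, replace = TRUE)
  apply(flank, 1, paste, collapse = "")
}

#' Generate a synthetic phosphoproteome
#'
#' Plants `round(fraction_regulated * n_sites)` regulated sites distributed
#' over the active kinases (windows sampled from the owning kinase's PSSM;
#' log2FC ~ Normal(+/- effect_size, noise_sd); raw p ~ Uniform(0, 1e-6)); the
#' first `n_coregulated` planted proteins receive one up- and one down-site
#' each. Null sites get uniform windows, log2FC ~ Normal(0, noise_sd) and
#' raw p ~ Uniform(0, 1). Adjusted p-values are produced by applying the
#' pipeline's own BH to the simulated raw p-values, so the p/log2FC joint
#' structure is internally consistent.
#'
#' @param truth a [synthetic_truth()]
#' @param library kinase library from [generate_kinase_library()] containing
#'   all active kinases
#' @param config a [run_config()]
#' @param seed integer seed
#' @param comparison comparison label (default `"combo_vs_ctrl"`)
#' @return list with `sites` (validated phosphosite data.frame, including the
#'   simulated `raw_p` column for calibration checks) and `truth` (updated
#'   with `planted_substrates` and `coregulated_proteins`)
#' @export
generate_phosphoproteome <- function(truth, library, config = run_config(),
                                     seed = 1L, comparison = "combo_vs_ctrl") {
  missing_kin <- setdiff(c(truth$active_kinases_up, truth$active_kinases_down),
                         names(library))
  if (length(missing_kin) > 0) {
    pn_stop("active kinases not present in the library",
            "phosnet_parameter_error")
  }
  set.seed(seed)
  n_planted <- round(truth$fraction_regulated * truth$n_sites)
  if (n_planted > truth$n_sites) {
    pn_stop("requested planted substrates exceed n_sites",
            "phosnet_parameter_error")
  }
  proteins_all <- sprintf("PROT%04d", seq_len(truth$n_proteins))

  owner <- character(0); direction <- character(0); protein <- character(0)
  n_cor <- min(truth$n_coregulated, floor(n_planted / 2))
  if (n_cor > 0) {
    cor_prot <- proteins_all[seq_len(n_cor)]
    owner <- c(rep_len(truth$active_kinases_up, n_cor),
               rep_len(truth$active_kinases_down, n_cor))
    direction <- c(rep("up", n_cor), rep("down", n_cor))
    protein <- c(cor_prot, cor_prot)
  } else {
    cor_prot <- character(0)
  }
  n_rest <- n_planted - 2 * n_cor
  if (n_rest > 0) {
    active <- c(truth$active_kinases_up, truth$active_kinases_down)
    rest_owner <- rep_len(active, n_rest)
    owner <- c(owner, rest_owner)
    direction <- c(direction,
                   ifelse(rest_owner %in% truth$active_kinases_up, "up", "down"))
    protein <- c(protein, sample(proteins_all, n_rest, replace = TRUE))
  }
  n_null <- truth$n_sites - length(owner)
  protein <- c(protein, sample(proteins_all, n_null, replace = TRUE))
  owner <- c(owner, rep(NA_character_, n_null))
  direction <- c(direction, rep("null", n_null))

  # unique 1-based positions per protein
  position <- ave(seq_along(protein), protein, FUN = seq_along) * 10L + 1L

  window <- character(length(protein))
  planted_idx <- which(!is.na(owner))
  for (kin in unique(owner[planted_idx])) {
    idx <- which(owner == kin & !is.na(owner))
    window[idx] <- sample_windows_from_model(library[[kin]], length(idx))
  }
  null_idx <- which(is.na(owner))
  if (length(null_idx) > 0) {
    window[null_idx] <- sample_null_windows(length(null_idx))
  }
  residue <- substr(window, ACCEPTOR_INDEX, ACCEPTOR_INDEX)

  log2fc <- numeric(length(protein))
  log2fc[direction == "up"] <- rnorm(sum(direction == "up"),
                                     truth$effect_size, truth$noise_sd)
  log2fc[direction == "down"] <- rnorm(sum(direction == "down"),
                                       -truth$effect_size, truth$noise_sd)
  log2fc[direction == "null"] <- rnorm(sum(direction == "null"),
                                       0, truth$noise_sd)
  raw_p <- numeric(length(protein))
  raw_p[direction != "null"] <- runif(sum(direction != "null"), 0, 1e-6)
  raw_p[direction == "null"] <- runif(sum(direction == "null"))
  raw_p <- pmax(raw_p, .Machine$double.xmin)
  adj_p <- bh_adjust(raw_p)

  sites <- data.frame(protein = protein, position = position,
                      residue = residue, window = window,
                      comparison = comparison, log2fc = log2fc,
                      adj_p = pmin(adj_p, 1), raw_p = raw_p,
                      stringsAsFactors = FALSE)
  sites <- validate_phosphosite_table(sites)

  truth$planted_substrates <- if (length(planted_idx) > 0) {
    data.frame(kinase = owner[planted_idx], protein = protein[planted_idx],
               position = position[planted_idx],
               direction = direction[planted_idx], stringsAsFactors = FALSE)
  } else {
    data.frame(kinase = character(0), protein = character(0),
               position = integer(0), direction = character(0))
  }
  truth$coregulated_proteins <- cor_prot
  list(sites = sites, truth = truth)
}

#' Generate synthetic annotation tables
#'
#' Builds, from a populated ground truth (after
#' [generate_phosphoproteome()]):
#' * an evidence table covering `evidence_fraction` of planted
#'   kinase-substrate pairs, each with in vitro / in vivo flags (at least one
#'   set; half the records site-level, half protein-level);
#' * an interaction table covering `interaction_fraction` of planted pairs
#'   with reference counts drawn from Geometric(0.5) + 1 (always >= 1);
#' * gene sets: one planted pathway `"PLANTED_ESSENTIAL"` built from the
#'   essential half of the co-regulated proteins plus a few random members,
#'   and `n_gene_sets - 1` random sets of size `set_size`;
#' * a dependency table: Chronos ~ Normal(0, 0.3) for all proteins, with the
#'   designated essential genes (the essential co-regulated half plus
#'   `n_random_essential` random others) shifted to Normal(-1, 0.15) and
#'   capped at -0.55 so the <= -0.5 rule classifies them essential with
#'   margin.
#'
#' @param truth a populated [synthetic_truth()]
#' @param seed integer seed
#' @param evidence_fraction fraction of planted pairs with curated evidence
#' @param interaction_fraction fraction of planted pairs with an interaction
#'   record
#' @param n_gene_sets total number of gene sets
#' @param set_size members per random set
#' @param n_random_essential additional random essential genes
#' @return list with `evidence`, `interactions`, `gene_sets`, `dependency`,
#'   `planted_pathway`, `essential_genes`
#' @export
generate_annotations <- function(truth, seed = 1L, evidence_fraction = 0.6,
                                 interaction_fraction = 0.5,
                                 n_gene_sets = 20L, set_size = 25L,
                                 n_random_essential = 40L) {
  if (is.null(truth$planted_substrates)) {
    pn_stop("truth must be populated by generate_phosphoproteome first",
            "phosnet_parameter_error")
  }
  set.seed(seed)
  planted <- truth$planted_substrates
  proteins_all <- sprintf("PROT%04d", seq_len(truth$n_proteins))

  # curated evidence
  pairs <- planted[!duplicated(paste(planted$kinase, planted$protein,
                                     planted$position)), ]
  n_ev <- round(evidence_fraction * nrow(pairs))
  evidence <- if (n_ev > 0) {
    ev <- pairs[sample(nrow(pairs), n_ev), c("kinase", "protein", "position")]
    ev$in_vitro <- rbinom(n_ev, 1, 0.7)
    ev$in_vivo <- rbinom(n_ev, 1, 0.7)
    none <- ev$in_vitro + ev$in_vivo == 0
    ev$in_vitro[none] <- 1L
    ev$position[sample(c(TRUE, FALSE), n_ev, replace = TRUE)] <- NA_integer_
    ev <- ev[!duplicated(paste(ev$kinase, ev$protein, ev$position)), ]
    rownames(ev) <- NULL
    ev
  } else {
    data.frame(kinase = character(0), protein = character(0),
               position = integer(0), in_vitro = integer(0),
               in_vivo = integer(0))
  }

  # interaction reference counts
  ppairs <- unique(planted[, c("kinase", "protein")])
  n_int <- round(interaction_fraction * nrow(ppairs))
  interactions <- if (n_int > 0) {
    it <- ppairs[sample(nrow(ppairs), n_int), ]
    it$n_refs <- rgeom(n_int, 0.5) + 1L
    rownames(it) <- NULL
    it
  } else {
    data.frame(kinase = character(0), protein = character(0),
               n_refs = integer(0))
  }

  # essential genes: essential half of the co-regulated proteins + randoms
  n_cor <- length(truth$coregulated_proteins)
  ess_cor <- truth$coregulated_proteins[seq_len(ceiling(n_cor / 2))]
  ess_rand <- sample(setdiff(proteins_all, truth$coregulated_proteins),
                     min(n_random_essential,
                         truth$n_proteins - n_cor))
  essential_genes <- c(ess_cor, ess_rand)

  # gene sets
  gene_sets <- list()
  if (length(ess_cor) > 0) {
    extras <- sample(setdiff(proteins_all, ess_cor),
                     max(0, set_size - length(ess_cor)))
    gene_sets[["PLANTED_ESSENTIAL"]] <- c(ess_cor, extras)
  }
  n_random_sets <- n_gene_sets - length(gene_sets)
  for (i in seq_len(n_random_sets)) {
    gene_sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(proteins_all, set_size)
  }

  # dependency scores
  chronos <- rnorm(truth$n_proteins, 0, 0.3)
  names(chronos) <- proteins_all
  chronos[essential_genes] <- pmin(rnorm(length(essential_genes), -1, 0.15),
                                   -0.55)
  dependency <- data.frame(gene = proteins_all, chronos = unname(chronos),
                           stringsAsFactors = FALSE)

  list(evidence = evidence, interactions = interactions,
       gene_sets = gene_sets, dependency = dependency,
       planted_pathway = if (length(ess_cor) > 0) "PLANTED_ESSENTIAL" else NA,
       essential_genes = essential_genes)
}

#' Simulate a complete synthetic experiment
#'
#' One-call wrapper that generates the kinase library, the phosphoproteome
#' and all annotation tables under a single seed. The defaults are the
#' package's reference study conditions: 50 kinases, 2000 sites on 800
#' proteins, 2 up-active and 2 down-active kinases, effect size 3 log2 units,
#' noise SD 0.3, 12% of sites regulated, 30 co-regulated proteins.
#'
#' @param n_kinases,n_proteins,n_sites experiment dimensions
#' @param n_active_up,n_active_down numbers of planted active kinases (drawn
#'   at random from the library)
#' @param effect_size,noise_sd,fraction_regulated,n_coregulated see
#'   [synthetic_truth()]
#' @param config a [run_config()]
#' @param seed integer master seed (sub-seeds are derived from it)
#' @return list with `library`, `sites`, `truth`, `annotations`
#' @export
simulate_experiment <- function(n_kinases = 50L, n_proteins = 800L,
                                n_sites = 2000L, n_active_up = 2L,
                                n_active_down = 2L, effect_size = 3,
                                noise_sd = 0.3, fraction_regulated = 0.12,
                                n_coregulated = 30L, config = run_config(),
                                seed = config$seed) {
  library <- generate_kinase_library(n_kinases, seed = seed)
  set.seed(seed)
  n_active <- n_active_up + n_active_down
  active <- if (n_active > 0) sample(names(library), n_active) else character(0)
  truth <- synthetic_truth(
    active_kinases_up = if (n_active_up > 0) active[seq_len(n_active_up)] else character(0),
    active_kinases_down = if (n_active_down > 0) active[n_active_up + seq_len(n_active_down)] else character(0),
    n_sites = n_sites, n_proteins = n_proteins, n_kinases = n_kinases,
    effect_size = effect_size, noise_sd = noise_sd,
    fraction_regulated = fraction_regulated,
    n_coregulated = n_coregulated, config = config)
  gp <- generate_phosphoproteome(truth, library, config, seed = seed + 1L)
  ann <- generate_annotations(gp$truth, seed = seed + 2L)
  list(library = library, sites = gp$sites, truth = gp$truth,
       annotations = ann)
}
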