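#' Read a phosphosite table
#'
#' Reads a tab-separated phosphosite table with one row per phosphosite per
#' treatment comparison. Required columns: `protein`, `position` (1-based
#' residue index), `residue` (S/T/Y), `window` (10-character sequence covering
#' positions -5..+4 with the acceptor at position 0; termini padded with
#' `"_"`), `comparison`, `log2fc`, `adj_p`.
#'
#' Validation enforces: windows over the 20 amino-acid alphabet plus the pad
#' character, acceptor residue in S/T/Y, window center equal to the acceptor
#' residue, adjusted p in (0, 1], and no duplicate
#' (protein, position, residue, comparison) keys. Malformed rows are reported
#' with their line numbers.
#'
#' @param path path to a TSV file with a header row
#' @return a `data.frame` with the columns above plus a `site` key column
#' @export
read_phosphosite_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_phosphosite_table(df)
}

#' Validate an in-memory phosphosite table
#'
#' @param df a data.frame as documented in [read_phosphosite_table()]
#' @return the validated data.frame with a `site` key column added
#' @export
validate_phosphosite_table <- function(df) {
  required <- c("protein", "position", "residue", "window",
                "comparison", "log2fc", "adj_p")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pn_stop(paste0("phosphosite table missing required column(s): ",
                   paste(missing, collapse = ", ")), "phosnet_schema_error")
  }
  df$position <- as.integer(df$position)
  df$log2fc <- as.numeric(df$log2fc)
  df$adj_p <- as.numeric(df$adj_p)

  bad <- function(cond, what) {
    if (any(cond)) {
      pn_stop(sprintf("%s at row(s): %s", what,
                      paste(utils::head(which(cond), 10), collapse = ", ")),
              "phosnet_validation_error")
    }
  }
  bad(!df$residue %in% c("S", "T", "Y"), "acceptor residue not in {S,T,Y}")
  bad(nchar(df$window) != WINDOW_LENGTH,
      sprintf("window not %d characters", WINDOW_LENGTH))
  allowed <- c(AA_ALPHABET, PAD_CHAR)
  win_ok <- vapply(strsplit(df$window, ""), function(ch) all(ch %in% allowed),
                   logical(1))
  bad(!win_ok, "window contains characters outside the amino-acid alphabet")
  center <- substr(df$window, ACCEPTOR_INDEX, ACCEPTOR_INDEX)
  bad(center != df$residue, "window center does not match acceptor residue")
  bad(!is.finite(df$adj_p) | df$adj_p <= 0 | df$adj_p > 1,
      "adjusted p-value outside (0, 1]")
  bad(!is.finite(df$log2fc), "non-finite log2 fold change")
  bad(is.na(df$position) | df$position < 1, "position not a 1-based index")

  key <- paste(df$protein, df$position, df$residue, df$comparison, sep = "\r")
  bad(duplicated(key), "duplicate (protein, position, residue, comparison) key")

  df$site <- site_key(df$protein, df$residue, df$position)
  df
}

#' @rdname read_phosphosite_table
#' @param df a phosphosite data.frame
#' @export
write_phosphosite_table <- function(df, path) {
  cols <- c("protein", "position", "residue", "window",
            "comparison", "log2fc", "adj_p")
  write.table(df[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GMT gene sets ---------------------------------------------------------------

#' Read / write GMT gene sets
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Duplicate members within a set are de-duplicated; empty sets and lines with
#' fewer than three fields are rejected.
#'
#' @param path file path
#' @return `read_gmt` returns a named list of character vectors (the set
#'   members), with the description stored in the `"description"` attribute of
#'   each element
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("SET1\tdesc\tA\tB\tB", tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(list(), names = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3)) {
    pn_stop(sprintf("GMT line(s) with fewer than 3 fields: %s",
                    paste(utils::head(which(n < 3), 10), collapse = ", ")),
            "phosnet_format_error")
  }
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      pn_stop(sprintf("empty gene set '%s'", f[1]), "phosnet_format_error")
    }
    structure(members, description = f[2])
  })
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets a named list of character vectors
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description") %||% "na"
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Kinase library --------------------------------------------------------------

#' Read / write a kinase PSSM library
#'
#' Long-format TSV with columns `kinase`, `motif_class`, `position` (-5..4),
#' `pref_S`, `pref_T` (acceptor preference, repeated on every row of a
#' kinase), and one column per residue of the 20 amino-acid alphabet holding
#' log2-odds scores. One block of 10 rows per kinase.
#'
#' @param path file path
#' @return `read_kinase_library` returns a named list of `kinase_model`
#'   objects (see [kinase_model()])
#' @export
read_kinase_library <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("kinase", "motif_class", "position", "pref_S", "pref_T",
                AA_ALPHABET)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pn_stop(paste0("kinase library missing column(s): ",
                   paste(missing, collapse = ", ")), "phosnet_schema_error")
  }
  models <- lapply(split(df, df$kinase), function(block) {
    block <- block[order(block$position), ]
    if (!identical(as.integer(block$position), WINDOW_POSITIONS)) {
      pn_stop(sprintf("kinase '%s': positions must be exactly -5..4",
                      block$kinase[1]), "phosnet_validation_error")
    }
    mat <- as.matrix(block[, AA_ALPHABET])
    rownames(mat) <- as.character(WINDOW_POSITIONS)
    kinase_model(kinase = block$kinase[1],
                 motif_class = block$motif_class[1],
                 pssm = mat,
                 acceptor_pref = c(S = block$pref_S[1], T = block$pref_T[1]))
  })
  models[order(names(models))]
}

#' @rdname read_kinase_library
#' @param library a named list of `kinase_model` objects
#' @export
write_kinase_library <- function(library, path) {
  blocks <- lapply(library, function(m) {
    data.frame(kinase = m$kinase, motif_class = m$motif_class,
               position = WINDOW_POSITIONS,
               pref_S = unname(m$acceptor_pref["S"]),
               pref_T = unname(m$acceptor_pref["T"]),
               as.data.frame(m$pssm), check.names = FALSE)
  })
  out <- do.call(rbind, blocks)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Annotation tables ------------------------------------------------------------

#' Read curated kinase-substrate evidence
#'
#' TSV with columns `kinase`, `protein`, `position` (empty/NA for a
#' protein-level record), `in_vitro`, `in_vivo` (0/1 flags). Each record must
#' set at least one evidence flag.
#'
#' @param path file path
#' @return data.frame
#' @export
read_evidence_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("kinase", "protein", "position", "in_vitro", "in_vivo")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pn_stop(paste0("evidence table missing column(s): ",
                   paste(missing, collapse = ", ")), "phosnet_schema_error")
  }
  df$in_vitro <- as.integer(df$in_vitro)
  df$in_vivo <- as.integer(df$in_vivo)
  if (any(df$in_vitro + df$in_vivo < 1)) {
    pn_stop("evidence record with no evidence flag set",
            "phosnet_validation_error")
  }
  df
}

#' Read a kinase-substrate interaction table with reference counts
#'
#' TSV with columns `kinase`, `protein`, `n_refs` (number of references
#' reporting the interaction, >= 1).
#'
#' @param path file path
#' @return data.frame
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("kinase", "protein", "n_refs")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pn_stop(paste0("interaction table missing column(s): ",
                   paste(missing, collapse = ", ")), "phosnet_schema_error")
  }
  df$n_refs <- as.integer(df$n_refs)
  if (any(is.na(df$n_refs) | df$n_refs < 1)) {
    pn_stop("interaction reference counts must be >= 1",
            "phosnet_validation_error")
  }
  df
}

#' Read a gene dependency table
#'
#' TSV with columns `gene`, `chronos` (Chronos dependency score; more negative
#' means more essential).
#'
#' @param path file path
#' @return data.frame
#' @export
read_dependency_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "chronos")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pn_stop(paste0("dependency table missing column(s): ",
                   paste(missing, collapse = ", ")), "phosnet_schema_error")
  }
  df$chronos <- as.numeric(df$chronos)
  df
}

# Network export ---------------------------------------------------------------

#' Write / read a kinase-substrate network
#'
#' Exports the bipartite kinase-substrate graph built by [build_network()].
#' GraphML carries all node and edge attributes (edge `weight` = final
#' kinase-substrate interaction score, `direction` = up/down, evidence flags;
#' substrate nodes carry Chronos score and essentiality). SIF is the minimal
#' `source<TAB>relation<TAB>target` triple format and round-trips only
#' node/edge identity.
#'
#' @param graph an `igraph` object from [build_network()]
#' @param path output file path
#' @param format `"graphml"` or `"sif"`
#' @return `path`, invisibly
#' @export
write_network <- function(graph, path, format = c("graphml", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) pn_stop(
                       "unknown network format (use 'graphml' or 'sif')",
                       "phosnet_usage_error"))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    rel <- if (igraph::ecount(graph) > 0 &&
               "direction" %in% igraph::edge_attr_names(graph)) {
      igraph::E(graph)$direction
    } else {
      rep("interacts", nrow(el))
    }
    lines <- if (nrow(el) > 0) paste(el[, 1], rel, el[, 2], sep = "\t") else character(0)
    isolated <- setdiff(igraph::V(graph)$name, unique(c(el)))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("graphml", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) pn_stop(
                       "unknown network format (use 'graphml' or 'sif')",
                       "phosnet_usage_error"))
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- parts[vapply(parts, length, integer(1)) >= 3]
    singles <- unlist(parts[vapply(parts, length, integer(1)) == 1])
    el <- do.call(rbind, lapply(edges, function(p) p[c(1, 3)]))
    g <- igraph::graph_from_edgelist(if (is.null(el)) matrix(character(0), ncol = 2) else el,
                                     directed = TRUE)
    if (length(singles) > 0) g <- igraph::add_vertices(g, length(singles), name = singles)
    if (length(edges) > 0) {
      igraph::E(g)$direction <- vapply(edges, `[`, character(1), 2)
    }
    g
  }
}

#' Write a JSON run summary
#'
#' @param summary a named list of scalars / small vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
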