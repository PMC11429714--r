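# Independent oracles and small fixtures shared across tests.

# Draw one element from a vector (safe for length-1 vectors).
sample1 <- function(v) v[sample.int(length(v), 1)]

# Upper-tail hypergeometric probability by exhaustive enumeration of the
# support: P(X >= x) with X ~ Hypergeom(m successes, n failures, k draws).
oracle_hyper_upper <- function(x, m, n, k) {
  support <- max(0, k - n):min(k, m)
  sum(choose(m, support) * choose(n, k - support) / choose(m + n, k) *
        (support >= x))
}

# Hand-stepped Benjamini-Hochberg: sort ascending, p_(i) * n / i, cumulative
# minimum from the largest rank down, cap at 1, restore order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) {
    if (n > 1) stepped[i] <- min(stepped[i], stepped[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(stepped, 1)
  out
}

# Build a window string from residues at positions -5..+4 (acceptor at 0).
winmake <- function(m5 = "A", m4 = "A", m3 = "A", m2 = "A", m1 = "A",
                    a0 = "S", p1 = "A", p2 = "A", p3 = "A", p4 = "A") {
  paste0(m5, m4, m3, m2, m1, a0, p1, p2, p3, p4)
}

# A zero PSSM with a few named entries set.
toy_pssm <- function(entries = list()) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(0, nrow = 10, ncol = 20,
              dimnames = list(as.character(c(-5:4)), aa))
  for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
  m
}

# ---------------------------------------------------------------------------
# Hand-computed 5-site x 4-kinase scoring instance ("the spreadsheet").
# Inputs below were chosen for easy hand arithmetic; the expected final
# scores were computed by hand from the scoring definitions
# (base KLS = percentile/100 * |activity|; +0.5 per evidence level;
# + n/(n+1); final = augmented KLS * regulation score; top 3 per site by
# |final|) and are frozen here.
spreadsheet_fixture <- function() {
  top_scores <- expand.grid(site = paste0("s", 1:5),
                            kinase = paste0("K", 1:4),
                            stringsAsFactors = FALSE)
  top_scores$protein <- c(A = "A", B = "A", C = "B", D = "C", E = "D")[
    match(top_scores$site, paste0("s", 1:5))]
  perc <- rbind(c(90, 80, 70, 60),    # s1: K1..K4
                c(100, 50, 25, 0),    # s2
                c(10, 20, 30, 95),    # s3
                c(50, 50, 50, 50),    # s4
                c(95, 10, 85, 40))    # s5
  top_scores$percentile <- perc[cbind(match(top_scores$site, paste0("s", 1:5)),
                                      match(top_scores$kinase, paste0("K", 1:4)))]
  top_scores$raw <- top_scores$percentile  # unused by scoring chain

  activities <- data.frame(kinase = paste0("K", 1:4),
                           activity = c(2, -1, 0.5, 3))
  regulated <- data.frame(
    site = paste0("s", 1:5),
    protein = c("A", "A", "B", "C", "D"),
    position = c(10L, 20L, 10L, 30L, 40L),
    comparison = "cmb",
    direction = c("up", "down", "up", "up", "down"),
    regulation_score = c(2, -1, 0.5, 1, -2),
    stringsAsFactors = FALSE)
  evidence <- data.frame(
    kinase = c("K1", "K1", "K3"),
    protein = c("A", "A", "D"),
    position = c(10L, NA, NA),
    in_vitro = c(1L, 1L, 0L),
    in_vivo = c(1L, 0L, 1L))
  interactions <- data.frame(kinase = c("K2", "K4"),
                             protein = c("A", "B"),
                             n_refs = c(3L, 1L))

  # frozen hand-computed final scores of the retained (site, kinase) rows
  expected <- data.frame(
    site  = c("s1", "s1", "s1",
              "s2", "s2", "s2",
              "s3", "s3", "s3",
              "s4", "s4", "s4",
              "s5", "s5", "s5"),
    kinase = c("K1", "K4", "K2",
               "K1", "K2", "K3",
               "K4", "K1", "K2",
               "K4", "K1", "K2",
               "K1", "K4", "K3"),
    final_score = c(5.6, 3.6, 3.1,
                    -2.5, -1.25, -0.125,
                    1.675, 0.1, 0.1,
                    1.5, 1.0, 0.5,
                    -3.8, -2.4, -1.85),
    stringsAsFactors = FALSE)
  # hand-computed kinase-substrate sums and pathway scores
  expected_ks <- data.frame(
    kinase = c("K1", "K1", "K1", "K1", "K2", "K2", "K2", "K3", "K3",
               "K4", "K4", "K4", "K4"),
    protein = c("A", "B", "C", "D", "A", "B", "C", "A", "D",
                "A", "B", "C", "D"),
    score = c(3.1, 0.1, 1.0, -3.8, 1.85, 0.1, 0.5, -0.125, -1.85,
              3.6, 1.675, 1.5, -2.4),
    stringsAsFactors = FALSE)
  gene_sets <- list(P1 = c("A", "B"), P2 = c("C", "D", "ZZZ"),
                    P3 = c("ZZZ"), P4 = c("A", "E"))
  expected_pathways <- data.frame(
    pathway = c("P1", "P2", "P4"),
    pathway_score = c(10.3, -5.05, 4.2125),
    stringsAsFactors = FALSE)
  list(top_scores = top_scores, activities = activities,
       regulated = regulated, evidence = evidence,
       interactions = interactions, gene_sets = gene_sets,
       detected = c("A", "B", "C", "D", "E"),
       expected = expected, expected_ks = expected_ks,
       expected_pathways = expected_pathways)
}

# Reference mitochondrial / glycolysis stress-test traces whose hand-
# substituted metric values are asserted in tests.
reference_ocr_trace <- function() {
  flux_trace(time = 1:12,
             rate = c(95, 98, 100, 45, 40, 42, 150, 145, 140, 12, 10, 11),
             events = data.frame(label = c("oligomycin", "FCCP",
                                           "rotenone/antimycin"),
                                 time = c(3.5, 6.5, 9.5)),
             modality = "OCR")
}

reference_ecar_trace <- function() {
  flux_trace(time = 1:12,
             rate = c(8, 9, 10, 45, 50, 48, 78, 80, 79, 5, 4, 3),
             events = data.frame(label = c("glucose", "oligomycin", "2-DG"),
                                 time = c(3.5, 6.5, 9.5)),
             modality = "ECAR")
}
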