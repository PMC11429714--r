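# Deterministic arithmetic for extracellular-flux stress tests (Seahorse-style
# OCR/ECAR traces) and stable-isotope tracing tables.

#' Construct an extracellular-flux trace
#'
#' @param time numeric measurement times (strictly increasing)
#' @param rate numeric rates (pmol O2/min for OCR, mpH/min for ECAR),
#'   normalized to cell number upstream
#' @param events data.frame with columns `label` (e.g. `"glucose"`,
#'   `"oligomycin"`, `"FCCP"`, `"rotenone/antimycin"`, `"2-DG"`) and `time`;
#'   events must be strictly ordered in time, with at least one measurement
#'   between consecutive events
#' @param modality `"OCR"` or `"ECAR"`
#' @return object of class `flux_trace`
#' @export
flux_trace <- function(time, rate, events, modality = c("OCR", "ECAR")) {
  modality <- match.arg(modality)
  if (length(time) != length(rate)) {
    pn_stop("time and rate must have equal length", "phosnet_validation_error")
  }
  if (is.unsorted(time, strictly = TRUE)) {
    pn_stop("measurement times must be strictly increasing",
            "phosnet_validation_error")
  }
  if (!all(c("label", "time") %in% names(events))) {
    pn_stop("events must have 'label' and 'time' columns",
            "phosnet_validation_error")
  }
  if (nrow(events) > 1 && is.unsorted(events$time, strictly = TRUE)) {
    pn_stop("injection events must be strictly ordered in time",
            "phosnet_validation_error")
  }
  bounds <- c(events$time, Inf)
  for (i in seq_len(nrow(events))) {
    if (!any(time > bounds[i] & time < bounds[i + 1])) {
      pn_stop(sprintf("no measurement between '%s' and the next event",
                      events$label[i]), "phosnet_validation_error")
    }
  }
  structure(list(time = time, rate = rate, events = events,
                 modality = modality), class = "flux_trace")
}

#' Read a flux trace from TSV
#'
#' Columns: `time`, `rate`, and optional `event` (non-empty on rows marking
#' an injection; the injection is taken to occur at that row's time, and
#' measurements at later times count as post-injection).
#'
#' @param path file path
#' @param modality `"OCR"` or `"ECAR"`
#' @return a [flux_trace()]
#' @export
read_flux_trace <- function(path, modality = c("OCR", "ECAR")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "rate") %in% names(df))) {
    pn_stop("flux trace needs 'time' and 'rate' columns",
            "phosnet_schema_error")
  }
  ev <- if ("event" %in% names(df)) {
    rows <- !is.na(df$event) & nzchar(df$event)
    data.frame(label = df$event[rows], time = df$time[rows],
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(0), time = numeric(0))
  }
  flux_trace(df$time, df$rate, ev, modality)
}

# Rates strictly after an event and up to (and including) the next event's
# time window; `after = NULL` means before the first event.
event_time <- function(trace, label) {
  hit <- grep(label, trace$events$label, ignore.case = TRUE)
  if (length(hit) == 0) {
    pn_stop(sprintf("trace is missing required injection event '%s'", label),
            "phosnet_validation_error")
  }
  trace$events$time[hit[1]]
}

rates_in_window <- function(trace, from, to) {
  trace$rate[trace$time > from & trace$time <= to]
}

#' Mitochondrial stress test metrics
#'
#' From an OCR trace with oligomycin, FCCP and rotenone/antimycin injections:
#' * non-mitochondrial respiration = minimum rate after rotenone/antimycin;
#' * basal = (last rate before the first injection) - non-mitochondrial;
#' * ATP-linked = (last rate before oligomycin) - (minimum rate after
#'   oligomycin, before FCCP);
#' * proton leak = (minimum rate after oligomycin) - non-mitochondrial;
#' * maximal = (maximum rate after FCCP, before rotenone/antimycin) -
#'   non-mitochondrial;
#' * spare capacity = maximal - basal.
#'
#' Non-mitochondrial and maximal respiration follow the vendor-standard
#' readings (post-rotenone/antimycin minimum; post-FCCP maximum minus
#' non-mitochondrial).
#'
#' @param trace an OCR [flux_trace()]
#' @return named list: `basal`, `atp_linked`, `proton_leak`, `maximal`,
#'   `spare`, `non_mito`
#' @export
mito_stress_metrics <- function(trace) {
  if (trace$modality != "OCR") {
    pn_stop("mitochondrial stress metrics require an OCR trace",
            "phosnet_validation_error")
  }
  t_oligo <- event_time(trace, "oligomycin")
  t_fccp <- event_time(trace, "FCCP")
  t_rot <- event_time(trace, "rotenone")
  t_first <- min(trace$events$time)

  pre_first <- trace$rate[trace$time <= t_first]
  pre_oligo <- trace$rate[trace$time <= t_oligo]
  post_oligo <- rates_in_window(trace, t_oligo, t_fccp)
  post_fccp <- rates_in_window(trace, t_fccp, t_rot)
  post_rot <- rates_in_window(trace, t_rot, Inf)

  non_mito <- min(post_rot)
  basal <- pre_first[length(pre_first)] - non_mito
  atp_linked <- pre_oligo[length(pre_oligo)] - min(post_oligo)
  proton_leak <- min(post_oligo) - non_mito
  maximal <- max(post_fccp) - non_mito
  list(basal = basal, atp_linked = atp_linked, proton_leak = proton_leak,
       maximal = maximal, spare = maximal - basal, non_mito = non_mito)
}

#' Glycolysis stress test metrics
#'
#' From an ECAR trace with glucose, oligomycin and 2-DG injections:
#' * glycolysis = (maximum rate after glucose and before oligomycin) -
#'   (last rate before glucose);
#' * glycolytic capacity = (maximum rate after oligomycin, before 2-DG) -
#'   (last rate before glucose);
#' * glycolytic reserve = capacity - glycolysis (may be negative; no
#'   clamping).
#'
#' @param trace an ECAR [flux_trace()]
#' @return named list: `glycolysis`, `glycolytic_capacity`,
#'   `glycolytic_reserve`
#' @export
glyco_stress_metrics <- function(trace) {
  if (trace$modality != "ECAR") {
    pn_stop("glycolysis stress metrics require an ECAR trace",
            "phosnet_validation_error")
  }
  t_gluc <- event_time(trace, "glucose")
  t_oligo <- event_time(trace, "oligomycin")
  t_2dg <- event_time(trace, "2-DG")

  pre_gluc <- trace$rate[trace$time <= t_gluc]
  post_gluc <- rates_in_window(trace, t_gluc, t_oligo)
  post_oligo <- rates_in_window(trace, t_oligo, t_2dg)

  glycolysis <- max(post_gluc) - pre_gluc[length(pre_gluc)]
  capacity <- max(post_oligo) - pre_gluc[length(pre_gluc)]
  list(glycolysis = glycolysis, glycolytic_capacity = capacity,
       glycolytic_reserve = capacity - glycolysis)
}

#' Isotopologue fractional abundances
#'
#' Each isotopologue's peak area divided by the sum of all isotopologue areas
#' of the metabolite; fractions sum to 1.
#'
#' @param areas nonnegative numeric vector of peak areas (M+0, M+1, ...),
#'   at least one positive
#' @return numeric vector of fractions
#' @examples
#' fractional_abundance(c(3, 1))  # 0.75 0.25
#' @export
fractional_abundance <- function(areas) {
  if (any(areas < 0) || any(!is.finite(areas))) {
    pn_stop("peak areas must be finite and nonnegative",
            "phosnet_validation_error")
  }
  total <- sum(areas)
  if (total == 0) {
    pn_stop("all-zero isotopologue vector", "phosnet_validation_error")
  }
  areas / total
}

#' Total-intensity normalization of a metabolite matrix
#'
#' Divides each sample's row by its row sum (samples x metabolites), so the
#' relative metabolite levels of every sample sum to 1. Idempotent and
#' invariant to positive per-sample scaling.
#'
#' @param metabolite_matrix nonnegative numeric matrix, samples in rows
#' @return the row-normalized matrix
#' @export
total_intensity_normalize <- function(metabolite_matrix) {
  m <- as.matrix(metabolite_matrix)
  if (any(m < 0) || any(!is.finite(m))) {
    pn_stop("metabolite intensities must be finite and nonnegative",
            "phosnet_validation_error")
  }
  rs <- rowSums(m)
  if (any(rs == 0)) {
    pn_stop("sample(s) with zero total intensity", "phosnet_validation_error")
  }
  sweep(m, 1, rs, "/")
}
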