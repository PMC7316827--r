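#' Run the full abdominal processing chain on a record
#'
#' Preprocess (comb filter), suppress the maternal ECG (template
#' subtraction), detect fetal QRS complexes (detection-function bank with
#' optimal-function selection) and, when reference fetal annotations are
#' present, score the detections within the +/- 40 ms tolerance.
#'
#' @param bundle a [record_bundle()] (only `abdominal_raw` is required).
#' @param tolerance_ms beat-matching tolerance for scoring.
#' @param ... passed to [detect_fqrs()].
#' @return list with `fecg` (suppressed [mcsignal()]), `maternal_r`,
#'   `detection` (see [detect_fqrs()]), `fetal_r` (detected
#'   [beat_ann()]), and, when a reference exists, `match`
#'   ([match_beats()]), `performance` and `rr_accuracy`.
#' @export
process_record <- function(bundle, tolerance_ms = 40, ...) {
  stopifnot(inherits(bundle, "record_bundle"))
  filtered <- preprocess_signal(bundle$abdominal_raw)
  sup <- suppress_mecg(filtered)
  det <- detect_fqrs(sup$fecg, ...)
  out <- list(fecg = sup$fecg, maternal_r = sup$maternal_r,
              detection = det, fetal_r = det$annotations)
  ref <- bundle$fetal_r
  if (!is.null(ref) && length(ref$locations) > 1) {
    keep <- if (is.null(ref$flags)) seq_along(ref$locations)
            else which(ref$flags == 1)
    m <- match_beats(ref$locations[keep], det$annotations$locations,
                     rate = bundle$abdominal_raw$rate,
                     tolerance_ms = tolerance_ms)
    out$match <- m
    out$performance <- performance_indices(m)
    out$rr_accuracy <- rr_accuracy(m)
  }
  out
}

#' Published per-record summary tables of the B1/B2 reference datasets
#'
#' Loads the per-record summaries distributed with the B1 (antenatal) and
#' B2 (labour) abdominal FECG reference datasets, shipped with this
#' package as plain CSV: amplitude-relationship indices (WM, WF, WEM,
#' WEF per record) and the FHR analysis results (signal loss, basal rate,
#' fluctuation, episode counts, oscillation and variability indices), plus
#' record durations. Useful as worked examples for the aggregation code
#' path and as reference operating points for the simulator.
#'
#' @param which one of `"b1_quality"`, `"b2_quality"`, `"b1_fhr"`,
#'   `"b2_fhr"`, `"records"`.
#' @return data.frame, one row per record.
#' @export
dataset_summary_table <- function(which = c("b1_quality", "b2_quality",
                                            "b1_fhr", "b2_fhr",
                                            "records")) {
  which <- match.arg(which)
  fn <- c(b1_quality = "b1_quality_indices.csv",
          b2_quality = "b2_quality_indices.csv",
          b1_fhr = "b1_fhr_analysis.csv",
          b2_fhr = "b2_fhr_analysis.csv",
          records = "records_meta.csv")[[which]]
  path <- system.file("extdata", fn, package = "fetalecg")
  if (path == "") stop("summary table not found: ", fn)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
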