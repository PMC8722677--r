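#' Mitochondrial stress-test OCR trace
#'
#' Oxygen consumption rate measurements over time with the three canonical
#' injections (oligomycin, FCCP, antimycin A) splitting the recording into
#' four phases.
#'
#' @param time_min ordered measurement times (minutes).
#' @param ocr oxygen consumption rate (pmol O2/min).
#' @param ecar optional extracellular acidification rate (mpH/min).
#' @param injections data.frame with `label` in {oligomycin, FCCP,
#'   antimycinA} and `time_min`, strictly increasing, within the time range.
#' @param cell_count positive cell count for normalization.
#' @param group_label population label.
#' @return an object of class `OCRTrace`.
#' @export
ocr_trace <- function(time_min, ocr, ecar = NULL, injections, cell_count,
                      group_label = "") {
  if (is.unsorted(time_min, strictly = TRUE)) stopf("time_min must be strictly increasing")
  if (length(ocr) != length(time_min)) stopf("ocr and time_min lengths differ")
  need <- c("oligomycin", "FCCP", "antimycinA")
  if (!identical(injections$label, need))
    stopf("injections must be exactly oligomycin, FCCP, antimycinA in order")
  it <- injections$time_min
  if (is.unsorted(it, strictly = TRUE) || it[1] <= min(time_min) || it[3] >= max(time_min))
    stopf("injection times must be strictly increasing and inside the time range")
  if (cell_count <= 0) stopf("cell_count must be positive")
  phase <- findInterval(time_min, it) + 1L
  if (any(tabulate(phase, 4L) < 2L)) stopf("each phase needs at least 2 measurements")
  structure(list(time_min = time_min, ocr = ocr, ecar = ecar,
                 injections = injections, cell_count = cell_count,
                 group_label = group_label, phase = phase),
            class = "OCRTrace")
}

#' Summarize the four phases of a stress-test trace
#'
#' Phase summaries follow the conventional stress-test reductions:
#' pre-oligomycin by its last measurement, oligomycin-to-FCCP by its
#' minimum, FCCP-to-antimycin by its maximum, post-antimycin by its
#' minimum. `method = "mean"` switches every phase to its mean.
#'
#' @param trace an [ocr_trace()].
#' @param method "conventional" (default) or "mean".
#' @return named numeric vector `c(basal_raw, post_oligo, post_fccp,
#'   post_antimycin)`, plus attribute `ecar` (per-phase mean ECAR, passed
#'   through untransformed) when ECAR is present.
#' @export
phase_levels <- function(trace, method = c("conventional", "mean")) {
  stopifnot(inherits(trace, "OCRTrace"))
  method <- match.arg(method)
  by_phase <- split(trace$ocr, trace$phase)
  lv <- if (method == "mean") vapply(by_phase, mean, numeric(1)) else c(
    tail(by_phase[[1]], 1), min(by_phase[[2]]), max(by_phase[[3]]), min(by_phase[[4]]))
  names(lv) <- c("basal_raw", "post_oligo", "post_fccp", "post_antimycin")
  if (!is.null(trace$ecar))
    attr(lv, "ecar") <- vapply(split(trace$ecar, trace$phase), mean, numeric(1))
  lv
}

#' Derive mitochondrial stress-test parameters from phase levels
#'
#' With phase levels L1..L4 (basal, post-oligomycin, post-FCCP,
#' post-antimycin): non-mitochondrial = L4; basal = L1 - L4; ATP-linked =
#' L1 - L2; proton leak = L2 - L4; maximal = L3 - L4; spare capacity =
#' maximal - basal. The identity basal = ATP-linked + proton leak holds
#' exactly by construction. When `normalize` is TRUE every parameter is
#' divided by cell_count/1000 (per-1000-cells units); raw values are kept
#' in the `raw` element.
#'
#' @param levels output of [phase_levels()].
#' @param cell_count cell count for normalization.
#' @param normalize divide by cell_count/1000 (default TRUE).
#' @return list of class `StressTestParams` with elements `non_mito`,
#'   `basal`, `atp_linked`, `proton_leak`, `maximal`, `spare_capacity`,
#'   `normalized`, `raw`.
#' @export
stress_params <- function(levels, cell_count = NULL, normalize = TRUE) {
  L <- unname(levels)
  check_finite(L, "phase levels")
  raw <- c(non_mito = L[4], basal = L[1] - L[4], atp_linked = L[1] - L[2],
           proton_leak = L[2] - L[4], maximal = L[3] - L[4],
           spare_capacity = (L[3] - L[4]) - (L[1] - L[4]))
  if (raw["basal"] < 0)
    warning("negative basal respiration: non-physiological trace")
  out <- raw
  if (normalize) {
    if (is.null(cell_count)) stopf("cell_count required for normalization")
    out <- raw / (cell_count / 1000)
  }
  structure(c(as.list(out), list(normalized = normalize, raw = raw)),
            class = "StressTestParams")
}

#' Full stress-test quantification of one trace
#'
#' @param trace an [ocr_trace()].
#' @param normalize normalize to cell count (default TRUE).
#' @param method phase summary method, see [phase_levels()].
#' @return a `StressTestParams` (see [stress_params()]).
#' @export
stress_test <- function(trace, normalize = TRUE, method = "conventional") {
  stress_params(phase_levels(trace, method), trace$cell_count, normalize)
}
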