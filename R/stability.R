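# Per-substitution protein-stability prediction through a pluggable
# predictor: an adapter for an external stand-alone tool (I-Mutant-style
# sequence predictors honour the line contract below) and a transparent
# built-in heuristic used when no external tool is configured.

new_stability_prediction <- function(variant_key, direction, ddg, method, note = "") {
  data.frame(variant_key = variant_key, direction = direction,
             ddg = ddg, method = method, note = note, stringsAsFactors = FALSE)
}

#' Built-in stability-direction heuristic
#'
#' A deliberately simple, fully transparent score from shipped
#' physicochemical tables: `s = -(0.2 * |dH| + 0.01 * |dV|)` where `dH` is
#' the Kyte-Doolittle hydropathy difference (mutant minus wild type) and
#' `dV` the residue-volume difference in cubic Angstrom. A substitution with
#' `s < -0.3` is called `decrease`, anything else `neutral`; the heuristic
#' never predicts `increase` because a magnitude-of-change score cannot
#' justify a stabilizing call. Rows are tagged `method = "baseline-heuristic"`
#' so reports always show which predictor produced them.
#'
#' @param variant one row of the canonical variant table (or any list with
#'   `wt`, `pos`, `mut`).
#' @return one-row `StabilityPrediction` data.frame: `variant_key`,
#'   `direction`, `ddg` (`NA`; the heuristic predicts direction only),
#'   `method`, `note`.
#' @export
predict_baseline <- function(variant) {
  props <- aa_properties()
  h <- stats::setNames(props$hydropathy, props$aa)
  v <- stats::setNames(props$volume, props$aa)
  s <- -(0.2 * abs(h[variant$mut] - h[variant$wt]) +
         0.01 * abs(v[variant$mut] - v[variant$wt]))
  direction <- if (s < -0.3) "decrease" else "neutral"
  new_stability_prediction(
    variant_key = paste0(variant$wt, variant$pos, variant$mut),
    direction = direction, ddg = NA_real_, method = "baseline-heuristic",
    note = sprintf("score=%.3f", s))
}

#' Stability prediction via an external tool adapter
#'
#' Contract: the configured executable reads one line
#' `"<sequence> <wt><pos><mut>"` on standard input and writes one line
#' `"<direction> <ddg>"` on standard output. A per-variant timeout (default
#' 120 s) or a crashing/garbled tool yields a `neutral` row with an
#' explanatory note — a failing predictor never aborts the pipeline. When a
#' ddG value is returned, direction is made consistent with its sign
#' (|ddG| < 0.05 kcal/mol is neutral; negative values destabilize).
#'
#' @param sequence one-letter protein sequence the position refers to.
#' @param variant one row of the canonical variant table.
#' @param adapter_config list with `exe` (path to the executable, checked
#'   before any variant runs) and optional `timeout` seconds.
#' @return one-row `StabilityPrediction` data.frame.
#' @export
predict_external <- function(sequence, variant, adapter_config) {
  exe <- adapter_config$exe
  if (is.null(exe) || !file.exists(exe)) {
    stop(sprintf("stability adapter executable not found: %s",
                 if (is.null(exe)) "(none configured)" else exe))
  }
  timeout <- adapter_config$timeout %||% 120
  key <- paste0(variant$wt, variant$pos, variant$mut)
  method <- adapter_config$name %||% basename(exe)
  if (variant$pos > nchar(sequence)) {
    stop(sprintf("variant %s: position beyond sequence length %d",
                 key, nchar(sequence)))
  }
  wt_at <- substr(sequence, variant$pos, variant$pos)
  if (toupper(wt_at) != variant$wt) {
    stop(sprintf("variant %s: sequence has %s at position %d", key, wt_at,
                 variant$pos))
  }
  input <- sprintf("%s %s", sequence, key)
  out <- tryCatch(
    suppressWarnings(system2(exe, stdout = TRUE, stderr = FALSE,
                             input = input, timeout = timeout)),
    error = function(e) conditionMessage(e)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status == 124) {
    return(new_stability_prediction(key, "neutral", NA_real_, method,
                                    note = "timeout"))
  }
  if (length(out) == 0L || (!is.null(status) && status != 0)) {
    return(new_stability_prediction(key, "neutral", NA_real_, method,
                                    note = "adapter failed"))
  }
  fields <- strsplit(trimws(out[1]), "\\s+")[[1]]
  direction <- tolower(fields[1])
  ddg <- if (length(fields) >= 2L) suppressWarnings(as.numeric(fields[2])) else NA_real_
  note <- ""
  if (!direction %in% c("increase", "decrease", "neutral")) {
    return(new_stability_prediction(key, "neutral", NA_real_, method,
                                    note = sprintf("unparsable output '%s'", out[1])))
  }
  if (!is.na(ddg)) {
    implied <- if (abs(ddg) < 0.05) "neutral" else if (ddg < 0) "decrease" else "increase"
    if (implied != direction) {
      note <- sprintf("direction adjusted to match ddG %.3f", ddg)
      direction <- implied
    }
  }
  new_stability_prediction(key, direction, ddg, method, note)
}

#' Predict stability change for every variant
#'
#' Dispatches to the external adapter when `adapter_config` is given,
#' otherwise to the built-in heuristic. Per-variant adapter failures
#' (precondition violations included) degrade to `neutral` rows with notes.
#'
#' @param variants canonical variant data.frame.
#' @param sequence protein sequence (required for the external adapter).
#' @param adapter_config adapter configuration, or `NULL` for the heuristic.
#' @return `StabilityPrediction` data.frame, one row per variant.
#' @export
predict_stability <- function(variants, sequence = NULL, adapter_config = NULL) {
  if (!is.null(adapter_config)) {
    exe <- adapter_config$exe
    if (is.null(exe) || !file.exists(exe)) {
      stop(sprintf("stability adapter executable not found: %s",
                   if (is.null(exe)) "(none configured)" else exe))
    }
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    if (is.null(adapter_config)) return(predict_baseline(v))
    tryCatch(predict_external(sequence, v, adapter_config),
             error = function(e) new_stability_prediction(
               paste0(v$wt, v$pos, v$mut), "neutral", NA_real_,
               adapter_config$name %||% basename(adapter_config$exe),
               note = sprintf("skipped: %s", conditionMessage(e))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
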