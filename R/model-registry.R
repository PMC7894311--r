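#' Model configuration
#'
#' One member of the 12-model factorial ensemble. The label scheme is
#' `M1xyz`: the first digit is the (single) carboxylation hypothesis, `x`
#' the TPU hypothesis (1 absent, 2 present), `y` the limiting-rate selection
#' hypothesis (1 strict minimum, 2 quadratic smoothing) and `z` the electron
#' transport hypothesis (1 non-rectangular hyperbola, 2 saturating
#' hyperbola of Harley, 3 linear with no maximum).
#'
#' @param model_id Label of the form `"M1xyz"`; alternatively supply the
#'   three choices explicitly.
#' @param tpu_included Logical.
#' @param selection `"minimum"` or `"quadratic_smoothing"`.
#' @param etrans_hypothesis `"nonrect_fw"`, `"hyperbola_harley"` or
#'   `"linear_cbgb"`.
#' @return A `model_config` list with fields `model_id`, `tpu_included`,
#'   `selection`, `etrans_hypothesis`.
#' @export
model_config <- function(model_id = NULL, tpu_included = FALSE,
                         selection = c("minimum", "quadratic_smoothing"),
                         etrans_hypothesis = c("nonrect_fw",
                                               "hyperbola_harley",
                                               "linear_cbgb")) {
  if (!is.null(model_id)) {
    if (!grepl("^M1[12][12][123]$", model_id))
      stop("invalid model_id: ", model_id)
    digits <- as.integer(strsplit(substr(model_id, 3, 5), "")[[1]])
    tpu_included <- digits[1] == 2
    selection <- c("minimum", "quadratic_smoothing")[digits[2]]
    etrans_hypothesis <-
      c("nonrect_fw", "hyperbola_harley", "linear_cbgb")[digits[3]]
  } else {
    selection <- match.arg(selection)
    etrans_hypothesis <- match.arg(etrans_hypothesis)
    model_id <- paste0("M1",
      if (tpu_included) 2 else 1,
      match(selection, c("minimum", "quadratic_smoothing")),
      match(etrans_hypothesis,
            c("nonrect_fw", "hyperbola_harley", "linear_cbgb")))
  }
  structure(list(model_id = model_id, tpu_included = tpu_included,
                 selection = selection,
                 etrans_hypothesis = etrans_hypothesis),
            class = "model_config")
}

#' The 12-model ensemble registry
#'
#' @return A data.frame with one row per model: `model_id`, `tpu_included`,
#'   `selection`, `etrans_hypothesis`. Ordered by id.
#' @export
model_registry <- function() {
  grid <- expand.grid(
    etrans = c("nonrect_fw", "hyperbola_harley", "linear_cbgb"),
    sel = c("minimum", "quadratic_smoothing"),
    tpu = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ids <- mapply(function(t, s, e)
    model_config(tpu_included = t, selection = s,
                 etrans_hypothesis = e)$model_id,
    grid$tpu, grid$sel, grid$etrans)
  out <- data.frame(model_id = ids, tpu_included = grid$tpu,
                    selection = grid$sel, etrans_hypothesis = grid$etrans,
                    stringsAsFactors = FALSE)
  out[order(out$model_id), , drop = FALSE]
}
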