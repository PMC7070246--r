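#' Homeostatic model assessment of insulin resistance
#'
#' `glucose * insulin / 22.5`, with fasting glucose in mmol/L and fasting
#' insulin in pmol/L. Note the insulin unit: the classical HOMA-IR formula
#' divides by 22.5 with insulin in uU/mL; here the index is computed exactly
#' as defined for this composite, with insulin in pmol/L, and is used only
#' relatively (it is z-standardized downstream, so any constant unit factor
#' cancels). Set `insulin_unit = "uU/mL"` for the classical variant.
#'
#' @param glucose fasting glucose, mmol/L (positive).
#' @param insulin fasting insulin, pmol/L by default (positive).
#' @param insulin_unit `"pmol/L"` (default) or `"uU/mL"`; the latter converts
#'   from pmol/L by 1 uU/mL = 6 pmol/L before applying the formula.
#' @return Numeric HOMA index.
#' @export
#' @examples
#' homa(22.5, 1)   # 1
#' homa(5, 45)     # 10
homa <- function(glucose, insulin, insulin_unit = c("pmol/L", "uU/mL")) {
  insulin_unit <- match.arg(insulin_unit)
  if (any(glucose <= 0) || any(insulin <= 0))
    stop("`glucose` and `insulin` must be positive")
  if (insulin_unit == "uU/mL") insulin <- insulin / 6
  glucose * insulin / 22.5
}

cs_markers <- c("sbp", "triglycerides", "chol_hdl_ratio", "homa",
                "waist_height", "fitness")

#' Cardiometabolic composite score
#'
#' Combines six markers — systolic blood pressure (mmHg), triglycerides
#' (mmol/L), total cholesterol:HDL ratio, HOMA (from glucose and insulin, see
#' [homa()]), waist:height ratio, and cardiorespiratory fitness (mL/kg/min) —
#' into one z-scale composite. All markers except fitness are risk markers
#' and are reversed (negated) before standardization, so a higher value of
#' every standardized marker, and of the composite, indicates better
#' cardiometabolic health. Each marker is standardized to cohort mean 0 and
#' sample SD 1; the composite score `cs` is the mean of the six standardized
#' values. Subjects with any missing marker are excluded (complete-case).
#'
#' @param panel data.frame with columns `sbp`, `triglycerides`,
#'   `chol_hdl_ratio`, `glucose`, `insulin`, `waist_height`, `fitness`
#'   (plus optionally `subject_id`). Alternatively a precomputed `homa`
#'   column may replace `glucose`/`insulin`.
#' @param insulin_unit passed to [homa()].
#' @return The input rows that are complete, with added columns `homa`, `cs`,
#'   and `z_<marker>` for each of the six standardized markers, plus an
#'   attribute `n_excluded`.
#' @export
composite_score <- function(panel, insulin_unit = "pmol/L") {
  panel <- as.data.frame(panel)
  if (!"homa" %in% names(panel)) {
    if (!all(c("glucose", "insulin") %in% names(panel)))
      stop("panel must contain `glucose` and `insulin` (or a `homa` column)")
    panel$homa <- homa(panel$glucose, panel$insulin, insulin_unit)
  }
  missing_cols <- setdiff(cs_markers, names(panel))
  if (length(missing_cols))
    stop("panel lacks marker column(s): ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(panel[cs_markers])
  out <- panel[complete, , drop = FALSE]
  if (nrow(out) < 2L) stop("need at least 2 complete subjects")
  Z <- sapply(cs_markers, function(m) {
    x <- out[[m]]
    if (m != "fitness") x <- -x          # reverse risk markers first
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance marker: ", m)
    (x - mean(x)) / s
  })
  colnames(Z) <- paste0("z_", cs_markers)
  out$cs <- rowMeans(Z)
  out <- cbind(out, Z)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!complete)
  out
}
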