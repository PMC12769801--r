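#' Construct a confusion matrix from prediction and reference maps
#'
#' Cross-tabulates algorithm calls against the reference standard (manual
#' chart review). Both inputs are named logical vectors keyed by patient id;
#' the key sets must match exactly.
#'
#' @param pred Named logical vector of algorithm calls.
#' @param ref Named logical vector of reference-standard labels.
#' @return A `pac_confusion` object with counts `tp`, `fn`, `fp`, `tn`
#'   (reference defines the positive condition).
#' @export
confusion <- function(pred, ref) {
  if (is.null(names(pred)) || is.null(names(ref))) {
    stop("pred and ref must be named by patient id", call. = FALSE)
  }
  only_pred <- setdiff(names(pred), names(ref))
  only_ref <- setdiff(names(ref), names(pred))
  if (length(only_pred) || length(only_ref)) {
    stop("patient key mismatch; only in pred: {",
         paste(only_pred, collapse = ", "), "}; only in ref: {",
         paste(only_ref, collapse = ", "), "}", call. = FALSE)
  }
  ref <- ref[names(pred)]
  confusion_matrix(tp = sum(pred & ref), fn = sum(!pred & ref),
                   fp = sum(pred & !ref), tn = sum(!pred & !ref))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts (reference standard in
#'   rows, algorithm in columns; `fn` are reference positives the algorithm
#'   missed, `fp` algorithm positives the reference rejects).
#' @return A `pac_confusion` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(counts), class = "pac_confusion")
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' observed agreement \eqn{p_o = (tp + tn)/n} and expected agreement
#' \eqn{p_e} from the row and column margins. For the degenerate
#' single-category table (\eqn{p_e = 1}) kappa is defined as 1 when observed
#' agreement is perfect and is an error otherwise.
#'
#' @param cm A `pac_confusion`.
#' @return Kappa at full precision (display convention is 2 decimals,
#'   half-away-from-zero).
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "pac_confusion"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  p_o <- (cm$tp + cm$tn) / n
  p_e <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
            (cm$fp + cm$tn) * (cm$fn + cm$tn)) / n^2
  if (p_e >= 1 - .Machine$double.eps^0.5) {
    if (p_o >= 1 - .Machine$double.eps^0.5) return(1.0)
    stop("kappa undefined: expected agreement is 1 but observed is not",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Criterion-validity metric report
#'
#' Sensitivity, specificity, positive and negative predictive value,
#' accuracy (= agreement rate), and unweighted Cohen's kappa, each carried at
#' full precision (`raw`) and at display precision (`display`: percentages
#' rounded half-away-from-zero to integers, kappa and agreement to two
#' decimals). A metric whose denominator is zero is reported as `NA`
#' (undefined), never as zero.
#'
#' @param cm A `pac_confusion`.
#' @return A `pac_metrics` object: named list of `list(raw, display)`.
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "pac_confusion"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  raw <- list(
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    ppv = safe_div(cm$tp, cm$tp + cm$fp),
    npv = safe_div(cm$tn, cm$tn + cm$fn),
    accuracy = (cm$tp + cm$tn) / n
  )
  raw$agreement <- raw$accuracy
  raw$kappa <- tryCatch(cohen_kappa(cm), error = function(e) NA_real_)
  disp <- function(x, pct) {
    if (is.na(x)) return(NA_real_)
    if (pct) round_half_up(100 * x, 0) else round_half_up(x, 2)
  }
  out <- lapply(names(raw), function(nm) {
    list(raw = raw[[nm]],
         display = disp(raw[[nm]],
                        pct = nm %in% c("sensitivity", "specificity",
                                        "ppv", "npv", "accuracy")))
  })
  names(out) <- names(raw)
  structure(out, class = "pac_metrics", n = n)
}

#' @export
print.pac_metrics <- function(x, ...) {
  cat("PAC criterion validity (n =", attr(x, "n"), ")\n")
  fmt <- function(nm, unit = "%") {
    v <- x[[nm]]$display
    if (is.na(v)) "undefined" else paste0(v, unit)
  }
  cat("  sensitivity:", fmt("sensitivity"),
      " specificity:", fmt("specificity"), "\n")
  cat("  PPV:", fmt("ppv"), " NPV:", fmt("npv"), "\n")
  cat("  accuracy:", fmt("accuracy"),
      " agreement:", fmt("agreement", ""), "\n")
  cat("  kappa:", fmt("kappa", ""), "\n")
  invisible(x)
}

#' Odds ratio with Wald 95% confidence interval from a 2x2 table
#'
#' Cross-product odds ratio
#' \eqn{(a d)/(b c)} for exposure among cases versus controls, with the Wald
#' interval \eqn{\exp(\ln OR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d})}. For a
#' single binary covariate this equals the logistic-regression estimate.
#' Zero cells are an error unless the Haldane-Anscombe correction (+0.5 to
#' every cell) is requested.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative integer counts.
#' @param haldane Apply the +0.5 continuity correction to all cells
#'   (default `FALSE`).
#' @param conf_z Normal quantile for the interval (default 1.96 for 95%).
#' @return A list with `or`, `ci_low`, `ci_high` at full precision and
#'   `display` (all three rounded half-away-from-zero to 1 decimal).
#' @examples
#' odds_ratio_wald(18, 80, 195, 1605)$display
#' @export
odds_ratio_wald <- function(exposed_cases, unexposed_cases,
                            exposed_controls, unexposed_controls,
                            haldane = FALSE, conf_z = 1.96) {
  cells <- c(exposed_cases, unexposed_cases, exposed_controls,
             unexposed_controls)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; set haldane = TRUE for the ",
           "Haldane-Anscombe correction", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * conf_z * se)
  list(or = or, ci_low = ci[1], ci_high = ci[2],
       display = c(or = round_half_up(or, 1),
                   ci_low = round_half_up(ci[1], 1),
                   ci_high = round_half_up(ci[2], 1)))
}

#' Eligibility funnel accounting
#'
#' Sequential exclusion accounting for a study cohort: starting size, one
#' row per exclusion stage, and the eligible remainder.
#'
#' @param cohort_size Starting cohort size.
#' @param exclusions Named integer vector (stage label -> count) or a
#'   two-column data frame (`label`, `count`). May be empty.
#' @return A list with `eligible_n` and a `funnel` data frame (`stage`,
#'   `excluded`, `remaining`).
#' @examples
#' eligibility_funnel(2595, c("index date before 2000" = 360,
#'                            "no EHR data" = 95,
#'                            "codes outside system" = 242))$eligible_n
#' @export
eligibility_funnel <- function(cohort_size, exclusions = integer()) {
  if (!is_scalar_number(cohort_size) || cohort_size < 0) {
    stop("cohort_size must be a single non-negative number", call. = FALSE)
  }
  if (is.data.frame(exclusions)) {
    counts <- stats::setNames(exclusions$count, exclusions$label)
  } else {
    counts <- exclusions
  }
  labels <- names(counts)
  counts <- if (length(counts)) as.numeric(counts) else numeric(0)
  if (is.null(labels) && length(counts)) {
    labels <- paste0("stage_", seq_along(counts))
  }
  if (any(counts < 0)) stop("exclusion counts must be >= 0", call. = FALSE)
  if (sum(counts) > cohort_size) {
    stop("exclusions (", sum(counts), ") exceed cohort size (",
         cohort_size, ")", call. = FALSE)
  }
  remaining <- cohort_size - cumsum(c(0, counts))[-1]
  funnel <- data.frame(stage = labels %||% character(0),
                       excluded = counts,
                       remaining = if (length(counts)) remaining else numeric(0),
                       stringsAsFactors = FALSE)
  list(eligible_n = cohort_size - sum(counts), funnel = funnel)
}

#' Validate predicted statuses against a reference standard
#'
#' Joins a predicted status table to a reference label table on patient id,
#' builds the confusion matrix, and computes the full criterion-validity
#' report.
#'
#' @param pred Data frame with `patient_id` and logical `asthma` (e.g. from
#'   [classify_corpus()] or [read_status_table()]).
#' @param ref Data frame with `patient_id` and logical `asthma` (e.g. from
#'   [read_labels()]).
#' @return A list with `confusion` (`pac_confusion`) and `metrics`
#'   (`pac_metrics`).
#' @export
validate_statuses <- function(pred, ref) {
  p <- stats::setNames(pred$asthma, pred$patient_id)
  r <- stats::setNames(ref$asthma, ref$patient_id)
  cm <- confusion(p, r)
  list(confusion = cm, metrics = diagnostic_metrics(cm))
}

#' @export
print.pac_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(reference = c("asthma", "no asthma"),
                              algorithm = c("asthma", "no asthma")))
  print(m)
  invisible(x)
}
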