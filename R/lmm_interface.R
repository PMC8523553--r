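#' Mixed model for similarity indices of one ROI and pairing
#'
#' REML fit of `si ~ visit + stimulation * task` with the four
#' stimulation-by-task condition cells as repeated measures under an
#' unstructured 4 x 4 within-subject covariance, Type-III F tests and
#' Satterthwaite denominator df. Subjects with missing condition cells are
#' retained with their available cells. If the data contain fewer design
#' columns (e.g. a two-condition sub-design with a single `condition`
#' factor and no visit), the formula reduces accordingly.
#'
#' @param design long-format data frame with columns `subject`, `si`, and
#'   either `stimulation` + `task` (plus optionally `visit`) or a single
#'   `condition` factor.
#' @param response name of the response column (default `"si"`).
#' @param control passed to [rm_lmm()].
#' @return an [rm_lmm()] object.
#' @export
fit_lmm_si <- function(design, response = "si", control = list()) {
  design <- as.data.frame(design)
  has <- function(v) v %in% names(design) &&
    length(unique(design[[v]][!is.na(design[[v]])])) > 1L
  if (has("stimulation") && has("task")) {
    rhs <- "stimulation * task"
    design$condition <- interaction(design$stimulation, design$task,
                                    drop = FALSE, sep = "_")
    within <- "condition"
  } else if ("condition" %in% names(design)) {
    rhs <- "condition"
    within <- "condition"
  } else {
    stop_mvcsi("mvcsi_invalid",
               "design needs stimulation+task or condition columns")
  }
  if (has("visit")) {
    design$visit <- factor(design$visit)  # visit order is a factor (1-4)
    rhs <- paste("visit +", rhs)
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  rm_lmm(fml, design, subject = "subject", within = within,
         cov_type = "unstructured", control = control)
}

#' Mixed model for block-level task performance
#'
#' REML fit of
#' `response ~ visit + stimulation * task * block` with within-subject
#' errors covarying as unstructured(4 conditions) Kronecker
#' compound-symmetry(blocks, correlation form): observations from the same
#' condition share a common block-to-block correlation while the four
#' condition cells carry a fully parameterised covariance. Type-III F
#' tests with Satterthwaite df.
#'
#' @param design long-format data frame with columns `subject`, `visit`,
#'   `stimulation`, `task`, `block` and the response (block-level mean RT
#'   of correct presses, or accuracy).
#' @param response response column name (default `"mean_rt_correct"`).
#' @param control passed to [rm_lmm()].
#' @return an [rm_lmm()] object.
#' @export
fit_lmm_behavior <- function(design, response = "mean_rt_correct",
                             control = list()) {
  design <- as.data.frame(design)
  need <- c("subject", "visit", "stimulation", "task", "block", response)
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop_mvcsi("mvcsi_invalid", "design lacks columns: %s",
               paste(miss, collapse = ", "))
  design$condition <- interaction(design$stimulation, design$task,
                                  drop = FALSE, sep = "_")
  design$visit <- factor(design$visit)
  design$block <- factor(design$block)
  if (nlevels(design$block) < 2L) {
    # single-block sub-design: the compound-symmetry factor is empty and
    # the model reduces to the condition-level unstructured fit
    fml <- stats::as.formula(
      paste(response, "~ visit + stimulation * task"))
    return(rm_lmm(fml, design, subject = "subject", within = "condition",
                  cov_type = "unstructured", control = control))
  }
  fml <- stats::as.formula(
    paste(response, "~ visit + stimulation * task * block"))
  rm_lmm(fml, design, subject = "subject",
         within = c("condition", "block"), cov_type = "kronecker_cs",
         control = control)
}
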