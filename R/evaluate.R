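# Discrimination and reclassification: Mann-Whitney AUROC with DeLong
# variance, paired DeLong AUC comparison, reclassification tables at a risk
# threshold, and the category-based net reclassification improvement.

# placement values: per-case fraction of controls scored below (ties half),
# per-control fraction of cases scored above. mean(v10) = mean(v01) = AUC.
.placements <- function(case_scores, control_scores) {
  m <- length(case_scores)
  n <- length(control_scores)
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(case_scores, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(control_scores, ties.method = "average")) / m
  list(v10 = v10, v01 = v01,
       auc = (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n))
}

#' Area under the ROC curve by the Mann-Whitney statistic
#'
#' `AUC = [#(case > control) + 1/2 #(case = control)] / (n_cases *
#' n_controls)`, computed via midranks in O(n log n). The standard error is
#' the DeLong placement-value estimate; the 95% CI is a normal approximation
#' on the AUC scale, clipped to [0, 1].
#'
#' @param case_scores,control_scores Numeric score vectors, both nonempty.
#' @return Object of class `auroc_result`: `auc`, `se`, `ci95`, `n_cases`,
#'   `n_controls`.
#' @export
auroc <- function(case_scores, control_scores) {
  if (!length(case_scores) || !length(control_scores)) {
    stop("auroc requires nonempty case and control score vectors", call. = FALSE)
  }
  p <- .placements(case_scores, control_scores)
  m <- length(case_scores)
  n <- length(control_scores)
  v10 <- if (m > 1) stats::var(p$v10) else 0
  v01 <- if (n > 1) stats::var(p$v01) else 0
  se <- sqrt(v10 / m + v01 / n)
  ci <- pmin(pmax(p$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(auc = p$auc, se = se, ci95 = ci, n_cases = m, n_controls = n),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("AUROC %.4f (se %.4f, 95%% CI %.4f-%.4f; %d cases, %d controls)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls))
  invisible(x)
}

#' DeLong comparison of two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same cases and controls,
#' using the DeLong structural-component (placement-value) covariance for
#' the paired difference. If the paired scores are identical the difference
#' and z are exactly zero.
#'
#' @param case_scores_a,control_scores_a Scores under model A.
#' @param case_scores_b,control_scores_b Scores under model B, same subjects
#'   in the same order (pairing is by position).
#' @return List: `auc_a`, `auc_b`, `difference` (A - B), `se`, `z`,
#'   `p_two_sided`.
#' @export
delong_compare <- function(case_scores_a, control_scores_a,
                           case_scores_b, control_scores_b) {
  m <- length(case_scores_a)
  n <- length(control_scores_a)
  if (length(case_scores_b) != m || length(control_scores_b) != n) {
    stop("unpaired inputs: both models must score the same cases and controls",
         call. = FALSE)
  }
  if (m < 2 || n < 2) stop("need at least 2 cases and 2 controls", call. = FALSE)
  pa <- .placements(case_scores_a, control_scores_a)
  pb <- .placements(case_scores_b, control_scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  var_diff <- max(var_diff, 0)
  diff <- pa$auc - pb$auc
  z <- if (var_diff == 0) 0 else diff / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
       se = sqrt(var_diff), z = z, p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Cross-tabulate risk reclassification between two models
#'
#' Subjects are classified high-risk when their predicted risk is strictly
#' greater than the threshold ("more than twice average lifetime risk"),
#' separately under the old and new model, and cross-tabulated separately
#' for cases and controls.
#'
#' @param risks_old,risks_new Per-subject risk probabilities in [0, 1].
#' @param status Per-subject `"case"`/`"control"` (character or factor).
#' @param threshold Risk threshold (> 0), e.g. twice the average lifetime
#'   risk.
#' @return Object of class `reclassification_table`: `threshold` plus 2x2
#'   integer matrices `cases` and `controls` with rows = old category
#'   (low, high) and columns = new category (low, high).
#' @export
reclassify <- function(risks_old, risks_new, status, threshold) {
  stopifnot(length(risks_old) == length(risks_new),
            length(status) == length(risks_old))
  if (any(risks_old < 0 | risks_old > 1 | risks_new < 0 | risks_new > 1)) {
    stop("risks must lie in [0, 1]", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  status <- as.character(status)
  tab1 <- function(keep) {
    old <- factor(risks_old[keep] > threshold, c(FALSE, TRUE), c("low", "high"))
    new <- factor(risks_new[keep] > threshold, c(FALSE, TRUE), c("low", "high"))
    m <- table(old = old, new = new)
    matrix(as.integer(m), 2, 2, dimnames = list(old = c("low", "high"),
                                                new = c("low", "high")))
  }
  reclassification_table(tab1(status == "case"), tab1(status == "control"),
                         threshold)
}

#' Construct a reclassification table from counts
#'
#' Useful for published 2x2 movement counts.
#'
#' @param cases,controls 2x2 matrices (or length-4 vectors, row-major
#'   low->low, low->high, high->low, high->high) of nonnegative integer
#'   counts; rows = old category (low, high), columns = new category.
#' @param threshold The risk threshold the categories refer to.
#' @return Object of class `reclassification_table`.
#' @export
reclassification_table <- function(cases, controls, threshold) {
  shape <- function(m) {
    m <- matrix(as.integer(m), 2, 2, byrow = !is.matrix(m),
                dimnames = list(old = c("low", "high"), new = c("low", "high")))
    if (any(m < 0)) stop("reclassification counts must be nonnegative", call. = FALSE)
    m
  }
  structure(list(threshold = threshold, cases = shape(cases),
                 controls = shape(controls)),
            class = "reclassification_table")
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat(sprintf("<reclassification_table> threshold %.4g (high risk = strictly greater)\n",
              x$threshold))
  for (g in c("controls", "cases")) {
    cat(g, ":\n", sep = "")
    print(x[[g]])
  }
  invisible(x)
}

#' Net reclassification improvement at a fixed threshold
#'
#' Two-category NRI: `(up_cases - down_cases)/n_cases - (up_controls -
#' down_controls)/n_controls`, with the standard (Pencina) variance
#' `[(up_c + down_c)/n_c^2 - (up_c - down_c)^2/n_c^3] + [same for
#' controls]`. The one-sided p-value tests improvement (upper tail); the
#' two-sided p is also reported.
#'
#' @param table A [reclassification_table()] with at least one case and one
#'   control counted.
#' @return Object of class `nri_result`: `nri`, `se`, `z`, `p_one_sided`,
#'   `p_two_sided`, plus the event/non-event components.
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "reclassification_table"))
  nc <- sum(table$cases)
  nk <- sum(table$controls)
  if (nc < 1 || nk < 1) {
    stop("NRI requires at least one case and one control", call. = FALSE)
  }
  up_c <- table$cases["low", "high"];  down_c <- table$cases["high", "low"]
  up_k <- table$controls["low", "high"]; down_k <- table$controls["high", "low"]
  event_net <- (up_c - down_c) / nc
  nonevent_net <- (down_k - up_k) / nk
  est <- event_net + nonevent_net
  v <- (up_c + down_c) / nc^2 - (up_c - down_c)^2 / nc^3 +
    (up_k + down_k) / nk^2 - (up_k - down_k)^2 / nk^3
  se <- sqrt(v)
  z <- if (se == 0) 0 else est / se
  structure(list(nri = est, se = se, z = z,
                 p_one_sided = stats::pnorm(z, lower.tail = FALSE),
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 event_net = event_net, nonevent_net = nonevent_net,
                 n_cases = nc, n_controls = nk),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI %.4f (se %.4f, z %.3f, one-sided p %.3g; events %+.4f, non-events %+.4f)\n",
              x$nri, x$se, x$z, x$p_one_sided, x$event_net, x$nonevent_net))
  invisible(x)
}
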