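#' Primary-screen plate retention rule
#'
#' A mutagenized line is retained when the fraction of anachronistic-sleep
#' (Ans) animals among those scored is at most `max_fraction` — the
#' "30% or less Ans animals" rule, boundary inclusive, with up to 10 young
#' adults scored per plate. Vectorized over plates.
#'
#' @param n_ans Number of Ans animals scored per plate (integer >= 0).
#' @param n_scored Number of animals scored per plate (integer >= 1).
#' @param max_fraction Retention threshold (default 0.30).
#' @return Logical vector: `TRUE` = retained.
#' @examples
#' ans_retention(3, 10)  # TRUE: 30% is retained
#' ans_retention(4, 10)  # FALSE
#' @export
ans_retention <- function(n_ans, n_scored, max_fraction = 0.30) {
  if (length(n_ans) != length(n_scored)) {
    stop_input("`n_ans` and `n_scored` must have equal length")
  }
  if (any(n_scored < 1)) stop_input("`n_scored` must be >= 1 on every plate")
  if (any(n_ans < 0 | n_ans > n_scored)) {
    stop_input("`n_ans` must satisfy 0 <= n_ans <= n_scored")
  }
  check_scalar(max_fraction, "max_fraction", lower = 0, upper = 1)
  n_ans / n_scored <= max_fraction
}

#' Secondary-screen selection by population sleep
#'
#' Selects a line for tertiary screening when its fractional population
#' sleep differs from the control mean by strictly more than `k` control
#' standard deviations, in either direction — both decreased and increased
#' sleepers are informative.
#'
#' @param line_fps FPS of the tested line (single value in `[0, 1]`).
#' @param control_fps Numeric vector of control FPS values (>= 2 values
#'   with nonzero spread).
#' @param k Width of the acceptance region in control SDs (default 2).
#' @return `"selected"` or `"not_selected"`.
#' @export
secondary_select <- function(line_fps, control_fps, k = 2) {
  check_scalar(line_fps, "line_fps", lower = 0, upper = 1)
  if (length(control_fps) < 2L) {
    stop_input("need at least 2 control FPS values")
  }
  s <- stats::sd(control_fps)
  if (!is.finite(s) || s == 0) {
    stop_input("control FPS values are degenerate (zero spread)")
  }
  check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  if (abs(line_fps - mean(control_fps)) > k * s) "selected" else "not_selected"
}

#' Tertiary-screen decision by two-tailed Student's t-test
#'
#' Compares per-animal total sleep between a mutant line and controls with
#' an equal-variance two-sample two-tailed t-test; a line has a sleep defect
#' when `p < alpha`. The direction (more or less sleep than control) is
#' reported alongside. Total sleep is the gating endpoint; lethargus
#' duration and MSBD are descriptive.
#'
#' @param line_sleep Per-animal total sleep of the line, either a numeric
#'   vector (seconds) or a data.frame with a `total_sleep_s` column as
#'   returned by [animal_metrics()].
#' @param control_sleep Same for the control group.
#' @param alpha Significance level (default 0.05).
#' @return List: `p_value`, `defect` (logical), `direction` (`"less"`,
#'   `"more"` or `"none"`), `mean_line`, `mean_control`, `n_line`,
#'   `n_control`.
#' @export
tertiary_test <- function(line_sleep, control_sleep, alpha = 0.05) {
  pull <- function(x, name) {
    if (is.data.frame(x)) {
      if (!"total_sleep_s" %in% names(x)) {
        stop_input(sprintf("`%s` data.frame needs a `total_sleep_s` column",
                           name))
      }
      x <- x$total_sleep_s
    }
    as.numeric(x)
  }
  a <- pull(line_sleep, "line_sleep")
  b <- pull(control_sleep, "control_sleep")
  if (length(a) < 2L || length(b) < 2L) {
    stop_input("each group needs at least 2 animals for a t-test")
  }
  if (length(a) < 10L || length(b) < 10L) {
    warning("fewer than 10 animals in a group; the screen protocol examines",
            " at least 10", call. = FALSE)
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  p <- unname(tt$p.value)
  defect <- p < alpha
  list(
    p_value = p,
    defect = defect,
    direction = if (!defect) "none" else if (mean(a) < mean(b)) "less" else "more",
    mean_line = mean(a), mean_control = mean(b),
    n_line = length(a), n_control = length(b)
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood method: with both
#' margins fixed, sum the hypergeometric probabilities of every table whose
#' point probability does not exceed that of the observed table. This is
#' the convention of common statistics software and the one used for the
#' retrospective comparison of screening routes.
#'
#' @param table A 2x2 matrix of non-negative counts, or the count `a` with
#'   `b`, `c`, `d` supplied separately (rows = groups, columns = outcomes).
#' @param b,c,d Remaining cells when `table` is given as the scalar `a`.
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' # MWT-passed lines 11/21 confirmed vs bypassed lines 5/11 confirmed:
#' fisher_exact_two_sided(11, 10, 5, 6)  # > 0.9999
#' @export
fisher_exact_two_sided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop_input("`table` must be 2x2")
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
    if (is.null(b) || is.null(c) || is.null(d)) {
      stop_input("supply a 2x2 matrix or all four cells a, b, c, d")
    }
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_input("all cells must be non-negative integers")
  }
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  if (m + n2 == 0 || k == 0 || (b + d) == 0 || m == 0 || n2 == 0) {
    stop_input("both margins must be positive")
  }
  # support of the (1,1) cell given fixed margins
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Screen-saturation gene estimate
#'
#' For an F2 recessive screen where a homozygous loss-of-function allele of
#' an average gene appears about once per `lines_per_gene` F2 lines, the
#' expected number of genes recoverable at this screen's hit rate is
#' `hits * lines_per_gene / f2_lines`.
#'
#' @param hits Number of confirmed mutant lines (>= 0).
#' @param f2_lines Number of F2 lines screened (> 0).
#' @param lines_per_gene F2 lines per loss-of-function allele of an average
#'   gene (default 5000).
#' @return List: `expected_genes` (real) and `rounded` (nearest integer).
#' @examples
#' saturation_estimate(16, 2132)  # 37.52 -> 38
#' @export
saturation_estimate <- function(hits, f2_lines, lines_per_gene = 5000) {
  check_scalar(hits, "hits", lower = 0)
  check_scalar(f2_lines, "f2_lines", lower = 0, strict_lower = TRUE)
  check_scalar(lines_per_gene, "lines_per_gene", lower = 0, strict_lower = TRUE)
  expected <- hits * lines_per_gene / f2_lines
  list(expected_genes = expected, rounded = as.integer(round(expected)))
}

#' Funnel accounting across screen stages
#'
#' Counts lines surviving each stage of the screen: F2 lines established,
#' retained by the primary Ans plate score, passing the rescreen (both
#' sublines suppressed), kept as independent lines (sibling lines from one
#' P0 deduplicated), tested in the tertiary chamber assay (selected by the
#' secondary screen or untrackable and passed through), and confirmed
#' tertiary hits. Later stages are conditioned on earlier ones, so counts
#' are non-increasing by construction.
#'
#' @param lines A data.frame with one row per F2 line and logical columns
#'   `primary_retained`, `rescreen_passed`, `independent`, a character
#'   column `secondary_status` (`"selected"`, `"not_selected"`,
#'   `"untrackable"`), and a logical column `tertiary_defect` (`NA` when
#'   not tested).
#' @return One-row data.frame: `f2_lines`, `primary_retained`,
#'   `rescreen_passed`, `independent_lines`, `tertiary_tested`,
#'   `tertiary_hits`.
#' @export
funnel_report <- function(lines) {
  cols <- c("primary_retained", "rescreen_passed", "independent",
            "secondary_status", "tertiary_defect")
  if (!nrow(lines)) {
    return(data.frame(f2_lines = 0L, primary_retained = 0L,
                      rescreen_passed = 0L, independent_lines = 0L,
                      tertiary_tested = 0L, tertiary_hits = 0L))
  }
  missing <- setdiff(cols, names(lines))
  if (length(missing)) {
    stop_input("`lines` is missing columns: ", paste(missing, collapse = ", "))
  }
  s1 <- lines$primary_retained %in% TRUE
  s2 <- s1 & lines$rescreen_passed %in% TRUE
  s3 <- s2 & lines$independent %in% TRUE
  s4 <- s3 & lines$secondary_status %in% c("selected", "untrackable")
  hits <- s4 & lines$tertiary_defect %in% TRUE
  data.frame(
    f2_lines = nrow(lines),
    primary_retained = sum(s1),
    rescreen_passed = sum(s2),
    independent_lines = sum(s3),
    tertiary_tested = sum(s4),
    tertiary_hits = sum(hits)
  )
}
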