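# Cold-stress phenotype metrics: electrolyte leakage index (ELI) and the
# IRRI Standard Evaluation Score (SES) for post-stress recovery.

#' Electrolyte leakage index
#'
#' ELI is the ratio of mean induced electrolyte leakage under stress to the
#' control mean. Injury is flagged when ELI > 1 with a one-sided two-sample
#' t-test (stress > control) at `p < alpha`.
#'
#' @param records data.frame for one accession with columns `condition`
#'   (`control`/`stress`) and `conductivity` (leakage ratio in `[0, 1]`).
#' @param alpha significance level for the injury flag.
#' @return list with `eli`, `p`, `significant`.
#' @export
compute_eli <- function(records, alpha = 0.05) {
  stopifnot(all(c("condition", "conductivity") %in% names(records)))
  if (any(records$conductivity < 0 | records$conductivity > 1))
    stop("conductivity values must lie in [0, 1]")
  ctl <- records$conductivity[records$condition == "control"]
  str <- records$conductivity[records$condition == "stress"]
  if (!length(ctl) || !length(str)) stop("both conditions must be present")
  if (mean(ctl) == 0) stop("zero control mean leakage")
  eli <- mean(str) / mean(ctl)
  # degenerate (constant) data cannot show evidence of injury
  p <- tryCatch(stats::t.test(str, ctl, alternative = "greater")$p.value,
                error = function(e) 1)
  list(eli = eli, p = p, significant = (eli > 1 && p < alpha))
}

#' Standard Evaluation Score from recovery fraction
#'
#' Maps a recovery fraction in `[0, 1]` to the 0-10 SES scale (0 = death,
#' 10 = full recovery) by half-up rounding of `10 * fraction`.
#'
#' @param recovery_fraction numeric in `[0, 1]` (vectorized).
#' @return integer score(s) in 0..10.
#' @export
ses_score <- function(recovery_fraction) {
  if (any(recovery_fraction < 0 | recovery_fraction > 1))
    stop("recovery_fraction must lie in [0, 1]")
  as.integer(floor(10 * recovery_fraction + 0.5))
}
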