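#' Build the analysis set for a chosen outcome
#'
#' Convenience dispatcher: change in past-week consumption or change in
#' AUDIT score among responders for that outcome, or
#' last-observation-carried-forward consumption levels over everyone.
#'
#' @param records Participant records.
#' @param outcome One of \code{"change_pwac"}, \code{"change_audit"},
#'   \code{"locf_pwac"}.
#' @return An \code{analysis_set}.
#' @export
build_analysis_set <- function(records,
                               outcome = c("change_pwac", "change_audit",
                                           "locf_pwac")) {
  outcome <- match.arg(outcome)
  switch(outcome,
         change_pwac  = change_scores(responders(records, "pwac"), "pwac"),
         change_audit = change_scores(responders(records, "audit"), "audit"),
         locf_pwac    = locf_set(records))
}

#' Top-up a trial dataset with extended recruitment
#'
#' Sequential evidence updating across recruitment phases: the contrast is
#' run on the original-phase data alone, then re-run on the original and
#' extended data pooled. Every snapshot is recomputed from the pooled raw
#' records up to that point — Bayes factors are never chained by
#' multiplying per-batch factors, because the half-normal prior is a model
#' of the effect, not a posterior to be updated batch by batch. This is
#' the "top-up" use of Bayes factors: unlike p-values, they may be
#' recomputed on a dataset supplemented after the planned stopping point,
#' regardless of the stopping rule.
#'
#' @param original,extended Participant records for the two recruitment
#'   phases; ids must be disjoint. \code{extended} may have zero rows.
#' @param spec A [contrast_spec()].
#' @param scales Prior scales for the Bayes-factor scan.
#' @param outcome Analysis outcome, see [build_analysis_set()].
#' @return An \code{evidence_trajectory}: list of snapshots, each holding
#'   the phase label, cumulative n, the \code{contrast_result} and the
#'   \code{bf_result} per scale. Coerce with \code{as.data.frame}.
#' @export
topup <- function(original, extended, spec, scales = c(5, 3, 0.5),
                  outcome = "change_pwac") {
  original <- validate_records(original)
  cumulative <- list(original = original)
  if (!is.null(extended) && nrow(extended) > 0L) {
    extended <- validate_records(extended)
    dup <- intersect(original$id, extended$id)
    if (length(dup))
      stop("participant id(s) present in both phases: ",
           paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
    cumulative$extended <- rbind(original, extended)
  }
  snapshots <- lapply(names(cumulative), function(ph) {
    recs <- cumulative[[ph]]
    aset <- build_analysis_set(recs, outcome)
    res <- run_contrast(aset, spec)
    list(phase = ph, n_cumulative = nrow(recs),
         n_analysed = length(aset$values),
         result = res, bfs = bf_scan(res$effect, scales))
  })
  structure(list(snapshots = snapshots, scales = scales, outcome = outcome,
                 spec = spec),
            class = "evidence_trajectory")
}

#' @export
as.data.frame.evidence_trajectory <- function(x, ...) {
  rows <- lapply(x$snapshots, function(s) {
    row <- data.frame(phase = s$phase, n_cumulative = s$n_cumulative,
                      n_analysed = s$n_analysed,
                      mean_diff = s$result$effect$mean_diff,
                      se = s$result$effect$se,
                      F = s$result$F, p = s$result$p)
    for (i in seq_along(x$scales))
      row[[sprintf("bf_h0_%g", x$scales[i])]] <- s$bfs[[i]]$bf
    row$category <- s$bfs[[1L]]$category
    row
  })
  do.call(rbind, rows)
}

#' @export
print.evidence_trajectory <- function(x, ...) {
  cat(sprintf("Evidence trajectory (%s, %s contrast [%s]):\n",
              x$outcome, x$spec$kind, paste(x$spec$modules, collapse = " x ")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Standardised effect size (Cohen's d) from group means and a common SD
#'
#' @param mean_a,mean_b Group means.
#' @param sd Common SD, > 0.
#' @return \code{|mean_a - mean_b| / sd}; planning reports round to 2
#'   decimals.
#' @examples
#' cohens_d(27, 22, 23)  # 0.22 to 2 dp
#' @export
cohens_d <- function(mean_a, mean_b, sd) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single positive number, got ", sd, call. = FALSE)
  abs(mean_a - mean_b) / sd
}

#' Translate a standardised effect onto another outcome scale
#'
#' Converts a Cohen's d on one outcome into the equivalent mean difference
#' on another by multiplying by that outcome's SD (e.g. the consumption
#' effect d = 0.22 becomes 0.22 x 6.56 = 1.4432 AUDIT points). Full
#' precision is retained; round only for display.
#'
#' @param d Positive standardised effect.
#' @param outcome_sd Positive SD of the target outcome.
#' @return \code{d * outcome_sd}.
#' @export
translate_effect <- function(d, outcome_sd) {
  for (nm in c("d", "outcome_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  d * outcome_sd
}

#' Two-sample power under the normal approximation
#'
#' Power of a two-sample two-tailed test at level \code{alpha} with 1:1
#' allocation, \code{n_per_group} per arm, true mean difference
#' \code{delta} and common SD \code{sd}:
#' \deqn{power = \Phi(|\delta| / (\sigma \sqrt{2/n}) - z_{1-\alpha/2}).}
#' At the sample sizes relevant for trial planning the normal
#' approximation differs from the noncentral-t answer by well under 0.002.
#' At \code{delta = 0} the value is alpha/2 — the rejection probability on
#' the predicted side; the two-sided rejection rate remains alpha.
#'
#' @param delta True mean difference between arms.
#' @param sd Common SD, > 0.
#' @param n_per_group Per-arm sample size, >= 2.
#' @param alpha Two-tailed significance level in (0, 1).
#' @return Power in (0, 1).
#' @examples
#' two_sample_power(5, 23, 336)  # about 0.80
#' @export
two_sample_power <- function(delta, sd, n_per_group, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1), got ", alpha, call. = FALSE)
  if (!is.numeric(sd) || sd <= 0)
    stop("'sd' must be > 0, got ", sd, call. = FALSE)
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop("'n_per_group' must be >= 2, got ", n_per_group, call. = FALSE)
  se <- sd * sqrt(2 / n_per_group)
  stats::pnorm(abs(delta) / se - stats::qnorm(1 - alpha / 2))
}

#' Default planning assumptions for the consumption outcome
#'
#' Control mean 27 units/week at follow-up, intervention mean 22
#' units/week (a 5-unit reduction), common SD 23 units, alpha 0.05
#' two-tailed, 1:1 allocation — giving d = 0.22 and 80% power at 336 per
#' group (672 total).
#'
#' @return Named list of the assumptions.
#' @export
planning_assumptions <- function() {
  list(control_mean = 27, intervention_mean = 22, common_sd = 23,
       alpha = 0.05, allocation = "1:1")
}
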