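#' Configuration of an analysis run
#'
#' Bundles the inputs and choices of a full report run: input CSV paths
#' (original phase, optional extended phase), the analysis outcome, the
#' prior scales (defaulting to 5, 3, 0.5 units/week for consumption
#' outcomes and 1.45 points for the AUDIT change, the conventional
#' large/medium/small scan), which contrasts to run, and the output
#' directory.
#'
#' @param input Path to the original-phase participant CSV.
#' @param extended Optional path to the extended-phase CSV; when given,
#'   an evidence-trajectory file is also written.
#' @param outcome \code{"change_pwac"}, \code{"change_audit"} or
#'   \code{"locf_pwac"}.
#' @param scales Positive prior scales; default depends on outcome.
#' @param contrasts \code{"mains"} (all five main effects), \code{"pairs"}
#'   (all ten two-way interactions), or a list of [contrast_spec()]
#'   objects (e.g. a named synergy subset).
#' @param out_dir Output directory, created if absent.
#' @param seed Optional integer recorded in the run log.
#' @return A \code{run_config} object.
#' @export
run_config <- function(input, extended = NULL,
                       outcome = c("change_pwac", "change_audit", "locf_pwac"),
                       scales = NULL, contrasts = "mains",
                       out_dir = ".", seed = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(scales))
    scales <- if (outcome == "change_audit") 1.45 else c(5, 3, 0.5)
  if (!is.numeric(scales) || length(scales) == 0L || any(scales <= 0))
    stop("'scales' must be a non-empty vector of positive numbers",
         call. = FALSE)
  if (is.character(contrasts)) {
    contrasts <- match.arg(contrasts, c("mains", "pairs"))
    codes <- names(trial_modules())
    contrasts <- if (contrasts == "mains") {
      lapply(codes, function(m) contrast_spec("main", m))
    } else {
      pairs <- utils::combn(codes, 2L, simplify = FALSE)
      lapply(pairs, function(p) contrast_spec("interaction", p))
    }
  }
  if (!all(vapply(contrasts, inherits, logical(1L), "contrast_spec")))
    stop("'contrasts' must be \"mains\", \"pairs\" or a list of contrast_spec",
         call. = FALSE)
  structure(list(input = input, extended = extended, outcome = outcome,
                 scales = scales, contrasts = contrasts,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run a full analysis and write report files
#'
#' Reads the participant CSV(s), applies eligibility filtering, builds
#' the analysis set for the configured outcome, runs every configured
#' contrast, and writes to the output directory: the rounded report table
#' (\code{report.csv} and a plain-text \code{report.txt}), the
#' full-precision table (\code{report_full.csv}), a run log
#' (\code{run_log.txt}: inputs, counts, exclusions, seed, number of
#' contrasts run — no multiplicity adjustment is applied), and, when an
#' extended-phase file is given, the evidence trajectory
#' (\code{trajectory.csv}). Outputs are deterministic functions of the
#' inputs and config.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the contrast results, the report data
#'   frame and the written file paths.
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config object", call. = FALSE)
  original <- read_trial_csv(config$input)
  extended <- if (!is.null(config$extended)) read_trial_csv(config$extended)

  original_ok <- filter_eligible(original)
  extended_ok <- if (!is.null(extended)) filter_eligible(extended)
  all_ok <- if (is.null(extended_ok)) original_ok else
    rbind(original_ok, extended_ok)

  aset <- build_analysis_set(all_ok, config$outcome)
  results <- lapply(config$contrasts, function(sp) run_contrast(aset, sp))
  tab <- report_table(results, config$scales, rounded = TRUE)
  tab_full <- report_table(results, config$scales, rounded = FALSE)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(report = file.path(config$out_dir, "report.csv"),
                report_full = file.path(config$out_dir, "report_full.csv"),
                text = file.path(config$out_dir, "report.txt"),
                log = file.path(config$out_dir, "run_log.txt"))
  utils::write.csv(tab, paths$report, row.names = FALSE)
  utils::write.csv(tab_full, paths$report_full, row.names = FALSE)
  writeLines(c(sprintf("Outcome: %s | prior scales: %s", config$outcome,
                       paste(config$scales, collapse = ", ")),
               utils::capture.output(print(tab, row.names = FALSE))),
             paths$text)

  acct <- phase_accounting(all_ok)
  log_lines <- c(
    sprintf("input: %s", config$input),
    sprintf("extended: %s", if (is.null(config$extended)) "(none)" else config$extended),
    sprintf("outcome: %s", config$outcome),
    sprintf("scales: %s", paste(config$scales, collapse = ",")),
    sprintf("seed: %s", if (is.null(config$seed)) "(none)" else config$seed),
    sprintf("records read: %d original, %d extended",
            nrow(original), if (is.null(extended)) 0L else nrow(extended)),
    sprintf("excluded by eligibility: %d (plus %d invalid)",
            attr(original_ok, "n_removed") +
              (if (is.null(extended_ok)) 0L else attr(extended_ok, "n_removed")),
            attr(original_ok, "n_rejected") +
              (if (is.null(extended_ok)) 0L else attr(extended_ok, "n_rejected"))),
    sprintf("analysed: %d of %d", length(aset$values), nrow(all_ok)),
    sprintf("contrasts run (unadjusted): %d", length(results)),
    utils::capture.output(print(acct, row.names = FALSE)))
  writeLines(log_lines, paths$log)

  trajectory <- NULL
  if (!is.null(extended_ok) && length(config$contrasts) >= 1L) {
    trajectory <- topup(original_ok, extended_ok, config$contrasts[[1L]],
                        scales = config$scales, outcome = config$outcome)
    paths$trajectory <- file.path(config$out_dir, "trajectory.csv")
    utils::write.csv(as.data.frame(trajectory), paths$trajectory,
                     row.names = FALSE)
  }
  invisible(list(results = results, table = tab, trajectory = trajectory,
                 paths = paths))
}

#' Bayes-factor table from printed group summaries
#'
#' Reproduces a published contrast row directly from the group sizes,
#' means and SDs a paper prints, with no raw data: builds the Welch-SE
#' effect estimate (mean difference = \code{mean_b - mean_a}, group A =
#' enhanced / "all on", group B = minimal / "all off"), then the pooled-F
#' columns and the Bayes factor at each prior scale.
#'
#' @param n_a,mean_a,sd_a Enhanced-group size, mean, SD.
#' @param n_b,mean_b,sd_b Minimal-group size, mean, SD.
#' @param scales Positive prior scales.
#' @param rounded Round for display as in [report_table()].
#' @return One-row data frame: mean_diff, se, F, p, one \code{bf_h0_*}
#'   column per scale, category.
#' @examples
#' # responders-only four-module synergy row
#' summary_mode(27, -21.6, 20.36, 12, -12.1, 26.82, scales = c(5, 3, 0.5))
#' @export
summary_mode <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b,
                         scales = c(5, 3, 0.5), rounded = TRUE) {
  eff <- effect_from_summaries(n_a, mean_a, sd_a, n_b, mean_b, sd_b)
  res <- structure(list(kind = "summary", modules = character(0L),
                        effect = eff,
                        F = NA_real_, p = NA_real_),
                   class = "contrast_result")
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  res$F <- eff$mean_diff^2 / (sp2 * (1 / n_a + 1 / n_b))
  res$p <- stats::pf(res$F, 1, n_a + n_b - 2, lower.tail = FALSE)
  tab <- report_table(list(res), scales, rounded = rounded)
  tab$contrast <- "summary"
  tab
}
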