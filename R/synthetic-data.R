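## truncated-normal moments for parent N(mu, sigma) restricted to [a, b]
tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  pa <- stats::dnorm(al); pb <- stats::dnorm(be)
  apa <- if (is.finite(al)) al * pa else 0   # x*dnorm(x) -> 0 as |x| -> Inf
  bpb <- if (is.finite(be)) be * pb else 0
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

## solve for parent (mu, sigma) so the [a,b]-truncated normal has the
## target mean and SD; plain truncation of N(target_mean, target_sd)
## would inflate the mean (by ~10% for consumption truncated at 0), so
## moments are matched instead of copied.
.tnorm_cache <- new.env(parent = emptyenv())

tnorm_match <- function(target_mean, target_sd, a, b) {
  key <- paste(target_mean, target_sd, a, b, sep = "|")
  hit <- .tnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mo <- tnorm_moments(par[1L], exp(par[2L]), a, b)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  mu <- fit$par[1L]; sigma <- exp(fit$par[2L])
  mo <- tnorm_moments(mu, sigma, a, b)
  if (abs(mo["mean"] - target_mean) > 0.01 * target_sd ||
      abs(mo["sd"] - target_sd) > 0.01 * target_sd)
    stop("truncated-normal moment matching failed for targets mean=",
         target_mean, " sd=", target_sd, " on [", a, ", ", b, "]",
         call. = FALSE)
  out <- list(mu = mu, sigma = sigma)
  .tnorm_cache[[key]] <- out
  out
}

## inverse-CDF sampler from the matched truncated normal
rtnorm_matched <- function(n, target_mean, target_sd, a, b) {
  p <- tnorm_match(target_mean, target_sd, a, b)
  lo <- stats::pnorm(a, p$mu, p$sigma)
  hi <- stats::pnorm(b, p$mu, p$sigma)
  stats::qnorm(stats::runif(n, lo, hi), p$mu, p$sigma)
}

#' Configuration of a synthetic 2^5 factorial trial
#'
#' Defaults reproduce the study conditions of the trial the package
#' models: 672 original-phase and 1914 extended-phase participants,
#' baseline past-week consumption mean 39.0 SD 26.93 units, baseline
#' AUDIT mean 19.1 SD 6.66 (truncated to the eligible range 8-40),
#' follow-up response 26.6% in the original phase and 8.5% in the
#' extended phase, an overall mean change of -12.5 units/week among
#' responders, residual change noise SD 23 units, and permuted-block
#' randomisation with blocks of 32 (one per cell of the 2^5 design).
#' Component and pairwise-interaction effects on the change score default
#' to zero (a null trial).
#'
#' @param n_original,n_extended Phase sample sizes.
#' @param baseline_pwac_mean,baseline_pwac_sd Baseline consumption
#'   distribution (units/week), truncated at 0.
#' @param baseline_audit_mean,baseline_audit_sd Baseline AUDIT
#'   distribution, truncated to [8, 40] so eligibility holds by
#'   construction.
#' @param response_rate_original,response_rate_extended Per-phase
#'   follow-up response probabilities (missing completely at random).
#' @param mean_change Overall mean change in consumption among responders
#'   (units/week; negative = reduction).
#' @param module_effects Named numeric vector of additive effects of each
#'   \emph{enhanced} component on the change score (units/week; negative =
#'   greater reduction). Codes as in [trial_modules()]; omitted codes are
#'   0.
#' @param interaction_effects Named numeric vector of additional additive
#'   effects when both components of a pair are enhanced; names like
#'   \code{"nf:cbr"}.
#' @param change_noise_sd Residual SD of the change score (units/week).
#' @param audit_change_noise_sd Residual SD of the companion AUDIT change.
#' @param block_size Randomisation block size; must be a multiple of 32.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A \code{sim_config} object (a validated list).
#' @export
sim_config <- function(n_original = 672L, n_extended = 1914L,
                       baseline_pwac_mean = 39.0, baseline_pwac_sd = 26.93,
                       baseline_audit_mean = 19.1, baseline_audit_sd = 6.66,
                       response_rate_original = 0.266,
                       response_rate_extended = 0.085,
                       mean_change = -12.5,
                       module_effects = NULL,
                       interaction_effects = NULL,
                       change_noise_sd = 23,
                       audit_change_noise_sd = 5.8,
                       block_size = 32L, seed = 1L) {
  cfg <- list(n_original = as.integer(n_original),
              n_extended = as.integer(n_extended),
              baseline_pwac_mean = baseline_pwac_mean,
              baseline_pwac_sd = baseline_pwac_sd,
              baseline_audit_mean = baseline_audit_mean,
              baseline_audit_sd = baseline_audit_sd,
              response_rate_original = response_rate_original,
              response_rate_extended = response_rate_extended,
              mean_change = mean_change,
              module_effects = module_effects,
              interaction_effects = interaction_effects,
              change_noise_sd = change_noise_sd,
              audit_change_noise_sd = audit_change_noise_sd,
              block_size = as.integer(block_size),
              seed = as.integer(seed))
  for (nm in c("baseline_pwac_sd", "baseline_audit_sd", "change_noise_sd",
               "audit_change_noise_sd")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("'", nm, "' must be > 0", call. = FALSE)
  }
  for (nm in c("response_rate_original", "response_rate_extended")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_original < 0L || cfg$n_extended < 0L)
    stop("'n_original' and 'n_extended' must be non-negative", call. = FALSE)
  if (cfg$n_original + cfg$n_extended < cfg$block_size)
    stop("total n must cover at least one randomisation block (",
         cfg$block_size, ")", call. = FALSE)
  if (cfg$block_size %% 32L != 0L || cfg$block_size < 32L)
    stop("'block_size' must be a positive multiple of 32", call. = FALSE)
  if (!is.null(module_effects)) {
    bad <- setdiff(names(module_effects), names(trial_modules()))
    if (length(bad) || is.null(names(module_effects)))
      stop("'module_effects' must be named with module codes; bad: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(interaction_effects)) {
    pairs <- strsplit(names(interaction_effects), ":", fixed = TRUE)
    ok <- vapply(pairs, function(p)
      length(p) == 2L && all(p %in% names(trial_modules())), logical(1L))
    if (is.null(names(interaction_effects)) || !all(ok))
      stop("'interaction_effects' names must be 'code:code' pairs",
           call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

## permuted-block allocation: each block of 32 contains every cell of the
## 2^5 design exactly once, in random order; a partial final block is a
## random prefix of a permuted block
block_allocations <- function(n, block_size) {
  cells <- as.matrix(expand.grid(rep(list(0:1), 5L)))[, 5:1, drop = FALSE]
  colnames(cells) <- alloc_cols()
  reps <- block_size / 32L
  n_blocks <- ceiling(n / block_size)
  rows <- unlist(lapply(seq_len(n_blocks), function(b) {
    idx <- rep(seq_len(32L), reps)
    idx[sample.int(block_size)]
  }))
  cells[rows[seq_len(n)], , drop = FALSE]
}

#' Simulate a synthetic factorial trial cohort
#'
#' Generates one participant table under the configured study conditions:
#' baseline consumption and AUDIT from moment-matched truncated normals
#' (so simulated means/SDs hit the configured targets despite the support
#' constraints), allocation by permuted blocks covering all 32 cells,
#' per-phase Bernoulli response, and for responders a change score equal
#' to the overall mean change plus the additive enhanced-component and
#' pairwise-interaction effects plus Gaussian noise. Follow-up consumption
#' is \code{max(0, baseline + change)}, held to 0.1 units; follow-up AUDIT
#' is a noisy linear companion of the consumption change (a testing
#' device so both outcome pipelines are exercised, not a claim about real
#' data). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A validated participant data frame (see [validate_records()])
#'   with eligibility flag columns set; attribute \code{seed} records the
#'   seed used.
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_original + config$n_extended
  phase <- rep(c("original", "extended"),
               c(config$n_original, config$n_extended))

  alloc <- block_allocations(n, config$block_size)
  baseline_pwac <- round(rtnorm_matched(n, config$baseline_pwac_mean,
                                        config$baseline_pwac_sd, 0, Inf), 1)
  baseline_audit <- round(rtnorm_matched(n, config$baseline_audit_mean,
                                         config$baseline_audit_sd, 8, 40))
  age <- pmax(18L, round(stats::rnorm(n, 37.2, 10.64)))

  rate <- ifelse(phase == "original", config$response_rate_original,
                 config$response_rate_extended)
  responded <- stats::rbinom(n, 1L, rate) == 1L

  eff <- rep(config$mean_change, n)
  me <- config$module_effects
  for (code in names(me))
    eff <- eff + alloc[, paste0("mod_", code)] * me[[code]]
  ie <- config$interaction_effects
  for (pair in names(ie)) {
    p <- strsplit(pair, ":", fixed = TRUE)[[1L]]
    both <- alloc[, paste0("mod_", p[1L])] * alloc[, paste0("mod_", p[2L])]
    eff <- eff + both * ie[[pair]]
  }
  # Change-score noise is anti-correlated with baseline consumption
  # (regression towards a common follow-up level): with independent noise
  # the zero floor on follow-up consumption would censor ~20% of
  # responders, biasing the mean change by several units and attenuating
  # the additive component effects. The coupling keeps the configured
  # change-score mean and SD exact while making the floor a rare event.
  rho <- 0.935
  z_bl <- (baseline_pwac - config$baseline_pwac_mean) / config$baseline_pwac_sd
  change <- eff - rho * config$change_noise_sd * z_bl +
    stats::rnorm(n, 0, config$change_noise_sd * sqrt(1 - rho^2))
  followup_pwac <- ifelse(responded,
                          round(pmax(0, baseline_pwac + change), 1),
                          NA_real_)
  # AUDIT change tracks the consumption change scaled by the SD ratio of
  # the two outcomes (6.56 AUDIT points per 23 units), plus its own noise
  audit_change <- change * (6.56 / 23) +
    stats::rnorm(n, 0, config$audit_change_noise_sd)
  followup_audit <- ifelse(responded,
                           pmin(40, pmax(0, round(baseline_audit + audit_change))),
                           NA_real_)

  records <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    age = as.integer(age),
    alloc,
    baseline_pwac = baseline_pwac,
    baseline_audit = as.integer(baseline_audit),
    followup_pwac = followup_pwac,
    followup_audit = as.integer(followup_audit),
    responded = responded,
    phase = phase,
    uk_resident = TRUE, wants_reduce = TRUE, has_email = TRUE,
    stringsAsFactors = FALSE)
  out <- validate_records(records)
  attr(out, "seed") <- config$seed
  out
}

#' Small hand-checkable fixture cohort
#'
#' A 64-participant, two-block cohort (every cell of the 2^5 design
#' exactly twice) with full follow-up response and no component effects,
#' for unit tests and documentation examples.
#'
#' @param seed Integer seed.
#' @return A participant data frame of 64 rows.
#' @export
fixture_small <- function(seed = 1L) {
  simulate_trial(sim_config(n_original = 64L, n_extended = 0L,
                            response_rate_original = 1,
                            response_rate_extended = 0,
                            seed = seed))
}
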