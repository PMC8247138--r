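## Synthetic longitudinal ASV count tables with planted temporal structure.
##
## The generator emulates a 6-subject, 15-timepoint isolation study: a core
## of high-abundance "stable" ASVs shared by most subjects, a large tail of
## low-abundance sporadic "transient" ASVs, piecewise-linear within-subject
## turnover with planted change-points, phase-aligned diet shifts, subject
## offsets and uneven negative-binomial sequencing depth.

#' Synthetic study design
#'
#' Defaults reproduce the emulated study conditions: 6 subjects sampled at
#' 15 timepoints (7 outbound, 5 return, 3 follow-up) across days 1-720 with
#' isolation ending at day 520, the last follow-up sample dropped for the
#' final two subjects (two discarded samples), change-points planted at
#' days 123 and 480 and per-segment turnover slopes
#' (+0.00103, -0.00064, +0.00123) per day.
#'
#' Within-subject turnover is induced by mean-reverting (AR(1)) drift of
#' stable-ASV log-abundances: at the transition ending on day t the step
#' standard deviation is chosen so that the expected consecutive-timepoint
#' Bray-Curtis dissimilarity tracks the planted piecewise-linear target
#' \eqn{v(t)}. Mean reversion (stationary log-sd \code{walk_sd}) keeps
#' between-subject divergence flat in time, matching the observed
#' between-subjects behaviour. Transient ASVs churn through a per-subject
#' on/off Markov switch, giving independent gain and loss events; after
#' isolation ends the gain probability rises so that the expected number of
#' newly formed subject-ASV edges per transition increases by
#' \code{postiso_formed_jump}.
#'
#' @param n_subjects number of subjects.
#' @param outbound_days,return_days,followup_days sampling days per phase.
#' @param n_dropped_followup number of subjects whose final follow-up
#'   sample is discarded (the last subjects by id, by convention).
#' @param isolation_end last day of isolation.
#' @param n_stable_asvs,n_transient_asvs family sizes.
#' @param stable_mean_abundance,transient_mean_abundance mean abundance
#'   (arbitrary relative units) of the two families.
#' @param stable_log_sd,transient_log_sd log-scale spread of base
#'   abundances across ASVs.
#' @param nb_dispersion negative-binomial size parameter of the count draw.
#' @param depth_range integer pair: uniform library-depth range.
#' @param planted_changepoints strictly increasing days inside the span.
#' @param segment_turnover_slopes per-day turnover slope per segment
#'   (length = changepoints + 1).
#' @param baseline_turnover expected within-subject Bray-Curtis at the
#'   start of the mission.
#' @param turnover_floor turnover contributed by sampling noise and
#'   transient churn, subtracted before converting the target into a drift
#'   step size.
#' @param step_concentration mixing weight in [0, 1] of the fixed-magnitude
#'   (random-direction) component of each drift step versus its Gaussian
#'   component. Concentrated magnitudes emulate coordinated community
#'   shifts and make per-transition turnover track the planted trajectory
#'   tightly; 0 gives pure lognormal diffusion.
#' @param step_sd_spread log-sd of per-ASV step-size multipliers (mean 1):
#'   with spread, a minority of ASVs carries most of the turnover, which
#'   is what makes per-ASV "drivers of diversity" detectable against
#'   quieter ASVs.
#' @param walk_sd stationary log-sd of the mean-reverting drift.
#' @param driver_boost step-size multiplier assigned to the designated
#'   driver ASVs.
#' @param subject_effect_sd log-scale sd of per-subject per-ASV offsets.
#' @param diet_effect_size log-fold shift of diet-responsive ASVs during
#'   the first food variant (FV) relative to TV/NR.
#' @param diet_asv_fraction fraction of stable ASVs that respond to diet.
#' @param n_driver_asvs stable ASVs whose drift steps have near-fixed
#'   magnitude and random sign, so their absolute consecutive differences
#'   cleanly follow the planted segment pattern ("drivers of diversity").
#' @param transient_on_prob,transient_off_prob per-transition Markov switch
#'   rates of transient ASVs.
#' @param churn_decay fractional linear decline of both switch rates across
#'   the full span (slightly fading churn).
#' @param postiso_formed_jump planted increase in expected formed edges per
#'   subject-transition after isolation ends.
#' @param seed default master seed for \code{\link{generateSynthetic}}.
#' @return a validated list of class \code{syntheticDesign}.
#' @export
syntheticDesign <- function(
    n_subjects = 6,
    outbound_days = c(1, 21, 52, 83, 114, 145, 176),
    return_days = c(271, 302, 364, 425, 480),
    followup_days = c(540, 630, 716),
    n_dropped_followup = 2,
    isolation_end = 520,
    n_stable_asvs = 600, n_transient_asvs = 1200,
    stable_mean_abundance = 100, transient_mean_abundance = 15,
    stable_log_sd = 0.25, transient_log_sd = 0.5,
    nb_dispersion = 60, depth_range = c(20000, 120000),
    planted_changepoints = c(123, 480),
    segment_turnover_slopes = c(0.00103, -0.00064, 0.00123),
    baseline_turnover = 0.35, turnover_floor = 0.04,
    step_concentration = 0.8, step_sd_spread = 0,
    walk_sd = 1.1, subject_effect_sd = 0.35,
    diet_effect_size = 0.6, diet_asv_fraction = 0.15,
    n_driver_asvs = 15, driver_boost = 1.5,
    transient_on_prob = 0.15, transient_off_prob = 0.45,
    churn_decay = 0.2, postiso_formed_jump = 28,
    seed = 42L) {
  d <- as.list(environment())
  days <- c(d$outbound_days, d$return_days, d$followup_days)
  if (any(diff(days) <= 0)) stop("sampling days must be strictly increasing")
  cps <- d$planted_changepoints
  if (length(cps) && (any(diff(cps) <= 0) || any(cps <= min(days)) ||
                      any(cps >= max(days))))
    stop("planted change-points must be strictly increasing and inside ",
         "the day range")
  if (length(d$segment_turnover_slopes) != length(cps) + 1)
    stop("need one turnover slope per segment (changepoints + 1)")
  if (d$n_subjects < 2) stop("need at least two subjects")
  if (d$n_dropped_followup > d$n_subjects)
    stop("cannot drop follow-up samples from more subjects than exist")
  for (f in c("stable_mean_abundance", "transient_mean_abundance",
              "nb_dispersion", "walk_sd"))
    if (d[[f]] <= 0) stop(f, " must be positive")
  for (f in c("subject_effect_sd", "diet_effect_size", "turnover_floor",
              "churn_decay", "postiso_formed_jump"))
    if (d[[f]] < 0) stop(f, " must be non-negative")
  if (d$transient_on_prob <= 0 || d$transient_on_prob >= 1 ||
      d$transient_off_prob <= 0 || d$transient_off_prob >= 1)
    stop("transient switch rates must lie in (0, 1)")
  if (d$n_driver_asvs > d$n_stable_asvs)
    stop("driver ASVs must be a subset of stable ASVs")
  structure(d, class = "syntheticDesign")
}

## planted within-subject turnover target v(day): piecewise-linear
## cumulative effect of the per-segment slopes from day 1
targetTurnover <- function(design, day) {
  bounds <- c(min(design$outbound_days), design$planted_changepoints,
              max(design$followup_days))
  s <- design$segment_turnover_slopes
  vapply(day, function(t) {
    cum <- 0
    for (j in seq_along(s)) {
      lo <- bounds[j]; hi <- bounds[j + 1]
      cum <- cum + s[j] * max(0, min(t, hi) - lo) * (t > lo)
      if (t <= hi) break
    }
    design$baseline_turnover + cum
  }, 0)
}

## Expected |1 - W| for a log-abundance step sigma*(gamma*R +
## sqrt(1-gamma^2)*Z) with R Rademacher, Z standard normal, mean-corrected
## so E[W] = 1. Closed form via the lognormal partial expectation; the
## gamma -> 1 limit is tanh(sigma).
expAbsStep <- function(sigma, gamma) {
  a <- gamma * sigma
  b <- sigma * sqrt(max(0, 1 - gamma^2))
  if (b < 1e-8) return(tanh(a))
  branch <- function(sgn) {
    m <- exp(sgn * a) / cosh(a)
    z0 <- (b^2 / 2 - log(m)) / b
    2 * pnorm(z0) - 2 * m * pnorm(z0 - b) + m - 1
  }
  (branch(1) + branch(-1)) / 2
}

## invert E[Bray-Curtis] ~ expAbsStep(sigma)/2 for the drift step size
turnoverStepSd <- function(v, floor, gamma) {
  eff <- pmin(pmax(v - floor, 0.02), 0.45)
  vapply(eff, function(e)
    uniroot(function(s) expAbsStep(s, gamma) - 2 * e,
            c(1e-4, 10), tol = 1e-8)$root, 0)
}

#' Generate a synthetic longitudinal count table
#'
#' @param design a \code{\link{syntheticDesign}}.
#' @param seed master seed (defaults to \code{design$seed}); the generator
#'   draws from the \code{"synthetic_data"} substream so other stages are
#'   unaffected.
#' @param tree if \code{TRUE} (default) also build a random coalescent
#'   phylogeny over all ASVs.
#' @return a \linkS4class{LongitudinalASVTable}; the phylogeny sits in
#'   \code{metadata(x)$tree} and the planted ground truth (stable /
#'   transient / driver / diet-responsive ASV ids, change-points, slopes,
#'   per-day turnover targets) in \code{metadata(x)$truth}.
#' @export
generateSynthetic <- function(design = syntheticDesign(),
                              seed = design$seed, tree = TRUE) {
  stopifnot(inherits(design, "syntheticDesign"))
  set.seed(seedFor(seed, "synthetic_data"))
  allDays <- c(design$outbound_days, design$return_days,
               design$followup_days)
  phase <- rep(c("outbound", "return", "followup"),
               c(length(design$outbound_days), length(design$return_days),
                 length(design$followup_days)))
  diet <- c(outbound = "FV", return = "TV", followup = "NR")[phase]
  nT <- length(allDays)
  maxDay <- max(allDays)
  subj <- sprintf("%04d", 5000 + seq_len(design$n_subjects))
  dropped <- if (design$n_dropped_followup > 0)
    utils::tail(subj, design$n_dropped_followup) else character()

  nS <- design$n_stable_asvs; nR <- design$n_transient_asvs
  stableIds <- sprintf("ASV_S%04d", seq_len(nS))
  transIds <- sprintf("ASV_T%04d", seq_len(nR))
  baseS <- rnorm(nS, log(design$stable_mean_abundance),
                 design$stable_log_sd)
  dietIdx <- sample(nS, round(design$diet_asv_fraction * nS))
  driverIdx <- if (design$n_driver_asvs > 0)
    sample(setdiff(seq_len(nS), dietIdx), design$n_driver_asvs)
  else integer()
  dietShift <- numeric(nS)
  dietShift[dietIdx] <- design$diet_effect_size

  ## drift step sd per transition, from the planted turnover trajectory
  vTarget <- targetTurnover(design, allDays)
  gamma <- design$step_concentration
  stepSd <- turnoverStepSd(vTarget, design$turnover_floor, gamma)
  V <- design$walk_sd^2
  if (any(stepSd[-1]^2 >= 4 * V))
    stop("turnover target too large for the stationary drift variance; ",
         "increase walk_sd")
  ## per-ASV step-size multipliers: drivers get a fixed boost, the rest a
  ## lognormal spread with mean 1

  ## transient churn: losses are per-ASV Bernoulli switches while gains
  ## arrive as a Poisson number of activations drawn from the off-pool.
  ## Exogenous gains keep gain and loss events independent (the paper's
  ## independence finding) and make the planted post-isolation jump in
  ## formed edges enter the expectation additively and exactly.
  decay <- 1 - design$churn_decay * allDays / maxDay
  piBar <- design$transient_on_prob /
    (design$transient_on_prob + design$transient_off_prob)
  postIso <- allDays > design$isolation_end
  gainRate <- design$transient_on_prob * (1 - piBar) * nR * decay +
    design$postiso_formed_jump * postIso
  pOff <- design$transient_off_prob * decay

  sizeMult <- exp(rnorm(nS, -design$step_sd_spread^2 / 2,
                        design$step_sd_spread))
  if (length(driverIdx)) sizeMult[driverIdx] <- design$driver_boost

  counts <- NULL; meta <- NULL
  for (s in seq_along(subj)) {
    keep <- if (subj[s] %in% dropped) seq_len(nT - 1) else seq_len(nT)
    offs <- rnorm(nS, 0, design$subject_effect_sd)
    ## stable: AR(1) deviations; step directions mix a fixed-magnitude
    ## (Rademacher) component with a Gaussian one; drivers step with pure
    ## fixed magnitude so their |difference| series is clean
    u <- matrix(0, nS, nT)
    u[, 1] <- rnorm(nS, 0, sqrt(V))
    eta <- sqrt(1 - gamma^2)
    ## drivers: deterministic alternating direction with exact step
    ## magnitude (random starting sign per subject) -- their |difference|
    ## series equals the planted step-size trajectory, stays bounded, and
    ## adds no stationary-variance inflation
    drvSign <- sample(c(-1, 1), length(driverIdx), replace = TRUE)
    for (k in 2:nT) {
      rho <- 1 - stepSd[k]^2 / (2 * V)
      innovSd <- sqrt(V * (1 - rho^2))
      dir <- gamma * sample(c(-1, 1), nS, replace = TRUE) +
        eta * rnorm(nS)
      u[, k] <- rho * u[, k - 1] + innovSd * dir
      if (length(driverIdx)) {
        drvSign <- -drvSign
        u[driverIdx, k] <- u[driverIdx, k - 1] +
          design$driver_boost * stepSd[k] * drvSign
      }
    }
    xs <- baseS + offs + sizeMult * u +
      outer(dietShift, as.numeric(diet == "FV"))
    ## transient: per-ASV loss switches, Poisson gains from the off-pool
    lev <- exp(rnorm(nR, log(design$transient_mean_abundance),
                     design$transient_log_sd))
    st <- matrix(FALSE, nR, nT)
    st[, 1] <- runif(nR) < piBar
    for (k in 2:nT) {
      stay <- st[, k - 1] & runif(nR) >= pOff[k]
      offPool <- which(!st[, k - 1])
      nGain <- min(rpois(1, gainRate[k]), length(offPool))
      st[, k] <- stay
      if (nGain > 0)
        st[sample(offPool, nGain), k] <- TRUE
    }
    w <- rbind(exp(xs), lev * st)
    for (k in keep) {
      p <- w[, k] / sum(w[, k])
      depth <- round(runif(1, design$depth_range[1], design$depth_range[2]))
      cts <- rnbinom(nS + nR, mu = p * depth, size = design$nb_dispersion)
      if (sum(cts) == 0) cts[which.max(p)] <- 1L
      counts <- cbind(counts, cts)
      meta <- rbind(meta, data.frame(
        sample_id = sprintf("%s_d%03d", subj[s], allDays[k]),
        subject = subj[s], day = allDays[k], diet = diet[k],
        phase = phase[k]))
    }
  }
  rownames(counts) <- c(stableIds, transIds)
  colnames(counts) <- meta$sample_id
  out <- LongitudinalASVTable(counts, meta,
                              isolationEnd = design$isolation_end)
  truth <- list(design = design, stable_asvs = stableIds,
                transient_asvs = transIds,
                driver_asvs = stableIds[driverIdx],
                diet_asvs = stableIds[dietIdx],
                changepoint_days = design$planted_changepoints,
                segment_slopes = design$segment_turnover_slopes,
                target_turnover = data.frame(day = allDays, v = vTarget))
  S4Vectors::metadata(out)$truth <- truth
  if (tree) {
    phy <- ape::rcoal(nS + nR, tip.label = sample(c(stableIds, transIds)))
    S4Vectors::metadata(out)$tree <- phy
  }
  out
}
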