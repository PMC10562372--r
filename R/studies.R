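# Seeded simulation studies wrapping the generator + estimators.
# These are the package's own operating-characteristic experiments:
# parameter recovery under trait-dependent rates, null calibration of
# the mixed-model LRT, and family-wise error of the Tukey procedure.

#' Parameter-recovery study for the phylogenetic mixed model
#'
#' For each replicate: simulate a Yule chronogram, a conditioned
#' 3-state (or k-state) trait history, and a phylogram with the given
#' state multipliers and lognormal noise; fit the mixed model of
#' log(root-to-tip brl) on the tip states with the phylogram-derived
#' kinship; record the contrast estimates, their standard errors, and
#' whether the per-category mean brl ordering matches the simulated
#' multiplier ordering.
#'
#' @param nReps number of replicates.
#' @param nTips tips per tree.
#' @param states trait labels, reference state first.
#' @param multipliers named multipliers (reference state must be 1).
#' @param noiseSd lognormal branch-segment noise sd.
#' @param minStateFrac conditioning threshold passed to the generator.
#' @param seed base seed; replicate r uses seed + 101 * r.
#' @return list with `perRep` (data.frame: one row per replicate and
#'   non-reference state, columns estimate, se, trueLog, covered),
#'   `coverage` (fraction of replicates with every contrast within
#'   2 SE of its true log multiplier), `orderingOk` (fraction with
#'   correct group-mean ordering).
#' @export
recoveryStudy <- function(nReps = 50, nTips = 500,
                          states = c("F", "EctoP", "EndoP"),
                          multipliers = c(F = 1, EctoP = 2, EndoP = 4),
                          noiseSd = 0.3, minStateFrac = 0.08, seed = 1) {
  ref <- states[1L]
  rows <- list(); orderOk <- logical(nReps); covered <- logical(nReps)
  for (r in seq_len(nReps)) {
    cfg <- SimulationConfig(nTips = nTips, lhtStates = states,
                            rootLht = ref, multipliers = multipliers,
                            noiseSd = noiseSd, minStateFrac = minStateFrac,
                            seed = seed + 101L * r)
    ds <- makeBenchmarkDataset(cfg)
    td <- traitData(ds@traits)
    lab <- setNames(td$lht, td$species)
    x <- brl(rootToTipLengths(ds@phylogram))
    sp <- names(x)
    K <- bmCovariance(ds@phylogram, "correlation")[sp, sp]
    X <- model.matrix(~ factor(lab[sp], levels = states))
    colnames(X) <- c("(Intercept)", states[-1L])
    fit <- plmmFit(log(x[sp]), X, K,
                   label = "log brl ~ state + RE")
    est <- coef(fit)[states[-1L]]
    se <- fit@se[states[-1L]]
    trueLog <- log(multipliers[states[-1L]] / multipliers[ref])
    hit <- abs(est - trueLog) <= 2 * se
    covered[r] <- all(hit)
    gm <- groupSummary(x, lab)
    obsOrder <- gm$category[order(gm$mean)]
    trueOrder <- names(sort(multipliers))
    orderOk[r] <- identical(obsOrder, trueOrder)
    rows[[r]] <- data.frame(rep = r, state = states[-1L],
                            estimate = unname(est), se = unname(se),
                            trueLog = unname(trueLog),
                            covered = unname(hit), row.names = NULL)
  }
  list(perRep = do.call(rbind, rows), coverage = mean(covered),
       orderingOk = mean(orderOk))
}

#' Null calibration of the mixed-model likelihood-ratio test
#'
#' With all state multipliers equal the trait has no effect on branch
#' lengths, so the chi-square LRT p-values of the trait model against
#' the intercept-only model should be approximately Uniform(0, 1).
#'
#' @param nReps replicates.
#' @param nTips tips per tree.
#' @param states trait labels.
#' @param noiseSd lognormal branch noise sd.
#' @param minStateFrac conditioning threshold.
#' @param seed base seed.
#' @return list with `p` (vector of LRT p-values), `ksP`
#'   (Kolmogorov-Smirnov p against Uniform(0,1)) and `rejectRate` at
#'   alpha = 0.05.
#' @export
nullCalibrationStudy <- function(nReps = 200, nTips = 100,
                                 states = c("F", "EctoP", "EndoP"),
                                 noiseSd = 0.3, minStateFrac = 0.08,
                                 seed = 1) {
  mult <- setNames(rep(1, length(states)), states)
  p <- numeric(nReps)
  for (r in seq_len(nReps)) {
    cfg <- SimulationConfig(nTips = nTips, lhtStates = states,
                            rootLht = states[1L], multipliers = mult,
                            noiseSd = noiseSd, minStateFrac = minStateFrac,
                            seed = seed + 313L * r)
    ds <- makeBenchmarkDataset(cfg)
    td <- traitData(ds@traits)
    lab <- setNames(td$lht, td$species)
    x <- brl(rootToTipLengths(ds@phylogram))
    sp <- names(x)
    K <- bmCovariance(ds@phylogram, "correlation")[sp, sp]
    y <- log(x[sp])
    X0 <- matrix(1, length(y), dimnames = list(NULL, "(Intercept)"))
    X1 <- model.matrix(~ factor(lab[sp], levels = states))
    alt <- plmmFit(y, X1, K)
    null <- plmmFit(y, X0, K)
    p[r] <- likelihoodRatioTest(alt, null)$p
  }
  list(p = p, ksP = stats::ks.test(p, "punif")$p.value,
       rejectRate = mean(p < 0.05))
}

#' Family-wise error of the Tukey HSD procedure under the global null
#'
#' Draws `k` independent normal groups with equal means and counts the
#' replicates in which any pair is declared significant.
#'
#' @param nReps replicates.
#' @param k number of groups.
#' @param n per-group sample size.
#' @param alpha nominal family-wise level.
#' @param seed seed.
#' @return list with `fwe` (observed family-wise error rate), `mcSe`
#'   (its Monte-Carlo standard error) and `nReps`.
#' @export
tukeyFweStudy <- function(nReps = 500, k = 4, n = 8, alpha = 0.05,
                          seed = 1) {
  withSeed(seed, {
    anySig <- vapply(seq_len(nReps), function(r) {
      v <- rnorm(k * n)
      g <- rep(letters[seq_len(k)], each = n)
      any(tukeyPairwise(v, g, alpha = alpha)$pairs$significant)
    }, logical(1))
    list(fwe = mean(anySig),
         mcSe = sqrt(mean(anySig) * (1 - mean(anySig)) / nReps),
         nReps = nReps)
  })
}
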