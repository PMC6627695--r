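#' Configuration for the synthetic Ct generator
#'
#' Describes a study-shaped synthetic qRT-PCR panel:
#' \deqn{Ct_{gs} = B_g + \delta_{g,group(s)} + u_s + \epsilon_{gs}}
#' with gene baselines \eqn{B_g} uniform over \code{baselineRange},
#' shared per-sample technical offsets \eqn{u_s \sim N(0, \tau^2)},
#' gene-specific Gaussian noise \eqn{\epsilon_{gs} \sim N(0, \sigma_g^2)},
#' and additive group shifts \eqn{\delta} for planted unstable genes.
#' Defaults emulate the chondrocyte study shape: 47 assays (46 miRNAs +
#' 1 snRNA) across 26 samples in three groups (PC 8, DC 9, HYP 9 — nine
#' donors, with the precursor sample of the last donor absent), mean Ct
#' spanning roughly 13-26 cycles.
#'
#' Planted roles are disjoint and assigned to randomly chosen genes:
#' \code{nStable} genes with \code{stableSD} noise and no shift,
#' \code{nUnstableVar} genes with \code{unstableSD} noise,
#' \code{nShifted} genes with a \code{shiftSize}-cycle shift in one group
#' (round-robin over groups); remaining background genes draw their noise
#' SD uniformly from \code{noiseRange}.  Missing (undetected) calls are
#' injected uniformly at random into background genes only, at
#' \code{missingRate}.
#'
#' @param nGenes total number of assays.
#' @param groupSizes named integer vector of samples per group (each >= 2).
#' @param baselineRange range of uniform gene baselines (cycles).
#' @param sampleOffsetSD tau, SD of the shared per-sample offset (cycles).
#' @param noiseRange range of background per-gene noise SDs (cycles).
#' @param nStable,stableSD planted stable genes and their noise SD.
#' @param nUnstableVar,unstableSD planted high-variance genes and their SD.
#' @param nShifted,shiftSize planted group-shifted genes and the shift
#'   magnitude (cycles).
#' @param missingRate probability an individual background-gene call is
#'   undetected.
#' @return A \code{SynthConfig} object.
#' @seealso [simulateCtExperiment()], [recoveryExperiment()]
#' @export
synthConfig <- function(nGenes = 47L,
                        groupSizes = c(PC = 8L, DC = 9L, HYP = 9L),
                        baselineRange = c(13, 26),
                        sampleOffsetSD = 0.5,
                        noiseRange = c(0.5, 1.2),
                        nStable = 3L, stableSD = 0.2,
                        nUnstableVar = 3L, unstableSD = 2,
                        nShifted = 3L, shiftSize = 2,
                        missingRate = 0) {
  new("SynthConfig",
      nGenes = as.integer(nGenes), groupSizes = groupSizes,
      baselineRange = as.numeric(baselineRange),
      sampleOffsetSD = as.numeric(sampleOffsetSD),
      noiseRange = as.numeric(noiseRange),
      nStable = as.integer(nStable), stableSD = as.numeric(stableSD),
      nUnstableVar = as.integer(nUnstableVar),
      unstableSD = as.numeric(unstableSD),
      nShifted = as.integer(nShifted), shiftSize = as.numeric(shiftSize),
      missingRate = as.numeric(missingRate))
}

#' @rdname synthConfig
#' @export
setClass("SynthConfig", representation(
  nGenes = "integer", groupSizes = "numeric", baselineRange = "numeric",
  sampleOffsetSD = "numeric", noiseRange = "numeric",
  nStable = "integer", stableSD = "numeric",
  nUnstableVar = "integer", unstableSD = "numeric",
  nShifted = "integer", shiftSize = "numeric", missingRate = "numeric"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nGenes < 3L) msg <- c(msg, "nGenes must be >= 3")
  if (is.null(names(object@groupSizes)) || any(object@groupSizes < 2)) {
    msg <- c(msg, "groupSizes must be named and each >= 2")
  }
  planted <- object@nStable + object@nUnstableVar + object@nShifted
  if (planted > object@nGenes) {
    msg <- c(msg, "planted gene sets exceed nGenes (must be disjoint)")
  }
  if (any(c(object@stableSD, object@unstableSD, object@sampleOffsetSD,
            object@noiseRange) < 0)) {
    msg <- c(msg, "all SDs must be >= 0")
  }
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msg <- c(msg, "missingRate must be in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d genes x %d samples (%s)\n",
    object@nGenes, sum(object@groupSizes),
    paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
          collapse = ", ")
  ))
  cat(sprintf(
    "  baseline U(%.1f, %.1f) | tau = %.2f | background sigma U(%.2f, %.2f)\n",
    object@baselineRange[1L], object@baselineRange[2L],
    object@sampleOffsetSD, object@noiseRange[1L], object@noiseRange[2L]
  ))
  cat(sprintf(
    "  planted: %d stable (sigma %.2f), %d unstable (sigma %.2f), %d shifted (delta %.1f) | missing %.1f%%\n",
    object@nStable, object@stableSD, object@nUnstableVar, object@unstableSD,
    object@nShifted, object@shiftSize, 100 * object@missingRate
  ))
})

#' Simulate a study-shaped Ct panel with known truth
#'
#' Draws one synthetic dataset from a [synthConfig()] model.  Fully
#' reproducible from \code{seed}; the per-sample offset SD \code{tau}
#' enters only as a multiplier on a pre-drawn standard-normal offset
#' stream, so two runs with the same seed and different
#' \code{sampleOffsetSD} share identical gene noise — the handle used to
#' study offset-only sensitivity.
#'
#' @param config a \code{SynthConfig}.
#' @param seed integer random seed.
#' @return A list with \code{experiment} (a \linkS4class{CtExperiment})
#'   and \code{truth}, a list carrying \code{baseline}, \code{sigma},
#'   \code{role}, the gene x group \code{shift} matrix, per-sample
#'   \code{offset}, and the realized \code{noise} matrix, satisfying
#'   \code{ct = baseline + shift[, group] + offset + noise} exactly at
#'   every detected cell.
#' @export
simulateCtExperiment <- function(config, seed) {
  stopifnot(is(config, "SynthConfig"))
  methods::validObject(config)
  set.seed(as.integer(seed))
  k <- config@nGenes
  groups <- factor(rep(names(config@groupSizes), config@groupSizes),
                   levels = names(config@groupSizes))
  n <- length(groups)
  ## nine-donor style labelling: donors recycle within each group
  donor <- unlist(lapply(config@groupSizes, function(m) {
    sprintf("D%02d", seq_len(m))
  }), use.names = FALSE)
  samples <- paste0(donor, "-", groups)
  genes <- c(sprintf("miR-s%03d", seq_len(k - 1L)), "snRNA-U44s")

  baseline <- stats::runif(k, config@baselineRange[1L],
                           config@baselineRange[2L])
  role <- rep("background", k)
  planted <- sample.int(k, config@nStable + config@nUnstableVar +
                          config@nShifted)
  role[planted] <- rep(c("stable", "unstable_variance", "group_shifted"),
                       c(config@nStable, config@nUnstableVar,
                         config@nShifted))
  sigma <- stats::runif(k, config@noiseRange[1L], config@noiseRange[2L])
  sigma[role == "stable"] <- config@stableSD
  sigma[role == "unstable_variance"] <- config@unstableSD

  shift <- matrix(0, k, nlevels(groups),
                  dimnames = list(genes, levels(groups)))
  shiftedIdx <- which(role == "group_shifted")
  for (i in seq_along(shiftedIdx)) {
    g <- 1L + (i - 1L) %% nlevels(groups)  # round-robin target group
    shift[shiftedIdx[i], g] <- config@shiftSize
  }

  noise <- matrix(stats::rnorm(k * n), k, n) * sigma
  offset <- config@sampleOffsetSD * stats::rnorm(n)
  ct <- baseline + shift[, as.integer(groups)] + noise +
    rep(offset, each = k)
  dimnames(ct) <- list(genes, samples)

  if (config@missingRate > 0) {
    bg <- role == "background"
    mask <- matrix(stats::runif(sum(bg) * n) < config@missingRate,
                   sum(bg), n)
    ct[bg, ][mask] <- NA_real_
  }

  truth <- list(baseline = stats::setNames(baseline, genes),
                sigma = stats::setNames(sigma, genes),
                role = stats::setNames(role, genes),
                shift = shift,
                offset = stats::setNames(offset, samples),
                noise = matrix(noise, k, n,
                               dimnames = list(genes, samples)))
  list(experiment = CtExperiment(ct, group = groups, donor = donor),
       truth = truth)
}

#' Parameter-recovery experiment over replicated synthetic panels
#'
#' Runs the full pipeline (detection filter, four stability estimators,
#' geometric-mean consensus) on \code{nReplicates} independent synthetic
#' datasets and summarizes how reliably the planted structure is
#' recovered:
#' \itemize{
#'   \item \code{stable_rank1_rate}: fraction of replicates whose
#'     consensus rank-1 gene is a planted stable gene;
#'   \item \code{shifted_bottom_decile_rate}: mean fraction of planted
#'     group-shifted genes ranked in the bottom 10\% by multi-group
#'     NormFinder;
#'   \item \code{bestkeeper_only_offset_rate}: fraction of replicates in
#'     which raising the per-sample offset SD to \code{tauHigh} (same
#'     seed, identical gene noise) inflates the mean BestKeeper
#'     dispersion while leaving every geNorm/delta-Ct/NormFinder
#'     stability value unchanged to 1e-9.
#' }
#'
#' @param config a \code{SynthConfig}; must plant at least one stable
#'   gene, and at least one shifted gene for the NormFinder summary.
#' @param nReplicates number of independent datasets.
#' @param seed integer; replicate r uses seed \code{seed + r}.
#' @param tauHigh raised per-sample offset SD for the sensitivity check
#'   (set \code{NULL} to skip it).
#' @return A list with the three rates, \code{n_replicates}, and the
#'   per-replicate consensus rank-1 gene roles.
#' @export
recoveryExperiment <- function(config, nReplicates = 100L, seed = 1L,
                               tauHigh = 2) {
  stopifnot(config@nStable >= 1L)
  rank1Role <- character(nReplicates)
  shiftedHit <- numeric(nReplicates)
  bkOnly <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    sim <- simulateCtExperiment(config, seed = seed + r)
    ce <- sim$experiment
    if (anyNA(ctValues(ce))) {
      ce <- suppressMessages(filterCompleteDetection(ce))
    }
    tabs <- runAllStability(ce, dataset = "pooled")
    cons <- combineRankings(tabs)
    rank1Role[r] <- unname(sim$truth$role[cons$gene[1L]])

    nf <- tabs$normfinder
    nGenes <- nrow(nf)
    shifted <- names(sim$truth$role)[sim$truth$role == "group_shifted"]
    shifted <- intersect(shifted, nf$gene)
    if (length(shifted)) {
      cutoff <- 0.9 * nGenes
      shiftedHit[r] <- mean(nf$rank[match(shifted, nf$gene)] > cutoff)
    } else {
      shiftedHit[r] <- NA_real_
    }

    if (!is.null(tauHigh)) {
      cfgHigh <- config
      cfgHigh@sampleOffsetSD <- as.numeric(tauHigh)
      simHigh <- simulateCtExperiment(cfgHigh, seed = seed + r)
      ceHigh <- simHigh$experiment
      if (anyNA(ctValues(ceHigh))) {
        ceHigh <- suppressMessages(filterCompleteDetection(ceHigh))
      }
      tabsHigh <- runAllStability(ceHigh, dataset = "pooled")
      sameVals <- function(m) {
        a <- tabs[[m]]; b <- tabsHigh[[m]]
        max(abs(a$value - b$value[match(a$gene, b$gene)]))
      }
      invariant <- max(sameVals("genorm"), sameVals("deltact"),
                       sameVals("normfinder")) < 1e-9
      inflated <- mean(tabsHigh$bestkeeper$value) >
        mean(tabs$bestkeeper$value)
      bkOnly[r] <- invariant && inflated
    }
  }
  list(
    stable_rank1_rate = mean(rank1Role == "stable"),
    shifted_bottom_decile_rate = mean(shiftedHit, na.rm = TRUE),
    bestkeeper_only_offset_rate = if (is.null(tauHigh)) NA_real_ else
      mean(bkOnly),
    n_replicates = nReplicates,
    rank1_roles = rank1Role
  )
}
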