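#' Create a generator configuration
#'
#' Builds a validated [GeneratorConfig-class].  The defaults describe the
#' structural conditions under which promoter-feature leakage is studied:
#' 400 promoter groups averaging 8 candidate pairs each (~3200 pairs) on a
#' 5 x 50 Mb genome, a 1:20 positive:negative ratio, 136 marks per region
#' (408 EPW features), pure promoter groups (every group entirely positive
#' or entirely negative), and zero genuine label signal.
#'
#' @param nChromosomes,chromLength,nPromoters,marksPerRegion,targetPosFraction,profileMode,groupSizeMean,groupSizeMax,betaA,betaB,trackSegmentBp,signalStrength,nSignalFeatures,featureNoiseSd,minDistance,maxDistance,seed
#'   See [GeneratorConfig-class].  \code{nSignalFeatures} defaults to 16,
#'   capped at \code{marksPerRegion}.
#' @return A [GeneratorConfig-class].
#' @examples
#' generatorConfig(nPromoters = 20, marksPerRegion = 8, seed = 1)
#' @export
generatorConfig <- function(nChromosomes = 5L, chromLength = 5e7,
                            nPromoters = 400L, marksPerRegion = 136L,
                            targetPosFraction = 1 / 21,
                            profileMode = c("pure_mixture", "beta"),
                            groupSizeMean = 8, groupSizeMax = 30L,
                            betaA = 0.2, betaB = 4.0,
                            trackSegmentBp = 5e4,
                            signalStrength = 0, nSignalFeatures = NULL,
                            featureNoiseSd = 0,
                            minDistance = 1e4, maxDistance = 2e6,
                            seed = 1L) {
  if (is.null(nSignalFeatures))
    nSignalFeatures <- min(16L, as.integer(marksPerRegion))
  new("GeneratorConfig",
      nChromosomes = as.integer(nChromosomes), chromLength = chromLength,
      nPromoters = as.integer(nPromoters),
      marksPerRegion = as.integer(marksPerRegion),
      targetPosFraction = targetPosFraction,
      profileMode = match.arg(profileMode),
      groupSizeMean = groupSizeMean, groupSizeMax = as.integer(groupSizeMax),
      betaA = betaA, betaB = betaB, trackSegmentBp = trackSegmentBp,
      signalStrength = signalStrength,
      nSignalFeatures = as.integer(nSignalFeatures),
      featureNoiseSd = featureNoiseSd,
      minDistance = minDistance, maxDistance = maxDistance,
      seed = as.integer(seed))
}

#' Sample a promoter-group positive/negative profile
#'
#' Draws, for each promoter, the number of positive and negative EP pairs
#' that will share it.  Group sizes are \code{2 + } a geometric draw with
#' mean \code{groupSizeMean - 2}, truncated at \code{groupSizeMax}, so
#' every promoter is shared by at least two pairs.  In
#' \code{"pure_mixture"} mode each group is entirely positive with
#' probability \code{targetPosFraction} (and entirely negative otherwise),
#' which makes the expected global positive fraction equal to
#' \code{targetPosFraction} while every multi-pair group is maximally
#' imbalanced.  In \code{"beta"} mode each group draws a positive fraction
#' \code{q ~ Beta(betaA, betaB)} and then
#' \code{n_pos ~ Binomial(size, q)}, producing mixed groups whose expected
#' positive fraction is \code{betaA / (betaA + betaB)}.
#'
#' Uses the current RNG state; [simulateEPDataset()] seeds it from the
#' configuration.
#'
#' @param config A [GeneratorConfig-class].
#' @return A \code{data.frame} with columns \code{n_pos}, \code{n_neg},
#'   one row per promoter.
#' @export
sampleGroupProfile <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  n <- config@nPromoters
  extra_mean <- config@groupSizeMean - 2
  sizes <- if (extra_mean <= 0) rep(2L, n) else
    2L + pmin(stats::rgeom(n, prob = 1 / (extra_mean + 1)),
              config@groupSizeMax - 2L)
  if (config@profileMode == "pure_mixture") {
    pos_group <- stats::runif(n) < config@targetPosFraction
    n_pos <- ifelse(pos_group, sizes, 0L)
  } else {
    q <- stats::rbeta(n, config@betaA, config@betaB)
    n_pos <- stats::rbinom(n, sizes, q)
  }
  data.frame(n_pos = as.integer(n_pos), n_neg = as.integer(sizes - n_pos))
}

## Enhancer-promoter gaps follow a distance-decay law: the log-scale
## position between minDistance and maxDistance is Beta(1, 3), so most
## pairs are proximal (tens of kb) with a thin tail of megabase-scale
## pairs, as in real EP candidate sets where contact frequency decays
## with genomic distance.  This keeps window-overlap components local
## instead of chaining whole chromosomes together.
.sampleGap <- function(n, config) {
  expo <- stats::rbeta(n, 1, 3)
  round(config@minDistance *
          (config@maxDistance / config@minDistance)^expo)
}

.PROM_WIDTH <- 2000
.ENH_WIDTH <- 1000

#' Lay out promoters and enhancers on a synthetic genome
#'
#' Places one 2 kb promoter per profile row uniformly at random on the
#' synthetic chromosomes (kept \code{maxDistance} away from chromosome
#' ends so both flanks are usable), then places each group's 1 kb
#' enhancers on a uniformly chosen side at log-uniform gaps in
#' \code{[minDistance, maxDistance]}.  No two elements overlap; positions
#' violating this are redrawn.  Positive labels are assigned to a random
#' subset of each group's enhancers according to the profile.
#'
#' Enhancers of one promoter that land on the same side have nested
#' windows, and nearby promoters' pairs can also overlap windows -- the
#' two geometric routes to shared window features.
#'
#' @param profile Output of [sampleGroupProfile()].
#' @param config A [GeneratorConfig-class].
#' @return An [EPDataset-class] with labels set and an empty feature
#'   table.
#' @export
layoutGenome <- function(profile, config) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0L,
            is(config, "GeneratorConfig"))
  sizes <- profile$n_pos + profile$n_neg
  if (any(sizes < 1L)) stop("every group needs at least one pair")
  margin <- config@maxDistance + .ENH_WIDTH
  lo <- margin
  hi <- config@chromLength - margin - .PROM_WIDTH
  if (hi <= lo)
    stop("chromosome too short (", config@chromLength,
         " bp) to host promoters with maxDistance = ", config@maxDistance)
  nprom <- nrow(profile)
  chroms <- paste0("chr", seq_len(config@nChromosomes))
  ## occupied elements per chromosome, 1-based closed for IRanges
  occupied <- stats::setNames(
    rep(list(IRanges()), config@nChromosomes), chroms)
  place <- function(chrom, width) {
    for (try in seq_len(200L)) {
      s <- floor(stats::runif(1, lo, hi))  # BED start
      cand <- IRanges(s + 1, s + width)
      if (!length(IRanges::findOverlaps(cand, occupied[[chrom]],
                                        minoverlap = 1L)))
        return(s)
    }
    stop("could not place an element without overlap; ",
         "genome too crowded for the requested layout")
  }
  prom_chrom <- sample(chroms, nprom, replace = TRUE)
  prom_start <- numeric(nprom)
  for (p in seq_len(nprom)) {
    s <- place(prom_chrom[p], .PROM_WIDTH)
    prom_start[p] <- s
    occupied[[prom_chrom[p]]] <- c(occupied[[prom_chrom[p]]],
                                   IRanges(s + 1, s + .PROM_WIDTH))
  }
  rows <- vector("list", nprom)
  for (p in seq_len(nprom)) {
    sz <- sizes[p]
    chrom <- prom_chrom[p]
    ps <- prom_start[p]; pe <- ps + .PROM_WIDTH
    enh_start <- numeric(sz)
    for (e in seq_len(sz)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        side <- if (stats::runif(1) < 0.5) -1 else 1
        gap <- .sampleGap(1, config)
        es <- if (side > 0) pe + gap else ps - gap - .ENH_WIDTH
        cand <- IRanges(es + 1, es + .ENH_WIDTH)
        if (es >= 0 && es + .ENH_WIDTH <= config@chromLength &&
            !length(IRanges::findOverlaps(cand, occupied[[chrom]],
                                          minoverlap = 1L))) {
          enh_start[e] <- es
          occupied[[chrom]] <- c(occupied[[chrom]], cand)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place an enhancer without overlap; ",
             "genome too crowded for the requested layout")
    }
    lab <- integer(sz)
    lab[sample.int(sz, profile$n_pos[p])] <- 1L
    rows[[p]] <- data.frame(
      pair_id = sprintf("prom%04d_e%02d", p, seq_len(sz)),
      chrom = chrom,
      enh_start = enh_start, enh_end = enh_start + .ENH_WIDTH,
      prom_start = ps, prom_end = pe,
      promoter_id = sprintf("prom%04d", p),
      label = lab)
  }
  EPDataset(do.call(rbind, rows))
}

## Integral of a piecewise-constant track (values `vals`, one column per
## mark, segment length `seg`) from 0 to each position in `x`.
.trackIntegral <- function(x, vals, seg) {
  k <- pmin(floor(x / seg), nrow(vals))
  cs <- rbind(0, apply(vals, 2, cumsum)) * seg
  part <- (x - k * seg) * vals[pmin(k + 1L, nrow(vals)), , drop = FALSE]
  part[x >= nrow(vals) * seg, ] <- 0
  cs[k + 1L, , drop = FALSE] + part
}

#' Generate E/P/W feature blocks for a laid-out dataset
#'
#' Fills the feature table with \code{marksPerRegion} features per block:
#' \itemize{
#'   \item P block: a standard-normal latent vector per promoter, shared
#'     bit-for-bit by every pair with that promoter -- the shared-promoter
#'     leakage mechanism.
#'   \item E block: an independent standard-normal latent vector per
#'     enhancer, plus \code{signalStrength} added to the first
#'     \code{nSignalFeatures} columns of positive pairs (the only genuine
#'     label signal; zero by default).
#'   \item W block: per-mark means over the pair's window of a
#'     per-chromosome piecewise-constant standard-normal latent track with
#'     \code{trackSegmentBp} segments, so pairs with overlapping windows
#'     have correlated W features (correlation 1 at identical windows) --
#'     the shared-window leakage mechanism.
#' }
#' With \code{featureNoiseSd > 0}, iid Gaussian noise is added to every
#' feature of every pair afterwards.
#'
#' Uses the current RNG state; [simulateEPDataset()] seeds it from the
#' configuration.
#'
#' @param dataset An [EPDataset-class] from [layoutGenome()] (any features
#'   are replaced).
#' @param config A [GeneratorConfig-class].
#' @return The dataset with the 3 x \code{marksPerRegion} feature columns
#'   attached.
#' @export
generateFeatures <- function(dataset, config) {
  stopifnot(is(dataset, "EPDataset"), is(config, "GeneratorConfig"))
  cd <- colData(dataset)
  n <- ncol(dataset)
  m <- config@marksPerRegion
  marks <- sprintf("M%03d", seq_len(m))
  prom_ids <- unique(cd$promoter_id)
  ## P: one latent per promoter, replicated across its pairs
  u <- matrix(stats::rnorm(length(prom_ids) * m), length(prom_ids), m)
  P <- u[match(cd$promoter_id, prom_ids), , drop = FALSE]
  ## E: one latent per pair (enhancers are pair-specific) + label signal
  E <- matrix(stats::rnorm(n * m), n, m)
  if (config@signalStrength > 0 && config@nSignalFeatures > 0L) {
    sig_cols <- seq_len(config@nSignalFeatures)
    E[cd$label == 1L, sig_cols] <- E[cd$label == 1L, sig_cols, drop = FALSE] +
      config@signalStrength
  }
  ## W: mean of a piecewise-constant latent track over the window
  seg <- config@trackSegmentBp
  nseg <- ceiling(config@chromLength / seg)
  wstart <- pmin(cd$enh_end, cd$prom_end)
  wend <- pmax(cd$enh_start, cd$prom_start)
  if (any(wstart >= wend))
    stop("zero-width window; cannot compute W features")
  W <- matrix(NA_real_, n, m)
  for (chrom in paste0("chr", seq_len(config@nChromosomes))) {
    vals <- matrix(stats::rnorm(nseg * m), nseg, m)
    idx <- which(cd$chrom == chrom)
    if (!length(idx)) next
    Fa <- .trackIntegral(wstart[idx], vals, seg)
    Fb <- .trackIntegral(wend[idx], vals, seg)
    W[idx, ] <- (Fb - Fa) / (wend[idx] - wstart[idx])
  }
  feat <- cbind(E, P, W)
  if (config@featureNoiseSd > 0)
    feat <- feat + matrix(stats::rnorm(n * 3L * m, sd = config@featureNoiseSd),
                          n, 3L * m)
  colnames(feat) <- c(paste0("E|", marks), paste0("P|", marks),
                      paste0("W|", marks))
  pairs <- data.frame(pair_id = colnames(dataset),
                      as.data.frame(cd[.PAIR_COLUMNS]))
  EPDataset(pairs, feat)
}

#' Simulate a complete synthetic EP dataset
#'
#' Runs the three generator stages -- [sampleGroupProfile()],
#' [layoutGenome()], [generateFeatures()] -- under the configuration's
#' seed.  The result is fully deterministic: the same configuration
#' (including seed) always yields a bit-identical dataset.
#'
#' With the default configuration (zero signal, pure promoter groups) the
#' label is conditionally independent of every feature given promoter
#' identity, so any above-random performance of a classifier evaluated
#' with a leakage-free partition indicates a defect, while high
#' random-CV performance quantifies leakage.
#'
#' @param config A [GeneratorConfig-class].
#' @return An [EPDataset-class] with labels and the full EPW feature
#'   table.
#' @examples
#' ds <- simulateEPDataset(generatorConfig(nPromoters = 10,
#'                                         marksPerRegion = 4, seed = 7))
#' ds
#' @export
simulateEPDataset <- function(config = generatorConfig()) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  withr::with_seed(config@seed, {
    profile <- sampleGroupProfile(config)
    ds <- layoutGenome(profile, config)
    generateFeatures(ds, config)
  })
}
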