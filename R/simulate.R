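# Seeded synthetic-cistrome generator. Latent regulatory sites are placed
# on a toy genome and assigned a co-binding code from a designed
# distribution; factor peak sets, tag tracks (Poisson background plus
# enrichment kernels at sites), heavy-tailed enhancer intensities, a
# knockdown that attenuates the anchor at cofactor-bound sites, and a
# patient cohort whose 3-gene expression code shifts event hazard are all
# derived from those latent sites. Every generator returns its ground
# truth, so each analysis stage is testable by parameter recovery.

# Default co-binding design over (GATA3, NR2F2, FOXA1): 25% of anchor sites
# bound by all three, 36% by exactly two, 24% by exactly one, 15% by none;
# cardinality mass split equally within each cardinality.
.defaultComboProbs <- function() {
  c("111" = 0.25, "110" = 0.12, "101" = 0.12, "011" = 0.12,
    "100" = 0.08, "010" = 0.08, "001" = 0.08, "000" = 0.15)
}

# Co-binding design for the knockdown experiment: the NR2F2 bit (second
# position) has marginal probability exactly 0.60.
.perturbComboProbs <- function() {
  c("111" = 0.25, "110" = 0.12, "011" = 0.13, "101" = 0.12,
    "010" = 0.10, "100" = 0.07, "001" = 0.06, "000" = 0.15)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cistrome generator with validated
#' defaults. The default co-binding design over (GATA3, NR2F2, FOXA1)
#' plants 25% triple-bound, 36% double, 24% single and 15% unbound anchor
#' sites; anchor tag enrichment grows with co-binding cardinality; the
#' enhancer-intensity distribution is a 95/5 gamma-body / Pareto-tail
#' mixture; the knockdown attenuates anchor tags 4x at NR2F2-bound sites;
#' and the cohort hazard is raised for patients whose 3-gene code has at
#' most one high bit.
#'
#' @param seed integer master seed.
#' @param genome named numeric of chromosome lengths (bp).
#' @param nSites number of latent regulatory sites.
#' @param factors ordered factor labels (code bit order).
#' @param comboProbs named probabilities over binary codes (sum 1).
#' @param peakWidthMean,peakWidthSd,minPeakWidth peak width model (bp).
#' @param jitterSd sd (bp) of per-factor peak-center displacement.
#' @param minSeparation minimum distance between latent site centers (bp).
#' @param anchorEnrichment named tag-rate multipliers by co-binding
#'   cardinality ("0".."k").
#' @param siteTagMean mean tags per site at multiplier 1.
#' @param backgroundRate background tags per bp.
#' @param knockdownAttenuation multiplicative tag attenuation (in (0, 1])
#'   applied at targeted sites in the knockdown condition.
#' @param knockdownTarget factor whose code bit selects targeted sites.
#' @param seTailFraction,seBodyShape,seBodyScale,seParetoShape,seParetoScale
#'   enhancer-intensity mixture: `1 - seTailFraction` of sites draw
#'   gamma(shape, scale) intensities, the rest Pareto(shape, scale).
#' @param atacLossRate fraction of condition-A peaks lost in condition B.
#' @param nPatients,hazardRatio,baseHazard,censorRate,exprHigh,exprLow,exprSd
#'   cohort model: exponential event times with per-code hazard
#'   multipliers, exponential censoring, and gaussian expression around a
#'   high or low mean per code bit.
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(seed = 1,
                      genome = c(chr1 = 1e8, chr2 = 8e7, chr3 = 6e7),
                      nSites = 20000,
                      factors = c("GATA3", "NR2F2", "FOXA1"),
                      comboProbs = .defaultComboProbs(),
                      peakWidthMean = 300, peakWidthSd = 50, minPeakWidth = 50,
                      jitterSd = 30, minSeparation = 4000,
                      anchorEnrichment = c("0" = 0.5, "1" = 1, "2" = 2, "3" = 4),
                      siteTagMean = 60, backgroundRate = 1e-5,
                      knockdownAttenuation = 0.25, knockdownTarget = "NR2F2",
                      seTailFraction = 0.05, seBodyShape = 5, seBodyScale = 2,
                      seParetoShape = 2.5, seParetoScale = 150,
                      atacLossRate = 0.69,
                      nPatients = 400, hazardRatio = 3, baseHazard = 0.05,
                      censorRate = 0.03, exprHigh = 9, exprLow = 2,
                      exprSd = 1.25) {
  cfg <- list(seed = seed, genome = genome, nSites = nSites, factors = factors,
              comboProbs = comboProbs, peakWidthMean = peakWidthMean,
              peakWidthSd = peakWidthSd, minPeakWidth = minPeakWidth,
              jitterSd = jitterSd, minSeparation = minSeparation,
              anchorEnrichment = anchorEnrichment, siteTagMean = siteTagMean,
              backgroundRate = backgroundRate,
              knockdownAttenuation = knockdownAttenuation,
              knockdownTarget = knockdownTarget,
              seTailFraction = seTailFraction, seBodyShape = seBodyShape,
              seBodyScale = seBodyScale, seParetoShape = seParetoShape,
              seParetoScale = seParetoScale, atacLossRate = atacLossRate,
              nPatients = nPatients, hazardRatio = hazardRatio,
              baseHazard = baseHazard, censorRate = censorRate,
              exprHigh = exprHigh, exprLow = exprLow, exprSd = exprSd)
  k <- length(factors)
  if (abs(sum(comboProbs) - 1) > 1e-9) stop("comboProbs must sum to 1")
  if (any(nchar(names(comboProbs)) != k))
    stop("comboProbs codes must have length k = ", k)
  if (any(comboProbs < 0)) stop("comboProbs must be nonnegative")
  if (knockdownAttenuation <= 0 || knockdownAttenuation > 1)
    stop("knockdownAttenuation must lie in (0, 1]")
  stopifnot(all(genome > 0), nSites > 0, peakWidthMean > 0, siteTagMean > 0,
            backgroundRate >= 0, seTailFraction >= 0, seTailFraction < 1,
            atacLossRate >= 0, atacLossRate <= 1, hazardRatio > 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

# Place n site centers on the genome, uniform, at least minSep apart.
.placeCenters <- function(genome, n, minSep) {
  total <- sum(genome)
  if (n * minSep >= total)
    stop("genome too small to place ", n, " sites ", minSep, " bp apart")
  nPer <- floor(n * genome / total)
  rem <- n - sum(nPer)
  if (rem > 0) nPer[seq_len(rem)] <- nPer[seq_len(rem)] + 1
  chrom <- character(0); center <- numeric(0)
  for (ch in names(genome)) {
    m <- nPer[[ch]]
    if (m == 0) next
    L <- genome[[ch]]
    if (m * minSep >= L)
      stop("chromosome ", ch, " too small for ", m, " sites")
    u <- sort(runif(m, 0, L - m * minSep))
    center <- c(center, floor(u + (seq_len(m) - 1) * minSep + minSep / 2))
    chrom <- c(chrom, rep(ch, m))
  }
  data.frame(chrom = chrom, center = center, stringsAsFactors = FALSE)
}

.drawWidths <- function(n, cfg) {
  pmax(round(rnorm(n, cfg$peakWidthMean, cfg$peakWidthSd)), cfg$minPeakWidth)
}

#' Simulate factor cistromes over latent co-bound sites
#'
#' Latent sites are placed uniformly (non-overlapping) and each draws a
#' co-binding code from `comboProbs`. The anchor emits a peak at every
#' latent site; factor i emits a peak (jittered center, random width) at
#' sites whose code has bit i set. The latent truth table is returned for
#' recovery tests. Deterministic given the config seed.
#'
#' @param config a [simConfig] object.
#' @return list with `anchor` (`GRanges`, named site_1..n in sorted order),
#'   `factors` (named list of `GRanges`), and `truth` (data.frame site_id,
#'   chrom, center, code aligned with `anchor`).
#' @export
simulateCistromes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  k <- length(config$factors)
  pl <- .placeCenters(config$genome, config$nSites, config$minSeparation)
  n <- nrow(pl)
  codes <- sample(names(config$comboProbs), n, replace = TRUE,
                  prob = config$comboProbs)
  aw <- .drawWidths(n, config)
  anchor <- GRanges(pl$chrom,
                    IRanges(pmax(pl$center - floor(aw / 2), 0) + 1,
                            width = aw))
  ord <- order(as.character(seqnames(anchor)), start(anchor))
  anchor <- anchor[ord]
  truth <- data.frame(site_id = paste0("site_", seq_len(n)),
                      chrom = pl$chrom[ord], center = pl$center[ord],
                      code = codes[ord], stringsAsFactors = FALSE)
  names(anchor) <- truth$site_id
  bits <- do.call(rbind, strsplit(truth$code, ""))
  factors <- list()
  for (i in seq_len(k)) {
    on <- which(bits[, i] == "1")
    if (!length(on)) {
      factors[[config$factors[i]]] <- GRanges()
      next
    }
    fw <- .drawWidths(length(on), config)
    fc <- truth$center[on] + round(rnorm(length(on), 0, config$jitterSd))
    gr <- GRanges(truth$chrom[on],
                  IRanges(pmax(fc - floor(fw / 2), 0) + 1, width = fw))
    factors[[config$factors[i]]] <- sort(gr)
  }
  list(anchor = anchor, factors = factors, truth = truth)
}

#' Simulate a tag track around sites over Poisson background
#'
#' Background tags arrive as Poisson(backgroundRate x chromosome length),
#' uniformly placed. Each site contributes Poisson(multiplier x
#' siteTagMean) tags placed with a truncated-normal kernel (sd = a quarter
#' of the site width) around the site center. `totalMapped` is the
#' realized tag count. Deterministic given the seed.
#'
#' @param config a [simConfig] object.
#' @param sites `GRanges` of sites (aligned with `multipliers`).
#' @param multipliers nonnegative per-site tag-rate multipliers.
#' @param label track label.
#' @param seed RNG seed (defaults to the config seed).
#' @param totalMapped library size recorded on the track; the default (NULL)
#'   uses the realized tag count. Pass a common nominal depth (e.g. 1e7)
#'   when two conditions are meant to be sequenced to comparable depth, so
#'   that density normalization does not convert a binding loss into an
#'   apparent library-size shift.
#' @return a [TagTrack-class].
#' @export
simulateTags <- function(config, sites, multipliers, label = "tags",
                         seed = config$seed, totalMapped = NULL) {
  stopifnot(inherits(config, "SimulationConfig"),
            length(multipliers) == length(sites), all(multipliers >= 0))
  set.seed(seed)
  chrom <- character(0); pos <- numeric(0)
  for (ch in names(config$genome)) {
    nb <- rpois(1, config$backgroundRate * config$genome[[ch]])
    if (nb > 0) {
      pos <- c(pos, floor(runif(nb, 0, config$genome[[ch]])))
      chrom <- c(chrom, rep(ch, nb))
    }
  }
  if (length(sites)) {
    counts <- rpois(length(sites), multipliers * config$siteTagMean)
    c0 <- .siteCenter0(sites)
    kernelSd <- pmax(width(sites) / 4, 1)
    idx <- rep(seq_along(sites), counts)
    if (length(idx)) {
      p <- round(rnorm(length(idx), c0[idx], kernelSd[idx]))
      p <- pmax(p, 0)
      pos <- c(pos, p)
      chrom <- c(chrom, as.character(seqnames(sites))[idx])
    }
  }
  if (!length(pos))
    return(new("TagTrack", label = label, tags = GRanges(),
               totalMapped = if (is.null(totalMapped)) 1 else totalMapped))
  tagTrack(chrom, pos, label = label, totalMapped = totalMapped)
}

#' Simulate heavy-tailed enhancer intensities
#'
#' Draws `n` region intensities from the body/tail mixture in the config:
#' a gamma body and, for a planted `seTailFraction` of regions, a Pareto
#' tail of exceptionally high values (the super-enhancer population).
#'
#' @param config a [simConfig] object.
#' @param n number of regions.
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `signal` (numeric) and `isTail` (logical planted truth).
#' @export
simulateSeSignals <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"), n > 0)
  set.seed(seed)
  isTail <- runif(n) < config$seTailFraction
  signal <- rgamma(n, shape = config$seBodyShape, scale = config$seBodyScale)
  nt <- sum(isTail)
  if (nt > 0)
    signal[isTail] <- config$seParetoScale *
      runif(nt)^(-1 / config$seParetoShape)
  list(signal = signal, isTail = isTail)
}

#' Simulate a survival cohort with planted expression codes
#'
#' Expression for each coded gene is gaussian around a high or low mean
#' according to the patient's planted code bit (separation chosen so the
#' mean-binarized E-code recovers the planted code for >= 95% of
#' patients, negative draws truncated at 0). Event times are exponential
#' with hazard `baseHazard x multiplier(code)`; by default the multiplier
#' is `hazardRatio` for codes with at most one high bit and 1 otherwise
#' (low expression of the trio raises the metastasis hazard). Independent
#' exponential censoring at `censorRate`.
#'
#' @param config a [simConfig] object.
#' @param codes planted per-patient binary codes over `config$factors`.
#' @param hazardByCode optional named hazard multipliers per code,
#'   overriding the default rule.
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `cohort` (a [CohortTable-class], E-codes unset) and
#'   `truth` (data.frame patient_id, code, hazardMultiplier).
#' @export
simulateCohort <- function(config, codes = NULL, hazardByCode = NULL,
                           seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  k <- length(config$factors)
  n <- config$nPatients
  if (is.null(codes)) {
    bits <- matrix(rbinom(n * k, 1, 0.5), n, k)
    codes <- apply(bits, 1L, paste0, collapse = "")
  } else {
    n <- length(codes)
    bits <- do.call(rbind, strsplit(codes, "")) == "1"
    bits <- matrix(as.integer(bits), n, k)
  }
  if (is.null(hazardByCode)) {
    mult <- ifelse(rowSums(bits) <= 1, config$hazardRatio, 1)
  } else {
    if (!all(codes %in% names(hazardByCode)))
      stop("hazardByCode missing some planted codes")
    mult <- unname(hazardByCode[codes])
  }
  expr <- matrix(0, n, k, dimnames = list(NULL, config$factors))
  for (j in seq_len(k)) {
    mu <- ifelse(bits[, j] == 1, config$exprHigh, config$exprLow)
    expr[, j] <- pmax(rnorm(n, mu, config$exprSd), 0)
  }
  tEvent <- rexp(n, rate = config$baseHazard * mult)
  tCens <- if (config$censorRate > 0) rexp(n, rate = config$censorRate)
           else rep(Inf, n)
  time <- pmin(tEvent, tCens)
  time <- pmax(time, 1e-6)
  event <- tEvent <= tCens
  ids <- paste0("p", seq_len(n))
  rownames(expr) <- ids
  list(cohort = cohortTable(expr, time, event, patientIds = ids),
       truth = data.frame(patient_id = ids, code = codes,
                          hazardMultiplier = mult, stringsAsFactors = FALSE))
}

#' Tag-rate multipliers for the anchor track by co-binding cardinality
#'
#' @param config a [simConfig] object.
#' @param codes per-site binary codes.
#' @return numeric multipliers aligned with `codes`.
#' @export
anchorMultipliers <- function(config, codes) {
  card <- as.character(.popcount(codes))
  unname(config$anchorEnrichment[card])
}
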