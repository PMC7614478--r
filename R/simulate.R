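# Ground-truthed synthetic multi-region cohort generator.
#
# The generator emulates the statistical structure the downstream
# analyses assume: clone trees with regionally varying clone mixtures,
# truncal and subclonal arm/focal copy-number events on phased
# haplotypes (with optional mirrored subclonal allelic imbalance), LOH
# accumulating irreversibly along branches, per-region purity/ploidy,
# and growth patterns drifting toward higher grade along descendant
# branches with a tunable upward bias. Copy number is emitted under a
# clonal-sweep approximation: each region's profile is its dominant
# clone's genotype plus Gaussian segment noise.

# approximate autosome lengths (Mb, scaled 1/10 on construction) and
# p-arm fractions
.CHROM_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
               134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
.PARM_FRAC <- c(0.50, 0.38, 0.46, 0.26, 0.27, 0.36, 0.38, 0.31, 0.35,
                0.29, 0.40, 0.27, 0.16, 0.16, 0.18, 0.41, 0.30, 0.22,
                0.42, 0.44, 0.27, 0.29)

#' Synthetic genome cytoband map
#'
#' Builds a 22-autosome genome at roughly one tenth of real chromosome
#' lengths, with each arm split into \code{bandsPerArm} equal cytobands
#' (88 bands at the default 2), preserving arm structure while keeping
#' simulated cohorts small.
#'
#' @param bandsPerArm cytobands per arm (default 2).
#' @return cytoband \code{GRanges} with mcols \code{band}, \code{arm}.
#' @export
syntheticGenome <- function(bandsPerArm = 2) {
  chrom <- character(0); st <- numeric(0); en <- numeric(0)
  bandName <- character(0); armName <- character(0)
  for (i in seq_along(.CHROM_MB)) {
    len <- .CHROM_MB[i] * 1e5
    cen <- round(len * .PARM_FRAC[i])
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 1 else cen + 1
      hi <- if (arm == "p") cen else len
      cuts <- round(seq(lo - 1, hi, length.out = bandsPerArm + 1))
      chrom <- c(chrom, rep(as.character(i), bandsPerArm))
      st <- c(st, cuts[-length(cuts)] + 1)
      en <- c(en, cuts[-1])
      bandName <- c(bandName, paste0(arm, seq_len(bandsPerArm)))
      armName <- c(armName, rep(arm, bandsPerArm))
    }
  }
  GRanges(chrom, IRanges(st, en), band = bandName, arm = armName)
}

#' Simulation configuration
#'
#' Defaults describe a moderately unstable multi-region lung
#' adenocarcinoma cohort; every rate and range is tunable. Rates are
#' mean events per tumour.
#'
#' @param nTumours number of tumours.
#' @param regionsRange min/max sampled regions per tumour.
#' @param cloneRange min/max clone-tree size (clusters incl. root).
#' @param branchingProb probability a new clone attaches to a random
#'   existing clone rather than the previous one (tree bushiness).
#' @param truncalArmEvents mean truncal arm events per tumour (at least
#'   two truncal arm-level LOH events are always planted, reflecting the
#'   near-ubiquity of truncal arm LOH in LUAD).
#' @param subclonalArmEvents mean subclonal arm events per tumour.
#' @param focalEvents mean focal (single-band) events per tumour.
#' @param lohFraction fraction of losses taken to full allelic loss
#'   (LOH) when a non-LOH loss is possible (post-WGD).
#' @param msaiProb probability a tumour carries a mirrored subclonal
#'   allelic imbalance event.
#' @param privateLohBands private LOH cytobands given to every non-root
#'   clone (ongoing instability; default 1).
#' @param purityRange per-region purity range (default \[0.1, 0.8\]).
#' @param wgdProb probability of whole-genome doubling.
#' @param emissionSigma Gaussian noise s.d. (copies) added per emitted
#'   segment haplotype.
#' @param lohFlipProb per-cytoband probability that a truly-LOH band
#'   loses its emitted LOH call (dropout-style call noise for
#'   robustness experiments).
#' @param mutationsPerCluster min/max mutations per cluster.
#' @param ccfJitter s.d. of optional noise on mutation CCFs (default 0).
#' @param rootGradeProbs distribution of the root clone's grade.
#' @param pUp,pDown per-branch probability of a one-step grade upgrade /
#'   downgrade (pUp + pDown <= 1).
#' @param plantPairProb fraction of tumours given a planted
#'   ancestor-descendant regional pair.
#' @param extraLohFraction planted descendant private LOH as a fraction
#'   of the trunk.
#' @param extraArmLoh planted descendant private arm-level LOH count.
#' @param bandsPerArm synthetic genome resolution.
#' @return a \code{morphoevo_sim_config} list.
#' @export
simConfig <- function(nTumours = 20,
                      regionsRange = c(2, 5),
                      cloneRange = c(3, 6),
                      branchingProb = 0.5,
                      truncalArmEvents = 4,
                      subclonalArmEvents = 2,
                      focalEvents = 1,
                      lohFraction = 0.6,
                      msaiProb = 0.2,
                      privateLohBands = 1,
                      purityRange = c(0.1, 0.8),
                      wgdProb = 0.25,
                      emissionSigma = 0.05,
                      lohFlipProb = 0,
                      mutationsPerCluster = c(10, 50),
                      ccfJitter = 0,
                      rootGradeProbs = c(low = 0.35, mid = 0.5, high = 0.15),
                      pUp = 0.45, pDown = 0.05,
                      plantPairProb = 0.7,
                      extraLohFraction = 0.15,
                      extraArmLoh = 2,
                      bandsPerArm = 2) {
  cfg <- as.list(environment())
  if (cfg$nTumours < 1 || cfg$regionsRange[1] < 1)
    stop("infeasible config: need >= 1 tumour and >= 1 region")
  if (cfg$pUp + cfg$pDown > 1) stop("pUp + pDown must be <= 1")
  if (any(c(cfg$truncalArmEvents, cfg$subclonalArmEvents, cfg$focalEvents,
            cfg$msaiProb, cfg$emissionSigma) < 0))
    stop("rates must be >= 0")
  class(cfg) <- "morphoevo_sim_config"
  cfg
}

.pick <- function(x) x[sample.int(length(x), 1)]

.patternsOfGrade <- function(grade) {
  names(GRADE_OF_PATTERN)[GRADE_OF_PATTERN == grade &
                            names(GRADE_OF_PATTERN) != "unknown"]
}

.driftPattern <- function(parentPattern, pUp, pDown) {
  g <- unname(GRADE_OF_PATTERN[parentPattern])
  gi <- match(g, GRADE_LEVELS)
  u <- stats::runif(1)
  if (u < pUp && gi < 3)
    .pick(.patternsOfGrade(GRADE_LEVELS[gi + 1]))
  else if (u >= pUp && u < pUp + pDown && gi > 1)
    .pick(.patternsOfGrade(GRADE_LEVELS[gi - 1]))
  else parentPattern
}

# descendants (incl. self) of clone i under parent vector
.subtreeOf <- function(parent, i) {
  out <- i
  repeat {
    kids <- which(parent %in% out & !(seq_along(parent) %in% out))
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

.ancestorPath <- function(parent, i) {
  path <- i
  while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
  path
}

# simulate a single tumour; returns list(bundle draft, truth)
.simulateTumour <- function(tid, cfg, bands) {
  nBands <- length(bands$width)
  armOf <- bands$armKey
  arms <- unique(armOf)

  nClones <- .pick(cfg$cloneRange[1]:cfg$cloneRange[2])
  parent <- rep(NA_integer_, nClones)
  for (i in seq_len(nClones)[-1])
    parent[i] <- if (i == 2 || stats::runif(1) < cfg$branchingProb)
      sample.int(i - 1, 1) else i - 1L

  # clone growth patterns via grade drift along edges
  rootGrade <- sample(names(cfg$rootGradeProbs), 1,
                      prob = cfg$rootGradeProbs)
  pattern <- character(nClones)
  pattern[1] <- .pick(.patternsOfGrade(rootGrade))
  for (i in seq_len(nClones)[-1])
    pattern[i] <- .driftPattern(pattern[parent[i]], cfg$pUp, cfg$pDown)

  # genotypes: per-clone events, genotype built by inheritance
  base <- if (stats::runif(1) < cfg$wgdProb) 2 else 1
  cnA <- matrix(base, nClones, nBands)
  cnB <- matrix(base, nClones, nBands)
  events <- list()
  applyArmLoss <- function(cl, arm, hap) {
    idx <- which(armOf == arm)
    sub <- .subtreeOf(parent, cl)
    if (hap == "A") cnA[sub, idx] <<- 0 else cnB[sub, idx] <<- 0
    events[[length(events) + 1L]] <<-
      list(clone = cl, type = "arm_loss_loh", arm = arm, hap = hap)
  }
  applyArmGain <- function(cl, arm) {
    idx <- which(armOf == arm)
    sub <- .subtreeOf(parent, cl)
    if (stats::runif(1) < 0.5) cnA[sub, idx] <<- cnA[sub, idx] + 1
    else cnB[sub, idx] <<- cnB[sub, idx] + 1
    events[[length(events) + 1L]] <<-
      list(clone = cl, type = "arm_gain", arm = arm)
  }
  usedArms <- character()
  freshArm <- function() {
    pool <- setdiff(arms, usedArms)
    if (!length(pool)) return(NA_character_)
    a <- .pick(pool)
    usedArms <<- c(usedArms, a)
    a
  }

  # truncal arm events: always >= 2 arm-level LOH, plus gains/losses
  nTrunc <- max(2, stats::rpois(1, cfg$truncalArmEvents))
  for (k in seq_len(nTrunc)) {
    a <- freshArm()
    if (is.na(a)) break
    if (k <= 2 || stats::runif(1) < 0.6) {
      # loss; LOH unless post-WGD non-LOH loss drawn
      if (k > 2 && base == 2 && stats::runif(1) > cfg$lohFraction) {
        idx <- which(armOf == a)
        cnA[, idx] <- cnA[, idx] - 1
        events[[length(events) + 1L]] <-
          list(clone = 1L, type = "arm_loss", arm = a)
      } else applyArmLoss(1L, a, .pick(c("A", "B")))
    } else applyArmGain(1L, a)
  }

  # subclonal arm events
  if (nClones > 1) {
    nSub <- stats::rpois(1, cfg$subclonalArmEvents)
    for (k in seq_len(nSub)) {
      a <- freshArm()
      if (is.na(a)) break
      cl <- .pick(2:nClones)
      if (stats::runif(1) < 0.5) applyArmLoss(cl, a, .pick(c("A", "B")))
      else applyArmGain(cl, a)
    }
    # mirrored subclonal allelic imbalance on one arm: the two clones
    # must sit on different lineages (neither ancestral to the other),
    # otherwise the second loss would stack into a homozygous deletion
    if (stats::runif(1) < cfg$msaiProb && nClones >= 3) {
      cand <- utils::combn(2:nClones, 2)
      unrelated <- cand[, !apply(cand, 2, function(p)
        p[1] %in% .subtreeOf(parent, p[2]) ||
          p[2] %in% .subtreeOf(parent, p[1])), drop = FALSE]
      if (ncol(unrelated)) {
        a <- freshArm()
        if (!is.na(a)) {
          cls <- unrelated[, sample.int(ncol(unrelated), 1)]
          applyArmLoss(cls[1], a, "A")
          applyArmLoss(cls[2], a, "B")
          events[[length(events) + 1L]] <-
            list(clone = cls, type = "msai", arm = a)
        }
      }
    }
    # every non-root clone carries some private LOH (ongoing CIN)
    if (cfg$privateLohBands > 0) {
      for (cl in 2:nClones) {
        for (j in seq_len(cfg$privateLohBands)) {
          cand <- which(cnA[cl, ] > 0 & cnB[cl, ] > 0)
          # avoid completing an arm: skip arms already touched
          cand <- cand[!(armOf[cand] %in% armOf[which(
            cnA[cl, ] == 0 | cnB[cl, ] == 0)])]
          if (!length(cand)) next
          b <- .pick(cand)
          sub <- .subtreeOf(parent, cl)
          if (stats::runif(1) < 0.5) cnA[sub, b] <- 0 else cnB[sub, b] <- 0
        }
      }
    }
  }

  # focal single-band events (gain +2 = amplification scale); the gained
  # haplotype must be present in every clone of the subtree so that a
  # gain never resurrects a lost allele (LOH stays irreversible)
  nFoc <- stats::rpois(1, cfg$focalEvents)
  for (k in seq_len(nFoc)) {
    cl <- if (nClones == 1 || stats::runif(1) < 0.5) 1L
          else .pick(2:nClones)
    sub <- .subtreeOf(parent, cl)
    okA <- which(apply(cnA[sub, , drop = FALSE] > 0, 2, all))
    okB <- which(apply(cnB[sub, , drop = FALSE] > 0, 2, all))
    useA <- stats::runif(1) < 0.5
    cand <- if (useA) okA else okB
    if (!length(cand)) { useA <- !useA; cand <- if (useA) okA else okB }
    if (!length(cand)) next
    b <- .pick(cand)
    if (useA) cnA[sub, b] <- cnA[sub, b] + 2
    else cnB[sub, b] <- cnB[sub, b] + 2
    events[[length(events) + 1L]] <-
      list(clone = cl, type = "focal_gain", band = b)
  }

  # regions: dominant clone + admixture along its ancestor path
  nRegions <- .pick(cfg$regionsRange[1]:cfg$regionsRange[2])
  dominant <- integer(nRegions)
  domWeight <- numeric(nRegions)
  for (r in seq_len(nRegions)) {
    dominant[r] <- sample.int(nClones, 1)
    domWeight[r] <- stats::runif(1, 0.7, 0.95)
  }

  planted <- NULL
  if (nRegions >= 2 && nClones >= 2 &&
      stats::runif(1) < cfg$plantPairProb) {
    planted <- tryCatch(
      .plantPair(parent, pattern, cnA, cnB, armOf, bands$width, cfg),
      error = function(e) NULL)
  }
  if (!is.null(planted)) {
    parent <- planted$parent
    pattern <- planted$pattern
    cnA <- planted$cnA
    cnB <- planted$cnB
    nClones <- length(parent)
    dominant[1] <- 1L                  # ancestor region: root clone
    dominant[2] <- planted$descClone   # descendant region
    domWeight[1] <- domWeight[2] <- 0.99
  }

  # clone mixtures and cluster CCFs
  regionIDs <- paste0("R", seq_len(nRegions))
  weights <- matrix(0, nClones, nRegions)
  for (r in seq_len(nRegions)) {
    path <- .ancestorPath(parent, dominant[r])
    w <- rep(0, nClones)
    w[dominant[r]] <- domWeight[r]
    rest <- setdiff(path, dominant[r])
    if (length(rest)) {
      shares <- stats::rexp(length(rest)) + 0.05
      w[rest] <- (1 - domWeight[r]) * shares / sum(shares)
    } else w[dominant[r]] <- 1
    weights[, r] <- w / sum(w)
  }
  ccf <- matrix(0, nClones, nRegions,
                dimnames = list(paste0("C", seq_len(nClones)), regionIDs))
  for (cl in seq_len(nClones)) {
    sub <- .subtreeOf(parent, cl)
    ccf[cl, ] <- colSums(weights[sub, , drop = FALSE])
  }

  # per-region metadata
  purity <- stats::runif(nRegions, cfg$purityRange[1], cfg$purityRange[2])
  if (!is.null(planted)) purity[1:2] <- stats::runif(2, 0.3, 0.8)
  ploidy <- vapply(seq_len(nRegions), function(r) {
    g <- cnA[dominant[r], ] + cnB[dominant[r], ]
    sum(g * bands$width) / sum(bands$width)
  }, numeric(1))
  regPattern <- pattern[dominant]

  regions <- data.frame(region_id = regionIDs, purity = purity,
                        ploidy = ploidy, growth_pattern = regPattern,
                        seeding_label = sample(
                          c("seeding", "non_seeding"), nRegions,
                          replace = TRUE, prob = c(0.3, 0.7)))
  regions$grade <- deriveGrade(regions$growth_pattern)

  # emission: merge equal-genotype adjacent bands, add segment noise
  chromIdx <- cumsum(c(TRUE, bands$chrom[-1] != bands$chrom[-nBands]))
  segdf <- do.call(rbind, lapply(seq_len(nRegions), function(r) {
    a <- cnA[dominant[r], ]
    b <- cnB[dominant[r], ]
    if (cfg$lohFlipProb > 0) {
      # call-dropout noise: each truly-LOH band loses its LOH call with
      # probability lohFlipProb (the dominant error mode of LOH calling;
      # spurious LOH needs a consistent phased BAF shift and is rare)
      flip <- stats::runif(nBands) < cfg$lohFlipProb &
        pmin(a, b) < LOH_MINOR_CN & (a + b) >= 0.5
      for (i in which(flip)) {
        if (a[i] < b[i]) a[i] <- 1 else b[i] <- 1
      }
    }
    newSeg <- c(TRUE, diff(chromIdx) != 0 | diff(a) != 0 | diff(b) != 0)
    first <- which(newSeg)
    last <- c(first[-1] - 1L, nBands)
    segA <- a[first] + stats::rnorm(length(first), 0, cfg$emissionSigma)
    segB <- b[first] + stats::rnorm(length(first), 0, cfg$emissionSigma)
    data.frame(region_id = regionIDs[r], chrom = bands$chrom[first],
               start = bands$start[first], end = bands$end[last],
               cnA = pmax(as.numeric(segA), 0),
               cnB = pmax(as.numeric(segB), 0))
  }))

  # mutation catalog from cluster CCFs
  mutPool <- cfg$mutationsPerCluster[1]:cfg$mutationsPerCluster[2]
  nMut <- mutPool[sample.int(length(mutPool), nClones, replace = TRUE)]
  clVec <- rep(seq_len(nClones), nMut)
  mIdx <- sequence(nMut)
  m <- ccf[clVec, , drop = FALSE]
  if (cfg$ccfJitter > 0) {
    zero <- m == 0
    m <- pmin(pmax(m + stats::rnorm(length(m), 0, cfg$ccfJitter), 0), 1)
    m[zero] <- 0
  }
  mutations <- data.frame(
    mutation_id = sprintf("%s_C%d_M%03d", tid, clVec, mIdx),
    cluster_id = paste0("C", clVec), m, check.names = FALSE,
    row.names = NULL)

  tree <- CloneTree(tid,
                    setNames(ifelse(is.na(parent), NA_character_,
                                    paste0("C", parent)),
                             paste0("C", seq_len(nClones))),
                    ccf, setNames(nMut, paste0("C", seq_len(nClones))))

  # tumour-level annotations from regional patterns
  tab <- table(regPattern)
  pct <- round(100 * as.numeric(tab) / sum(tab), 1)
  pct[1] <- pct[1] + (100 - sum(pct))
  names(pct) <- names(tab)
  anyHigh <- any(regions$grade == "high")
  ann <- list(predominant = names(pct)[which.max(pct)], pattern_pct = pct,
              stas = stats::runif(1) < (0.2 + 0.4 * anyHigh),
              necrosis = any(regPattern == "solid") && stats::runif(1) < 0.6,
              relapse = sample(c("none", "intrathoracic", "extrathoracic"),
                               1, prob = c(0.6, 0.25, 0.15)))


  # ground truth, including true % subclonal SCNA from noiseless genotypes
  truth <- list(
    parent = parent, clone_patterns = pattern, dominant = dominant,
    weights = weights, events = events,
    loh_bands = lapply(seq_len(nClones), function(cl)
      which(pmin(cnA[cl, ], cnB[cl, ]) < LOH_MINOR_CN &
              cnA[cl, ] + cnB[cl, ] >= 0.5)),
    planted_pair = if (!is.null(planted))
      list(ancestor = regionIDs[1], descendant = regionIDs[2],
           transition = planted$transition) else NULL,
    pct_subclonal_scna_true =
      .truePctSubclonal(cnA, cnB, dominant, ploidy, bands$width))
  list(tid = tid, regions = regions, segdf = segdf, tree = tree,
       mutations = mutations, annotations = ann, truth = truth)
}

# per-band true % subclonal SCNA from clone genotypes
.truePctSubclonal <- function(cnA, cnB, dominant, ploidy, widths) {
  nR <- length(dominant)
  if (nR < 2) return(NA_real_)
  state <- sapply(seq_len(nR), function(r) {
    st <- classifySegmentState(cnA[dominant[r], ], cnB[dominant[r], ],
                               ploidy[r])
    ifelse(st$homdel_excluded, 0L, ifelse(st$gain, 1L,
                                          ifelse(st$loss, -1L, 0L)))
  })
  anyEvent <- rowSums(state != 0L) > 0L
  clonal <- anyEvent & apply(state, 1, function(x)
    length(unique(x)) == 1L)
  denom <- sum(widths[anyEvent])
  if (denom == 0) return(NA_real_)
  100 * sum(widths[anyEvent & !clonal]) / denom
}

# graft a planted descendant clone onto the tree and return modified
# genotype matrices
.plantPair <- function(parent, pattern, cnA, cnB, armOf, widths, cfg) {
  nClones <- length(parent)
  rootLoh <- which(pmin(cnA[1, ], cnB[1, ]) < LOH_MINOR_CN)
  trunk <- length(rootLoh)
  armBands <- cfg$extraArmLoh * cfg$bandsPerArm
  target <- max(armBands, round(cfg$extraLohFraction * trunk))
  # new clone: child of root
  d <- nClones + 1L
  parent <- c(parent, 1L)
  cnA <- rbind(cnA, cnA[1, ])
  cnB <- rbind(cnB, cnB[1, ])
  # pattern with the configured upward bias
  u <- stats::runif(1)
  g <- unname(GRADE_OF_PATTERN[pattern[1]])
  gi <- match(g, GRADE_LEVELS)
  newPattern <-
    if (u < cfg$pUp && gi < 3) .pick(.patternsOfGrade(GRADE_LEVELS[gi + 1]))
    else if (u >= cfg$pUp && u < cfg$pUp + cfg$pDown && gi > 1)
      .pick(.patternsOfGrade(GRADE_LEVELS[gi - 1]))
    else pattern[1]
  pattern <- c(pattern, newPattern)
  # arm-level private LOH
  hetArms <- unique(armOf[which(cnA[d, ] > 0 & cnB[d, ] > 0)])
  lohArms <- unique(armOf[rootLoh])
  pool <- setdiff(hetArms, lohArms)
  if (length(pool) < cfg$extraArmLoh || trunk == 0)
    stop("trunk too small to satisfy planted-pair fractions")
  chosen <- pool[sample.int(length(pool), cfg$extraArmLoh)]
  newLoh <- integer()
  for (a in chosen) {
    idx <- which(armOf == a)
    if (stats::runif(1) < 0.5) cnA[d, idx] <- 0 else cnB[d, idx] <- 0
    newLoh <- c(newLoh, idx)
  }
  # scattered single-band LOH to reach the target branch length,
  # placed on arms untouched so far (never completing an arm)
  extra <- target - length(newLoh)
  if (extra > 0) {
    usable <- which(cnA[d, ] > 0 & cnB[d, ] > 0 &
                      !(armOf %in% c(chosen, lohArms)))
    byArm <- split(usable, armOf[usable])
    cand <- unlist(lapply(byArm, function(i) i[1]), use.names = FALSE)
    if (length(cand) < extra)
      stop("trunk too small to satisfy planted-pair fractions")
    cnPick <- cand[sample.int(length(cand), extra)]
    for (b in cnPick)
      if (stats::runif(1) < 0.5) cnA[d, b] <- 0 else cnB[d, b] <- 0
  }
  gTrans <- {
    ga <- match(unname(GRADE_OF_PATTERN[pattern[1]]), GRADE_LEVELS)
    gd <- match(unname(GRADE_OF_PATTERN[newPattern]), GRADE_LEVELS)
    if (gd > ga) "upward" else if (gd < ga) "downward" else "same"
  }
  list(parent = parent, pattern = pattern, cnA = cnA, cnB = cnB,
       descClone = d, transition = gTrans)
}

#' Simulate a ground-truthed multi-region cohort
#'
#' Deterministic given \code{seed}: the same seed yields byte-identical
#' cohorts (and files via \code{\link{writeCohort}}).
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer RNG seed.
#' @return list with \code{bundles} (named list of
#'   \code{\linkS4class{TumourBundle}}), \code{cytobands}
#'   (\code{GRanges}) and \code{truth} (named list per tumour).
#' @export
simulateCohort <- function(config = simConfig(), seed = 1) {
  if (!inherits(config, "morphoevo_sim_config"))
    stop("config must come from simConfig()")
  set.seed(seed)
  cyto <- syntheticGenome(config$bandsPerArm)
  bands <- list(chrom = as.character(seqnames(cyto)),
                start = start(cyto), end = end(cyto),
                width = width(cyto),
                armKey = paste0(as.character(seqnames(cyto)),
                                mcols(cyto)$arm))
  tumours <- lapply(seq_len(config$nTumours), function(i)
    .simulateTumour(sprintf("T%03d", i), config, bands))
  # assemble all segment GRanges in one construction, then slice
  allseg <- do.call(rbind, lapply(tumours, function(t)
    cbind(tumour_id = t$tid, t$segdf)))
  gr <- GRanges(allseg$chrom, IRanges(allseg$start, allseg$end),
                cnA = allseg$cnA, cnB = allseg$cnB)
  idx <- split(seq_len(nrow(allseg)),
               paste(allseg$tumour_id, allseg$region_id))
  bundles <- lapply(tumours, function(t) {
    segs <- lapply(t$regions$region_id, function(rid)
      gr[idx[[paste(t$tid, rid)]]])
    names(segs) <- t$regions$region_id
    TumourBundle(t$tid, t$regions, segs, t$tree, t$mutations,
                 t$annotations)
  })
  names(bundles) <- vapply(tumours, `[[`, character(1), "tid")
  truth <- lapply(tumours, `[[`, "truth")
  names(truth) <- names(bundles)
  list(bundles = bundles, cytobands = cyto, truth = truth)
}

#' Null cohort: growth patterns independent of clonal structure
#'
#' Runs the full genomic simulation, then redraws every region's growth
#' pattern i.i.d. from the cohort's marginal pattern distribution,
#' severing any link between morphology and lineage. Used as the
#' type-I-error harness for the permutation tests.
#'
#' @inheritParams simulateCohort
#' @return as \code{\link{simulateCohort}}.
#' @export
nullCohort <- function(config = simConfig(), seed = 1) {
  cohort <- simulateCohort(config, seed)
  pool <- unlist(lapply(cohort$bundles, function(b)
    regionTable(b)$growth_pattern))
  cohort$bundles <- lapply(cohort$bundles, function(b) {
    reg <- regionTable(b)
    reg$growth_pattern <- sample(pool, nrow(reg), replace = TRUE)
    reg$grade <- deriveGrade(reg$growth_pattern)
    initialize(b, regions = reg)
  })
  cohort
}

#' Write a simulated cohort's ground truth to JSON
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param path output path.
#' @export
writeTruth <- function(cohort, path) {
  jsonlite::write_json(cohort$truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Plant an ancestor-descendant regional pair into a tumour draft
#'
#' Grafts a fresh descendant clone onto the root of a drafted tumour:
#' the descendant inherits the root genotype and receives
#' \code{extraArmLoh} private arm-level LOH events plus scattered
#' single-band LOH so that its private branch totals
#' \code{max(extraArmLoh} arm bands\code{, extraLohFraction x trunk)}
#' cytobands, where the trunk is the root clone's LOH band count. The
#' first draft region is designated the (near-pure) ancestor, the
#' second the descendant. Errors when the trunk or the supply of
#' LOH-free heterozygous arms cannot satisfy the request.
#'
#' @param draft list with \code{parent} (integer parent vector),
#'   \code{pattern} (clone growth patterns), \code{cnA}, \code{cnB}
#'   (clone x band haplotype copy matrices), \code{armOf} (arm key per
#'   band) and \code{widths} (band widths).
#' @param extraLohFraction descendant private LOH as a fraction of the
#'   trunk (default 0.15).
#' @param extraArmLoh private arm-level LOH events (default 2).
#' @param pUp,pDown grade-drift probabilities for the descendant's
#'   pattern.
#' @param bandsPerArm cytobands per arm in the draft genome.
#' @return the modified draft plus \code{descClone} (index of the new
#'   clone) and \code{transition} (true grade-transition direction).
#' @export
plantAncestorPair <- function(draft, extraLohFraction = 0.15,
                              extraArmLoh = 2, pUp = 0.45, pDown = 0.05,
                              bandsPerArm = 2) {
  cfg <- list(extraLohFraction = extraLohFraction,
              extraArmLoh = extraArmLoh, pUp = pUp, pDown = pDown,
              bandsPerArm = bandsPerArm)
  .plantPair(draft$parent, draft$pattern, draft$cnA, draft$cnB,
             draft$armOf, draft$widths, cfg)
}
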