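# Segment state classification, arm clonality, MSAI, focal gains, and
# the minimum-consistent single-sample profile.

test_that("ploidy-adjusted log ratio and thresholds behave at boundaries", {
  expect_equal(ploidyAdjustedLogratio(4, 2), 1)
  expect_equal(ploidyAdjustedLogratio(2, 2), 0)
  expect_equal(ploidyAdjustedLogratio(1.5, 2), -0.415, tolerance = 1e-3)
  expect_identical(ploidyAdjustedLogratio(0, 2), -Inf)
  expect_error(ploidyAdjustedLogratio(2, 0), "ploidy")

  st <- classifySegmentState(c(2.1, 1.0, 0.1), c(2.2, 0.2, 0.1), 2)
  expect_true(st$amp[1] && st$gain[1])
  expect_true(st$loss[2] && st$loh[2])
  expect_true(st$homdel_excluded[3])
  expect_false(any(st$amp[3], st$gain[3], st$loss[3], st$loh[3]))
  expect_error(classifySegmentState(-1, 1, 2), ">= 0")

  # right-continuity: value exactly at the threshold carries the event
  for (thr in c(4, 2.5)) {
    atT <- classifySegmentState(thr / 2, thr / 2, 2)
    below <- classifySegmentState(thr / 2 - 1e-9, thr / 2 - 1e-9, 2)
    flag <- if (thr == 4) "amp" else "gain"
    expect_true(atT[[flag]])
    expect_false(below[[flag]])
  }
  atLoss <- classifySegmentState(0.75, 0.75, 2)
  above <- classifySegmentState(0.75 + 1e-9, 0.75 + 1e-9, 2)
  expect_true(atLoss$loss)
  expect_false(above$loss)
  # amp implies gain; gain and loss never co-occur
  set.seed(42)
  rnd <- classifySegmentState(runif(200, 0, 3), runif(200, 0, 3), 2)
  expect_true(all(!rnd$amp | rnd$gain))
  expect_false(any(rnd$gain & rnd$loss))
})

test_that("arm fraction altered matches a per-base oracle", {
  cy <- toyCytobands()
  # q arm (4001-10000) half covered by a lost segment
  p <- segGR("1", c(1, 4001, 7001), c(4000, 7000, 10000),
             c(1, 0, 1), c(1, 1, 1))
  expect_equal(armFractionAltered(p, "1q", "loss", 2, cy), 3000 / 6000)
  # fully gained arm
  pg <- segGR("1", 1, 4000, 2, 1)
  expect_equal(armFractionAltered(pg, "1p", "gain", 2, cy), 1)
  # no segments on the arm
  expect_equal(armFractionAltered(pg, "1q", "gain", 2, cy), 0)
  expect_error(armFractionAltered(pg, "2p", "gain", 2, cy), "unknown arm")

  set.seed(7)
  for (rep in 1:25) {
    prof <- randomProfile(10000, nSeg = sample(3:8, 1))
    for (ev in c("gain", "loss", "loh")) {
      for (arm in c("1p", "1q")) {
        lo <- if (arm == "1p") 1 else 4001
        hi <- if (arm == "1p") 4000 else 10000
        oracle <- baseStates(prof, 2, 10000)
        col <- if (ev == "loh") "loh" else ev
        frac <- sum(oracle[[col]][lo:hi]) / (hi - lo + 1)
        expect_equal(armFractionAltered(prof, arm, ev, 2, cy), frac,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("arm clonality follows the 98/75 rules with MSAI escalation", {
  cy <- toyCytobands()
  mkBundle <- function(fracR2, msai = FALSE) {
    # R1: whole q arm gained; R2: fracR2 of q arm gained
    r2end <- 4000 + round(fracR2 * 6000)
    segsR2 <- if (fracR2 > 0)
      segGR("1", c(1, 4001, r2end + 1), c(4000, r2end, 10000),
            c(1, 2, 1), c(1, 1, 1))
    else segGR("1", c(1, 4001), c(4000, 10000), c(1, 1), c(1, 1))
    if (msai) {
      # opposite-haplotype gain in R2 over the whole arm
      segsR2 <- segGR("1", c(1, 4001), c(4000, 10000), c(1, 1), c(1, 2))
    }
    b <- toyBundle()
    b@segments <- list(
      R1 = segGR("1", c(1, 4001), c(4000, 10000), c(1, 2), c(1, 1)),
      R2 = segsR2)
    b
  }
  expect_equal(callArmClonality(mkBundle(0.80), "1q", "gain", cy)$clonality,
               "truncal")
  expect_equal(callArmClonality(mkBundle(0.50), "1q", "gain", cy)$clonality,
               "subclonal")
  callM <- callArmClonality(mkBundle(1, msai = TRUE), "1q", "gain", cy)
  expect_true(callM$msai)
  expect_equal(callM$clonality, "subclonal")
  expect_equal(callArmClonality(mkBundle(0), "1q", "gain", cy)$clonality,
               "subclonal")  # R1 carries it fully, R2 not at all
  expect_equal(callArmClonality(mkBundle(0), "1q", "loss", cy)$clonality,
               "absent")     # nobody reaches 98% loss

  # single region can only be truncal or absent
  b1 <- mkBundle(0.8)
  b1@segments <- b1@segments["R1"]
  b1@regions <- b1@regions[1, , drop = FALSE]
  expect_equal(callArmClonality(b1, "1q", "gain", cy)$clonality, "truncal")

  # ubiquity mode: present everywhere = truncal, partial = subclonal
  expect_equal(callArmClonality(mkBundle(0.80), "1q", "gain", cy,
                                clonalityMode = "ubiquity")$clonality,
               "truncal")
  expect_equal(callArmClonality(mkBundle(0.30), "1q", "gain", cy,
                                clonalityMode = "ubiquity")$clonality,
               "subclonal")
})

test_that("MSAI detection matches an exhaustive pairwise oracle", {
  iv <- GRanges("1", IRanges(1, 1000))
  p1 <- segGR("1", 1, 1000, 2, 1)
  p2 <- segGR("1", 1, 1000, 1, 2)
  p3 <- segGR("1", 1, 1000, 3, 1)
  expect_true(detectMSAI(list(R1 = p1, R2 = p2), iv)$msai)
  expect_false(detectMSAI(list(R1 = p1, R2 = p3), iv)$msai)
  expect_equal(detectMSAI(list(R1 = p1, R2 = p2), iv)$pair, c("R1", "R2"))
  noAB <- GRanges("1", IRanges(1, 1000))
  expect_error(detectMSAI(list(R1 = noAB, R2 = noAB), iv), "unphased")

  # randomized 3-region toys vs brute force over base pairs
  set.seed(13)
  for (rep in 1:20) {
    profs <- list(R1 = randomProfile(1000, 4), R2 = randomProfile(1000, 4),
                  R3 = randomProfile(1000, 4))
    got <- detectMSAI(profs, GRanges("1", IRanges(1, 1000)))$msai
    imb <- sapply(profs, function(p) {
      d <- numeric(1000)
      for (i in seq_along(p)) {
        idx <- start(p)[i]:end(p)[i]
        diff <- mcols(p)$cnA[i] - mcols(p)$cnB[i]
        d[idx] <- sign(diff) * (abs(diff) > 0.5)
      }
      d
    })
    brute <- FALSE
    for (i in 1:2) for (j in (i + 1):3) {
      opp <- sum(imb[, i] == 1 & imb[, j] == -1) >= 500 ||
        sum(imb[, i] == -1 & imb[, j] == 1) >= 500
      if (opp) brute <- TRUE
    }
    expect_equal(got, brute)
  }
})

test_that("amplification clonality applies the ploidy+1 rule", {
  mk <- function(cnR1, cnR2) {
    b <- toyBundle()
    b@segments <- list(
      R1 = segGR("1", c(1, 4001), c(4000, 10000), c(cnR1 - 1, 1), c(1, 1)),
      R2 = segGR("1", c(1, 4001), c(4000, 10000), c(cnR2 - 1, 1), c(1, 1)))
    b
  }
  iv <- GRanges("1", IRanges(1, 4000))
  expect_equal(callAmplificationClonality(mk(4.5, 3.2), iv), "truncal")
  expect_equal(callAmplificationClonality(mk(4.5, 2.4), iv), "subclonal")
  expect_equal(callAmplificationClonality(mk(3.5, 3.2), iv), "none")
})

test_that("focal gain classification is all/some/none across regions", {
  mk3 <- function(lr) {
    cn <- 2 * 2^lr  # total CN giving the requested log ratio at ploidy 2
    b <- toyBundle()
    b@regions <- data.frame(region_id = paste0("R", seq_along(lr)),
                            purity = 0.5, ploidy = 2,
                            growth_pattern = "acinar",
                            seeding_label = "unknown")
    b@regions$grade <- "mid"
    b@segments <- setNames(lapply(cn, function(x)
      segGR("1", 1, 10000, x / 2, x / 2)), b@regions$region_id)
    b
  }
  iv <- GRanges("1", IRanges(2000, 6000))
  expect_equal(classifyFocalGain(mk3(c(0.5, 0.4, 0.6)), iv), "truncal")
  expect_equal(classifyFocalGain(mk3(c(0.5, 0.1)), iv), "subclonal")
  expect_equal(classifyFocalGain(mk3(c(0.1, 0.0)), iv), "none")
})

test_that("minimum-consistent profile equals the per-base minimum", {
  # single region: identity up to ploidy correction
  p <- segGR("1", c(1, 5001), c(5000, 10000), c(2, 1), c(2, 1))
  mp <- buildMinConsistentProfile(list(R1 = p), c(R1 = 4))
  expect_equal(sum(width(mp)), 10000)
  expect_equal(mcols(mp)$cn, c(2, 1))  # 4/4*2, 2/4*2

  # shared segment values {4, 2} at ploidy 2 -> min 2
  p1 <- segGR("1", 1, 1000, 2, 2)
  p2 <- segGR("1", 1, 1000, 1, 1)
  mp2 <- buildMinConsistentProfile(list(a = p1, b = p2), c(a = 2, b = 2))
  expect_equal(mcols(mp2)$cn, 2)

  # differing breakpoints -> union segmentation, per-base minima
  q1 <- segGR("1", c(1, 5001), c(5000, 10000), c(2, 1), c(2, 1))
  q2 <- segGR("1", c(1, 3001), c(3000, 10000), c(1, 3), c(1, 0))
  mp3 <- buildMinConsistentProfile(list(a = q1, b = q2), c(a = 2, b = 2))
  expect_equal(length(mp3), 3)
  oracle <- sapply(1:10000, function(pos) {
    v1 <- if (pos <= 5000) 4 else 2
    v2 <- if (pos <= 3000) 2 else 3
    min(v1, v2)
  })
  got <- rep(mcols(mp3)$cn, width(mp3))
  expect_equal(got, as.numeric(oracle))
  expect_equal(sum(width(mp3)), 10000)

  # random toys: per-base oracle, full coverage preserved
  set.seed(23)
  for (rep in 1:10) {
    r1 <- randomProfile(2000, 4)
    r2 <- randomProfile(2000, 5)
    pl <- c(a = 2, b = runif(1, 1.5, 4))
    mp <- buildMinConsistentProfile(list(a = r1, b = r2), pl)
    base1 <- rep(NA_real_, 2000); base2 <- rep(NA_real_, 2000)
    for (i in seq_along(r1))
      base1[start(r1)[i]:end(r1)[i]] <-
        (mcols(r1)$cnA[i] + mcols(r1)$cnB[i]) / pl["a"] * 2
    for (i in seq_along(r2))
      base2[start(r2)[i]:end(r2)[i]] <-
        (mcols(r2)$cnA[i] + mcols(r2)$cnB[i]) / pl["b"] * 2
    oracle <- pmin(base1, base2, na.rm = TRUE)
    got <- rep(mcols(mp)$cn, width(mp))
    expect_equal(got, as.numeric(oracle), tolerance = 1e-12)
  }
  expect_error(buildMinConsistentProfile(list(), numeric()), "empty")

  seg <- gisticSegTable(mp2, "S1")
  expect_named(seg, c("sample", "chrom", "start", "end", "num_markers",
                      "log2ratio"))
  expect_equal(seg$log2ratio, 0)
})
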