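# Ancestor-like / descendant-like pair inference, grade transitions,
# and the Monte-Carlo permutation machinery.

test_that("eligibility keeps purity >= 0.15 and drops metastases", {
  reg <- data.frame(region_id = c("R1", "R2", "R3", "R4"),
                    purity = c(0.10, 0.20, 0.15, 0.5),
                    seeding_label = c("non_seeding", "seeding",
                                      "non_seeding", "metastasis"))
  keep <- eligibleRegions(reg)
  expect_setequal(keep$region_id, c("R2", "R3"))  # boundary 0.15 kept
  expect_warning(eligibleRegions(reg[1, , drop = FALSE]), "no eligible")
})

test_that("pair LOH trees count shared and private bands correctly", {
  cy <- toyCytobands()
  mkCalls <- function(loh, lost = rep(NA_character_, 4)) {
    data.frame(chrom = "1", arm = c("p", "p", "q", "q"),
               band = c("p1", "p2", "q1", "q2"),
               width = c(2000, 2000, 3000, 3000),
               loh = as.integer(loh), lost = lost)
  }
  # identical full-LOH vectors
  tr <- pairLohTree(mkCalls(c(1, 1, 1, 1)), mkCalls(c(1, 1, 1, 1)))
  expect_equal(tr$trunk, 4)
  expect_equal(tr$branch_a + tr$branch_b, 0)
  expect_equal(tr$shared_arm_loh, 2)
  # disjoint LOH sets
  tr2 <- pairLohTree(mkCalls(c(1, 1, 0, 0)), mkCalls(c(0, 0, 1, 1)))
  expect_equal(tr2$trunk, 0)
  expect_equal(tr2$branch_a, 2)
  expect_equal(tr2$branch_b, 2)
  expect_equal(tr2$shared_arm_loh, 0)
  # mirrored haplotypes are not shared ancestry
  tr3 <- pairLohTree(mkCalls(c(1, 1, 0, 0), c("A", "A", NA, NA)),
                     mkCalls(c(1, 1, 0, 0), c("B", "B", NA, NA)))
  expect_equal(tr3$trunk, 0)
  expect_equal(tr3$branch_a, 2)
  tr3p <- pairLohTree(mkCalls(c(1, 1, 0, 0), c("A", "A", NA, NA)),
                      mkCalls(c(1, 1, 0, 0), c("B", "B", NA, NA)),
                      haplotypeAware = FALSE)
  expect_equal(tr3p$trunk, 2)

  # random vectors vs set-operation oracle
  set.seed(79)
  for (rep in 1:30) {
    a <- rbinom(4, 1, 0.5); b <- rbinom(4, 1, 0.5)
    tr4 <- pairLohTree(mkCalls(a), mkCalls(b))
    expect_equal(tr4$trunk, sum(a & b))
    expect_equal(tr4$branch_a, sum(a & !b))
    expect_equal(tr4$branch_b, sum(b & !a))
  }
  expect_error(pairLohTree(mkCalls(c(1, 1, 1, 1)),
                           mkCalls(c(1, 1, 1, 1))[1:3, ]), "mismatched")
})

test_that("pair classification enforces the X/Y and arm-count rules", {
  tree <- function(trunk, ba, bb, armB = 2, shared = 1)
    list(trunk = trunk, branch_a = ba, branch_b = bb,
         shared_arm_loh = shared, private_arm_loh_a = 0,
         private_arm_loh_b = armB)
  call <- classifyPair(tree(100, 1, 15), "A", "B")
  expect_equal(call$ancestor_region, "A")
  expect_equal(call$descendant_region, "B")
  # "more than one" arm-level private LOH: exactly 1 fails
  expect_null(classifyPair(tree(100, 1, 15, armB = 1), "A", "B"))
  # no ancestor-like region at 5% branch
  expect_null(classifyPair(tree(100, 5, 15), "A", "B"))
  # zero trunk or failed arm gate
  expect_null(classifyPair(tree(0, 0, 5), "A", "B"))
  expect_null(classifyPair(tree(100, 1, 15, shared = 0), "A", "B"))
  # orientation swaps with the branch lengths
  rev <- classifyPair(list(trunk = 100, branch_a = 15, branch_b = 1,
                           shared_arm_loh = 1, private_arm_loh_a = 2,
                           private_arm_loh_b = 0), "A", "B")
  expect_equal(rev$ancestor_region, "B")
  expect_equal(rev$descendant_region, "A")
})

test_that("planted pairs are recovered with correct orientation", {
  cfg <- simConfig(nTumours = 8, regionsRange = c(2, 4), plantPairProb = 1,
                   emissionSigma = 0)
  co <- simulateCohort(cfg, seed = 83)
  calls <- cohortPairs(co)
  nPlanted <- 0
  for (tid in names(co$truth)) {
    pp <- co$truth[[tid]]$planted_pair
    if (is.null(pp)) next
    nPlanted <- nPlanted + 1
    hit <- calls[calls$tumour_id == tid &
                   calls$ancestor_region == pp$ancestor &
                   calls$descendant_region == pp$descendant, ]
    expect_equal(nrow(hit), 1)
    # never called with reversed orientation
    revHit <- calls[calls$tumour_id == tid &
                      calls$ancestor_region == pp$descendant &
                      calls$descendant_region == pp$ancestor, ]
    expect_equal(nrow(revHit), 0)
  }
  expect_gt(nPlanted, 0)

  # two identical regions produce no call
  b <- toyBundle()
  g <- segGR("1", c(1, 4001), c(4000, 10000), c(1, 0), c(1, 1))
  b@segments <- list(R1 = g, R2 = g)
  expect_equal(nrow(inferPairs(b, toyCytobands())), 0)
})

test_that("below-threshold or single-arm plants are rejected by design", {
  # descendant private LOH below Y% of trunk -> no call
  cfgLow <- simConfig(nTumours = 6, regionsRange = c(2, 2),
                      plantPairProb = 1, emissionSigma = 0,
                      truncalArmEvents = 14, subclonalArmEvents = 0,
                      privateLohBands = 0, msaiProb = 0, focalEvents = 0,
                      extraLohFraction = 0.05, extraArmLoh = 0)
  coLow <- simulateCohort(cfgLow, seed = 89)
  callsLow <- cohortPairs(coLow)
  expect_equal(nrow(callsLow), 0)

  # exactly one private arm-level LOH fails the "more than one" rule
  cfgOne <- simConfig(nTumours = 6, regionsRange = c(2, 2),
                      plantPairProb = 1, emissionSigma = 0,
                      subclonalArmEvents = 0, privateLohBands = 0,
                      msaiProb = 0, focalEvents = 0, extraArmLoh = 1,
                      extraLohFraction = 0)
  coOne <- simulateCohort(cfgOne, seed = 97)
  expect_equal(nrow(cohortPairs(coOne)), 0)

  # the default 0.15 / 2-arm plant is detected (control for the above)
  cfgOk <- simConfig(nTumours = 6, regionsRange = c(2, 2),
                     plantPairProb = 1, emissionSigma = 0,
                     subclonalArmEvents = 0, privateLohBands = 0,
                     msaiProb = 0, focalEvents = 0)
  coOk <- simulateCohort(cfgOk, seed = 89)
  expect_gt(nrow(cohortPairs(coOk)), 0)
})

test_that("dominant-mutation counts per pair match a filter oracle", {
  co <- simulateCohort(simConfig(nTumours = 6, plantPairProb = 1),
                       seed = 101)
  calls <- cohortPairs(co)
  cats <- lapply(co$bundles, mutationCatalog)
  out <- comparePairTMB(calls, cats)
  for (k in seq_len(nrow(out))) {
    cc <- cats[[out$tumour_id[k]]]
    for (side in c("ancestor", "descendant")) {
      rid <- out[[paste0(side, "_region")]][k]
      oracle <- sum(!is.na(cc[[rid]]) & cc[[rid]] >= 0.95)
      expect_equal(out[[paste0(side, "_tmb95")]][k], oracle)
    }
  }
})

test_that("grade transitions compare descendant vs ancestor grade", {
  regions <- data.frame(tumour_id = "T",
                        region_id = c("R1", "R2", "R3", "R4"),
                        grade = c("low", "high", "mid", "mid"))
  calls <- data.frame(tumour_id = "T",
                      ancestor_region = c("R1", "R2", "R3"),
                      descendant_region = c("R2", "R3", "R4"))
  got <- gradeTransition(calls, regions)$transition
  expect_equal(got, c("upward", "downward", "same"))
  # unknown grade -> NA
  regions$grade[4] <- "unknown"
  got2 <- gradeTransition(calls, regions)$transition
  expect_true(is.na(got2[3]))
})

test_that("permutation p follows (r+1)/(n+1) and its bounds", {
  co <- simulateCohort(simConfig(nTumours = 10, plantPairProb = 1,
                                 pUp = 1, pDown = 0,
                                 rootGradeProbs = c(low = 1, mid = 0,
                                                    high = 0)),
                       seed = 103)
  calls <- cohortPairs(co)
  elig <- eligibleTable(co)
  pt <- permutationTest(calls, elig, "upward_count", nPerm = 1000,
                        seed = 7)
  expect_gte(pt$empirical_p, 1 / 1001)
  expect_lte(pt$empirical_p, 1)
  expect_equal(pt$empirical_p, (pt$r + 1) / (pt$n_perm + 1))
  # identical seed and inputs -> identical result
  pt2 <- permutationTest(calls, elig, "upward_count", nPerm = 1000,
                         seed = 7)
  expect_identical(pt, pt2)
  # every permutation >= observed when observed is 0 under geq rule
  callsNoGrade <- calls
  eligSame <- elig
  eligSame$grade <- "mid"  # all same grade: observed = 0, all perms = 0
  ptSame <- permutationTest(callsNoGrade, eligSame, "upward_count",
                            nPerm = 200, seed = 1, exceedance = "geq")
  expect_equal(ptSame$r, ptSame$n_perm)
  expect_equal(ptSame$empirical_p, 1)
  expect_error(permutationTest(calls, elig, nPerm = 0), "nPerm")
  expect_error(permutationTest(calls[0, ], elig), "no calls")
})

test_that("the tmb_greater statistic permutes regional burdens", {
  co <- simulateCohort(simConfig(nTumours = 8, plantPairProb = 1),
                       seed = 107)
  calls <- cohortPairs(co)
  elig <- eligibleTable(co)
  cats <- lapply(co$bundles, mutationCatalog)
  elig$tmb95 <- vapply(seq_len(nrow(elig)), function(i) {
    cc <- cats[[elig$tumour_id[i]]][[elig$region_id[i]]]
    sum(!is.na(cc) & cc >= 0.95)
  }, numeric(1))
  pt <- permutationTest(calls, elig, "tmb_greater_count", nPerm = 200,
                        seed = 3)
  withTmb <- comparePairTMB(calls, cats)
  expect_equal(pt$observed,
               sum(withTmb$descendant_tmb95 > withTmb$ancestor_tmb95))
})

test_that("sensitivity grid is consistent with single runs", {
  co <- simulateCohort(simConfig(nTumours = 8, plantPairProb = 1),
                       seed = 109)
  grid <- suppressWarnings(
    sensitivityGrid(co, XValues = c(2, 20), YValues = c(10, 1000),
                    nPerm = 100, seed = 5))
  # X=2/Y=10 cell equals the default single run
  single <- cohortPairs(co)
  ptSingle <- permutationTest(single, eligibleTable(co), "upward_count",
                              nPerm = 100, seed = 5)
  row <- grid[grid$X == 2 & grid$Y == 10, ]
  expect_equal(row$n_pairs, nrow(single))
  expect_equal(row$empirical_p, ptSingle$empirical_p)
  # absurd Y gives zero pairs and NA p; X >= Y cells are skipped
  rowHuge <- grid[grid$X == 2 & grid$Y == 1000, ]
  expect_equal(rowHuge$n_pairs, 0)
  expect_true(is.na(rowHuge$empirical_p))
  expect_false(any(grid$X >= grid$Y))
})
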