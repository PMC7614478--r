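# Heterogeneity metrics against closed forms and per-base brute-force
# oracles.

test_that("wGII is the unweighted mean of per-chromosome aberrant fractions", {
  neutral <- segGR("1", 1, 10000, 1, 1)
  expect_equal(wGII(neutral, 2), 0)
  # chr1 fully gained, chr2 fully neutral
  p <- suppressWarnings(
    c(segGR("1", 1, 10000, 2, 1), segGR("2", 1, 10000, 1, 1)))
  expect_equal(wGII(p, 2), 0.5)
  expect_error(wGII(segGR("X", 1, 100, 1, 1), 2), "autosomal")

  set.seed(31)
  for (rep in 1:30) {
    prof <- suppressWarnings(
      c(randomProfile(5000, 4, "1"), randomProfile(5000, 4, "2")))
    pl <- runif(1, 1.8, 3.5)
    st1 <- baseStates(prof[seqnames(prof) == "1"], pl, 5000)
    st2 <- baseStates(prof[seqnames(prof) == "2"], pl, 5000)
    perChrom <- sapply(list(st1, st2), function(s) {
      cov <- s$covered
      if (!any(cov)) return(NA_real_)
      sum((s$gain | s$loss)[cov]) / sum(cov)
    })
    expect_equal(wGII(prof, pl), mean(perChrom, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("FLOH is the covered-genome LOH fraction", {
  expect_equal(fLOH(segGR("1", 1, 100, 1, 1)), 0)
  expect_equal(fLOH(segGR("1", 1, 100, 2, 0)), 1)
  set.seed(37)
  for (rep in 1:30) {
    prof <- randomProfile(8000, 6)
    st <- baseStates(prof, 2, 8000)
    oracle <- sum(st$loh[st$covered]) / sum(st$covered)
    expect_equal(fLOH(prof), oracle, tolerance = 1e-12)
  }
})

test_that("tumour mean metric is the arithmetic mean", {
  expect_equal(tumourMeanMetric(0.2), 0.2)
  expect_equal(tumourMeanMetric(c(0.1, 0.3)), 0.2)
  expect_equal(tumourMeanMetric(c(0.1, 0.2, 0.6)), 0.3)
  expect_error(tumourMeanMetric(numeric()), "no regional")
})

test_that("percent subclonal SCNA matches a per-base region-set oracle", {
  # identical gained profiles -> nothing subclonal
  b <- toyBundle()
  g <- segGR("1", c(1, 4001), c(4000, 10000), c(2, 1), c(1, 1))
  b@segments <- list(R1 = g, R2 = g)
  expect_equal(pctSubclonalSCNA(b), 0)

  # gain private to one of two regions -> fully subclonal
  b2 <- toyBundle()
  b2@segments <- list(
    R1 = segGR("1", c(1, 4001), c(4000, 10000), c(2, 1), c(1, 1)),
    R2 = segGR("1", c(1, 4001), c(4000, 10000), c(1, 1), c(1, 1)))
  expect_equal(pctSubclonalSCNA(b2), 100)

  # single region -> NA sentinel with warning
  b1 <- toyBundle()
  b1@segments <- b1@segments["R1"]
  b1@regions <- b1@regions[1, , drop = FALSE]
  expect_warning(expect_true(is.na(pctSubclonalSCNA(b1))), "single region")

  set.seed(41)
  for (rep in 1:20) {
    b3 <- toyBundle()
    b3@regions <- data.frame(region_id = c("R1", "R2", "R3"),
                             purity = 0.5, ploidy = 2,
                             growth_pattern = "acinar",
                             seeding_label = "unknown")
    b3@regions$grade <- "mid"
    profs <- list(R1 = randomProfile(6000, 5),
                  R2 = randomProfile(6000, 5),
                  R3 = randomProfile(6000, 4))
    b3@segments <- profs
    states <- sapply(profs, function(p) {
      s <- baseStates(p, 2, 6000)
      ifelse(s$gain, 1L, ifelse(s$loss, -1L, 0L))
    })
    anyEv <- rowSums(states != 0) > 0
    clonal <- anyEv & apply(states, 1, function(x) length(unique(x)) == 1)
    oracle <- if (!any(anyEv)) NA_real_
              else 100 * sum(anyEv & !clonal) / sum(anyEv)
    got <- suppressWarnings(pctSubclonalSCNA(b3))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("TMB clonality splits mutations by root cluster", {
  tr <- toyTree()
  cat0 <- toyMutations(tr)
  res <- tmbClonality(tr, cat0)
  expect_equal(res$truncal_tmb, 10)
  expect_equal(res$subclonal_tmb, 5)
  expect_equal(res$pct_subclonal_tmb, 100 * 5 / 15)
  allRoot <- cat0; allRoot$cluster_id <- "C1"
  expect_equal(tmbClonality(tr, allRoot)$pct_subclonal_tmb, 0)
  bad <- cat0; bad$cluster_id[1] <- "C9"
  expect_error(tmbClonality(tr, bad), "unknown cluster")
  # random reassignment vs direct recount
  set.seed(43)
  rnd <- cat0
  rnd$cluster_id <- sample(c("C1", "C2"), nrow(rnd), replace = TRUE)
  res2 <- tmbClonality(tr, rnd)
  expect_equal(res2$truncal_tmb, sum(rnd$cluster_id == "C1"))
  expect_equal(res2$subclonal_tmb, sum(rnd$cluster_id == "C2"))
})

test_that("illusion-of-clonality counts regionally clonal subclonal mutations", {
  mk <- function(ccfC2) {
    ccf <- rbind(C1 = c(1, 1), C2 = ccfC2)
    colnames(ccf) <- c("R1", "R2")
    CloneTree("T", c(C1 = NA_character_, C2 = "C1"), ccf,
              c(C1 = 30L, C2 = 20L))
  }
  tr <- mk(c(0.95, 0.10))
  expect_equal(illusionClonalityCount(tr, toyMutations(tr)), 20)
  tr2 <- mk(c(0.5, 0.4))
  expect_equal(illusionClonalityCount(tr2, toyMutations(tr2)), 0)
  # root cluster never counts even at CCF 1 everywhere
  tr3 <- mk(c(0, 0))
  cat3 <- toyMutations(tr3)
  expect_equal(illusionClonalityCount(tr3, cat3), 0)
  expect_lte(illusionClonalityCount(tr, toyMutations(tr)),
             tmbClonality(tr, toyMutations(tr))$subclonal_tmb)
})

test_that("clone proportions are CCF minus children, renormalised", {
  p <- cloneProportions(toyTree(childCCF = c(0.4, 0.4)), "R1")
  expect_equal(unname(p), c(0.6, 0.4))
  # root with two children at 0.5 each
  ccf <- rbind(C1 = 1, C2 = 0.5, C3 = 0.5)
  colnames(ccf) <- "R1"
  tr <- CloneTree("T", c(C1 = NA_character_, C2 = "C1", C3 = "C1"), ccf)
  expect_equal(unname(cloneProportions(tr, "R1")), c(0, 0.5, 0.5))

  # random valid trees vs exhaustive subtraction oracle
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
    w <- runif(n); w <- w / sum(w)
    ccfV <- vapply(seq_len(n), function(cl) {
      sub <- cl
      repeat {
        kids <- which(parent %in% sub & !(seq_len(n) %in% sub))
        if (!length(kids)) break
        sub <- c(sub, kids)
      }
      sum(w[sub])
    }, numeric(1))
    ccfM <- matrix(ccfV, n, 1,
                   dimnames = list(paste0("C", 1:n), "R1"))
    par <- setNames(ifelse(is.na(parent), NA_character_,
                           paste0("C", parent)), paste0("C", 1:n))
    tr <- CloneTree("T", par, ccfM)
    got <- cloneProportions(tr, "R1")
    expect_equal(sum(got), 1)
    expect_equal(unname(got), w, tolerance = 1e-9)
  }
})

test_that("Shannon diversity closed forms and relabelling invariance", {
  expect_equal(subclonalDiversity(1), 0)
  expect_equal(subclonalDiversity(c(0.5, 0.5)), log(2))
  expect_equal(subclonalDiversity(rep(0.25, 4)), log(4))
  set.seed(53)
  p <- runif(5); p <- p / sum(p)
  expect_equal(subclonalDiversity(p), subclonalDiversity(sample(p)))
  expect_lte(subclonalDiversity(p), log(5))
})

test_that("recent expansion score is the max regional leaf CCF", {
  tr <- toyTree(childCCF = c(0.2, 0.9))
  expect_equal(as.numeric(recentExpansionScore(tr)), 0.9)
  # two leaves with per-region maxima 0.3 / 0.4
  ccf <- rbind(C1 = c(1, 1), C2 = c(0.3, 0.1), C3 = c(0.2, 0.4))
  colnames(ccf) <- c("R1", "R2")
  tr2 <- CloneTree("T", c(C1 = NA_character_, C2 = "C1", C3 = "C1"), ccf)
  expect_equal(as.numeric(recentExpansionScore(tr2)), 0.4)
  # monotone: raising any leaf CCF never lowers the score
  ccf3 <- ccf; ccf3["C2", "R1"] <- 0.35
  tr3 <- CloneTree("T", c(C1 = NA_character_, C2 = "C1", C3 = "C1"), ccf3)
  expect_gte(as.numeric(recentExpansionScore(tr3)),
             as.numeric(recentExpansionScore(tr2)))
  # degenerate root-only tree
  tr4 <- CloneTree("T", c(C1 = NA_character_),
                   matrix(c(1, 0.98), 1, dimnames = list("C1", c("R1", "R2"))))
  s4 <- recentExpansionScore(tr4)
  expect_true(attr(s4, "degenerate"))
  expect_equal(as.numeric(s4), 1)
})

test_that("tumour metric panel respects its internal identities", {
  co <- simulateCohort(simConfig(nTumours = 4), seed = 19)
  for (b in co$bundles) {
    m <- tumourMetrics(b)
    expect_gte(m$wgii_mean, 0); expect_lte(m$wgii_mean, 1)
    expect_gte(m$floh_mean, 0); expect_lte(m$floh_mean, 1)
    expect_lte(m$illusion_tmb, m$subclonal_tmb)
    expect_equal(m$pct_subclonal_tmb,
                 100 * m$subclonal_tmb / (m$truncal_tmb + m$subclonal_tmb))
    if (!is.na(m$pct_subclonal_scna)) {
      expect_gte(m$pct_subclonal_scna, 0)
      expect_lte(m$pct_subclonal_scna, 100)
    }
  }
})
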