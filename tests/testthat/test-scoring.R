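test_that("global score follows the bounded-difference formula", {
  one <- function(target, model)
    globalCadScore(data.frame(src = "A|1|", snk = "A|2|",
                              target = target, model = model))
  expect_equal(one(10, 7), 0.7)
  expect_equal(one(10, 10), 1)
  expect_equal(one(10, 0), 0)   # contact entirely lost
  expect_equal(one(10, 25), 0)  # overshoot bounded by the target area
  G <- randomContactSet(12, seed = 5)
  expect_equal(globalCadScore(transform(G, model = target)), 1)
})

test_that("an empty reference set gives an explicit undefined-score error", {
  empty <- data.frame(src = character(0), snk = character(0),
                      target = numeric(0), model = numeric(0))
  expect_error(globalCadScore(empty), class = "cadscorer_undefined_score")
})

test_that("raw and normalized local errors follow the per-residue sums", {
  G <- data.frame(src = c("A|1|", "A|1|", "A|2|"),
                  snk = c("A|2|", "A|3|", "A|3|"),
                  target = c(10, 5, 8), model = c(7, 5, 8))
  raw <- localErrorsRaw(G)
  expect_equal(raw$delta[raw$resKey == "A|1|"], 3)
  expect_equal(raw$targetSum[raw$resKey == "A|1|"], 15)
  nrm <- localErrorsNormalized(raw)
  expect_equal(nrm$epsilon[nrm$resKey == "A|1|"], 0.2)
  expect_equal(nrm$epsilon[nrm$resKey == "A|2|"], 0)

  lost <- localErrorsNormalized(localErrorsRaw(transform(G, model = 0)))
  expect_equal(lost$epsilon, rep(1, 2))
  expect_equal(lost$delta, c(15, 8))

  # residues without outgoing pairs are flagged not analyzed
  all3 <- localErrorsRaw(G, residues = c("A|1|", "A|2|", "A|3|"))
  expect_false(all3$analyzed[all3$resKey == "A|3|"])
  expect_equal(all3$delta[all3$resKey == "A|3|"], 0)
})

test_that("window smoothing truncates at termini and keeps chains apart", {
  delta <- c(3, 6, 9)
  ts <- c(10, 10, 10)
  sm <- smoothErrors(delta, ts, chain = rep("A", 3), w = 1)
  expect_equal(sm$delta_w, c(4.5, 6, 7.5))
  expect_equal(sm$epsilon_w, c(9 / 20, 18 / 30, 15 / 20))
  sm0 <- smoothErrors(delta, ts, chain = rep("A", 3), w = 0)
  expect_equal(sm0$delta_w, delta)
  expect_equal(sm0$epsilon_w, delta / ts)
  # chain boundary: windows never mix chains
  smAB <- smoothErrors(c(3, 9), c(10, 10), chain = c("A", "B"), w = 3)
  expect_equal(smAB$delta_w, c(3, 9))
  expect_error(smoothErrors(delta, ts, rep("A", 3), w = -1), "non-negative")
  # epsilon_w is a ratio of sums, not a mean of ratios
  sm2 <- smoothErrors(c(1, 50), c(2, 100), chain = c("A", "A"), w = 1)
  expect_equal(sm2$epsilon_w, c(0.5, 0.5))
  expect_equal(sm2$delta_w, c(25.5, 25.5))
})

test_that("global score is the area-weighted aggregation of local errors", {
  for (seed in 1:8) {
    G <- randomContactSet(20, seed)
    raw <- localErrorsRaw(G)
    expect_equal(1 - sum(raw$delta) / sum(raw$targetSum), globalCadScore(G),
                 tolerance = 1e-12)
  }
})

test_that("scores and normalized errors stay within [0,1] on random inputs", {
  for (seed in 1:25) {
    G <- randomContactSet(30, seed)
    s <- globalCadScore(G)
    expect_gte(s, 0)
    expect_lte(s, 1)
    eps <- localErrorsNormalized(localErrorsRaw(G))$epsilon
    expect_true(all(eps >= 0 & eps <= 1))
  }
})

test_that("the score is invariant under rigid motion of the model", {
  t <- makeToyPeptide(6, seed = 3)
  m <- perturbStructure(t, 0.5, seed = 9)
  rot <- rotationMatrix(1.0, 0.4, -0.7)
  m2 <- rigidTransform(m, rot, shift = c(20, 5, -8))
  dirs <- fibonacciSphereDirections(800)
  ti <- computeContactInventory(t, directions = dirs)
  mi <- computeContactInventory(m, directions = dirs)
  mi2 <- computeContactInventory(m2, directions = dirs %*% t(rot))
  s1 <- scoreVariant(ti, mi, "A-A")@globalScore
  s2 <- scoreVariant(ti, mi2, "A-A")@globalScore
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("scoring is asymmetric: G always comes from the first argument", {
  t <- makeToyPeptide(6, seed = 1)
  m <- perturbStructure(t, 1.5, seed = 2)
  dirs <- fibonacciSphereDirections(600)
  ti <- computeContactInventory(t, directions = dirs)
  mi <- computeContactInventory(m, directions = dirs)
  stm <- scoreVariant(ti, mi, "A-A")@globalScore
  smt <- scoreVariant(mi, ti, "A-A")@globalScore
  # both are valid scores but need not coincide
  expect_true(stm >= 0 && stm <= 1 && smt >= 0 && smt <= 1)
})

test_that("all applicable variants are reported, undefined ones included", {
  pep <- makeToyPeptide(5, seed = 1)
  ip <- computeContactInventory(pep, samplingDensity = 500)
  rp <- scoreAllVariants(ip, ip)
  expect_setequal(names(rp), c("A-A", "A-M", "A-S", "M-M", "M-S", "S-S"))

  dup <- makeToyDuplex(3, seed = 1)
  idup <- computeContactInventory(dup, samplingDensity = 500)
  rd <- scoreAllVariants(idup, idup)
  expect_setequal(names(rd),
                  c("A-A", "A-M", "A-S", "M-M", "M-S", "S-S",
                    "S-S-stacking", "S-S-non-stacking"))
  expect_true(all(vapply(rd, function(r) r@status, "") == "ok"))

  # glycine-only chain has no side-chain atoms at all -> S-S undefined
  gly <- looseStructure(list(
    list(chain = "A", resSeq = 1L, resName = "GLY",
         atoms = c("N", "CA", "C", "O"), elements = c("N", "C", "C", "O"),
         x = c(0, 1.4, 2.4, 2.4), y = c(0, 0.4, -0.4, -1.6), z = 0),
    list(chain = "A", resSeq = 2L, resName = "GLY",
         atoms = c("N", "CA", "C", "O"), elements = c("N", "C", "C", "O"),
         x = c(4.3, 5.7, 6.7, 6.7), y = c(0, 0.4, -0.4, -1.6), z = 0)))
  ig <- computeContactInventory(gly, samplingDensity = 500)
  rg <- scoreAllVariants(ig, ig)
  expect_equal(rg[["S-S"]]@status, "undefined")
  expect_true(is.na(rg[["S-S"]]@globalScore))
  expect_equal(rg[["A-A"]]@status, "ok")
})

test_that("cadScore runs end to end and enforces consistency", {
  t <- makeToyPeptide(6, seed = 1)
  m <- perturbStructure(t, 0.3, seed = 5)
  res <- cadScore(t, m, samplingDensity = 400)
  expect_s4_class(res, "CadScoreResult")
  gs <- globalScore(res)
  expect_true(all(gs[!is.na(gs)] >= 0 & gs[!is.na(gs)] <= 1))
  # self-comparison is exactly 1
  self <- cadScore(t, t, samplingDensity = 400)
  expect_true(all(globalScore(self) == 1))
  # a residue-name mismatch aborts unless tolerated
  bad <- m
  a <- atoms(bad)
  a$resName[a$resSeq == 3] <- "GLY"
  bad@atoms <- a
  expect_error(cadScore(t, bad, samplingDensity = 400), "consistency")
  expect_s4_class(cadScore(t, bad, samplingDensity = 400,
                           allowSeqMismatch = TRUE), "CadScoreResult")
})

test_that("target residues missing from the model count as fully lost", {
  t <- makeToyPeptide(6, seed = 1)
  m <- t
  m@atoms <- atoms(m)[atoms(m)$resSeq != 3, ]
  res <- cadScore(t, m, samplingDensity = 500)
  aa <- reports(res)[["A-A"]]
  p <- profile(aa)
  expect_equal(p$epsilon[p$resSeq == 3], 1)
  expect_lt(aa@globalScore, 1)
})
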