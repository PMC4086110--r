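test_that("fibonacci directions are unit, near-uniform and validated", {
  expect_error(fibonacciSphereDirections(0), "positive")
  expect_equal(dim(fibonacciSphereDirections(1)), c(1L, 3L))
  d <- fibonacciSphereDirections(1000)
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-12))
  expect_lt(sqrt(sum(colMeans(d)^2)), 0.01)
})

test_that("two-atom contact areas match the spherical-cap closed form", {
  for (case in list(c(1.7, 1.7, 3.4), c(1.5, 2.0, 3.0), c(1.4, 1.8, 4.0))) {
    s <- makeTwoAtomSystem(case[1], case[2], case[3])
    ac <- computeAtomContacts(s, samplingDensity = 2000)
    a12 <- ac$area[ac$src == 1 & !is.na(ac$snk)]
    expect_equal(a12, sphericalCapArea(case[1], case[2], case[3]),
                 tolerance = 0.02)
    a21 <- ac$area[ac$src == 2 & !is.na(ac$snk)]
    expect_equal(a21, sphericalCapArea(case[2], case[1], case[3]),
                 tolerance = 0.02)
  }
})

test_that("disjoint and isolated atoms are fully solvent-accessible", {
  s <- makeTwoAtomSystem(1.7, 1.7, 10)
  ac <- computeAtomContacts(s, samplingDensity = 1000)
  expect_true(all(is.na(ac$snk)))
  expect_equal(ac$area, rep(4 * pi * 3.1^2, 2))

  one <- makeTwoAtomSystem(1.7, 1.7, 10)
  one@atoms <- atoms(one)[1, ]
  ac1 <- computeAtomContacts(one, samplingDensity = 777)
  expect_equal(nrow(ac1), 1L)
  expect_true(is.na(ac1$snk))
  expect_equal(ac1$area, 4 * pi * 3.1^2)
})

test_that("per-atom areas always sum to the full contact-sphere area", {
  s <- makeToyPeptide(6, seed = 4)
  ac <- computeAtomContacts(s, samplingDensity = 400)
  a <- atoms(s)
  tot <- rowsum(ac$area, ac$src)
  expect_equal(as.numeric(tot),
               4 * pi * (a$vdw[as.integer(rownames(tot))] + 1.4)^2,
               tolerance = 1e-12)
})

test_that("directed areas are symmetric for equal radii and monotone in d", {
  prev <- Inf
  for (d in seq(2.6, 6.4, by = 0.4)) {
    s <- makeTwoAtomSystem(1.7, 1.7, d)
    ac <- computeAtomContacts(s, samplingDensity = 2000)
    a12 <- sum(ac$area[ac$src == 1 & !is.na(ac$snk)])
    a21 <- sum(ac$area[ac$src == 2 & !is.na(ac$snk)])
    expect_lte(abs(a12 - a21), max(0.05 * a12, 0.5))  # sampling tolerance
    expect_lte(a12, prev + 1e-9)
    prev <- a12
  }
})

test_that("coincident atom centers are rejected", {
  s <- makeTwoAtomSystem(1.7, 1.7, 3)
  a <- atoms(s)
  a[2, c("x", "y", "z")] <- a[1, c("x", "y", "z")]
  s@atoms <- a
  expect_error(computeAtomContacts(s), "degenerate")
  unassigned <- makeToyPeptide(2)
  unassigned@atoms$vdw <- NA_real_
  expect_error(computeAtomContacts(unassigned), "radii")
})

test_that("engine agrees with the independent high-density oracle", {
  set.seed(11)
  for (n in c(3, 5)) {
    at <- data.frame(chain = "A", resSeq = seq_len(n), icode = "",
                     resName = "LIG", atomName = paste0("X", seq_len(n)),
                     element = sample(c("C", "N", "O"), n, replace = TRUE),
                     x = runif(n, 0, 4), y = runif(n, 0, 4), z = runif(n, 0, 4),
                     vdw = NA_real_, altLoc = "", occupancy = 1)
    st <- suppressWarnings(assignRadii(cadscorer:::.newStructure(at, "protein")))
    e <- computeAtomContacts(st, samplingDensity = 2000)
    o <- bruteForceContactOracle(st, denseN = 200000)
    key <- function(d) paste(d$src, d$snk)
    allk <- union(key(e), key(o))
    ea <- e$area[match(allk, key(e))]; ea[is.na(ea)] <- 0
    oa <- o$area[match(allk, key(o))]; oa[is.na(oa)] <- 0
    expect_true(all(abs(ea - oa) <= pmax(0.05 * oa, 0.5)))
  }
})

test_that("areas are invariant under rigid motion of the structure", {
  s <- makeToyPeptide(4, seed = 2)
  rot <- rotationMatrix(0.3, -1.1, 2.2)
  s2 <- rigidTransform(s, rot, shift = c(5, -3, 11))
  dirs <- fibonacciSphereDirections(800)
  ac1 <- computeAtomContacts(s, directions = dirs)
  ac2 <- computeAtomContacts(s2, directions = dirs %*% t(rot))
  expect_equal(ac1$snk, ac2$snk)
  expect_equal(ac1$area, ac2$area, tolerance = 1e-9)
})

test_that("covalent peptide/phosphodiester contacts are excluded", {
  # dipeptide whose only interatomic contact is the C(1)-N(2) bond pair
  dip <- looseStructure(list(
    list(chain = "A", resSeq = 1L, resName = "ALA", atoms = "C",
         elements = "C", x = 0, y = 0, z = 0),
    list(chain = "A", resSeq = 2L, resName = "ALA", atoms = "N",
         elements = "N", x = 1.33, y = 0, z = 0)))
  inv <- computeContactInventory(dip, samplingDensity = 500)
  expect_equal(nrow(variantAreas(inv, "A-A")), 0L)

  dinuc <- looseStructure(list(
    list(chain = "A", resSeq = 1L, resName = "A", atoms = "O3'",
         elements = "O", x = 0, y = 0, z = 0),
    list(chain = "A", resSeq = 2L, resName = "A", atoms = "P",
         elements = "P", x = 1.6, y = 0, z = 0)), "nucleic")
  expect_equal(nrow(variantAreas(computeContactInventory(dinuc, 1.4, 500),
                                 "A-A")), 0L)

  # the same atom pair on different chains is NOT excluded
  cross <- looseStructure(list(
    list(chain = "A", resSeq = 1L, resName = "ALA", atoms = "C",
         elements = "C", x = 0, y = 0, z = 0),
    list(chain = "B", resSeq = 2L, resName = "ALA", atoms = "N",
         elements = "N", x = 1.33, y = 0, z = 0)))
  expect_gt(nrow(variantAreas(computeContactInventory(cross, 1.4, 500),
                              "A-A")), 0L)
})

test_that("residue aggregation groups atom areas by subset variant", {
  two <- looseStructure(list(
    list(chain = "A", resSeq = 1L, resName = "ALA", atoms = "CB",
         elements = "C", x = 0, y = 0, z = 0),
    list(chain = "B", resSeq = 1L, resName = "ALA", atoms = "CB",
         elements = "C", x = 4.0, y = 0, z = 0)))
  inv <- computeContactInventory(two, samplingDensity = 1000)
  ss <- variantAreas(inv, "S-S")
  expect_equal(nrow(ss), 2L)  # directed both ways
  expect_equal(sort(ss$src), c("A|1|", "B|1|"))
  expect_equal(ss$area[1], ss$area[2], tolerance = 0.03)
  aa <- variantAreas(inv, "A-A")
  expect_equal(sort(aa$area), sort(ss$area))  # only side-chain atoms exist
  expect_equal(nrow(variantAreas(inv, "M-M")), 0L)
  # absent pairs read as zero by the set builder
  G <- buildReferenceSet(inv, wholeSelection(), "M-M")
  expect_equal(nrow(G), 0L)
})

test_that("stacking classifier separates face-to-face from side-by-side", {
  hexAt <- function(chain, resSeq, cx, cy, cz, rot = diag(3)) {
    ang <- (0:5) * pi / 3
    p <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0) %*% t(rot)
    list(chain = chain, resSeq = resSeq, resName = "A",
         atoms = c("N1", "C2", "N3", "C4", "C5", "C6"),
         elements = c("N", "C", "N", "C", "C", "C"),
         x = p[, 1] + cx, y = p[, 2] + cy, z = p[, 3] + cz)
  }
  # parallel bases displaced 3.4 A along the shared normal -> stacking
  st <- looseStructure(list(hexAt("A", 1L, 0, 0, 0),
                            hexAt("A", 2L, 0, 0, 3.4)), "nucleic")
  expect_true(classifyStacking(st, "A|1|", "A|2|"))
  # coplanar side-by-side bases (Watson-Crick-like) -> non-stacking
  side <- looseStructure(list(hexAt("A", 1L, 0, 0, 0),
                              hexAt("B", 1L, 6, 0, 0)), "nucleic")
  expect_false(classifyStacking(side, "A|1|", "B|1|"))
  # normals 90 degrees apart -> non-stacking
  perp <- looseStructure(list(hexAt("A", 1L, 0, 0, 0),
                              hexAt("A", 2L, 0, 0, 3.4,
                                    rotationMatrix(pi / 2, 0, 0))), "nucleic")
  expect_false(classifyStacking(perp, "A|1|", "A|2|"))
  # fewer than 3 base ring atoms is an error
  tiny <- looseStructure(list(
    list(chain = "A", resSeq = 1L, resName = "A", atoms = c("N1", "C2"),
         elements = c("N", "C"), x = c(0, 1.4), y = 0, z = 0),
    hexAt("A", 2L, 0, 0, 3.4)), "nucleic")
  expect_error(classifyStacking(tiny, "A|1|", "A|2|"), "ring atoms")
})

test_that("engine converges to the oracle as density grows", {
  s <- makeTwoAtomSystem(1.6, 1.9, 3.2)
  exact <- sphericalCapArea(1.6, 1.9, 3.2)
  err <- vapply(c(500, 2000, 10000), function(n) {
    ac <- computeAtomContacts(s, samplingDensity = n)
    abs(ac$area[ac$src == 1 & !is.na(ac$snk)] - exact)
  }, 0)
  expect_lt(err[3], err[1])
  expect_lt(err[3] / exact, 0.01)
})
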