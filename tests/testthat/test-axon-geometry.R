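# Cross-section normalization, the glomerulus long axis, medians, axon
# tips, and equal-synapse compartments.

parallelSkeletons <- function() {
  list(a = straightSkeleton(11, 1000, y = 0, id = "a"),
       b = straightSkeleton(11, 1000, y = 2000, id = "b"),
       c = straightSkeleton(11, 1000, y = 1000, id = "c"))
}

test_that("cross-section positions land the reference pair at (0,0)/(0,1)", {
  sks <- parallelSkeletons()
  pos <- crossSectionPositions(sks, c(5000, 0, 0), c(1, 0, 0),
                               thickness = 1000, refPair = c("a", "b"))
  expect_equal(unname(pos["a", ]), c(0, 0))
  expect_equal(unname(pos["b", ]), c(0, 1))
  # an axon midway between the references maps to (0, 0.5)
  expect_equal(unname(pos["c", ]), c(0, 0.5))
  expect_error(crossSectionPositions(sks, c(5000, 0, 0), c(1, 0, 0), 1000,
                                     refPair = c("a", "zz")),
               "absent from the slab")
})

test_that("in-slab node centroids are used and misses are reported", {
  # axon running inside the slab plane: all 10 nodes average
  inPlane <- skeleton(data.frame(node_id = 1:10, parent_id = c(NA, 1:9),
                                 x = 5000, y = seq(0, 900, by = 100),
                                 z = 0), "flat")
  sks <- c(parallelSkeletons(), list(flat = inPlane),
           list(far = straightSkeleton(3, 100, id = "far")))
  pos <- crossSectionPositions(sks, c(5000, 0, 0), c(1, 0, 0),
                               thickness = 1000, refPair = c("a", "b"))
  expect_equal(attr(pos, "omitted"), "far")
  # flat's centroid is y = 450 -> normalized to (0, 0.225)
  expect_equal(unname(pos["flat", ]), c(0, 0.225))
})

test_that("cross-section output is invariant to rigid motion of the scene", {
  sks <- parallelSkeletons()
  pos <- crossSectionPositions(sks, c(5000, 0, 0), c(1, 0, 0), 1000,
                               c("a", "b"))
  # rotate everything 90 degrees about z ((x, y) -> (y, -x)) and translate
  rot <- function(sk) {
    nd <- sk@nodes
    xy <- cbind(nd$y, -nd$x)
    nd$x <- xy[, 1] + 1e5; nd$y <- xy[, 2] - 3e4; nd$z <- nd$z + 2e4
    skeleton(nd, sk@neuronId)
  }
  pos2 <- crossSectionPositions(lapply(sks, rot),
                                c(0 + 1e5, -5000 - 3e4, 2e4), c(0, -1, 0),
                                1000, c("a", "b"))
  expect_equal(pos2, pos, tolerance = 1e-6)
})

test_that("the long axis is the principal axis of the presynapse cloud", {
  onX <- cbind(seq(-500, 500, length.out = 21), 0, 0)
  ax <- glomerulusLongAxis(onX)
  expect_equal(abs(ax@direction), c(1, 0, 0))
  expect_error(glomerulusLongAxis(onX[1, , drop = FALSE]), "degenerate")
  withr::with_seed(13, {
    # synthetic cylinder, 40 um long, 5 um radius, tilted axis
    t <- runif(3000, -20000, 20000)
    axDir <- c(2, 1, 0.5) / sqrt(sum(c(2, 1, 0.5)^2))
    perp1 <- c(-1, 2, 0) / sqrt(5)
    perp2 <- c(axDir[2] * perp1[3] - axDir[3] * perp1[2],
               axDir[3] * perp1[1] - axDir[1] * perp1[3],
               axDir[1] * perp1[2] - axDir[2] * perp1[1])
    r <- 5000 * sqrt(runif(3000)); th <- runif(3000, 0, 2 * pi)
    cyl <- outer(t, axDir) + outer(r * cos(th), perp1) +
      outer(r * sin(th), perp2)
    axc <- glomerulusLongAxis(cyl)
    ang <- acos(abs(sum(axc@direction * axDir))) * 180 / pi
    expect_lt(ang, 2)
    expect_false(axc@nearIsotropic)
    # an isotropic sphere is flagged
    sph <- matrix(rnorm(3000 * 3), ncol = 3)
    expect_true(glomerulusLongAxis(sph)@nearIsotropic)
  })
})

test_that("median axis positions are robust medians of projections", {
  ax <- new("LongAxis", origin = c(0, 0, 0), direction = c(1, 0, 0),
            extent = c(0, 100), eigenvalues = c(1, 0, 0),
            nearIsotropic = FALSE)
  sym <- cbind(c(1, 2, 3, 4, 5), 0, 0)
  expect_equal(medianAxisPosition(sym, ax), 3)
  expect_equal(medianAxisPosition(cbind(c(1, 2, 100), 5, -2), ax), 2)
  expect_error(medianAxisPosition(sym[0, , drop = FALSE], ax), "empty")
  # skeleton-node and presynapse medians agree for uniform synapses
  sk <- straightSkeleton(101, spacing = 400)
  presyn <- withr::with_seed(5, cbind(runif(400, 0, 4e4), 0, 0))
  expect_lt(abs(medianAxisPosition(sk, ax) -
                medianAxisPosition(presyn, ax)), 1200)
})

test_that("axon tips average the farthest nodes along the arbor", {
  sk <- straightSkeleton(100, spacing = 400)
  tip <- axonTipPosition(sk, entryPoint = c(0, 0, 0))
  expect_equal(tip[1], mean((90:99) * 400))
  ten <- straightSkeleton(10, spacing = 400)
  expect_equal(axonTipPosition(ten, c(0, 0, 0))[1], 9 * 400)
  expect_error(axonTipPosition(straightSkeleton(9), c(0, 0, 0)),
               "too few")
  # a branched axon: the tip lies on the long branch
  nodes <- data.frame(node_id = 1:30, parent_id = c(NA, 1:19, 10, 21:29),
                      x = c((0:19) * 400, rep(10 * 400, 10)),
                      y = c(rep(0, 20), (1:10) * 200), z = 0)
  yTree <- skeleton(nodes)
  tipY <- axonTipPosition(yTree, c(0, 0, 0))
  expect_gt(tipY[1], 6000)   # on the long x branch, not the short spur
  expect_lt(abs(tipY[2]), 1)
})

test_that("compartments hold equal presynapse counts with quantile bounds", {
  ax <- new("LongAxis", origin = c(0, 0, 0), direction = c(1, 0, 0),
            extent = c(0, 100), eigenvalues = c(1, 0, 0),
            nearIsotropic = FALSE)
  p100 <- cbind(runif(100), 0, 0)
  part <- partitionCompartments(p100, ax, 10)
  expect_equal(tabulate(part@assignment, 10), rep(10L, 10))
  expect_false(is.unsorted(part@boundaries))
  p101 <- cbind(runif(101), 0, 0)
  part2 <- partitionCompartments(p101, ax, 10)
  expect_equal(sort(tabulate(part2@assignment, 10)),
               c(rep(10L, 9), 11L))
  expect_error(partitionCompartments(p100[1:5, ], ax, 10), "invalid size")
  # all presynapses at one coordinate: deterministic and flagged
  tied <- cbind(rep(1, 40), 0, 0)
  pt <- partitionCompartments(tied, ax, 4)
  expect_true(pt@degenerate)
  expect_equal(pt@assignment, rep(1:4, each = 10))
  expect_identical(pt@assignment,
                   partitionCompartments(tied, ax, 4)@assignment)
})

test_that("the glomerulus mask keeps in-volume nodes and drops far ones", {
  presyn <- cbind(runif(200, 0, 10000), runif(200, -500, 500),
                  runif(200, -500, 500))
  mask <- glomerulusMask(presyn, margin = 1000)
  expect_true(all(mask(presyn)))
  expect_false(any(mask(cbind(c(-50000, 50000), 0, 0))))
  sk <- straightSkeleton(100, spacing = 1000)  # runs 0..99 um along x
  inGlom <- maskSkeleton(sk, mask)
  expect_lt(max(inGlom@nodes$x), 12000)
  expect_equal(sum(is.na(inGlom@nodes$parent_id)), 1L)
})
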