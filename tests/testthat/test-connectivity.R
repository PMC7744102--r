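# Connectivity matrices, the distance-weighted shuffle test, the
# presynapse-based distance, compartment RI, proximity profiles, and
# synapse density per cable.

test_that("connectivity matrices group counts and apply the threshold", {
  tm <- data.frame(id = c("l1", "l2", "g1"),
                   type = c("LC", "LC", "G"), side = "R")
  empty <- synapseTable(data.frame(pre_id = character(),
                                   post_id = character(),
                                   x = numeric(), y = numeric(),
                                   z = numeric()))
  m0 <- buildConnectivityMatrix(empty, tm)
  expect_true(all(m0@counts == 0))
  # a 14-synapse pair is zeroed at threshold 15 but kept in the archive
  syn <- synapseTable(data.frame(pre_id = rep("l1", 14), post_id = "g1",
                                 x = 0, y = 0, z = 0))
  m <- buildConnectivityMatrix(syn, tm, threshold = 15)
  expect_equal(m@counts["LC:R", "G:R"], 0)
  expect_equal(m@raw$count[m@raw$pre == "l1" & m@raw$post == "g1"], 14)
  expect_equal(buildConnectivityMatrix(syn, tm, threshold = 14)@counts[
    "LC:R", "G:R"], 14)
  expect_error(buildConnectivityMatrix(syn, tm[-1, ], 0), "missing")
})

test_that("generator target counts round-trip through the matrix builder", {
  cn <- generateConnectome(smallConfig(seed = 17))
  ids <- rownames(eyeCenters(cn))
  # expand counts into synapse records and rebuild
  cnt <- cn@targetCounts
  rec <- do.call(rbind, lapply(rownames(cnt), function(t)
    data.frame(pre_id = rep(ids, cnt[t, ]), post_id = t,
               x = 0, y = 0, z = 0)))
  tm <- data.frame(id = c(ids, rownames(cnt)),
                   type = c(ids, rownames(cnt)), side = "R")
  m <- buildConnectivityMatrix(synapseTable(rec), tm)
  for (t in rownames(cnt)) for (i in ids)
    expect_equal(unname(m@counts[paste0(i, ":R"), paste0(t, ":R")]),
                 unname(cnt[t, i]))
})

test_that("the distance-weighted shuffle preserves both multisets", {
  withr::with_seed(19, {
    ec <- cbind(lon = runif(6, -60, 60), lat = runif(6, 0, 140))
    rownames(ec) <- paste0("n", 1:6)
    W <- matrix(rpois(36, 3), 6, 6, dimnames = list(rownames(ec),
                                                    rownames(ec)))
    diag(W) <- 0
  })
  D <- glomotopy:::metricDist(ec, "greatcircle")
  b <- lcLcDistanceBias(ec, W, nShuffles = 100, seed = 23)
  # every null weighted mean is built from the same distances and weights:
  # it must lie within the convex hull of the per-neuron distance range
  Wp <- W + t(W)
  lo <- mean(vapply(1:6, function(i) min(D[i, -i]), numeric(1)))
  hi <- mean(vapply(1:6, function(i) max(D[i, -i]), numeric(1)))
  expect_true(all(b$null >= lo - 1e-9 & b$null <= hi + 1e-9))
  expect_equal(length(b$perNeuron), 6L)
})

test_that("uniform weights make the shuffle test exactly null", {
  ec <- makeLobulaGrid(4, 4, jitterSd = 3, seed = 29)
  u <- matrix(1, 16, 16, dimnames = list(rownames(ec), rownames(ec)))
  diag(u) <- 0
  b <- lcLcDistanceBias(ec, u, nShuffles = 200, seed = 31)
  expect_equal(b$observed, mean(b$null))
  expect_equal(b$p, 0.5)
  expect_error(lcLcDistanceBias(ec, u * 0, 200, 1), "all synapse counts")
})

test_that("distance-decayed connectivity is detected as biased", {
  cn <- generateConnectome(smallConfig(lcLcDecayScale = 10, seed = 37))
  ec <- eyeCenters(cn)
  ids <- rownames(ec)
  lc <- cn@lcLcSynapses@synapses
  cnt <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  tab <- table(lc$pre_id, lc$post_id)
  cnt[rownames(tab), colnames(tab)] <- tab
  b <- lcLcDistanceBias(ec, cnt, nShuffles = 1000, seed = 41)
  expect_lt(b$p, 0.05)
  expect_lt(b$observed, mean(b$null))
})

test_that("presynapseDistance is a symmetric pooled nearest-neighbour mean", {
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(3, 4, 0), 1)
  expect_equal(presynapseDistance(a, b), 5)
  expect_equal(presynapseDistance(a, a), 0)
  expect_error(presynapseDistance(a[0, , drop = FALSE], b), "empty")
  withr::with_seed(43, {
    for (rep in 1:20) {
      x <- matrix(rnorm(30), ncol = 3)
      y <- matrix(rnorm(24), ncol = 3)
      expect_equal(presynapseDistance(x, y), presynapseDistance(y, x))
    }
  })
})

test_that("compartment RI separates structure from its randomized control", {
  cn <- generateConnectome(smallConfig(seed = 47))
  ax <- glomerulusLongAxis(cn@presynapses)
  part <- partitionCompartments(cn@presynapses, ax, 5)
  pd <- data.frame(neuron_id = cn@presynapses@synapses$pre_id,
                   cn@presynapses@synapses[, c("x", "y", "z")],
                   compartment = part@assignment)
  obs <- compartmentRI(pd, eyeCenters(cn), 2:4)
  ctrl <- compartmentRI(pd, eyeCenters(cn), 2:4, randomize = TRUE,
                        seed = 53)
  expect_gt(obs@populationRI, ctrl@populationRI)
  # the randomized control is centred on zero across seeds
  ctrls <- vapply(1:40, function(s)
    compartmentRI(pd, eyeCenters(cn), 2:4, randomize = TRUE,
                  seed = s)@populationRI, numeric(1))
  expect_lt(abs(mean(ctrls)), 3 * sd(ctrls) / sqrt(length(ctrls)) + 0.02)
  # selecting all compartments equals using every presynapse at once
  all1 <- compartmentRI(pd, eyeCenters(cn), 1:5)
  pd2 <- pd; pd2$compartment <- 1L
  all2 <- compartmentRI(pd2, eyeCenters(cn), 1)
  expect_equal(all1@perPointRI, all2@perPointRI)
  expect_error(compartmentRI(pd[pd$neuron_id %in% pd$neuron_id[1], ],
                             eyeCenters(cn), 1:5), "fewer than 3")
})

test_that("proximity profiles recover constructed parallel offsets", {
  ax <- new("LongAxis", origin = c(0, 0, 0), direction = c(1, 0, 0),
            extent = c(0, 80000), eigenvalues = c(1, 0, 0),
            nearIsotropic = FALSE)
  target <- straightSkeleton(81, spacing = 1000, y = 0, id = "t")
  near <- straightSkeleton(81, spacing = 1000, y = 2000, id = "near")
  far <- straightSkeleton(81, spacing = 1000, y = 6000, id = "far")
  prof <- targetProximityProfile(target, list(near = near, far = far), ax,
                                 sliceThickness = 1000, nSlices = 80,
                                 groups = list(near = "near", far = "far"))
  expect_equal(nrow(prof), 80L)
  expect_equal(unique(round(prof$near)), 2000)
  expect_equal(unique(round(prof$far)), 6000)
  # a target coincident with one axon is at distance zero everywhere
  prof0 <- targetProximityProfile(target, list(self = target), ax,
                                  sliceThickness = 1000, nSlices = 80)
  expect_true(all(prof0$all == 0))
  # slices beyond the target are missing, not zero
  shortT <- straightSkeleton(11, spacing = 1000, y = 0, id = "s")
  profS <- targetProximityProfile(shortT, list(near = near), ax,
                                  sliceThickness = 1000, nSlices = 80)
  expect_true(all(is.na(profS$all[40:80])))
})

test_that("synapse density per cable flags non-uniform placement", {
  ax <- new("LongAxis", origin = c(0, 0, 0), direction = c(1, 0, 0),
            extent = c(0, 40000), eigenvalues = c(1, 0, 0),
            nearIsotropic = FALSE)
  sk <- straightSkeleton(101, spacing = 400)
  uni <- withr::with_seed(59, cbind(runif(500, 0, 40000), 0, 0))
  resU <- synapseDensityPerCable(sk, uni, ax, nSlices = 10)
  expect_lt(resU$maxRelDeviation, 0.5)
  expect_equal(sum(resU$profile$count), 500)
  # all synapses in one slice of ten: a gross violation, well above 50%
  lump <- cbind(runif(500, 0, 4000), 0, 0)
  resL <- synapseDensityPerCable(sk, lump, ax, nSlices = 10)
  expect_gt(resL$maxRelDeviation, 0.5)
  # refining the slicing never changes the total synapse count
  res20 <- synapseDensityPerCable(sk, uni, ax, nSlices = 20)
  expect_equal(sum(res20$profile$count), sum(resU$profile$count))
})
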