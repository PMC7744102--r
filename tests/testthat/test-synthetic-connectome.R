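# The synthetic connectome generator: determinism, structural invariants,
# the scramble dial, RF-center recovery, and synthetic traces.

test_that("the lobula lattice is exact at zero jitter and deterministic", {
  g0 <- makeLobulaGrid(6, 11, jitterSd = 0)
  expect_equal(nrow(g0), 66L)
  expect_equal(sort(unique(g0[, "lon"])),
               -90 + (180 / 11) * (1:11 - 0.5))
  expect_equal(sort(unique(g0[, "lat"])),
               -10 + (170 / 6) * (1:6 - 0.5))
  g1 <- makeLobulaGrid(6, 11, jitterSd = 2, seed = 5)
  expect_identical(g1, makeLobulaGrid(6, 11, jitterSd = 2, seed = 5))
  expect_false(identical(g1, makeLobulaGrid(6, 11, jitterSd = 2, seed = 6)))
  expect_error(makeLobulaGrid(2, 1), "below 3")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(connectomeConfig(scramble = 1.2), "scramble")
  expect_error(connectomeConfig(jitterSd = -1), "jitterSd")
  expect_error(connectomeConfig(nNeurons = 2), "at least 3")
  expect_error(connectomeConfig(nNeurons = 80, gridShape = c(6, 11)),
               "lattice")
  expect_error(connectomeConfig(targetSpecs = list(list(center = c(0, 0),
                                                        spread = 10,
                                                        total = 5,
                                                        transmitter = "x"))),
               "transmitter")
})

test_that("identical config and seed give identical connectomes", {
  a <- generateConnectome(smallConfig(seed = 5))
  b <- generateConnectome(smallConfig(seed = 5))
  expect_identical(a@eyeCenters, b@eyeCenters)
  expect_identical(a@presynapses@synapses, b@presynapses@synapses)
  expect_identical(a@lcLcSynapses@synapses, b@lcLcSynapses@synapses)
  expect_identical(a@targetCounts, b@targetCounts)
  expect_identical(lapply(a@neurons, slot, "nodes"),
                   lapply(b@neurons, slot, "nodes"))
  expect_false(identical(a@eyeCenters,
                         generateConnectome(smallConfig(seed = 6))@eyeCenters))
})

test_that("structural invariants hold for generated connectomes", {
  cn <- generateConnectome(connectomeConfig(seed = 89))
  ids <- names(cn@neurons)
  expect_length(ids, 65)
  syn <- cn@lcLcSynapses@synapses
  expect_true(all(syn$pre_id %in% ids))
  expect_true(all(syn$post_id %in% ids))
  expect_true(all(cn@presynapses@synapses$pre_id %in% ids))
  # per-target counts sum to the configured totals
  totals <- vapply(cn@config@targetSpecs, `[[`, numeric(1), "total")
  expect_equal(unname(rowSums(cn@targetCounts)), totals)
  # dendrite centers are denser near the visual midline
  ec <- eyeCenters(cn)
  expect_gt(sum(abs(ec[, "lon"]) < 30), sum(abs(ec[, "lon"]) > 60))
  # each skeleton is a valid rooted tree with both compartments labeled
  expect_true(all(vapply(cn@neurons, function(sk) {
    isTRUE(validObject(sk, test = TRUE)) &&
      all(c("dendrite", "axon") %in% sk@nodes$label)
  }, logical(1))))
})

test_that("the scramble dial moves the axis mapping from ordered to random", {
  r0 <- riPopulation(axisMapping(generateConnectome(
    connectomeConfig(scramble = 0, seed = 97))), significance = "none")
  expect_gt(r0@populationRI, 0.9)
  # scramble 1: RI centred on zero across seeds
  r1 <- vapply(1:60, function(s)
    popRI(axisMapping(generateConnectome(smallConfig(scramble = 1,
                                                     seed = s)))),
    numeric(1))
  expect_lt(abs(mean(r1)), 3 * sd(r1) / sqrt(length(r1)))
  # intermediate scrambles interpolate monotonically (means over seeds)
  mu <- vapply(c(0, 0.5, 1), function(sc) mean(vapply(1:25, function(s)
    popRI(axisMapping(generateConnectome(smallConfig(scramble = sc,
                                                     seed = s)))),
    numeric(1))), numeric(1))
  expect_true(all(diff(mu) < 0))
})

test_that("a zero-spread target lands all synapses on its nearest neuron", {
  cn0 <- generateConnectome(smallConfig(seed = 101))
  ec <- eyeCenters(cn0)
  onTop <- rownames(ec)[7]
  cn <- generateConnectome(smallConfig(
    seed = 101,
    targetSpecs = list(list(center = unname(ec[onTop, ]), spread = 0,
                            total = 200, transmitter = "excitatory"))))
  expect_equal(unname(cn@targetCounts[1, onTop]), 200)
  expect_true(all(cn@targetCounts[1, setdiff(colnames(cn@targetCounts),
                                             onTop)] == 0))
})

test_that("anatomical RF recovery finds every generated target center", {
  for (s in 1:5) {
    cn <- generateConnectome(smallConfig(seed = s))
    grid <- list(lon = seq(-90, 90, 2), lat = seq(-10, 160, 2))
    for (t in rownames(cn@targetCounts)) {
      rf <- anatomicalRF(eyeCenters(cn), cn@targetCounts[t, ], grid = grid)
      err <- glomotopy:::greatCircleDeg(rbind(rfArgmax(rf)),
                                        cn@truth$rfCenters[t, ,
                                                           drop = FALSE])
      expect_lt(err[1, 1], cn@truth$rfSpreads[which(rownames(
        cn@targetCounts) == t)])
    }
  }
})

test_that("synthetic traces have exact noiseless amplitudes", {
  ec <- rbind(a = c(0, 75))
  rf <- anatomicalRF(ec, c(a = 1), halfWidth = 10)
  tr <- makeTraces(rf, rbind(c(0, 75), c(80, 20)), gain = 4, noiseSd = 0,
                   framesPerEpoch = 20, baseline = 100)
  dff <- apply(tr$traces, 2, deltaFOverF, mode = "epoch")
  expect_equal(max(dff[, 1]), 4 * max(rf@values) / 100)
  # where the field is (numerically) zero the trace is flat
  expect_lt(diff(range(tr$traces[, 2])), 1e-6)
  expect_error(makeTraces(rf, rbind(c(200, 0))), "outside")
  # deterministic under a seed when noisy
  n1 <- makeTraces(rf, rbind(c(0, 75)), noiseSd = 2, seed = 7)
  n2 <- makeTraces(rf, rbind(c(0, 75)), noiseSd = 2, seed = 7)
  expect_identical(n1$traces, n2$traces)
})
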