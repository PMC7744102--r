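# Gaussian anatomical receptive fields, population sums, contours, and
# compartment fields.

test_that("a single Gaussian peaks at its center with its weight", {
  ec <- rbind(a = c(10, 80))
  rf <- anatomicalRF(ec, c(a = 7), halfWidth = 30)
  expect_equal(rfArgmax(rf), c(lon = 10, lat = 80))
  expect_equal(max(rf@values), 7, tolerance = 1e-6)
  expect_error(anatomicalRF(ec, c(a = 0)), "all-zero")
  expect_error(anatomicalRF(ec, c(a = -1)), "non-negative")
})

test_that("two equal neurons far apart give two equal local maxima", {
  ec <- rbind(a = c(-45, 75), b = c(45, 75))
  rf <- anatomicalRF(ec, c(a = 1, b = 1), halfWidth = 30)
  va <- rfValueAt(rf, c(-45, 75)); vb <- rfValueAt(rf, c(45, 75))
  expect_equal(va, vb)
  expect_gt(va, rfValueAt(rf, c(0, 75)))  # a saddle between the peaks
})

test_that("the field is linear in the weights and sums over populations", {
  ec <- rbind(a = c(-20, 60), b = c(15, 90), c = c(40, 40))
  w1 <- c(a = 2, b = 0, c = 1); w2 <- c(a = 1, b = 3, c = 0)
  f1 <- anatomicalRF(ec, w1); f2 <- anatomicalRF(ec, w2)
  fsum <- anatomicalRF(ec, w1 + w2)
  expect_equal(f1@values + f2@values, fsum@values)
  # populationRF is the same pointwise sum
  pop <- populationRF(list(f1, f2))
  expect_equal(pop@values, fsum@values)
  expect_equal(populationRF(list(f1))@values, f1@values)
  bad <- anatomicalRF(ec, w1, grid = list(lon = seq(-10, 10, 1),
                                          lat = seq(50, 70, 1)))
  expect_error(populationRF(list(f1, bad)), "grids differ")
})

test_that("a dense uniform lattice of equal Gaussians is flat inside", {
  ec <- as.matrix(expand.grid(lon = seq(-85, 85, by = 5),
                              lat = seq(-5, 155, by = 5)))
  rownames(ec) <- paste0("c", seq_len(nrow(ec)))
  rf <- anatomicalRF(ec, setNames(rep(1, nrow(ec)), rownames(ec)),
                     halfWidth = 30, grid = list(lon = seq(-20, 20, 2),
                                                 lat = seq(55, 95, 2)))
  ripple <- diff(range(rf@values)) / mean(rf@values)
  expect_lt(ripple, 0.02)
})

test_that("contours match the closed-form Gaussian level set", {
  ec <- rbind(a = c(0, 75))
  rf <- anatomicalRF(ec, c(a = 1), halfWidth = 30)
  sigma <- 30 / sqrt(2 * log(2))
  for (f in c(0.6, 0.7)) {
    ct <- rfContour(rf, f)
    expect_length(ct, 1)
    r <- sqrt((ct[[1]]$lon - 0)^2 + (ct[[1]]$lat - 75)^2)
    expect_lt(max(abs(r - sigma * sqrt(-2 * log(f)))), 1)  # one grid step
    expect_true(attr(ct[[1]], "closed"))
  }
  # monotone nesting: the 70% contour lies strictly inside the 60%
  r70 <- sqrt((rfContour(rf, 0.7)[[1]]$lon)^2 +
                (rfContour(rf, 0.7)[[1]]$lat - 75)^2)
  r60 <- sqrt((rfContour(rf, 0.6)[[1]]$lon)^2 +
                (rfContour(rf, 0.6)[[1]]$lat - 75)^2)
  expect_lt(max(r70), min(r60))
  expect_error(rfContour(rf, 0), "fraction")
  expect_error(rfContour(rf, 1), "fraction")
})

test_that("mass is conserved in proportion to the summed weights", {
  # two interior Gaussians at different centers: grid integrals must scale
  # with the weights to quadrature accuracy
  fa <- anatomicalRF(rbind(a = c(-15, 60)), c(a = 1), halfWidth = 20)
  fb <- anatomicalRF(rbind(b = c(20, 90)), c(b = 2), halfWidth = 20)
  expect_equal(sum(fb@values) / sum(fa@values), 2, tolerance = 0.01)
  fab <- anatomicalRF(rbind(a = c(-15, 60), b = c(20, 90)),
                      c(a = 1, b = 2), halfWidth = 20)
  expect_equal(sum(fab@values), sum(fa@values) + sum(fb@values))
})

test_that("compartment fields partition the whole-population field", {
  cn <- generateConnectome(smallConfig(seed = 61))
  ax <- glomerulusLongAxis(cn@presynapses)
  part <- partitionCompartments(cn@presynapses, ax, 5)
  pd <- data.frame(neuron_id = cn@presynapses@synapses$pre_id,
                   compartment = part@assignment)
  grid <- list(lon = seq(-90, 90, 5), lat = seq(-10, 160, 5))
  comps <- lapply(1:5, function(k)
    compartmentRF(pd, eyeCenters(cn), k, grid = grid))
  whole <- anatomicalRF(eyeCenters(cn),
                        table(pd$neuron_id)[rownames(eyeCenters(cn))],
                        grid = grid)
  expect_equal(Reduce(`+`, lapply(comps, function(g) g@values)),
               whole@values)
  expect_error(compartmentRF(pd, eyeCenters(cn), 99), "empty compartment")
  # one neuron's synapses alone give a single-Gaussian field
  solo <- pd[pd$neuron_id == pd$neuron_id[1], ]
  rfSolo <- compartmentRF(solo, eyeCenters(cn), solo$compartment[1],
                          grid = grid)
  peak <- rfArgmax(rfSolo)
  truth <- eyeCenters(cn)[solo$neuron_id[1], ]
  expect_lt(max(abs(peak - truth)), 5)  # one coarse grid step
})

test_that("lateral compartments of an ordered connectome view dorsal space", {
  # with scramble 0 the axis order follows latitude, so the compartment
  # nearest the glomerulus tip must peak at higher latitude than the
  # entry-side compartment
  cn <- generateConnectome(connectomeConfig(seed = 67))
  ax <- glomerulusLongAxis(cn@presynapses)
  part <- partitionCompartments(cn@presynapses, ax, 10)
  pd <- data.frame(neuron_id = cn@presynapses@synapses$pre_id,
                   compartment = part@assignment)
  grid <- list(lon = seq(-90, 90, 2), lat = seq(-10, 160, 2))
  s <- projectOntoAxis(cn@presynapses, ax)
  tipEnd <- which.max(vapply(1:10, function(k) mean(s[part@assignment == k]),
                             numeric(1)))
  entryEnd <- which.min(vapply(1:10, function(k)
    mean(s[part@assignment == k]), numeric(1)))
  latTip <- rfArgmax(compartmentRF(pd, eyeCenters(cn), tipEnd,
                                   grid = grid))["lat"]
  latEntry <- rfArgmax(compartmentRF(pd, eyeCenters(cn), entryEnd,
                                     grid = grid))["lat"]
  expect_gt(latTip, latEntry)
})
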