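# Shared fixtures and independent oracles used across the suite.

# Literal bubble sort, counting swaps: the O(n^2) oracle for the
# merge-count implementation.
bubbleSortSwaps <- function(a, b) {
  p <- match(b, a)
  swaps <- 0L
  n <- length(p)
  repeat {
    done <- TRUE
    for (i in seq_len(n - 1)) {
      if (p[i] > p[i + 1]) {
        tmp <- p[i]; p[i] <- p[i + 1]; p[i + 1] <- tmp
        swaps <- swaps + 1L
        done <- FALSE
      }
    }
    if (done) return(swaps)
  }
}

# All permutations of 1..n (n small), as a list.
allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# A generic planar point set with no duplicate inter-point distances.
genericPoints <- function(n, seed = 1) {
  withr::with_seed(seed, cbind(runif(n, 0, 10), runif(n, 0, 10)))
}

# Straight-line skeleton along x with nNodes nodes and given spacing (nm).
straightSkeleton <- function(nNodes, spacing = 400, y = 0, z = 0,
                             id = "s", label = "axon") {
  skeleton(data.frame(node_id = seq_len(nNodes),
                      parent_id = c(NA, seq_len(nNodes - 1)),
                      x = (seq_len(nNodes) - 1) * spacing,
                      y = y, z = z, radius = NA, label = label),
           neuronId = id)
}

# Symmetric Hausdorff distance between two point sets (matrices).
hausdorff <- function(a, b) {
  D <- glomotopy:::crossDist(as.matrix(a), as.matrix(b))
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# Population RI as a bare number, without the significance test.
popRI <- function(mapping) {
  riPopulation(mapping, significance = "none")@populationRI
}

# A small, fast generator configuration for seed-sweep tests (the full-size
# defaults are exercised in the acceptance suite).
smallConfig <- function(...) {
  connectomeConfig(nNeurons = 20, gridShape = c(5, 4), presynPerNeuron = 20,
                   lcLcTotal = 400, nodeSpacing = 2000, ...)
}
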