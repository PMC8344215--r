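root <- ld$mrca_polyplax$v1
tr3 <- ape::read.tree(text = "((a,b),c);")

test_that("a zero-rate branch is the null process", {
  cfg <- evolutionConfig(event_rate = 0, swap_prob = 0, seed = 1)
  set.seed(1)
  res <- simulateBranch(root, cfg)
  expect_identical(miniStrings(res$karyotype), miniStrings(root))
  expect_equal(nrow(res$log), 0L)
})

test_that("full NCR bias sends every destination to a boundary slot", {
  cfg <- evolutionConfig(event_rate = 100, ncr_bias = 1, cluster_prob = 0.2,
                         inversion_prob = 0.1, swap_prob = 0, seed = 5)
  set.seed(5)
  res <- simulateBranch(root, cfg)
  expect_gt(nrow(res$log), 50L)
  expect_true(all(res$log$class == "adjacent"))
  expect_true(isComplete(res$karyotype))
})

test_that("gene content is conserved and tips are complete over a tree", {
  cfg <- evolutionConfig(event_rate = 2, ncr_bias = 0.5, cluster_prob = 0.1,
                         inversion_prob = 0.1, swap_prob = 0.2, seed = 9)
  sim <- simulateTree(ld$tree, root, cfg)
  expect_length(sim$tips, 16L)
  expect_true(all(vapply(sim$tips, isComplete, logical(1))))
  ## minichromosome capacity is respected
  for (k in sim$tips)
    expect_true(all(lengths(minichromosomes(k)) <= 8L))
})

test_that("identical config and seed give identical datasets; subtrees are stable", {
  cfg <- evolutionConfig(event_rate = 1, seed = 42)
  s1 <- simulateTree(tr3, root, cfg)
  s2 <- simulateTree(tr3, root, cfg)
  expect_identical(s1$log, s2$log)
  expect_identical(lapply(s1$tips, miniStrings), lapply(s2$tips, miniStrings))
  ## extending the tree elsewhere does not perturb an untouched subtree
  tr4 <- ape::read.tree(text = "((a,b),(c,d));")
  s3 <- simulateTree(tr4, root, cfg)
  expect_identical(miniStrings(s1$tips$a), miniStrings(s3$tips$a))
  expect_identical(miniStrings(s1$tips$b), miniStrings(s3$tips$b))
})

test_that("replaying the event log reproduces every tip exactly", {
  cfg <- evolutionConfig(event_rate = 2, ncr_bias = 0.5, cluster_prob = 0.15,
                         inversion_prob = 0.2, swap_prob = 0.3, seed = 77)
  sim <- simulateTree(ld$tree, root, cfg)
  expect_gt(nrow(sim$log), 0L)
  for (tp in names(sim$tips)) {
    lg <- tipLog(sim, tp)
    rk <- if (is.null(lg)) root else replayLog(root, lg)
    expect_identical(miniStrings(rk), miniStrings(sim$tips[[tp]]),
                     info = tp)
  }
})

test_that("realized event counts follow the configured Poisson rate", {
  ns <- integer(200)
  for (r in 1:200) {
    cfg <- evolutionConfig(event_rate = 0.5, swap_prob = 0, seed = 1000 + r)
    sim <- simulateTree(tr3, root, cfg)
    ns[r] <- nrow(sim$log)
  }
  ## 4 branches/replicate; mean per-branch count within 3 SE of the rate
  mean_per_branch <- mean(ns) / 4
  se <- sqrt(0.5 / (200 * 4))
  expect_lt(abs(mean_per_branch - 0.5), 3 * se)
})

test_that("at low rate the detector recovers the logged events exactly", {
  hits <- 0L
  for (s in 1:40) {
    cfg <- evolutionConfig(event_rate = 0.7, ncr_bias = 0.5,
                           cluster_prob = 0, inversion_prob = 0.3,
                           swap_prob = 0, seed = s)
    set.seed(s)
    res <- simulateBranch(root, cfg)
    lg <- res$log
    if (nrow(lg) == 0L || anyDuplicated(lg$unit) ||
        anyDuplicated(lg$dest_mini) || any(lg$dest_mini %in% lg$source_mini))
      next
    hits <- hits + 1L
    ev <- detectEvents(root, res$karyotype, clusterMode = FALSE)
    ev <- ev[!ev$identity_swap, , drop = FALSE]
    expect_setequal(ev$unit, lg$unit)
    for (i in seq_len(nrow(lg))) {
      row <- ev[ev$unit == lg$unit[i], ]
      expect_identical(row$class, lg$class[i])
      expect_identical(row$inverted, lg$inverted[i])
    }
  }
  expect_gte(hits, 5L)  # the property was actually exercised
})

test_that("unbiased destinations track the slot census at 10,000 events", {
  cfg <- evolutionConfig(event_rate = 1, ncr_bias = 0, cluster_prob = 0,
                         inversion_prob = 0, swap_prob = 0, seed = 1)
  set.seed(1)
  mins <- minichromosomes(root)
  n <- 10000L
  adj <- logical(n)
  for (i in seq_len(n)) {
    ev <- MitoKaryo:::.drawEvent(mins, cfg, "b")  # fresh karyotype each draw
    adj[i] <- ev$log$class == "adjacent"
  }
  p0 <- 22 / 48
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(adj) - p0), 3 * se)
})

test_that("degenerate single-minichromosome karyotypes are refused", {
  k1 <- Karyotype("one", list(c("cox1", "A", "C")))
  cfg <- evolutionConfig(event_rate = 5, swap_prob = 0, seed = 2)
  set.seed(2)
  expect_error(simulateBranch(k1, cfg), "no eligible destination")
})

test_that("calibration under full bias observes 100% adjacency", {
  cfg <- evolutionConfig(event_rate = 1, ncr_bias = 1, cluster_prob = 0,
                         inversion_prob = 0, swap_prob = 0, seed = 30)
  cal <- calibrationExperiment(tr3, root, cfg, 40)
  expect_equal(cal$mean_destination_adjacent, 1)
  ## detected adjacency can be lower: a later arrival at a boundary pushes
  ## an earlier one inward
  expect_lte(cal$mean_observed_adjacent, 1)
  expect_error(calibrationExperiment(tr3, root, cfg, 0), "replicates")
})
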