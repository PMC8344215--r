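test_that("event detection against the Polyplax ancestor recovers the published events", {
  anc <- ld$mrca_polyplax$v1
  rec <- ld$karyotypes[["Polyplax_reclinata"]]
  spi <- ld$karyotypes[["Polyplax_spinulosa"]]
  ev <- detectEvents(anc, rec)
  expect_setequal(ev$unit, c("A", "T"))
  expect_true(all(ev$class == "adjacent"))
  expect_true(ev$inverted[ev$unit == "T"])
  expect_false(ev$inverted[ev$unit == "A"])
  expect_false(any(ev$identity_swap))
  ## spinulosa adds the L1/L2 identity swap on top of the same A/T events
  ev2 <- detectEvents(anc, spi)
  expect_setequal(ev2$unit, c("A", "T", "L1", "L2"))
  expect_setequal(ev2$unit[ev2$identity_swap], c("L1", "L2"))
  ## identity: no events against itself
  expect_equal(nrow(detectEvents(anc, anc)), 0L)
  ## different backbone sets are refused
  kt <- Karyotype("other", list(c("cox1", "cox2"), "~nad1"))
  expect_error(detectEvents(anc, kt), "backbone change")
})

test_that("the ancestor-level comparison finds the five translocated tRNA genes", {
  ev <- detectEvents(ld$mrca_sucking_lice, ld$mrca_polyplax$v1)
  expect_setequal(ev$unit, c("N", "S1-S2", "I", "Q"))
  expect_true(all(ev$class == "adjacent"))
  expect_equal(length(unique(unlist(strsplit(ev$unit, "-")))), 5L)
})

test_that("pair-table events classify destinations from the arrangement string", {
  ev <- detectEventsFromPairs(ld$pairs)
  expect_equal(nrow(ev), nrow(ld$pairs))
  ## trnD first in the derived arrangement of Pedicinus obtusus: adjacent
  d1 <- ev[ev$unit == "D" & ev$species == "Pedicinus obtusus", ]
  expect_identical(d1$class, "adjacent")
  ## trnM is internal in the same arrangement: intergenic
  m1 <- ev[ev$unit == "M" & ev$species == "Pedicinus obtusus", ]
  expect_identical(m1$class, "intergenic")
  bad <- data.frame(gene = "K", mrca_arrangement = "K-nad4",
                    derived_arrangement = "cox1-L2", species = "x",
                    genus = "X")
  expect_error(detectEventsFromPairs(bad), "malformed row")
})

test_that("congeneric grouping merges within genus only and is order-invariant", {
  ev <- detectEventsFromPairs(ld$pairs)
  gr <- groupEvents(ev)
  ## trnT to T-D-H shared by three Pediculus species: one event
  tdh <- gr[gr$unit == "T" & gr$destination == "T-D-H", ]
  expect_equal(nrow(tdh), 1L)
  expect_equal(tdh$n_species, 3L)
  ## trnI to P-nad2-I in three Pediculus plus Pthirus pubis: two genera,
  ## two events
  pni <- gr[gr$unit == "I" & gr$destination == "P-nad2-I", ]
  expect_equal(nrow(pni), 2L)
  expect_setequal(pni$genus, c("Pediculus", "Pthirus"))
  ## single-species events form groups of one
  expect_equal(gr$n_species[gr$unit == "N" & gr$genus == "Microthoracius"], 1L)
  ## grand totals
  expect_equal(nrow(gr), 54L)
  expect_equal(sum(gr$class == "adjacent"), 32L)
  ## invariance to input order
  set.seed(3)
  gr2 <- groupEvents(ev[sample(nrow(ev)), ])
  expect_identical(gr, gr2)
})

test_that("the T4 site census reproduces the within-Polyplax expected probabilities", {
  anc <- ld$mrca_polyplax$v1
  a <- censusSites(anc, "A")
  expect_equal(c(a$adjacent_slots, a$intergenic_slots, a$total_slots),
               c(21L, 27L, 48L))
  expect_equal(100 * a$expected_adjacent_prob, 43.75)
  p <- censusSites(anc, "P")
  expect_equal(c(p$adjacent_slots, p$total_slots), c(22L, 48L))
  s <- censusSites(anc, c("S1", "S2"))
  expect_equal(c(s$adjacent_slots, s$intergenic_slots, s$total_slots),
               c(21L, 26L, 47L))
  expect_equal(round(100 * s$expected_adjacent_prob, 2), 44.68)
  ## toy karyotype: two-gene minichromosome, NCR-resident single unit
  toy <- Karyotype("toy", list(c("cox1", "A")))
  ty <- censusSites(toy, "A")
  expect_equal(c(ty$adjacent_slots, ty$intergenic_slots, ty$total_slots),
               c(1L, 2L, 3L))
  expect_error(censusSites(anc, c("A", "F")), "not found at consecutive")
})

test_that("the ancestor-level census uses the overridden base counts", {
  mrca <- ld$mrca_sucking_lice
  for (u in list("N", "I", "Q")) {
    cs <- censusSites(mrca, u, base_override = c(22L, 24L))
    expect_equal(c(cs$adjacent_slots, cs$total_slots), c(21L, 46L))
    expect_equal(round(100 * cs$expected_adjacent_prob, 2), 45.65)
  }
  s <- censusSites(mrca, c("S1", "S2"), base_override = c(22L, 24L))
  expect_equal(c(s$adjacent_slots, s$intergenic_slots, s$total_slots),
               c(21L, 24L, 45L))
  expect_equal(round(100 * s$expected_adjacent_prob, 2), 46.67)
})

test_that("the per-gene T8 census removes the unit's own slot", {
  mrca <- ld$mrca_sucking_lice
  ## NCR-resident gene: numerator and denominator both drop
  n <- censusSites(mrca, "N", mode = "T8", base_override = c(22L, 24L))
  expect_equal(c(n$adjacent_slots, n$total_slots), c(21L, 45L))
  expect_equal(round(100 * n$expected_adjacent_prob, 2), 46.67)
  expect_equal(round(100 * n$expected_intergenic_prob, 2), 53.33)
  ## intergenic-resident gene: own slot leaves the intergenic numerator
  ## only; the two class probabilities deliberately do not sum to 1
  s1 <- censusSites(mrca, "S1", mode = "T8", base_override = c(22L, 24L))
  expect_equal(c(s1$adjacent_slots, s1$intergenic_slots, s1$total_slots),
               c(22L, 23L, 46L))
  expect_equal(round(100 * s1$expected_adjacent_prob, 2), 47.83)
  expect_lt(s1$expected_adjacent_prob + s1$expected_intergenic_prob, 1)
  expect_error(censusSites(mrca, c("S1", "S2"), mode = "T8",
                           base_override = c(22L, 24L)),
               "single-gene")
})

test_that("T4 class counts always sum to the total over all units and fixtures", {
  for (k in c(ld$karyotypes, ld$mrca_polyplax,
              list(ld$mrca_sucking_lice))) {
    for (g in mtGeneSet("tRNA")) {
      st <- tryCatch(censusSites(k, g), error = function(e) NULL)
      if (is.null(st)) next
      expect_equal(st$adjacent_slots + st$intergenic_slots, st$total_slots)
    }
  }
})

test_that("adjacency tables carry observed percentages per moving unit", {
  rep <- runReproduce()
  t4 <- rep$polyplax_adjacency
  expect_setequal(t4$unit, c("A", "F", "P", "T", "S1-S2"))
  expect_true(all(t4$observed_adjacent == 100))
  expect_true(all(t4$observed_intergenic == 0))
  expect_equal(t4$n_events[t4$unit == "A"], 2L)
  expect_equal(t4$n_events[t4$unit == "S1-S2"], 3L)
  t8 <- rep$nonpolyplax_adjacency
  expect_equal(nrow(t8), 19L)
  expect_equal(t8$observed_adjacent[t8$unit == "M"], 80)
  expect_equal(t8$n_events[t8$unit == "M"], 5L)
})

test_that("the pooled t test matches an independent implementation and is antisymmetric", {
  ## published inputs
  x <- c(43.75, 43.75, 45.83, 45.83, 44.68)
  tt <- pooledTTest(x, rep(100, 5))
  expect_equal(tt$t, -118.61978, tolerance = 1e-7)
  expect_equal(tt$df, 8L)
  expect_lt(tt$p, 1e-5)
  ## independent oracle: stats::t.test with pooled variance
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(5, 50, 10); b <- rnorm(7, 60, 5)
    mine <- pooledTTest(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    ## antisymmetry
    swap <- pooledTTest(b, a)
    expect_equal(swap$t, -mine$t, tolerance = 1e-12)
    expect_equal(swap$p, mine$p, tolerance = 1e-12)
  }
  ## degenerate cases
  z <- pooledTTest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(pooledTTest(1, c(1, 2)), "n >= 2")
})
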