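test_that("character extraction separates backbone and tRNA placement families", {
  ch <- extractCharacters(ld$karyotypes)
  bb <- ch[ch$type == "backbone" & ch$character_id == "atp8-atp6", ]
  expect_equal(nrow(bb), 3L)
  expect_true(all(bb$state == "present"))
  ## cox1-L2: same placement in reclinata and asiatica, different in
  ## spinulosa (which carries L1 there)
  l2 <- ch[ch$type == "trna" & ch$character_id == "L2", ]
  st <- setNames(l2$state, l2$taxon)
  expect_identical(st[["Polyplax_reclinata"]], st[["Polyplax_asiatica"]])
  expect_false(identical(st[["Polyplax_reclinata"]],
                         st[["Polyplax_spinulosa"]]))
  ## S1-S2 is detected as a cluster unit
  expect_true("S1-S2" %in% ch$character_id)
  ## a taxon missing a gene gets NA for its placement character
  inc <- Karyotype("incomplete", list(c("cox1", "A"), "~nad1"))
  ch2 <- extractCharacters(list(a = ld$karyotypes[[1]], b = inc))
  expect_true(is.na(ch2$state[ch2$character_id == "F" & ch2$taxon == "b"]))
})

test_that("candidate rules: shared-with-outgroup, shared-by-all, and the fallback", {
  ing <- c(x = "s1", y = "s1", z = "s2")
  ## rule 1: state present in one ingroup taxon and one outgroup taxon
  c1 <- candidateStates(ing, outgroupStates = "s2")
  expect_true("s2" %in% c1$candidates)
  expect_false(c1$fallback)
  ## rule 2: a state carried by every ingroup taxon qualifies without
  ## outgroup support
  c2 <- candidateStates(c(x = "s1", y = "s1", z = "s1"), character())
  expect_identical(c2$candidates, "s1")
  expect_identical(unique(c2$rule), "rule2")
  ## NA taxa do not vote in rule 2
  c3 <- candidateStates(c(x = "s1", y = "s1", z = NA), character())
  expect_identical(c3$candidates, "s1")
  ## fallback: neither rule fires, all observed ingroup states compete
  c4 <- candidateStates(ing, outgroupStates = "s9")
  expect_true(c4$fallback)
  expect_setequal(c4$candidates, c("s1", "s2"))
  expect_error(candidateStates(c(x = NA, y = NA)), "uninformative")
})

test_that("fixed-root parsimony equals brute-force enumeration on trees up to 6 leaves", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    tr <- randomTopology(n)
    alpha <- letters[1:sample(2:3, 1)]
    st <- setNames(sample(alpha, n, replace = TRUE), tr$tip.label)
    if (rep %% 5 == 0) st[sample(n, 1)] <- NA  # missing data path
    cand <- sample(alpha, 1)
    expect_equal(parsimonyChanges(tr, st, cand),
                 bruteForceChanges(tr, st, cand),
                 info = sprintf("rep %d", rep))
  }
  ## exhaustive 4-leaf check over all tip-state combinations
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  for (combo in 0:15) {
    st <- setNames(ifelse(bitwAnd(combo, 2^(0:3)) > 0, "a", "b"),
                   tr$tip.label)
    for (cand in c("a", "b"))
      expect_equal(parsimonyChanges(tr, st, cand),
                   bruteForceChanges(tr, st, cand))
  }
  ## all tips identical to the candidate: zero changes
  st <- setNames(rep("a", 4), tr$tip.label)
  expect_equal(parsimonyChanges(tr, st, "a"), 0L)
})

test_that("both S1-S2 placements are equally parsimonious on the Polyplax subtree", {
  sub <- ape::read.tree(
    text = "((Polyplax_reclinata,Polyplax_spinulosa),Polyplax_asiatica);")
  ch <- extractCharacters(ld$karyotypes)
  s12 <- ch[ch$character_id == "S1-S2", ]
  st <- setNames(s12$state, s12$taxon)
  states <- unique(st)
  expect_length(states, 2L)
  expect_equal(parsimonyChanges(sub, st, states[1]),
               parsimonyChanges(sub, st, states[2]))
})

test_that("the inferred Polyplax ancestor matches the published reconstruction", {
  res <- inferAncestor(ld$tree, ld$karyotypes, ld$ingroup,
                       pairs = ld$pairs,
                       pairAncestor = ld$mrca_sucking_lice,
                       ancestorLabel = "MRCA Polyplax")
  vs <- variants(res)
  expect_length(vs, 2L)
  for (v in vs) {
    expect_true(validObject(v))
    expect_length(minichromosomes(v), 11L)
    expect_true(isComplete(v))  # every placed gene exactly once
  }
  ## the single ambiguity is the S1-S2 cluster
  expect_identical(unique(alternatives(res)$unit), "S1-S2")
  ## variants equal the published ancestral arrangements
  got <- lapply(vs, miniStrings)
  want <- list(miniStrings(ld$mrca_polyplax$v1),
               miniStrings(ld$mrca_polyplax$v2))
  expect_true(setequal(
    vapply(got, paste, character(1), collapse = ";"),
    vapply(want, paste, character(1), collapse = ";")))
})

test_that("inference is invariant to taxon input order and to outgroup clade resolution", {
  base <- inferAncestor(ld$tree, ld$karyotypes, ld$ingroup,
                        pairs = ld$pairs,
                        pairAncestor = ld$mrca_sucking_lice)
  ## reversed input order
  r2 <- inferAncestor(ld$tree, rev(ld$karyotypes), rev(ld$ingroup),
                      pairs = ld$pairs,
                      pairAncestor = ld$mrca_sucking_lice)
  expect_identical(lapply(variants(base), miniStrings),
                   lapply(variants(r2), miniStrings))
  ## permuted resolution of the Pediculus/Pthirus/Pedicinus/Haematopinus clade
  alt <- ape::read.tree(text = paste0(
    "(Haematomyzus_elephantis,(Microthoracius_praelongiceps,((((Polyplax_",
    "reclinata,Polyplax_spinulosa),Polyplax_asiatica),(Hoplopleura_akanezumi,",
    "Hoplopleura_kitti)),((((Pediculus_schaeffi,(Pediculus_capitis,",
    "Pediculus_humanus)),(Pedicinus_obtusus,Pedicinus_badii)),Pthirus_pubis),",
    "(Haematopinus_asini,(Haematopinus_apri,Haematopinus_suis))))));"))
  r3 <- inferAncestor(alt, ld$karyotypes, ld$ingroup,
                      pairs = ld$pairs,
                      pairAncestor = ld$mrca_sucking_lice)
  expect_identical(lapply(variants(base), miniStrings),
                   lapply(variants(r3), miniStrings))
})

test_that("identical tips reconstruct themselves with zero changes and no ties", {
  tr <- ape::read.tree(text = "((a,b),c);")
  k <- ld$karyotypes[["Polyplax_reclinata"]]
  ks <- list(a = k, b = k, c = k)
  res <- inferAncestor(tr, ks, c("a", "b", "c"))
  expect_length(variants(res), 1L)
  expect_identical(miniStrings(variants(res)[[1]]), miniStrings(k))
  expect_true(all(changeCounts(res)$changes == 0L))
  expect_equal(nrow(alternatives(res)), 0L)
})

test_that("removing P. asiatica makes the shared reclinata/spinulosa state ancestral", {
  tr <- ape::read.tree(text = "(Polyplax_reclinata,Polyplax_spinulosa);")
  ks <- ld$karyotypes[c("Polyplax_reclinata", "Polyplax_spinulosa")]
  res <- inferAncestor(tr, ks, names(ks),
                       pairs = ld$pairs,
                       pairAncestor = ld$mrca_sucking_lice)
  expect_length(variants(res), 1L)
  v <- miniStrings(variants(res)[[1]])
  ## rule 2 now places trnT and trnA inside the cox2 minichromosome
  expect_true("~T-D-Y-cox2-nad6-A" %in% v)
  ## the L1/L2 identity conflict resolves to the outgroup-supported layout
  expect_true("cox1-L2" %in% v)
  expect_true("M-L1-rrnL-V" %in% v)
})
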