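test_that("is_raf checks both conditions, brute-forced on the toys", {
  expect_false(is_raf(toy1(), character()))  # a RAF is non-empty
  expect_true(is_raf(toy2(), "r1"))          # catalyst a is food
  # toy1: all three non-empty subsets, checked against the oracle
  t1 <- toy1()
  expect_false(is_raf(t1, "r1"))  # catalyst c not in F u {ab}
  expect_false(is_raf(t1, "r2"))  # catalyst ab not in F u {c}
  expect_true(is_raf(t1, c("r1", "r2")))  # mutual catalysis
  for (sub in list("r1", "r2", c("r1", "r2"))) {
    expect_identical(is_raf(t1, sub), oracle_is_raf(t1, sub))
  }
  expect_error(is_raf(t1, "r9"), "unknown reaction")
})

test_that("max_raf agrees with exhaustive search on the toys", {
  expect_equal(max_raf(toy1())$reaction_ids, c("r1", "r2"))
  expect_equal(max_raf(toy2())$reaction_ids, "r1")
  expect_equal(max_raf(toy3())$reaction_ids, c("r1", "r2"))
  # a CRS whose only reaction is uncatalysed has no RAF
  bare <- parse_crs("food: a\nelements: a, b\nr1: a -> b")
  mr <- max_raf(bare)
  expect_true(mr$is_empty)
  expect_length(mr$reaction_ids, 0)
  # p = 0 polymer systems have no RAF either
  g0 <- generate_polymer_crs(polymer_config(4, catalysis_prob = 0, seed = 3))
  expect_true(max_raf(g0)$is_empty)
})

test_that("max_raf postconditions hold on random instances", {
  for (s in 1:30) {
    net <- random_crs(7 + s %% 4, 5 + s %% 5, p = 0.25, seed = 100 + s)
    mr <- max_raf(net)
    if (!mr$is_empty) {
      expect_true(is_raf(net, mr$reaction_ids))
      # every reaction of the maxRAF is catalysed by F u its products
      avail <- union(net$food,
                     unique(unlist(lapply(net$reactions[mr$reaction_ids],
                                          `[[`, "products"))))
      for (id in mr$reaction_ids) {
        expect_true(any(net$reactions[[id]]$catalysts %in% avail))
      }
      # maximality: no single outside reaction can be added
      for (extra in setdiff(names(net$reactions), mr$reaction_ids)) {
        expect_false(is_raf(net, c(mr$reaction_ids, extra)))
      }
    }
  }
})

test_that("the two prune orders reach the same fixed point", {
  for (s in 1:20) {
    net <- random_crs(8, 7, p = 0.3, seed = 200 + s)
    expect_identical(max_raf(net, prune_order = "closure_first")$reaction_ids,
                     max_raf(net, prune_order = "catalysis_first")$reaction_ids)
  }
})

test_that("closed RAFs: the maxRAF is closed, sub-RAFs may be transient", {
  t1 <- toy1()
  expect_true(is_closed_raf(t1, max_raf(t1)$reaction_ids))
  t3 <- toy3()
  expect_false(is_closed_raf(t3, "r1"))  # r2's inputs are all available
  expect_true(is_closed_raf(t3, c("r1", "r2")))
  expect_error(is_closed_raf(t3, "r2"), "not a RAF")
})

test_that("closure of a subRAF is a closed superset and idempotent", {
  t3 <- toy3()
  expect_equal(closure_of_subraf(t3, "r1"), c("r1", "r2"))
  expect_equal(closure_of_subraf(t3, c("r1", "r2")), c("r1", "r2"))
  for (s in 1:15) {
    net <- random_crs(8, 6, p = 0.35, seed = 300 + s)
    for (raf in oracle_all_rafs(net)) {
      cl <- closure_of_subraf(net, raf)
      expect_true(all(raf %in% cl))
      expect_true(is_closed_raf(net, cl))
      expect_identical(closure_of_subraf(net, cl), cl)
    }
  }
})

test_that("co-RAF detection matches the definition", {
  t3 <- toy3()
  expect_true(is_co_raf(t3, raf = "r1", candidate = "r2"))
  expect_false(is_co_raf(t3, raf = "r1", candidate = character()))
  expect_error(is_co_raf(t3, raf = "r1", candidate = "r1"), "disjoint")
  # a candidate that is itself a RAF is not a co-RAF
  td <- toy_disjoint()
  expect_false(is_co_raf(td, raf = "r1", candidate = "r2"))
})

test_that("irrRAFs are found exhaustively and by sampled contraction", {
  irr1 <- find_irr_rafs(toy1(), mode = "exhaustive")
  expect_equal(irr1, list(c("r1", "r2")), ignore_attr = TRUE)
  expect_true(attr(irr1, "unique"))
  irr3 <- find_irr_rafs(toy3(), mode = "exhaustive")
  expect_equal(irr3, list("r1"), ignore_attr = TRUE)
  irr_d <- find_irr_rafs(toy_disjoint(), mode = "exhaustive")
  expect_equal(irr_d, list("r1", "r2"), ignore_attr = TRUE)
  expect_false(attr(irr_d, "unique"))
  # sampled irrRAFs are a subset of the exhaustive ones on small fixtures
  for (net in list(toy1(), toy3(), toy_disjoint())) {
    ex <- find_irr_rafs(net, mode = "exhaustive")
    sm <- find_irr_rafs(net, mode = "sample", seed = 5, restarts = 20)
    for (s in sm) {
      expect_true(any(vapply(ex, identical, logical(1), s)))
    }
  }
  big <- generate_polymer_crs(polymer_config(5, catalysis_prob = 0.05,
                                             seed = 11))
  expect_error(find_irr_rafs(big, mode = "exhaustive"), "refused")
})

test_that("union decomposability distinguishes composite from irreducible", {
  expect_false(is_union_decomposable(toy1(), c("r1", "r2")))
  td <- toy_disjoint()
  expect_true(is_union_decomposable(td, c("r1", "r2")))
  # any irrRAF is undecomposable by definition
  for (net in list(toy1(), toy3(), td)) {
    for (irr in find_irr_rafs(net, mode = "exhaustive")) {
      expect_false(is_union_decomposable(net, irr))
    }
  }
})

test_that("the union of any two RAFs of a CRS is a RAF", {
  nets <- c(list(toy1(), toy2(), toy3(), toy_disjoint()),
            lapply(1:10, function(s) random_crs(8, 6, p = 0.35,
                                                seed = 400 + s)))
  for (net in nets) {
    rafs <- oracle_all_rafs(net)
    if (length(rafs) < 2) next
    for (i in seq_along(rafs)) {
      for (j in seq_along(rafs)) {
        expect_true(is_raf(net, union(rafs[[i]], rafs[[j]])))
      }
    }
  }
})

test_that("RAF poset has a unique maximal element equal to max_raf", {
  for (s in 1:12) {
    net <- random_crs(8, 6, p = 0.35, seed = 500 + s)
    rafs <- oracle_all_rafs(net)
    mr <- max_raf(net)
    if (length(rafs) == 0) {
      expect_true(mr$is_empty)
    } else {
      # every RAF is contained in the maxRAF
      for (raf in rafs) expect_true(all(raf %in% mr$reaction_ids))
      expect_identical(mr$reaction_ids, sort(oracle_max_raf(net)))
    }
  }
})

test_that("enlarging the foodset never shrinks the maxRAF", {
  for (s in 1:15) {
    net <- random_crs(9, 7, p = 0.3, seed = 600 + s)
    before <- max_raf(net)$reaction_ids
    extras <- setdiff(net$elements, net$food)
    if (length(extras) == 0) next
    grown <- crs(net$elements, net$reactions,
                 c(net$food, extras[seq_len(min(2, length(extras)))]))
    after <- max_raf(grown)$reaction_ids
    expect_true(all(before %in% after))
  }
})
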