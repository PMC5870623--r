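test_that("positive elimination drops hopeless candidates", {
  meta <- mk_meta(c("F1", "F2"))
  # lone domain with H - T^d = -1 and no context partners
  model0 <- mk_model(c("F1", "F2"))
  expect_equal(nrow(positive_elimination(cand("F1", 1, 50, -1), meta, model0)), 0)

  # H - T^d = -1 rescued by a +2 partner
  model2 <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 2))
  sub <- rbind(cand("F1", 1, 50, -1), cand("F2", 100, 150, 3))
  expect_equal(nrow(positive_elimination(sub, meta, model2)), 2)

  # conflicting pair: the +5 between them is zeroed, both eliminated
  model5 <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 5))
  conf <- rbind(cand("F1", 1, 100, -1), cand("F2", 1, 100, -1))
  expect_equal(nrow(positive_elimination(conf, meta, model5)), 0)
})

test_that("positive elimination iterates to a fixpoint", {
  # F2 is only held above water by context from F1; F1 itself is hopeless
  # (-3 + 2 < 0), so once F1 goes, F2 must go in a later iteration
  meta <- mk_meta(c("F1", "F2", "F3"))
  model <- forge_model(c("F1", "F2", "F3"), scores = list("F1>F2" = 2))
  sub <- rbind(cand("F1", 1, 50, -3), cand("F2", 100, 150, -1),
               cand("F3", 200, 250, -1))
  surv <- positive_elimination(sub, meta, model)
  expect_equal(nrow(surv), 0)
  expect_equal(attr(surv, "pe_iterations"), c(3L, 1L, 0L))
})

test_that("positive elimination removes families that cannot pay their surcharge", {
  meta <- mk_meta("F1", t_dom = 10, t_seq = 15)   # t_tilde = 5
  model <- mk_model("F1")
  sub <- rbind(cand("F1", 1, 50, 12), cand("F1", 100, 150, 11))  # S+ sum = 3 < 5
  expect_equal(nrow(positive_elimination(sub, meta, model)), 0)
})

test_that("PE per-iteration candidate counts are recorded and non-increasing", {
  for (s in 1:20) {
    inst <- generate_instance(k = 10, seed = 800 + s)
    surv <- positive_elimination(inst$candidates, inst$meta, inst$model)
    sizes <- attr(surv, "pe_iterations")
    expect_true(all(diff(sizes) <= 0))
    expect_lte(length(sizes), nrow(inst$candidates) + 2)
  }
})

test_that("trivial-solution test fires only when survivors are provably optimal", {
  meta <- mk_meta(c("F1", "F2"))
  pos <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 1))
  good <- rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2))
  expect_true(is_trivial(good, meta, pos))
  # single survivor
  expect_true(is_trivial(cand("F1", 1, 50, 3), meta, pos))
  # a conflicting pair blocks the shortcut
  expect_false(is_trivial(rbind(cand("F1", 1, 100, 3), cand("F2", 1, 100, 2)),
                          meta, pos))
  # negative context blocks it
  neg <- forge_model(c("F1", "F2"), scores = list("F1>F2" = -0.5))
  expect_false(is_trivial(good, meta, neg))
  # the guard beyond the classic condition: two sub-threshold domains held up
  # only by shared positive context are NOT trivially optimal (empty set wins)
  model2 <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 2))
  shaky <- rbind(cand("F1", 1, 50, -1.5), cand("F2", 100, 150, -1.5))
  expect_equal(nrow(positive_elimination(shaky, meta, model2)), 2)  # PE keeps both
  expect_false(is_trivial(shaky, meta, model2))
  expect_equal(brute_force(shaky, meta, model2)$objective, 0)
})

test_that("ILP structure matches the formulation", {
  meta <- mk_meta(c("F1", "F2"))
  model <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 1),
                       penalty = -0.5)
  two <- rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2))
  inst <- build_ilp(two, meta, model)
  expect_equal(length(inst$variables), 3)                 # x1, x2, y1_2
  expect_equal(vapply(inst$constraints, `[[`, "", "type"),
               c("and_le_i", "and_le_j", "and_ge"))
  expect_equal(unname(inst$objective), c(3, 2, 1))

  confl <- rbind(cand("F1", 1, 100, 3), cand("F2", 1, 100, 2))
  inst2 <- build_ilp(confl, meta, model)
  types2 <- vapply(inst2$constraints, `[[`, "", "type")
  expect_true("clique" %in% types2)
  cl <- inst2$constraints[[which(types2 == "clique")]]
  expect_equal(cl$vars, c("x1", "x2"))
  expect_equal(cl$rhs, 1)

  meta_tt <- mk_meta("F1", t_dom = 10, t_seq = 15)        # t_tilde = 5
  fam2 <- rbind(cand("F1", 1, 50, 13), cand("F1", 100, 150, 14))
  inst3 <- build_ilp(fam2, meta_tt, forge_model("F1"))
  types3 <- vapply(inst3$constraints, `[[`, "", "type")
  expect_equal(sum(types3 == "or_ge"), 2)                 # f >= x_i twice
  expect_equal(sum(types3 == "or_le"), 1)                 # f <= x1 + x2
  expect_true("f_F1" %in% inst3$variables)
  expect_equal(unname(inst3$objective["f_F1"]), -5)
})

test_that("pair variables are omitted for zero context scores", {
  meta <- mk_meta(c("F1", "F2"))
  inst <- build_ilp(rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2)),
                    meta, mk_model(c("F1", "F2")))   # empty net: all S = 0
  expect_equal(inst$variables, c("x1", "x2"))
  expect_equal(length(inst$constraints), 0)
})

test_that("solve_ilp picks the right subsets on hand-checked instances", {
  meta <- mk_meta(c("F1", "F2"))
  mk2 <- function(s) forge_model(c("F1", "F2"), scores = list("F1>F2" = s))
  two <- rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2))
  sol_neg <- solve_ilp(build_ilp(two, meta, mk2(-6)))
  expect_equal(sol_neg$objective, 3)          # keep only the 3-bit domain
  expect_equal(sol_neg$selected, 1L)
  sol_pos <- solve_ilp(build_ilp(two, meta, mk2(1)))
  expect_equal(sol_pos$objective, 6)          # keep both
  expect_equal(sol_pos$selected, c(1L, 2L))
  # everything negative, no positive context: the ILP's optimum is empty
  bad <- rbind(cand("F1", 1, 50, -3), cand("F2", 100, 150, -2))
  sol_bad <- solve_ilp(build_ilp(bad, meta, mk2(-1)))
  expect_equal(sol_bad$objective, 0)
  expect_equal(length(sol_bad$selected), 0)
})

test_that("brute force enumerates feasible subsets with documented tie-breaks", {
  meta <- mk_meta(c("F1", "F2", "F3"))
  model <- mk_model(c("F1", "F2", "F3"))
  expect_equal(brute_force(cand("F1", 1, 10, 5)[0, ], meta, model)$objective, 0)
  # triangle of mutual conflicts, scores 3 > 2 > 1
  tri <- rbind(cand("F1", 1, 100, 3), cand("F2", 1, 100, 2),
               cand("F3", 1, 100, 1))
  sol <- brute_force(tri, meta, model)
  expect_equal(sol$objective, 3)
  expect_equal(sol$candidates$family_id, "F1")
  expect_error(brute_force(do.call(rbind, replicate(21, cand("F1", 1, 10, 1),
                                                    simplify = FALSE)),
                           meta, model, limit = 20), "limited")
})

test_that("predict equals the oracle on seeded random instances", {
  for (s in 1:150) {
    inst <- generate_instance(k = 2 + (s %% 11), seed = 2000 + s)
    p <- predict_domains(inst$candidates, inst$meta, inst$model)
    b <- brute_force(inst$candidates, inst$meta, inst$model)
    expect_equal(p$objective, b$objective, tolerance = 1e-9,
                 label = paste("seed", 2000 + s))
    expect_gte(p$objective, 0)
    # returned selections are conflict-free
    expect_equal(nrow(conflict_edges(p$candidates, inst$meta)), 0)
  }
})

test_that("PE never changes the oracle optimum and the trivial path is sound", {
  n_trivial <- 0
  for (s in 1:80) {
    inst <- generate_instance(k = 2 + (s %% 9), seed = 3000 + s)
    full <- brute_force(inst$candidates, inst$meta, inst$model)
    surv <- positive_elimination(inst$candidates, inst$meta, inst$model)
    expect_equal(brute_force(surv, inst$meta, inst$model)$objective,
                 full$objective, tolerance = 1e-9)
    if (is_trivial(surv, inst$meta, inst$model)) {
      n_trivial <- n_trivial + 1
      expect_equal(context_objective(surv, inst$meta, inst$model),
                   full$objective, tolerance = 1e-9)
    }
  }
  expect_gt(n_trivial, 0)  # the shortcut actually fires on this world
})

test_that("any valid clique cover yields the same optimum as single-edge constraints", {
  for (s in 1:25) {
    inst <- generate_instance(k = 8, conflict_rate = 0.5, seed = 4000 + s)
    surv <- order_candidates(inst$candidates)
    edges <- conflict_edges(surv, inst$meta)
    greedy <- greedy_clique_cover(nrow(surv), edges)
    edgewise <- lapply(seq_len(nrow(edges)), function(r) as.integer(edges[r, ]))
    s1 <- solve_ilp(build_ilp(surv, inst$meta, inst$model, cliques = greedy))
    s2 <- solve_ilp(build_ilp(surv, inst$meta, inst$model, cliques = edgewise))
    expect_equal(s1$objective, s2$objective, tolerance = 1e-9)
  }
})

test_that("predict handles edge cases and reports status", {
  meta <- mk_meta(c("F1", "F2"))
  model <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 1))
  empty <- predict_domains(cand("F1", 1, 10, 5)[0, ], meta, model)
  expect_equal(empty$status, "empty")
  expect_equal(empty$objective, 0)

  clean <- predict_domains(rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2)),
                           meta, model)
  expect_equal(clean$status, "trivial")
  expect_false(clean$diagnostics$used_ilp)
  expect_equal(clean$objective, 6)

  confl <- predict_domains(rbind(cand("F1", 1, 100, 3), cand("F2", 1, 100, 2)),
                           meta, model)
  expect_equal(confl$status, "optimal")
  expect_true(confl$diagnostics$used_ilp)
  expect_equal(confl$objective, 3)
})

test_that("solution objective matches a recomputation from the breakdown", {
  for (s in 1:30) {
    inst <- generate_instance(k = 9, seed = 5000 + s)
    p <- predict_domains(inst$candidates, inst$meta, inst$model)
    expect_equal(p$objective,
                 context_objective(p$candidates, inst$meta, inst$model),
                 tolerance = 1e-9)
  }
})
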