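test_that("objective sums domain, all-ordered-pair and family terms", {
  meta <- mk_meta(c("F1", "F2"))
  model <- forge_model(c("F1", "F2"), scores = list("F1>F2" = 1))
  sub <- rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2))
  expect_equal(context_objective(sub, meta, model), 6)   # 3 + 2 + 1

  expect_equal(context_objective(sub[0, ], meta, model), 0)  # null model

  # a single domain can be worse than predicting nothing via its surcharge
  meta2 <- mk_meta("F1", t_dom = 10, t_seq = 12)
  expect_equal(meta2$t_tilde, 2)
  expect_equal(context_objective(cand("F1", 1, 50, 11.5), meta2, model), -0.5)
})

test_that("objective charges each selected family's surcharge once", {
  meta <- mk_meta("F1", t_dom = 10, t_seq = 12)
  model <- forge_model("F1", scores = list("F1>F1" = 0.5))
  sub <- rbind(cand("F1", 1, 50, 13), cand("F1", 100, 150, 14))
  # (3) + (4) + S + (-2): surcharge applies once, not per instance
  expect_equal(context_objective(sub, meta, model), 5.5)
})

test_that("objective refuses conflicting subsets", {
  meta <- mk_meta(c("F1", "F2"))
  model <- mk_model(c("F1", "F2"))
  sub <- rbind(cand("F1", 1, 100, 3), cand("F2", 1, 100, 2))
  expect_error(context_objective(sub, meta, model), "conflicting")
  expect_silent(context_objective(sub, meta, model, check_conflicts = FALSE))
})

test_that("objective equals the sum of its breakdown terms", {
  for (s in 1:60) {
    inst <- generate_instance(k = sample(1:8, 1), conflict_rate = 0, seed = 600 + s)
    val <- context_objective(inst$candidates, inst$meta, inst$model,
                             breakdown = TRUE)
    br <- attr(val, "breakdown")
    expect_lt(abs(as.numeric(val) -
                  (sum(br$domain$term) + sum(br$pair$term) - sum(br$family$t_tilde))),
              1e-9)
  }
})

test_that("markov score keeps only consecutive pairs and matches for k <= 2", {
  fams <- c("F1", "F2", "F3")
  meta <- mk_meta(fams)
  model <- forge_model(fams, scores = list("F1>F2" = 1, "F2>F3" = 2,
                                           "F1>F3" = 0.5))
  d1 <- cand("F1", 1, 50, 3); d2 <- cand("F2", 100, 150, 2)
  d3 <- cand("F3", 200, 250, 1)
  for (sub in list(d1[0, ], d1, rbind(d1, d2)))
    expect_equal(markov_score(sub, meta, model),
                 context_objective(sub, meta, model))
  k3 <- rbind(d1, d2, d3)
  expect_equal(context_objective(k3, meta, model) - markov_score(k3, meta, model),
               0.5)  # exactly the non-adjacent S(F1,F3)
  # k = 1 is just H - T^d - t_tilde
  meta2 <- mk_meta("F1", t_dom = 10, t_seq = 12)
  expect_equal(markov_score(cand("F1", 1, 50, 13), meta2, model), 1)
})

test_that("objective minus markov equals the non-adjacent context sum", {
  for (s in 1:40) {
    inst <- generate_instance(k = sample(3:9, 1), conflict_rate = 0,
                              seed = 700 + s)
    sub <- order_candidates(inst$candidates)
    k <- nrow(sub)
    extra <- 0
    for (i in seq_len(k - 2))
      for (j in seq(i + 2, k))
        extra <- extra + pair_score(inst$model, sub$family_id[i], sub$family_id[j])
    expect_lt(abs(context_objective(sub, inst$meta, inst$model) -
                  markov_score(sub, inst$meta, inst$model) - extra), 1e-9)
  }
})

test_that("swapping two domains' positions changes the objective directionally", {
  fams <- c("F1", "F2")
  meta <- mk_meta(fams)
  model <- forge_model(fams, scores = list("F1>F2" = 1.25, "F2>F1" = -0.75))
  fwd <- rbind(cand("F1", 1, 50, 3), cand("F2", 100, 150, 2))
  rev <- rbind(cand("F2", 1, 50, 2), cand("F1", 100, 150, 3))
  expect_equal(context_objective(fwd, meta, model) -
                 context_objective(rev, meta, model),
               1.25 - (-0.75))
})

test_that("standard Pfam filter applies thresholds then clan resolution", {
  meta <- mk_meta(c("A", "B", "C", "D"), t_dom = 25, t_seq = 25,
                  clan_id = c("CL1", "CL1", "CL2", ""))
  cands <- rbind(
    cand("A", 1, 60, 24.9, p = 1e-9),          # below T^d -> dropped
    cand("A", 100, 160, 30, p = 1e-9, clan = "CL1"),
    cand("B", 160, 220, 28, p = 1e-5, clan = "CL1"),   # 1 shared residue w/ A
    cand("C", 150, 260, 40, p = 1e-7, clan = "CL2"))   # other clan: kept
  out <- standard_pfam_filter(cands, meta)
  expect_equal(sort(out$family_id), c("A", "C"))
  expect_true(all(out$bitscore >= 25))
})

test_that("standard Pfam filter enforces the family sequence threshold", {
  meta <- mk_meta(c("A", "B"), t_dom = c(20, 20), t_seq = c(45, 20))
  cands <- rbind(cand("A", 1, 60, 22), cand("A", 100, 160, 21),  # sum 43 < 45
                 cand("B", 200, 260, 21))
  out <- standard_pfam_filter(cands, meta)
  expect_equal(out$family_id, "B")
})

test_that("clan metadata fills empty candidate clans before resolution", {
  meta <- mk_meta(c("A", "B"), t_dom = 10, clan_id = "CL9")
  cands <- rbind(cand("A", 1, 100, 30, p = 1e-9),
                 cand("B", 100, 200, 20, p = 1e-4))  # strict 1-residue overlap
  out <- standard_pfam_filter(cands, meta)
  expect_equal(out$family_id, "A")  # most significant kept
})
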