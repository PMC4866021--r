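ranked4 <- tibble::tibble(accession = c("g1", "g2", "g3", "g4"),
                          rank_value = c(4, 3, 2, 1))

test_that("worked running-sum examples reproduce exactly", {
  top <- compute_es(ranked4, "g1", weight_p = 0)
  expect_equal(top$running_sum, c(1, 2/3, 1/3, 0))
  expect_equal(top$es, 1)
  expect_equal(top$es_position, 1L)

  bottom <- compute_es(ranked4, "g4", weight_p = 0)
  expect_equal(bottom$running_sum, c(-1/3, -2/3, -1, 0))
  expect_equal(bottom$es, -1)
  expect_equal(bottom$es_position, 3L)

  weighted <- compute_es(ranked4, c("g1", "g3"), weight_p = 1)
  expect_equal(weighted$running_sum, c(2/3, 1/6, 1/2, 0))  # N_R = 4 + 2 = 6
  expect_equal(weighted$es, 2/3)
  expect_equal(weighted$es_position, 1L)
})

test_that("degenerate sets are rejected per contract", {
  expect_error(compute_es(ranked4, "absent"), "no members")
  expect_error(compute_es(ranked4, c("g1", "g2", "g3", "g4")), "whole")
  expect_error(prepare_ranked_list(tibble::tibble(accession = "a",
                                                  rank_value = 1)),
               "at least 2")
})

test_that("implementation matches the brute-force oracle on random instances", {
  withr::with_seed(42, {
    for (i in 1:300) {
      n <- sample(3:50, 1)
      ranked <- random_ranked(n, signed = i %% 3 == 0)
      nh <- sample(seq_len(n - 1), 1)
      members <- sample(ranked$accession, nh)
      p <- sample(c(0, 1), 1)
      got <- compute_es(ranked, members, weight_p = p)
      want <- oracle_es(ranked$rank_value, ranked$accession %in% members, p)
      expect_equal(got$es, want$es, tolerance = 1e-12)
      expect_equal(got$es_position, want$pos)
      expect_lt(max(abs(got$running_sum - want$run)), 1e-9)
      expect_lt(abs(got$running_sum[n]), 1e-9)  # walk returns to zero
    }
  })
})

test_that("reversing the ranked list negates the unweighted score", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(4:40, 1)
      ranked <- random_ranked(n)
      members <- sample(ranked$accession, sample(seq_len(n - 1), 1))
      fwd <- compute_es(ranked, members, weight_p = 0)
      rev <- compute_es(ranked[n:1, ], members, weight_p = 0)
      expect_equal(abs(rev$es), abs(fwd$es), tolerance = 1e-9)
      # sign negation holds whenever the extremum's sign is unambiguous
      # (a walk can touch +m and -m exactly; either is then a valid score)
      a <- abs(fwd$running_sum)
      tied_both_signs <- any(fwd$running_sum >= max(a) - 1e-12) &&
        any(fwd$running_sum <= -(max(a) - 1e-12))
      if (!tied_both_signs) expect_equal(rev$es, -fwd$es, tolerance = 1e-9)
    }
  })
})

test_that("leading edge collects the hits driving the extremum", {
  weighted <- compute_es(ranked4, c("g1", "g3"), weight_p = 1)
  expect_equal(leading_edge(ranked4, weighted), "g1")
  bottom <- compute_es(ranked4, "g4", weight_p = 0)
  expect_equal(leading_edge(ranked4, bottom), "g4")
  # all hits before a positive extremum: the edge is the whole in-list set
  front <- compute_es(ranked4, c("g1", "g2"), weight_p = 0)
  expect_gt(front$es, 0)
  expect_setequal(leading_edge(ranked4, front), c("g1", "g2"))
  # trace flags agree with the extraction (cross-view consistency)
  res <- suppressWarnings(run_mtisea(
    list(s1 = c("g1", "g3")), ranked4, weight_p = 1, n_perm = 50,
    min_set_size = 2, seed = 3))
  tr <- res$traces$s1
  expect_equal(nrow(tr), 2)                       # one row per hit
  expect_equal(tr$accession[tr$leading_edge], "g1")
})

test_that("NES is sign-stratified self-normalization with seeded permutations", {
  # zero score: zero NES regardless of the permutations
  expect_equal(mirlink:::normalize_es(0, c(-0.5, 0.4, 0.7))$nes, 0)

  # self-normalization: same-sign permutations equal to |es| give NES = sign(es)
  expect_equal(mirlink:::normalize_es(0.8, c(0.8, 0.8, 0.8, -0.5))$nes, 1)
  expect_equal(mirlink:::normalize_es(-0.6, c(-0.6, -0.6, 0.3))$nes, -1)
  # no same-sign permutation: NES undefined, reported missing
  expect_warning(und <- mirlink:::normalize_es(0.5, c(-0.4, -0.2)),
                 "undefined")
  expect_true(is.na(und$nes))

  # degenerate near-full set: sign preserved, magnitude near unity
  r5 <- tibble::tibble(accession = paste0("g", 1:5), rank_value = 5:1)
  es <- compute_es(r5, paste0("g", 1:4), weight_p = 0)$es
  nes <- compute_nes(r5, paste0("g", 1:4), es, weight_p = 0,
                     n_perm = 400, seed = 9)$nes
  expect_equal(sign(nes), sign(es))
  expect_gt(abs(nes), 0.5)
  expect_lt(abs(nes), 2)

  # fixed seed: bit-identical; different seed: varies within Monte-Carlo error
  ranked <- random_ranked(60)
  es2 <- compute_es(ranked, ranked$accession[c(2, 5, 9, 30)], 1)$es
  a <- compute_nes(ranked, ranked$accession[c(2, 5, 9, 30)], es2, 1,
                   n_perm = 200, seed = 77)
  b <- compute_nes(ranked, ranked$accession[c(2, 5, 9, 30)], es2, 1,
                   n_perm = 200, seed = 77)
  d <- compute_nes(ranked, ranked$accession[c(2, 5, 9, 30)], es2, 1,
                   n_perm = 200, seed = 78)
  expect_identical(a$nes, b$nes)
  expect_identical(a$perm_es, b$perm_es)
  expect_false(identical(a$nes, d$nes))
  expect_lt(abs(a$nes - d$nes), 0.5)
})

test_that("FDR q-values are monotone in NES and clipped to [0, 1]", {
  # single set with every permutation NES less extreme: q = 0
  expect_equal(compute_fdr(2.5, c(0.3, 1.1, -0.8, 0.9)), 0)
  # pooled ranking property within the positive stratum
  obs <- c(2.8, 1.2, 0.7, -1.5, -0.3)
  perm <- c(seq(-2, 2, length.out = 200))
  q <- compute_fdr(obs, perm)
  expect_true(all(q >= 0 & q <= 1))
  pos <- obs >= 0
  expect_true(all(diff(q[pos][order(-obs[pos])]) >= 0))
  expect_true(is.na(compute_fdr(c(1, NA), perm)[2]))
})

test_that("run_mtisea ranks by NES, skips ineligible sets, and is seed-stable", {
  g <- generate_ranked(n = 120, n_planted = 1, planted_size = 8,
                       loading_frac = 1, top_quantile = 0.1,
                       n_null_sets = 8, null_set_size = 8, seed = 4)
  sets <- c(g$sets, list(tiny = g$ranked$accession[1:2],
                         gone = c("ZZZ1", "ZZZ2", "ZZZ3")))
  res <- suppressWarnings(run_mtisea(sets, g$ranked, weight_p = 1,
                                     n_perm = 300, seed = 15))
  r <- tidy(res)
  expect_equal(r$mirna_key[1], "planted_1")           # planted set wins
  expect_equal(r$nes, sort(r$nes, decreasing = TRUE))
  expect_setequal(res$skipped$mirna_key, c("tiny", "gone"))
  expect_setequal(res$skipped$reason,
                  c("below min_set_size", "no members in ranked list"))
  # every trace has one row per in-list member, flags match leading edges
  for (key in names(res$traces)) {
    expect_equal(nrow(res$traces[[key]]),
                 r$set_size[r$mirna_key == key])
    expect_setequal(res$traces[[key]]$accession[res$traces[[key]]$leading_edge],
                    res$leading_edges[[key]])
    expect_lt(abs(res$running_sums[[key]][120]), 1e-9)
  }
  res2 <- suppressWarnings(run_mtisea(sets, g$ranked, weight_p = 1,
                                      n_perm = 300, seed = 15))
  expect_identical(tidy(res), tidy(res2))
  expect_equal(glance(res)$n_sets, 9)
})

test_that("duplicated ranked accessions keep first occurrence with a warning", {
  expect_warning(
    pr <- prepare_ranked_list(tibble::tibble(
      accession = c("a", "b", "a", "c"), rank_value = c(5, 4, 3, 2))),
    "duplicated"
  )
  expect_equal(pr$accession, c("a", "b", "c"))
  expect_equal(pr$rank_value[pr$accession == "a"], 5)
  # stable order on ties: input order preserved
  tied <- prepare_ranked_list(tibble::tibble(accession = c("x", "y", "z"),
                                             rank_value = c(1, 1, 1)))
  expect_equal(tied$accession, c("x", "y", "z"))
})
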