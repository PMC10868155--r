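test_that("membership-mode classification follows the shared-group rules", {
  gs <- gold_membership(c("g1", "g2", "g2", "g3"),
                        c("K1", "K1", "K2", "K2"))
  expect_identical(classify_pair("g1", "g2", gs), "TP")   # share K1
  expect_identical(classify_pair("g1", "g3", gs), "FP")   # disjoint maps
  expect_identical(classify_pair("g2", "g3", gs), "TP")   # share K2
  expect_identical(classify_pair("g1", "g9", gs), "EXCLUDED") # unmapped
  expect_error(classify_pair("g1", "g1", gs), "self-pairs")
})

test_that("pairs-mode classification matches brute-force lookups", {
  set.seed(41)
  genes <- sprintf("g%02d", 1:20)
  idx <- t(combn(20, 2))
  chosen <- idx[sample.int(nrow(idx), 40L), ]
  gs <- gold_pairs(genes[chosen[, 1L]], genes[chosen[, 2L]])
  universe <- unique(c(genes[chosen[, 1L]], genes[chosen[, 2L]]))
  all_pairs <- t(combn(genes, 2))
  labels <- classify_pairs(all_pairs[, 1L], all_pairs[, 2L], gs)
  gold_set <- paste(pmin(genes[chosen[, 1]], genes[chosen[, 2]]),
                    pmax(genes[chosen[, 1]], genes[chosen[, 2]]))
  for (r in seq_len(nrow(all_pairs))) {
    a <- all_pairs[r, 1L]; b <- all_pairs[r, 2L]
    expected <- if (paste(min(a, b), max(a, b)) %in% gold_set) "TP"
      else if (a %in% universe && b %in% universe) "FP"
      else "EXCLUDED"
    expect_identical(labels[r], expected)
  }
  # strict mode: everything absent from the gold set is a false positive
  strict <- classify_pairs(all_pairs[, 1L], all_pairs[, 2L], gs,
                           strict_fp = TRUE)
  expect_true(all(strict[labels == "EXCLUDED"] == "FP"))
  expect_identical(strict[labels != "EXCLUDED"],
                   labels[labels != "EXCLUDED"])
})

test_that("cumulative curves accumulate one unit per evaluable pair", {
  gs <- gold_membership(c("a", "b", "c", "d"), c("K1", "K1", "K2", "K2"))
  net <- as_scored_network(data.frame(
    gene1 = c("a", "a", "c"), gene2 = c("b", "c", "d"),
    score = c(0.9, 0.8, 0.7)))
  cv <- cumulative_curve(net, gs)
  expect_equal(cv$points$cum_tp, c(1, 1, 2))   # TP, FP, TP
  expect_equal(cv$points$cum_fp, c(0, 1, 1))
  expect_equal(cv$points$cum_tp + cv$points$cum_fp,
               seq_len(nrow(cv$points)))
  # excluded pairs are skipped, all-excluded is an error with coverage info
  gs2 <- gold_membership(c("x", "y"), c("K1", "K1"))
  expect_error(cumulative_curve(net, gs2), "no evaluable pairs")
})

test_that("curve points dominate predecessors by exactly one coordinate", {
  fx <- tiny_fixture()
  net <- pairwise_pcc(preprocess_matrix(fx$matrix))
  cv <- cumulative_curve(net, fx$gold)
  steps <- cbind(diff(c(0, cv$points$cum_fp)), diff(c(0, cv$points$cum_tp)))
  expect_true(all(rowSums(steps) == 1))
  expect_true(all(steps %in% c(0, 1)))
  # independent single pass over the ranked list
  labels <- character(0); tp <- 0; fp <- 0
  for (r in seq_len(nrow(net))) {
    lab <- classify_pair(net$gene1[r], net$gene2[r], fx$gold)
    if (lab == "EXCLUDED") next
    if (lab == "TP") tp <- tp + 1 else fp <- fp + 1
    labels <- c(labels, lab)
  }
  n <- nrow(cv$points)
  expect_equal(cv$points$cum_tp[n], tp)
  expect_equal(cv$points$cum_fp[n], fp)
})

test_that("random rankings score near the gold standard's base rate", {
  fx <- tiny_fixture(seed = 6L)
  net <- pairwise_pcc(preprocess_matrix(fx$matrix))
  set.seed(44)
  shuffled <- net
  shuffled$score <- sample(net$score)
  cv <- cumulative_curve(as_scored_network(shuffled), fx$gold)
  # base rate among evaluable pairs of the planted modules
  g <- lengths(fx$modules)
  n_mapped <- sum(g)
  base <- sum(choose(g, 2)) / choose(n_mapped, 2)
  k <- 100L
  tp_frac <- cv$points$cum_tp[k] / k
  expect_lt(abs(tp_frac - base), 3 * sqrt(base * (1 - base) / k))
})

test_that("tp_at_fp reads the curve at matched specificity", {
  cv <- structure(list(points = data.frame(
    cum_fp = c(0, 0, 1, 2, 2), cum_tp = c(1, 2, 2, 2, 3))),
    class = "vaenet_curve")
  expect_equal(tp_at_fp(cv, 0), 2)
  expect_equal(tp_at_fp(cv, 1), 2)
  expect_equal(tp_at_fp(cv, 5), 3)
})
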