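# ROC/AUC, enrichment, confusion statistics, partial-rank reconstruction,
# Cheng-Prusoff.

test_that("AUC follows the rank-sum conventions on canonical cases", {
  # all actives above all decoys
  s1 <- data.frame(score = c(5, 4, 3, 2, 1),
                   label = c("active", "active", "decoy", "decoy", "decoy"))
  expect_equal(roc_validation(s1)$auc, 1.0)
  # all scores equal: ties contribute 1/2
  s2 <- data.frame(score = rep(1, 6), label = rep(c("active", "decoy"), 3))
  expect_equal(roc_validation(s2)$auc, 0.5)
  # alternating A, D, A, D by rank
  s3 <- data.frame(score = c(4, 3, 2, 1),
                   label = c("active", "decoy", "active", "decoy"))
  expect_equal(roc_validation(s3)$auc, 0.75)
  expect_equal(pairwise_auc(s3$score, s3$label == "active"), 0.75)
  expect_error(roc_validation(data.frame(score = 1:3, label = rep("active", 3))),
               "at least one")
})

test_that("rank-sum AUC equals brute-force pairwise counting on random lists", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    score <- sample(0:30, n, replace = TRUE)  # deliberate ties
    label <- ifelse(runif(n) < 0.3, "active", "decoy")
    if (length(unique(label)) < 2) next
    r <- roc_validation(data.frame(score = score, label = label))
    expect_equal(r$auc, pairwise_auc(score, label == "active"), tolerance = 1e-12)
  }
})

test_that("rank-sum AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  score <- rnorm(120)
  label <- ifelse(runif(120) < 0.4, "active", "decoy")
  ours <- roc_validation(data.frame(score = score, label = label))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = label, predictor = score,
                                        levels = c("decoy", "active"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curve is monotone and enrichment factors are well-formed", {
  set.seed(21)
  score <- rnorm(150)
  label <- ifelse(runif(150) < 0.2, "active", "decoy")
  r <- roc_validation(data.frame(score = score, label = label))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_true(all(r$ef >= 0))
  expect_named(r$ef, c("EF1", "EF5"))
})

test_that("confusion statistics reproduce their definition and scale freely", {
  cs <- confusion_stats(56, 82, 67)
  expect_equal(cs$sensitivity_pct, 68)
  expect_equal(cs$n_fp, 11)
  expect_equal(confusion_stats(0, 82, 0)$sensitivity_pct, 0)
  expect_equal(confusion_stats(82, 82, 82), list(sensitivity_pct = 100,
                                                 sensitivity = 1, n_fp = 0))
  # scale-free in all three counts
  expect_equal(confusion_stats(56, 82, 67)$sensitivity_pct,
               confusion_stats(560, 820, 670)$sensitivity_pct)
  expect_error(confusion_stats(5, 3, 10), "exceeds")
  expect_error(confusion_stats(5, 10, 3), "exceeds")
})

test_that("partial-rank reconstruction is exact against pairwise counting", {
  # tiny list: 2 actives at ranks 1 and 4, 2 decoys at 2 and 3
  p <- partial_rank_list(2, 2, listed_decoy_ranks = c(2, 3),
                         straggler_active_ranks = 4, top_block_size = 1)
  out <- auc_from_partial_ranks(p)
  lab <- out$labels
  expect_equal(lab, c("active", "decoy", "decoy", "active"))
  expect_equal(out$auc, pairwise_auc(rev(seq_along(lab)), lab == "active"))
  # a clean block with no decoys or stragglers gives AUC 1
  p1 <- partial_rank_list(3, 5, integer(), integer(), 3)
  expect_equal(auc_from_partial_ranks(p1)$auc, 1.0)
})

test_that("Cheng-Prusoff conversion behaves across its domain", {
  expect_equal(cheng_prusoff(100, 0, 2), 100)        # L = 0 limit
  expect_equal(cheng_prusoff(100, 1, 1), 50)
  # Ki strictly decreases with increasing radioligand concentration
  L <- seq(0, 50, by = 5)
  ki <- cheng_prusoff(250, L, kd = 3.7)
  expect_true(all(diff(ki) < 0))
  expect_error(cheng_prusoff(100, 1, 0), "kd")
  expect_error(cheng_prusoff(-1, 1, 1), "ic50")
})

test_that("library composition accounting recomputes the printed shares", {
  comp <- library_composition()
  expect_equal(nrow(comp), 7L)
  expect_equal(sum(comp$n_molecules), 2989670L)
  sh <- library_shares()
  expect_equal(sh$np_share_pct, 1.44)
  expect_true(sh$printed_np_share_consistent)
  # the printed synthetic share does not follow from the table's own counts
  expect_false(sh$printed_syn_share_consistent)
  expect_equal(sh$np_share_pct + sh$syn_share_pct, 100, tolerance = 0.01)
})
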