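test_that("performance metrics evaluate their closed forms", {
  m <- performance_metrics(list(TP = 8, FP = 2, TN = 9, FN = 1))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9, tolerance = 1e-6)
  expect_equal(m$specificity, 9 / 11, tolerance = 1e-6)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-6)
  expect_equal(m$accuracy, 0.85)
  # 0/0 cases are undefined, not zero
  m0 <- performance_metrics(list(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$recall))
  perf <- performance_metrics(list(TP = 7, FP = 0, TN = 5, FN = 0))
  expect_true(all(unlist(perf) == 1))
})

test_that("disparate impact follows the positive-rate ratio", {
  preds <- data.frame(
    label = rep("PD", 100),
    predicted = rep(c("PD", "non-PD", "PD", "non-PD"), c(10, 40, 20, 30)),
    sex = rep(c("female", "male"), each = 50))
  expect_equal(disparate_impact(preds, "sex"), 0.5)
  # identical groups sit at the fairness fixed point
  same <- data.frame(label = rep(c("PD", "non-PD"), 20),
                     predicted = rep(c("PD", "non-PD"), 20),
                     sex = rep(c("male", "female"), each = 20))
  expect_equal(disparate_impact(same, "sex"), 1.0)
  # swapping the privilege assignment inverts the ratio
  swapped <- privilege_map(sex = c("female", "male"))
  expect_equal(disparate_impact(preds, "sex", swapped),
               1 / disparate_impact(preds, "sex"))
  # zero privileged positive rate leaves DI undefined
  none <- data.frame(label = rep("PD", 20),
                     predicted = rep(c("PD", "non-PD"), c(5, 15)),
                     sex = rep(c("female", "male"), each = 10))
  none$predicted[none$sex == "male"] <- "non-PD"
  expect_true(is.na(disparate_impact(none, "sex")))
})

test_that("equal opportunity is the TPR ratio with undefined cases flagged", {
  preds <- data.frame(
    label = rep("PD", 20),
    predicted = rep(c("PD", "non-PD", "PD", "non-PD"), c(6, 4, 8, 2)),
    hand = rep(c("left", "right"), each = 10))
  expect_equal(equal_opportunity(preds, "hand"), 0.6 / 0.8)
  equal <- preds; equal$predicted <- "PD"
  expect_equal(equal_opportunity(equal, "hand"), 1.0)
  # unprivileged group without positives: TPR undefined
  nopos <- preds; nopos$label[nopos$hand == "left"] <- "non-PD"
  expect_true(is.na(equal_opportunity(nopos, "hand")))
})

test_that("equalized odds supports the absolute and signed conventions", {
  # TPRs 0.9 vs 0.8, FPRs 0.1 vs 0.3 (u vs p), built from 20-row groups
  mk_group <- function(tpr, fpr, value) {
    data.frame(
      label = rep(c("PD", "non-PD"), each = 10),
      predicted = c(rep(c("PD", "non-PD"), c(tpr * 10, 10 - tpr * 10)),
                    rep(c("PD", "non-PD"), c(fpr * 10, 10 - fpr * 10))),
      device = value)
  }
  preds <- rbind(mk_group(0.9, 0.1, "Windows"), mk_group(0.8, 0.3, "Mac"))
  expect_equal(equalized_odds(preds, "device"), 0.2)
  expect_equal(equalized_odds(preds, "device", convention = "signed"), 0.1)
  ideal <- rbind(mk_group(0.7, 0.2, "Windows"), mk_group(0.7, 0.2, "Mac"))
  expect_equal(equalized_odds(ideal, "device"), 0)
})

test_that("fairness metrics match the row-enumeration oracle on random tables", {
  priv <- privilege_map()
  for (i in 1:120) {
    preds <- random_prediction_table(sample(10:100, 1), seed = 7000 + i)
    for (a in c("sex", "race", "device", "hand")) {
      o <- oracle_group_fairness(preds, a, priv)
      expect_equal(disparate_impact(preds, a, priv), o$di, tolerance = 1e-12)
      expect_equal(equal_opportunity(preds, a, priv), o$eo, tolerance = 1e-12)
      expect_equal(equalized_odds(preds, a, priv), o$eodds_abs,
                   tolerance = 1e-12)
      expect_equal(equalized_odds(preds, a, priv, convention = "signed"),
                   o$eodds_signed, tolerance = 1e-12)
    }
    cc <- confusion_counts(preds)
    expect_identical(cc, oracle_confusion(preds))
  }
})

test_that("fairness fixed points hold exactly and metrics ignore row order", {
  set.seed(31)
  for (i in 1:40) {
    preds <- random_prediction_table(60, seed = 500 + i)
    shuffled <- preds[sample(nrow(preds)), ]
    for (a in c("sex", "device")) {
      expect_equal(disparate_impact(preds, a),
                   disparate_impact(shuffled, a))
      expect_equal(equalized_odds(preds, a), equalized_odds(shuffled, a))
      eod <- equalized_odds(preds, a)
      if (!is.na(eod)) expect_gte(eod, 0)
    }
  }
})

test_that("group-balanced bootstrap reports replicate means and stds", {
  # degenerate table: every row identical within group -> zero spread
  preds <- data.frame(
    label = "PD", score = 0.9, predicted = "PD",
    sex = rep(c("male", "female"), each = 25),
    race_binary = "White", device = "Windows", hand = "right")
  boot <- bootstrap_group_metrics(preds, "sex", B = 20, seed = 2)
  s <- boot$summary
  expect_true(all(s$sd[s$metric %in% c("sensitivity_u", "sensitivity_p",
                                       "di", "eo")] == 0))
  expect_equal(s$mean[s$metric == "di"], 1)
  # B = 1: the mean is the single replicate
  b1 <- bootstrap_group_metrics(preds, "sex", B = 1, seed = 3)
  expect_equal(b1$summary$mean[b1$summary$metric == "di"],
               b1$replicates$di[1])
  expect_equal(boot$m, 25)
})

test_that("bootstrap DI concentrates on the plug-in estimate at large B", {
  preds <- random_prediction_table(160, seed = 77)
  plug_in <- disparate_impact(preds, "sex")
  boot <- bootstrap_group_metrics(preds, "sex", B = 2000, seed = 5)
  di <- boot$replicates$di
  se <- sd(di, na.rm = TRUE) / sqrt(sum(!is.na(di)))
  expect_lt(abs(mean(di, na.rm = TRUE) - plug_in),
            max(3 * se, 0.08 * plug_in))
})

test_that("significance flags separate identical and disjoint groups", {
  same <- data.frame(
    label = rep(rep(c("PD", "non-PD"), each = 20), 2),
    score = rep(c(0.9, 0.1), each = 20),
    predicted = rep(rep(c("PD", "non-PD"), each = 20), 2),
    sex = rep(c("male", "female"), each = 40),
    race_binary = "White", device = "Windows", hand = "right")
  bsame <- bootstrap_group_metrics(same, "sex", B = 60, seed = 4)
  fsame <- significance_flags(bsame)
  expect_true(all(!fsame[c("sensitivity", "specificity", "precision")]))
  # one group perfect, the other fully wrong: flags must fire
  diff <- same
  diff$predicted[diff$sex == "female"] <-
    ifelse(diff$label[diff$sex == "female"] == "PD", "non-PD", "PD")
  diff$score[diff$sex == "female"] <-
    1 - diff$score[diff$sex == "female"]
  bdiff <- bootstrap_group_metrics(diff, "sex", B = 60, seed = 4)
  fdiff <- significance_flags(bdiff)
  expect_true(all(fdiff[c("sensitivity", "specificity", "auroc")]))
  # too few valid replicates leaves the flag undefined
  b2 <- bootstrap_group_metrics(same, "sex", B = 10, seed = 1)
  expect_true(all(is.na(significance_flags(b2))))
})

test_that("stratified importance is normalized, seeded, and finds planted signal", {
  set.seed(8)
  n <- 120
  feats <- data.frame(participant_id = sprintf("S%03d", 1:n),
                      noise1 = rnorm(n), noise2 = rnorm(n),
                      noise3 = rnorm(n),
                      label = sample(c("PD", "non-PD"), n, TRUE),
                      device = sample(c("Windows", "Mac"), n, TRUE))
  feats$planted <- ifelse(feats$label == "PD", 1, 0) + rnorm(n, 0, 0.01)
  imp <- stratified_importance(feats, seed = 6, k = Inf)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "planted")
  expect_identical(stratified_importance(feats, seed = 6, k = Inf), imp)
  # subgroup refit works on row subsets and rejects single-class subgroups
  sub <- stratified_importance(feats, subset = feats$device == "Windows",
                               seed = 2)
  expect_equal(sub$feature[1], "planted")
  one_class <- feats[feats$label == "PD", ]
  expect_error(stratified_importance(one_class), "single class")
})

test_that("the full report covers every attribute with consistent metadata", {
  preds <- random_prediction_table(140, seed = 10)
  rep <- fairness_report(preds, B = 40, seed = 3)
  expect_named(rep$attributes, c("sex", "race", "device", "hand"))
  blk <- rep$attributes$device
  expect_equal(blk$privileged, "Mac")
  expect_equal(blk$unprivileged, "Windows")
  expect_true(all(c("di", "eo", "eodds") %in% blk$summary$metric))
  json <- withr::local_tempfile(fileext = ".json")
  md <- withr::local_tempfile(fileext = ".md")
  write_fairness_report(rep, json, md)
  back <- jsonlite::read_json(json)
  expect_equal(names(back$attributes), c("sex", "race", "device", "hand"))
  expect_true(any(grepl("privileged", readLines(md))))
})
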