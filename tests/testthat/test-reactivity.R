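test_that("expression-fraction filters keep and drop genes at the stated cutoffs", {
  set.seed(1)
  n_r <- 10
  m <- matrix(0, 4, 20,
              dimnames = list(c("up9", "up7", "ieg", "dn3"),
                              paste0("n", 1:20)))
  r_ids <- paste0("n", 1:n_r)
  m["up9", 1:9] <- 3     # expressed in 9/10 reactivated
  m["up7", 1:7] <- 3     # 7/10
  m["ieg", 1:10] <- 3
  m["dn3", c(1:3, 11:20)] <- 3  # 3/10 reactivated
  de <- data.frame(gene = rownames(m), p_adj = 0.001,
                   direction = c("up", "up", "up", "down"),
                   stringsAsFactors = FALSE)
  de_1h <- data.frame(gene = rownames(m),
                      p_adj = c(0.9, 0.9, 0.001, 0.9))
  sel <- select_predictive_genes(de, m, r_ids, de_1h_vs_HC = de_1h)
  expect_setequal(sel$gene, c("up9", "dn3"))  # 90% kept, 70% dropped,
                                              # 1-h DE gene excluded
  expect_equal(sel$reactivated_expression_fraction[sel$gene == "up9"], 0.9)
  # selection is idempotent and order-invariant
  sel2 <- select_predictive_genes(de[c(3, 1, 4, 2), ], m, r_ids,
                                  de_1h_vs_HC = de_1h)
  expect_identical(sel, sel2)
  expect_error(select_predictive_genes(de, m, r_ids,
                                       batch_assoc_genes = rownames(m)),
               "no predictive genes")
})

test_that("batch-associated genes are detected and excluded", {
  set.seed(2)
  m <- matrix(abs(rnorm(40 * 30, 3, 0.5)), 40, 30,
              dimnames = list(paste0("g", 1:40), paste0("n", 1:30)))
  batch <- rep(c("b1", "b2"), each = 15)
  m[1:5, batch == "b2"] <- m[1:5, batch == "b2"] + 2
  hits <- batch_associated_genes(m, batch)
  expect_true(all(paste0("g", 1:5) %in% hits))
  expect_lte(length(setdiff(hits, paste0("g", 1:5))), 2)
})

test_that("the trained forests recover reactivity with low hold-out error", {
  fit <- fit_cohort_model()
  model <- fit$model
  gt <- fit$co$sim$truth$gene_truth
  # every selected gene is either planted predictive or a late-program gene
  kinds <- gt$temporal_group[match(fit$genes$gene, gt$gene)]
  pred <- gt$predictive[match(fit$genes$gene, gt$gene)]
  expect_gte(mean(pred | kinds %in% c("4", "5")), 0.9)
  # structural guarantees
  expect_length(intersect(model$train_ids, model$test_ids), 0)
  expect_setequal(c(model$train_ids, model$test_ids), fit$co$aa_ids)
  # per-class hold-out error at most 25%
  expect_true(all(model$holdout_error <= 0.25))
  # pairwise ROC on held-out nuclei
  roc_i <- evaluate_roc(model, fit$co$X[, fit$co$aa_ids],
                        fit$co$labels[fit$co$aa_ids], "i")
  roc_ii <- evaluate_roc(model, fit$co$X[, fit$co$aa_ids],
                         fit$co$labels[fit$co$aa_ids], "ii")
  expect_gte(roc_i$auc, 0.9)
  expect_gte(roc_ii$auc, 0.9)
  expect_error(train_reactivity_models(fit$co$X[, fit$co$aa_ids],
                                       fit$co$labels[fit$co$aa_ids],
                                       fit$genes, gini_pool_cutoff = Inf,
                                       n_trees = 200),
               "pooled set empty")
})

test_that("primed single-exposure nuclei are recognised as predicted-Reactivated", {
  fit <- fit_cohort_model()
  co <- fit$co
  late_ids <- co$nt$nucleus_id[co$nt$condition %in% c("NE4h", "NE5h")]
  pred <- predict_primed(fit$model, co$X[, late_ids])
  primed <- co$nt$primed[match(late_ids, co$nt$nucleus_id)]
  expect_gte(mean(pred$label[primed] == "pR"), 0.9)
  expect_gte(mean(pred$label[!primed] == "pNR"), 0.9)
  expect_true(all(pred$prob_reactivated >= 0 & pred$prob_reactivated <= 1))
  # three-way probabilities sum to one
  expect_equal(rowSums(pred[, fit$model$classes]),
               rep(1, nrow(pred)), tolerance = 1e-9)
  # a nucleus identical to a training Reactivated one dominates baseline
  r_train <- fit$model$train_ids[co$labels[fit$model$train_ids] ==
                                   "Reactivated"][1]
  base_id <- co$nt$nucleus_id[co$nt$activity_state == "baseline"][1]
  twin <- co$X[, c(r_train, base_id)]
  colnames(twin) <- c("twinR", "twinB")
  p2 <- predict_primed(fit$model, twin)
  expect_gte(p2$prob_reactivated[1], p2$prob_reactivated[2])
  expect_error(predict_primed(fit$model, co$X[1:5, late_ids]), "absent")
})

test_that("ROC points match brute-force threshold enumeration", {
  probs <- c(0.9, 0.8, 0.3, 0.1)
  labs <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(probs, labs)
  expect_equal(r$auc, 1.0)
  # independent enumeration over all thresholds
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  oracle <- t(sapply(thr, function(t) c(
    sum(probs >= t & !labs) / sum(!labs),
    sum(probs >= t & labs) / sum(labs))))
  expect_equal(as.matrix(r$points), oracle, ignore_attr = TRUE)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  # interleaved scores: AUC equals the rank statistic (3 of the 4
  # positive/negative pairs correctly ordered)
  r2 <- roc_curve(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 3 / 4, tolerance = 1e-12)
  expect_error(roc_curve(probs, rep(TRUE, 4)), "both classes")
})

test_that("label-shuffled control gives chance-level AUC", {
  fit <- fit_cohort_model()
  co <- fit$co
  test_i <- fit$model$test_ids[co$labels[fit$model$test_ids] %in%
                                 c("Reactivated", "NewlyActivated")]
  genes <- rownames(fit$model$model_i$importance)
  probs <- predict(fit$model$model_i, t(co$X[genes, test_i]),
                   type = "prob")[, "Reactivated"]
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    roc_curve(probs, sample(co$labels[test_i]),
              positive = "Reactivated")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a second simulated cohort validates the model via the reactivity component", {
  fit <- fit_cohort_model()
  co2 <- aa_cohort(202)
  r2 <- names(co2$labels)[co2$labels == "Reactivated"]
  na2 <- names(co2$labels)[co2$labels == "NewlyActivated"]
  fos_pos <- c(r2, na2)
  probs <- setNames(predict_primed(fit$model,
                                   co2$X[, fos_pos])$prob_reactivated,
                    fos_pos)
  comp <- reactivity_component(co2$X[, co2$aa_ids], r2, na2, probs = probs)
  expect_lt(comp$correlation$p, 0.01)
  expect_false(comp$degenerate)
  # pure-noise control: correlation collapses
  set.seed(7)
  noise <- matrix(abs(rnorm(length(fos_pos) * 300, 3, 1)), 300,
                  dimnames = list(paste0("g", 1:300), fos_pos))
  pnoise <- setNames(runif(length(fos_pos)), fos_pos)
  cnull <- reactivity_component(noise, r2, na2, probs = pnoise)
  expect_gt(cnull$correlation$p, 0.01)
  # degenerate grouping flagged
  dup <- co2$X[, co2$aa_ids]
  same <- reactivity_component(dup, co2$aa_ids[1:4], co2$aa_ids[1:4])
  expect_true(same$t == 0 || same$t_p > 0.99)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:5) {
    scores <- runif(30)
    labs <- runif(30) < plogis(4 * (scores - 0.5))
    if (!any(labs) || all(labs)) next
    ours <- roc_curve(scores, labs)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(labs, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("a serialized model round-trips and keeps predicting", {
  fit <- fit_cohort_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_reactivity_model(fit$model, path)
  spec <- jsonlite::read_json(path)
  expect_setequal(unlist(spec$features), fit$model$features)
  back <- read_reactivity_model(path)
  co <- fit$co
  late_ids <- co$nt$nucleus_id[co$nt$condition %in% c("NE4h", "NE5h")]
  expect_identical(predict_primed(back, co$X[, late_ids]),
                   predict_primed(fit$model, co$X[, late_ids]))
})
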