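test_that("fold-change labelling applies the noise band and the single-cut variant", {
  expect_identical(label_by_foldchange(-0.5), "positive")
  expect_identical(label_by_foldchange(0.0), "excluded")
  expect_identical(label_by_foldchange(0.7), "negative")
  expect_identical(label_by_foldchange(c(-0.21, -0.2, 0.2, 0.21)),
                   c("positive", "excluded", "excluded", "negative"))
  expect_identical(label_by_foldchange(-0.6, positive_cut = -0.7), "negative")
  expect_identical(label_by_foldchange(-0.8, positive_cut = -0.7), "positive")
})

test_that("MCC matches hand arithmetic and its boundary conventions", {
  expect_equal(mcc(list(tp = 10, fp = 0, fn = 0, tn = 10)), 1.0)
  expect_equal(mcc(list(tp = 25, fp = 25, fn = 25, tn = 25)), 0.0)
  # hand-evaluated: (tp*tn - fp*fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))
  expect_equal(mcc(list(tp = 40, fp = 10, fn = 20, tn = 30)),
               (40 * 30 - 10 * 20) / sqrt(50 * 60 * 40 * 50))
  expect_equal(mcc(list(tp = 5, fp = 0, fn = 0, tn = 0)), 0)  # degenerate factor
  expect_error(mcc(list(tp = 0, fp = 0, fn = 0, tn = 0)), "undefined")
  # symmetry under simultaneous label/prediction swap
  expect_equal(mcc(list(tp = 40, fp = 10, fn = 20, tn = 30)),
               mcc(list(tp = 30, fp = 20, fn = 10, tn = 40)))
})

test_that("precision and recall are the two stated ratios with NA flags", {
  expect_equal(precision_recall(list(tp = 50, fp = 50, fn = 0))$precision, 0.5)
  expect_equal(precision_recall(list(tp = 60, fp = 0, fn = 40))$recall, 0.6)
  pr <- precision_recall(list(tp = 0, fp = 0, fn = 0))
  expect_true(is.na(pr$precision) && is.na(pr$recall))
})

test_that("confusion counting matches an independent tally on random labels", {
  set.seed(71)
  lab <- sample(c("positive", "negative", "excluded"), 500, replace = TRUE)
  cl <- sample(c("positive", "negative"), 500, replace = TRUE)
  cc <- confusion_counts(lab, cl)
  expect_identical(cc$tp, sum(lab == "positive" & cl == "positive"))
  expect_identical(cc$tn, sum(lab == "negative" & cl == "negative"))
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, sum(lab != "excluded"))
  cc2 <- confusion_counts(lab, cl, excluded_as_negative = TRUE)
  expect_identical(cc2$tp + cc2$fp + cc2$fn + cc2$tn, 500L)
})

test_that("AU-ROC equals exhaustive pair counting with half-credit ties", {
  pair_auc <- function(score, lab) {
    p <- score[lab == "positive"]; n <- score[lab == "negative"]
    tot <- 0
    for (x in p) for (y in n) tot <- tot + (x > y) + 0.5 * (x == y)
    tot / (length(p) * length(n))
  }
  # 6-item toy with a tie across classes
  score <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  lab <- c("positive", "positive", "negative", "negative", "positive", "negative")
  expect_equal(roc_auc(score, lab)$auc, pair_auc(score, lab))
  # perfectly separated scores
  expect_equal(roc_auc(c(3, 2, 1, 0), c("positive", "positive", "negative", "negative"))$auc, 1.0)
  # invariance under strictly monotone transforms
  set.seed(72)
  s <- rnorm(60); l <- sample(c("positive", "negative"), 60, replace = TRUE)
  expect_equal(roc_auc(s, l)$auc, roc_auc(exp(s), l)$auc)
  expect_equal(roc_auc(s, l)$auc, pair_auc(s, l))
  expect_error(roc_auc(1:3, rep("positive", 3)), "at least one")
})

test_that("random balanced scores give chance-level AUC", {
  set.seed(73)
  s <- runif(4000)
  l <- rep(c("positive", "negative"), 2000)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.03)
})

test_that("grid search recovers a planted optimum and applies the tie rule", {
  # one miRNA, two targets: TX1 carries a perfect site (high HP), TX2 a
  # 1-mismatch site (hp below 0.0179 but above 0.005). Labels mark only TX1
  # as downregulated, so the coarse tau that admits TX2 loses MCC and the
  # strict tau wins.
  seed7 <- "UGGCAUC"
  perfect <- reverse_complement(seed7)
  # terminal mismatch (MRE position 7 faces seed position 1): mild enough
  # to stay above the coarse tau but below the strict one
  onemm <- perfect; substr(onemm, 7, 7) <- "C"
  mk <- function(site) paste0(strrep("A", 30), site, strrep("A", 30))
  cond <- cell_conditions(
    "opt", mirna_abundance = c(mir = 0),
    transcript_abundance = c(TX1 = 200, TX2 = 200, TX3 = 200),
    mirna_seq = c(mir = paste0("G", seed7, strrep("G", 14))),
    transcripts = data.frame(
      id = c("TX1", "TX2", "TX3"),
      sequence = c(mk(perfect), mk(onemm), mk("AAAAAAA")),
      cds_start = 0, cds_end = 10))
  m <- energy_model()
  hp1 <- hybridization_probability(seed7, perfect, m)
  hp2 <- hybridization_probability(seed7, onemm, m)
  expect_gt(hp1, 0.0179)
  expect_true(hp2 > 0.005 && hp2 < 0.0179)
  labels <- data.frame(experiment = 1L,
                       transcript = c("TX1", "TX2", "TX3"),
                       label = c("positive", "negative", "negative"))
  gs <- grid_search(cond, list(list(mirna = "mir", copies = 1e5)), labels,
                    tau_grid = c(0.005, 0.0179), alpha_grid = c(512, 1024),
                    model = m)
  expect_identical(nrow(gs$table), 4L)
  expect_equal(gs$best$tau, 0.0179)
  expect_equal(gs$best$mcc, 1.0)
  # ties on MCC resolve to the lowest tau then the lowest alpha
  expect_equal(gs$best$alpha, 512)
  expect_error(grid_search(cond, list(), labels, numeric(0), 512), "")
})
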