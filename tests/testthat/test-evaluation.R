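# Metrics: ROC/PR AUC, MCC, accuracy/precision, recovery rate, confusion.

test_that("roc_auc handles separation, ties and matches pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), c(rep(1, 5), rep(0, 5))), 0.5)
  # 6-point case against exhaustive pair counting
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.4)
  y <- c(0, 0, 1, 1, 0, 1)
  pairs <- 0; total <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    total <- total + 1
    pairs <- pairs + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  expect_equal(roc_auc(s, y), pairs / total)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "one class")
})

test_that("roc_auc agrees with pROC and obeys its invariants", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:80, 1)
    s <- runif(n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    ours <- roc_auc(s, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
    # symmetry and monotone-transform invariance
    expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1, tolerance = 1e-12)
    expect_equal(roc_auc(exp(3 * s), y), ours, tolerance = 1e-12)
  }
})

test_that("pr_auc matches an independent step-by-step recomputation", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 50
    s <- runif(n); y <- rbinom(n, 1, 0.3)
    if (sum(y) %in% c(0, n)) next
    ours <- pr_auc(s, y)
    # independent recomputation: walk thresholds, collect (recall, precision)
    th <- sort(unique(s), decreasing = TRUE)
    pts <- t(vapply(th, function(t) {
      pred <- s >= t
      c(rec = sum(pred & y == 1) / sum(y == 1),
        prec = sum(pred & y == 1) / sum(pred))
    }, c(rec = 0, prec = 0)))
    rec <- c(0, pts[, "rec"]); prec <- c(pts[1, "prec"], pts[, "prec"])
    ref <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("mcc, accuracy and precision follow the textbook formulas", {
  expect_equal(mcc_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(accuracy_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  # confusion (TP,FP,FN,TN) = (1,1,1,1) -> MCC 0
  expect_equal(mcc_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.0)
  expect_equal(mcc_score(c(0, 0), c(1, 0)), 0)  # degenerate denominator
  expect_equal(precision_score(c(0, 0), c(1, 0)), 0)
  set.seed(23)
  for (rep in 1:10) {
    p <- rbinom(50, 1, 0.5); y <- rbinom(50, 1, 0.5)
    tp <- sum(p & y); tn <- sum(!p & !y); fp <- sum(p & !y); fn <- sum(!p & y)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    ref <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(mcc_score(p, y), ref, tolerance = 1e-12)
    expect_equal(accuracy_score(p, y), (tp + tn) / 50, tolerance = 1e-12)
    if (sum(p) > 0) expect_equal(precision_score(p, y), tp / (tp + fp))
  }
})

test_that("recovery rate takes the top 10 percent with documented tie rule", {
  set.seed(24)
  # 30 residues: k = 3; all top-3 true -> recovered
  s <- c(rep(0.9, 3), runif(27, 0, 0.5))
  y <- c(1, 1, 1, rep(0, 27))
  r <- recovery_rate(s, y)
  expect_equal(r$k, 3L)
  expect_equal(r$rate, 1.0)
  expect_true(r$recovered)
  y2 <- c(1, 0, 0, rep(0, 27))
  expect_equal(recovery_rate(s, y2)$rate, 1 / 3)
  # k floors at 1
  expect_equal(recovery_rate(c(0.3, 0.1), c(1, 0))$k, 1L)
  # brute-force sort oracle on random cases
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    s <- round(runif(n), 2)  # provoke ties
    y <- rbinom(n, 1, 0.3)
    r <- recovery_rate(s, y)
    k <- max(1, floor(0.1 * n + 0.5))
    ord <- order(-s, seq_len(n))
    expect_equal(r$k, as.integer(k))
    expect_equal(r$rate, mean(y[ord[1:k]] == 1))
  }
})

test_that("confusion matrix tallies true channel vs argmax prediction", {
  ch <- c("protein", "ion", "ligand")
  lab <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  colnames(lab) <- ch
  perfect <- lab * 0.9 + 0.01
  m <- confusion_by_type(perfect, lab)
  expect_equal(sum(m) - sum(diag(m)), 0)
  expect_equal(diag(m), c(protein = 1, ion = 1, ligand = 1))
  # all mass on channel 1
  allp <- cbind(rep(0.9, 4), 0.1, 0.1); colnames(allp) <- ch
  m2 <- confusion_by_type(allp, lab)
  expect_true(all(m2[, c("ion", "ligand")] == 0))
  # manual tally on a random 10-residue case
  set.seed(25)
  pred <- matrix(runif(30), 10, 3, dimnames = list(NULL, ch))
  lab3 <- matrix(rbinom(30, 1, 0.4), 10, 3, dimnames = list(NULL, ch))
  m3 <- confusion_by_type(pred, lab3)
  ref <- matrix(0, 3, 3, dimnames = list(ch, ch))
  for (r in 1:10) {
    if (max(pred[r, ]) <= 0.5) next
    pc <- which.max(pred[r, ])
    for (tc in which(lab3[r, ] == 1)) ref[tc, pc] <- ref[tc, pc] + 1
  }
  expect_equal(m3, ref)
  mn <- confusion_by_type(pred, lab3, normalize = TRUE)
  expect_true(all(rowSums(mn) <= 1 + 1e-12))
})

test_that("metric report aggregates identical structures consistently", {
  set.seed(26)
  s <- runif(40); y <- rbinom(40, 1, 0.4)
  rep1 <- metric_report(list(s), list(y))
  rep3 <- metric_report(list(s, s, s), list(y, y, y))
  meds <- attr(rep3, "medians")
  expect_equal(unname(meds["roc_auc"]), rep1$roc_auc[1])
  expect_equal(nrow(rep3), 3L)
  expect_true(all(rep3$roc_auc == rep1$roc_auc[1]))
})
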