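# brute-force metric oracles: plain-loop reimplementations of the formulas
oracle_metrics <- function(ya, yp) {
  n <- length(ya)
  num <- sum((ya - mean(ya)) * (yp - mean(yp)))
  r <- num / (sqrt(sum((ya - mean(ya))^2)) * sqrt(sum((yp - mean(yp))^2)))
  ab <- coef(lm(ya ~ yp))
  sdv <- sqrt(sum((ab[2] * yp + ab[1] - ya)^2) / (n - 1))
  num_ci <- 0
  z <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (ya[i] > ya[j]) {
        z <- z + 1
        u <- yp[i] - yp[j]
        num_ci <- num_ci + if (u > 0) 1 else if (u == 0) 0.5 else 0
      }
    }
  }
  list(
    r = r, rmse = sqrt(mean((yp - ya)^2)), mae = mean(abs(yp - ya)),
    sd = sdv, ci = num_ci / z
  )
}

test_that("pearson_r matches hand cases and the formula oracle", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_r(y, y), 1.0)
  expect_equal(pearson_r(y, -y), -1.0)
  yp <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(pearson_r(y, yp), oracle_metrics(y, yp)$r, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1), c(1, 2)), "variance")
})

test_that("rmse and mae use absolute errors", {
  y <- c(5, 5)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  # signed errors +1 and -1: MAE must be 1, not 0
  expect_equal(mae(c(4, 6), c(5, 5)), 1.0)
  expect_equal(rmse(c(4, 6), c(5, 5)), 1.0)
})

test_that("sd_corrected removes any perfect linear relationship", {
  y <- c(1, 2, 3, 5)
  expect_equal(sd_corrected(y, y), 0)
  expect_equal(sd_corrected(y, 2 * y), 0) # slope absorbed
  expect_equal(sd_corrected(y, -3 * y + 7), 0)
  ya <- c(1, 2, 3)
  yp <- c(1, 1, 4)
  expect_equal(sd_corrected(ya, yp), oracle_metrics(ya, yp)$sd, tolerance = 1e-12)
  expect_error(sd_corrected(ya, c(2, 2, 2)), "constant")
})

test_that("concordance index handles ties with h(0) = 0.5", {
  expect_equal(concordance_index(1:5, 1:5 * 2), 1.0)
  expect_equal(concordance_index(1:5, rev(1:5)), 0.0)
  expect_equal(concordance_index(c(1, 2), c(5, 5)), 0.5)
  expect_error(concordance_index(c(3, 3), c(1, 2)), "tied")
})

test_that("all five metrics agree with brute-force oracles on random data", {
  set.seed(7)
  for (n in c(10, 50, 200)) {
    ya <- round(runif(n, 2, 12), 2) # includes ties in y_act
    yp <- ya + rnorm(n)
    o <- oracle_metrics(ya, yp)
    expect_equal(pearson_r(ya, yp), o$r, tolerance = 1e-9)
    expect_equal(rmse(ya, yp), o$rmse, tolerance = 1e-9)
    expect_equal(mae(ya, yp), o$mae, tolerance = 1e-9)
    expect_equal(sd_corrected(ya, yp), o$sd, tolerance = 1e-9)
    expect_equal(concordance_index(ya, yp), o$ci, tolerance = 1e-9)
  }
})

test_that("metrics are invariant to permutation of the samples", {
  set.seed(8)
  ya <- runif(40, 2, 12)
  yp <- ya + rnorm(40)
  p <- sample(40)
  expect_equal(pearson_r(ya, yp), pearson_r(ya[p], yp[p]))
  expect_equal(sd_corrected(ya, yp), sd_corrected(ya[p], yp[p]))
  expect_equal(concordance_index(ya, yp), concordance_index(ya[p], yp[p]))
  expect_equal(roc_auc(yp, ya > 7), roc_auc(yp[p], (ya > 7)[p]))
})

test_that("evaluate_predictions returns the full metric report", {
  set.seed(9)
  df <- data.frame(y_act = runif(30, 2, 12))
  df$y_pred <- df$y_act + rnorm(30, sd = 0.5)
  rep <- evaluate_predictions(df)
  expect_s3_class(rep, "metrics_report")
  expect_named(rep, c("n", "r", "rmse", "mae", "sd", "ci"))
  expect_equal(rep$n, 30L)
  expect_true(rep$r > 0.9 && rep$ci > 0.8)
})

test_that("roc_auc follows the rank statistic with tie handling", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  # exhaustive pair-counting oracle on a worked 6-compound set
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  pairs <- 0
  wins <- 0
  for (i in which(labels)) {
    for (j in which(!labels)) {
      pairs <- pairs + 1
      wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  expect_equal(roc_auc(scores, labels), wins / pairs)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("roc_auc equals the concordance index for binary outcomes", {
  set.seed(10)
  scores <- rnorm(60)
  labels <- runif(60) < 0.4
  expect_equal(roc_auc(scores, labels), concordance_index(as.numeric(labels), scores))
})

test_that("enrichment factor is the ratio of hit rates in the top fraction", {
  scores <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  labels <- c(TRUE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 5))
  # top 10% = 1 compound, which is active: EF = (1/1)/(2/10) = 5
  expect_equal(enrichment_factor(scores, labels, 0.1), 5.0)
  expect_equal(enrichment_factor(scores, labels, 1.0), 1.0)
  # no active in the top 20% after reshuffling scores
  scores2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 10, 9)
  expect_equal(enrichment_factor(scores2, labels, 0.2), 0.0)
  rep <- screening_report(scores, labels)
  expect_length(rep$ef, 10L)
  expect_equal(rep$n_actives, 2L)
})
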