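# Loss and metric arithmetic against closed forms and set-arithmetic oracles.

test_that("cross-entropy matches closed-form values", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(cross_entropy_loss(y, y), 1e-6)             # perfect prediction
  expect_equal(cross_entropy_loss(matrix(0.5, 2, 2), y), log(2),
               tolerance = 1e-9)                        # 0.693147
  expect_equal(cross_entropy_loss(matrix(0.8), matrix(1)), -log(0.8),
               tolerance = 1e-9)                        # 0.223144
  expect_error(cross_entropy_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("dice loss follows the smoothed 1 - soft-dice form", {
  y <- matrix(0, 4, 4); y[1:2, 1:2] <- 1
  expect_lt(dice_loss(y, y), 1e-6)
  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(z, z), 0)                      # 0/0 guarded by eps
  # 4 true pixels, prediction hits exactly 2 of them with probability 1
  p <- matrix(0, 4, 4); p[1:2, 1] <- 1
  expect_equal(dice_loss(p, y), 1 - 2 * 2 / (2 + 4), tolerance = 1e-5)
})

test_that("combined loss interpolates its endpoints linearly", {
  set.seed(401)
  p <- matrix(runif(64), 8, 8)
  y <- random_mask(8, 8)
  ce <- cross_entropy_loss(p, y)
  dl <- dice_loss(p, y)
  expect_equal(combined_loss(p, y, loss_config(lambda = 1)), ce)
  expect_equal(combined_loss(p, y, loss_config(lambda = 0)), dl)
  expect_equal(combined_loss(p, y, loss_config(lambda = 0.5)), (ce + dl) / 2)
  # frozen arithmetic: 0.5 * 0.693147 + 0.5 * 0.333333 = 0.513240
  expect_equal(0.5 * 0.693147 + 0.5 * 0.333333, 0.513240)
  lams <- seq(0, 1, 0.1)
  vals <- vapply(lams, function(l) combined_loss(p, y, loss_config(lambda = l)),
                 numeric(1))
  expect_equal(vals, ce * lams + dl * (1 - lams))       # monotone between ends
  expect_error(loss_config(lambda = 1.2), "lambda")
})

test_that("mask metrics match hand arithmetic and reject non-binary input", {
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1                  # |A| = 4
  b2 <- matrix(0, 4, 4); b2[1, 1:2] <- 1                # |B| = 2, inter = 2
  expect_equal(dice_score(a, a), 1)
  expect_equal(jaccard_score(a, a), 1)
  expect_equal(rvd_score(a, a), 0)
  b4 <- matrix(0, 4, 4); b4[2, 1:4] <- 1                # disjoint
  expect_equal(dice_score(a, b4), 0)
  bX <- matrix(0, 4, 4); bX[1, 1:2] <- 1; bX[2, 1:2] <- 1  # |B|=4, inter=2
  expect_equal(dice_score(a, bX), 0.5)
  expect_equal(jaccard_score(a, bX), 2 / 6, tolerance = 1e-9)
  b6 <- matrix(0, 4, 4); b6[1, 1:4] <- 1; b6[2, 1:2] <- 1  # |B| = 6
  expect_equal(rvd_score(a, b6), 0.5)
  expect_equal(rvd_score(a, b2), -0.5)
  empty <- matrix(0, 4, 4)
  expect_equal(dice_score(empty, empty), 1)
  expect_equal(jaccard_score(empty, empty), 1)
  expect_true(is.na(rvd_score(empty, a)))
  expect_error(dice_score(a * 2, a), "binary")
})

test_that("metric identities hold on 200 seeded random mask pairs", {
  set.seed(402)
  for (i in 1:200) {
    a <- random_mask(32, 32, runif(1, 0.1, 0.9))
    b <- random_mask(32, 32, runif(1, 0.1, 0.9))
    d <- dice_score(a, b)
    j <- jaccard_score(a, b)
    expect_true(j >= 0 && j <= d && d <= 1)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-9)
    # symmetry of overlap metrics; antisymmetric volume relation
    expect_identical(d, dice_score(b, a))
    expect_identical(j, jaccard_score(b, a))
    if (sum(a) > 0 && sum(b) > 0) {
      r_ab <- rvd_score(a, b)
      r_ba <- rvd_score(b, a)
      expect_equal((1 + r_ab) * (1 + r_ba), 1, tolerance = 1e-9)
      expect_false(isTRUE(all.equal(r_ab, r_ba)) && sum(a) != sum(b))
    }
    if (i <= 20) {
      o <- oracle_mask_metrics(a, b)
      expect_equal(d, o$dice)
      expect_equal(j, o$jaccard)
      expect_equal(rvd_score(a, b), o$rvd)
    }
  }
})

test_that("batched loss gradient matches finite differences and per-image components", {
  ns <- asNamespace("scaunet")
  set.seed(403)
  logits <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  y <- array(rbinom(32, 1, 0.5), c(4, 4, 2))
  cfg <- loss_config()
  lg <- ns$combined_loss_grad(logits, y, cfg)
  # scalar value equals the public per-image functions recombined
  probs <- lg$prob
  ce <- cross_entropy_loss(probs, y)
  dl <- mean(c(dice_loss(probs[, , 1], y[, , 1]),
               dice_loss(probs[, , 2], y[, , 2])))
  expect_equal(lg$ce, ce, tolerance = 1e-10)
  expect_equal(lg$dice_loss, dl, tolerance = 1e-10)
  expect_equal(lg$loss, 0.5 * ce + 0.5 * dl, tolerance = 1e-10)
  eps <- 1e-6
  for (i in sample(length(logits), 8)) {
    l2 <- logits; l2[i] <- l2[i] + eps
    up <- ns$combined_loss_grad(l2, y, cfg)$loss
    l2[i] <- l2[i] - 2 * eps
    dn <- ns$combined_loss_grad(l2, y, cfg)$loss
    expect_equal(lg$dlogits[i], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("metrics reports aggregate per-image values and serialise", {
  set.seed(404)
  truths <- replicate(5, random_mask(8, 8), simplify = FALSE)
  preds <- replicate(5, random_mask(8, 8), simplify = FALSE)
  truths[[3]] <- matrix(0, 8, 8)        # empty ground truth -> RVD missing
  rep_ <- metrics_report(truths, preds, ids = paste0("img", 1:5))
  expect_s3_class(rep_, "scau_metrics")
  expect_equal(rep_$dice, mapply(dice_score, truths, preds))
  sm <- glance(rep_)
  expect_equal(sm$mean_dice, mean(rep_$dice))
  expect_equal(sm$n_rvd_missing, 1L)
  expect_equal(sm$mean_rvd, mean(rep_$rvd, na.rm = TRUE))
  dir <- tempfile()
  paths <- write_metrics_report(rep_, dir)
  csv <- utils::read.csv(paths["csv"])
  expect_equal(nrow(csv), 5)
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js$mean_dice, sm$mean_dice)
})
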