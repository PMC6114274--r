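# independent brute-force discrete NB: shares the fitted bins, recomputes
# priors, Laplace-smoothed bin counts and the posterior from scratch
oracle_posterior <- function(instances, space, bit, mbit, alpha = 1) {
  lab <- instances$label
  bin_of <- function(x, cuts) findInterval(x, cuts) + 1L
  nb_b <- length(space$bit_cuts) + 1L
  nb_m <- length(space$mbit_cuts) + 1L
  pr <- c(positive = mean(lab == "positive"),
          negative = mean(lab == "negative"))
  num <- c(positive = NA_real_, negative = NA_real_)
  for (cl in c("positive", "negative")) {
    bi <- bin_of(instances$bit[lab == cl], space$bit_cuts)
    mi <- bin_of(instances$mean_bit[lab == cl], space$mbit_cuts)
    pb <- (sum(bi == bin_of(bit, space$bit_cuts)) + alpha) /
      (length(bi) + alpha * nb_b)
    pm <- (sum(mi == bin_of(mbit, space$mbit_cuts)) + alpha) /
      (length(mi) + alpha * nb_m)
    num[cl] <- pr[cl] * pb * pm
  }
  unname(num["positive"] / sum(num))
}

test_that("MDL discretization separates cleanly split classes", {
  cuts <- discretize(c(1, 2, 18, 19), c("n", "n", "p", "p"))
  expect_identical(length(cuts), 1L)
  expect_gt(cuts, 2)
  expect_lt(cuts, 18)
  # constant input: fallback leaves no interior structure to cut
  expect_length(discretize(rep(5, 10), rep(c("n", "p"), 5)), 0L)
  # cut-points are strictly increasing
  set.seed(12)
  x <- c(rnorm(50, 0), rnorm(50, 6))
  cuts2 <- discretize(x, rep(c("n", "p"), each = 50))
  expect_true(all(diff(cuts2) > 0))
})

test_that("fit_space separates well-separated classes and records the bound", {
  inst <- data.frame(bit = c(30, 32, 2, 3), mean_bit = c(3, 3.2, 0.3, 0.2),
                     label = c("positive", "positive", "negative",
                               "negative"))
  sp <- fit_space(inst)
  expect_equal(sum(sp$priors), 1)
  expect_equal(sp$min_neg_bit, 2)
  # with 2+2 points and alpha = 1 the separated-side posterior is exactly
  # 0.5 * 0.75^2 / (0.5 * 0.75^2 + 0.5 * 0.25^2) = 0.9
  expect_gte(posterior(sp, 31, 3.1), 0.9)
  expect_lte(posterior(sp, 2.5, 0.25), 0.1)
  # conditional tables are distributions per class
  expect_equal(colSums(sp$cond_bit), c(positive = 1, negative = 1))
  expect_equal(colSums(sp$cond_mbit), c(positive = 1, negative = 1))
})

test_that("posterior equals the brute-force oracle on small training sets", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    lab <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("positive", "negative")
    inst <- data.frame(
      bit = round(stats::rnorm(n, ifelse(lab == "positive", 20, 5), 4), 2),
      mean_bit = round(stats::rnorm(n, ifelse(lab == "positive", 2, .5),
                                    .4), 2),
      label = lab)
    sp <- fit_space(inst)
    for (q in list(c(25, 2.5), c(1, 0.1), c(12, 1), c(-50, 9))) {
      expect_equal(posterior(sp, q[1], q[2]),
                   oracle_posterior(inst, sp, q[1], q[2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("posterior agrees with an independent discrete NB implementation", {
  skip_if_not_installed("e1071")
  set.seed(14)
  n <- 60
  lab <- rep(c("positive", "negative"), each = n / 2)
  inst <- data.frame(bit = rnorm(n, ifelse(lab == "positive", 20, 6), 3),
                     mean_bit = rnorm(n, ifelse(lab == "positive", 2, .6),
                                      .3),
                     label = lab)
  sp <- fit_space(inst)
  nb_bins <- length(sp$bit_cuts) + 1L
  mb_bins <- length(sp$mbit_cuts) + 1L
  fb <- factor(findInterval(inst$bit, sp$bit_cuts) + 1L,
               levels = seq_len(nb_bins))
  fm <- factor(findInterval(inst$mean_bit, sp$mbit_cuts) + 1L,
               levels = seq_len(mb_bins))
  fit <- e1071::naiveBayes(data.frame(b = fb, m = fm),
                           factor(lab, levels = c("negative", "positive")),
                           laplace = 1)
  qb <- c(22, 4, 13)
  qm <- c(2.2, 0.4, 1.2)
  newd <- data.frame(
    b = factor(findInterval(qb, sp$bit_cuts) + 1L,
               levels = seq_len(nb_bins)),
    m = factor(findInterval(qm, sp$mbit_cuts) + 1L,
               levels = seq_len(mb_bins)))
  want <- predict(fit, newd, type = "raw")[, "positive"]
  expect_equal(posterior(sp, qb, qm), unname(want), tolerance = 1e-9)
})

test_that("posteriors are proper probabilities with symmetric behaviour", {
  set.seed(15)
  # identical positive and negative distributions: posterior ~ 0.5
  x <- rnorm(40, 10, 2); m <- rnorm(40, 1, .2)
  inst <- data.frame(bit = c(x, x), mean_bit = c(m, m),
                     label = rep(c("positive", "negative"), each = 40))
  sp <- fit_space(inst)
  p <- posterior(sp, c(10, 5, 15, -100, 100), c(1, .5, 1.5, -10, 10))
  expect_equal(p, rep(0.5, 5), tolerance = 1e-9)
  # boundary bins: far outside the range still defined in [0, 1]
  sp2 <- fit_space(data.frame(bit = c(30, 31, 2, 3),
                              mean_bit = c(3, 3, .2, .3),
                              label = c("positive", "positive",
                                        "negative", "negative")))
  pp <- posterior(sp2, c(-1e6, 1e6), c(-1e6, 1e6))
  expect_true(all(pp >= 0 & pp <= 1))
  # single-class input is unlearnable
  expect_error(fit_space(data.frame(bit = 1:3, mean_bit = 1:3,
                                    label = "positive")), "unlearnable")
})

test_that("posterior is stable under duplicating the training set", {
  set.seed(16)
  lab <- rep(c("positive", "negative"), each = 25)
  inst <- data.frame(bit = rnorm(50, ifelse(lab == "positive", 18, 5), 3),
                     mean_bit = rnorm(50, ifelse(lab == "positive", 2, .5),
                                      .3),
                     label = lab)
  sp1 <- fit_space(inst)
  sp2 <- fit_space(rbind(inst, inst))
  # with the same bins, duplication only attenuates the Laplace smoothing
  # (counts and bin totals double while +1 stays fixed) and the MDL
  # criterion may refine bins, so invariance is approximate, not exact
  q <- seq(0, 25, length.out = 11)
  expect_equal(posterior(sp1, q, q / 10), posterior(sp2, q, q / 10),
               tolerance = 0.05)
  # with smoothing disabled and bins frozen it is exact
  sp1a <- fit_space(inst, alpha = 1e-12)
  sp2a <- fit_space(rbind(inst, inst), alpha = 1e-12)
  if (identical(sp1a$bit_cuts, sp2a$bit_cuts) &&
      identical(sp1a$mbit_cuts, sp2a$mbit_cuts)) {
    expect_equal(posterior(sp1a, q, q / 10), posterior(sp2a, q, q / 10),
                 tolerance = 1e-9)
  }
})

test_that("well-separated Gaussian classes are classified accurately", {
  set.seed(17)
  n <- 500
  train <- data.frame(
    bit = c(rnorm(n, 30, 3), rnorm(n, 12, 3)),
    mean_bit = c(rnorm(n, 3, .3), rnorm(n, 1.2, .3)),
    label = rep(c("positive", "negative"), each = n))
  test <- data.frame(
    bit = c(rnorm(n, 30, 3), rnorm(n, 12, 3)),
    mean_bit = c(rnorm(n, 3, .3), rnorm(n, 1.2, .3)),
    label = rep(c("positive", "negative"), each = n))
  sp <- fit_space(train)
  pred <- ifelse(posterior(sp, test$bit, test$mean_bit) > 0.5,
                 "positive", "negative")
  expect_gte(mean(pred == test$label), 0.95)
  # 1-D consistency: smallest bit with high posterior (at a typical
  # positive-class mean-bit) lies above the bit-score lower bound
  bits <- seq(min(train$bit), max(train$bit), length.out = 400)
  hi <- bits[posterior(sp, bits, 3) > 0.9]
  expect_gt(length(hi), 0L)
  expect_gt(min(hi), sp$min_neg_bit)
})

test_that("probability spaces round-trip through the JSON store", {
  set.seed(18)
  lab <- rep(c("positive", "negative"), each = 10)
  tr <- data.frame(domain_acc = "PF1", model_type = "SCM",
                   bit = rnorm(20, ifelse(lab == "positive", 20, 5), 2),
                   mean_bit = rnorm(20, ifelse(lab == "positive", 2, .5),
                                    .2),
                   label = lab)
  tr2 <- tr; tr2$model_type <- "CCM"
  spaces <- fit_spaces(rbind(tr, tr2))
  expect_identical(names(spaces), c("PF1/CCM", "PF1/SCM"))
  tf <- withr::local_tempfile(fileext = ".json")
  save_spaces(spaces, tf)
  back <- load_spaces(tf)
  expect_identical(names(back), names(spaces))
  for (k in names(spaces)) {
    expect_equal(back[[k]]$bit_cuts, spaces[[k]]$bit_cuts)
    expect_equal(back[[k]]$cond_bit, spaces[[k]]$cond_bit)
    expect_equal(back[[k]]$priors, spaces[[k]]$priors)
    expect_equal(back[[k]]$min_neg_bit, spaces[[k]]$min_neg_bit)
    q <- c(3, 18); qm <- c(.4, 2.1)
    expect_equal(posterior(back[[k]], q, qm), posterior(spaces[[k]], q, qm),
                 tolerance = 1e-12)
  }
  # corrupt / mismatched stores are rejected
  writeLines("{not json", tf)
  expect_error(load_spaces(tf))
  jsonlite::write_json(list(format = "other_v9", spaces = list()), tf,
                       auto_unbox = TRUE)
  expect_error(load_spaces(tf), "version mismatch")
})
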