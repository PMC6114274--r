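# independent brute-force enumerator of the terminal ladder
oracle_ladder <- function(len, params = fragment_params()) {
  L <- if (len < 15) params$L_small else if (len <= 75) params$L_mid
       else params$L_large
  M <- min(params$max_frac * len, params$max_len)
  N <- 1L
  while (M > N * L) N <- N + 1L
  pmin(seq_len(N) * L, len)
}

test_that("terminal fragment ladders follow the length-class rules", {
  expect_identical(terminal_fragment_lengths(100), c(10L, 20L, 30L))
  expect_identical(terminal_fragment_lengths(10), c(1L, 2L, 3L))
  expect_identical(terminal_fragment_lengths(300),
                   as.integer(seq(10, 90, by = 10)))
  # 100-aa domain: 6 terminal fragments, no internal ones
  set.seed(1)
  f100 <- generate_positive_fragments(rand_aa(100))
  expect_identical(nrow(f100), 6L)
  expect_identical(sort(unique(f100$kind)), c("prefix", "suffix"))
  # 300-aa domain: 18 terminal + 10 internal
  f300 <- generate_positive_fragments(rand_aa(300))
  expect_identical(sum(f300$kind != "internal"), 18L)
  expect_identical(sum(f300$kind == "internal"), 10L)
})

test_that("terminal ladders match the brute-force enumerator for lengths 2-500", {
  for (len in 2:500) {
    expect_identical(terminal_fragment_lengths(len), oracle_ladder(len),
                     info = paste("len", len))
  }
})

test_that("internal fragments stay inside the uncovered middle region", {
  set.seed(2)
  len <- 400L
  f <- generate_positive_fragments(rand_aa(len))
  internal <- f[f$kind == "internal", ]
  expect_identical(nrow(internal), 10L)
  covered <- max(terminal_fragment_lengths(len))
  expect_true(all(internal$start > covered))
  expect_true(all(internal$end <= len - covered))
  expect_true(all(internal$end >= internal$start))
  expect_true(all(nchar(f$fragment) == f$end - f$start + 1L))
})

test_that("the raw internal-length sampler is centred near 50", {
  set.seed(3)
  lens <- internal_fragment_lengths(10000L)
  expect_lt(abs(mean(lens) - 50), 1)
  expect_true(all(lens >= 1L))
})

test_that("simple decoys are the 2-mer shuffle and the reversal", {
  expect_identical(generate_simple_decoys("ABCD")[2], "DCBA")
  set.seed(4)
  shuffles <- replicate(20, generate_simple_decoys("ABCD")[1])
  expect_true(all(shuffles %in% c("ABCD", "CDAB")))
  expect_true(all(c("ABCD", "CDAB") %in% shuffles))
  # odd trailing residue stays last
  odd <- replicate(10, generate_simple_decoys("ABCDE")[1])
  expect_true(all(substr(odd, 5, 5) == "E"))
})

test_that("2-mer shuffling preserves the non-overlapping 2-mer multiset", {
  set.seed(5)
  for (i in 1:10) {
    s <- rand_aa(sample(6:20, 1))
    d <- generate_simple_decoys(s)[1]
    mers <- function(x) {
      n2 <- nchar(x) %/% 2L
      sort(substring(x, seq(1, by = 2, length.out = n2),
                     seq(2, by = 2, length.out = n2)))
    }
    expect_identical(mers(d), mers(s))
    expect_identical(nchar(d), nchar(s))
  }
})

test_that("Markov emission covers the 160,000-tuple space and is a distribution", {
  m0 <- fit_markov3("AC", W = 1)  # too short: no counts
  expect_identical(length(m0$emission), 160000L)
  expect_equal(m0$emission, rep(1 / 160000, 160000), tolerance = 1e-12)
  # one tuple observed 9 times: AAAA in a run of 12 A's
  m1 <- fit_markov3(strrep("A", 12), W = 1)
  expect_identical(m1$N, 9L)
  expect_equal(m1$emission[1L], 10 / 160009, tolerance = 1e-12)
  for (W in c(1, 10, 57)) {
    m <- fit_markov3(c("MKVLMKVL", "ACDEFGHIK"), W = W)
    expect_equal(sum(m$emission), 1, tolerance = 1e-9)
    expect_true(all(m$emission > 0))
  }
})

test_that("Markov decoys are reproducible and biased toward domain tuples", {
  seqs <- replicate(5, rand_aa(60))
  set.seed(6)
  d1 <- sample_markov_decoys(fit_markov3(seqs, W = 50), c(30L, 40L))
  set.seed(6)
  d2 <- sample_markov_decoys(fit_markov3(seqs, W = 50), c(30L, 40L))
  expect_identical(d1, d2)
  expect_identical(nchar(d1), c(30L, 40L))
})

test_that("negative-generation planning follows the 50% rule", {
  p <- plan_negative_generation(100)
  expect_identical(p$required, 50L)
  p2 <- plan_negative_generation(100, 10)
  expect_identical(p2$deficit, 40L)
  expect_identical(p2$decoy_budget, as.integer(ceiling(40 / 5e-4)))
  p3 <- plan_negative_generation(100, 10, model_type = "CCM")
  expect_identical(p3$decoy_budget, as.integer(ceiling(40 / 5e-3)))
  p4 <- plan_negative_generation(100, 60)
  expect_identical(p4$deficit, 0L)
  expect_identical(p4$decoy_budget, 0L)
  expect_identical(plan_negative_generation(101)$required, 51L)
  expect_error(plan_negative_generation(0), "n_pos")
})

test_that("select_negatives dedupes points and keeps the most distant", {
  inst <- data.frame(domain_acc = "d", model_type = "SCM",
                     bit = c(3, 4, 3, 0, 5),
                     mean_bit = c(4, 0, 4, 3, 0),
                     label = "negative")
  sel <- select_negatives(inst, 10)
  expect_identical(nrow(sel), 4L)  # one duplicate (3,4) removed
  d <- sqrt(sel$bit^2 + sel$mean_bit^2)
  expect_true(all(diff(d) <= 0))
  sel2 <- select_negatives(inst, 2)
  expect_identical(nrow(sel2), 2L)
  expect_equal(sqrt(sel2$bit^2 + sel2$mean_bit^2), c(5, 5))
  expect_identical(nrow(select_negatives(NULL, 5)), 0L)
})

test_that("screen_decoy applies the per-model-class acceptance rules", {
  set.seed(7)
  st <- small_domain_setup(len = 80, n_clades = 1L, n_cal = 100L)
  # the consensus itself must be accepted by the SCM (bit > 0) and the CCM
  inst <- screen_decoy(st$fam$consensus, st$dm)
  expect_true("SCM" %in% inst$model_type)
  expect_true(all(inst$label == "negative"))
  expect_true(all(inst$bit[inst$model_type == "SCM"] > 0))
  expect_lte(sum(inst$model_type == "CCM"), 1L)  # best CCM only
  # an all-mismatch decoy is rejected
  none <- screen_decoy(strrep("W", 60), st$dm)
  expect_identical(nrow(none), 0L)
})

test_that("weight calibration walks W upward and reports failures", {
  set.seed(8)
  seqs <- replicate(4, rand_aa(40))
  # permissive SCM: anything scores positive -> rate immediately in range
  easy <- build_pssm(rep(strrep("A", 12), 3), pseudocount = 0.5)
  easy$log_odds[] <- abs(easy$log_odds)  # force positive scores
  easy$lo_rev <- easy$log_odds[12:1, ]
  cal <- calibrate_markov_weight(seqs, easy, W0 = 10, batch = 20L,
                                 accept_min = 1L, accept_max = 20L)
  expect_equal(cal$W, 10)
  expect_gte(cal$rate, 1L)
  # impossible SCM: nothing ever accepted -> calibration failure
  hard <- easy
  hard$log_odds[] <- -50
  hard$lo_rev[] <- -50
  expect_error(
    calibrate_markov_weight(seqs, hard, W0 = 10, batch = 10L, max_W = 12),
    "calibration failed")
})

test_that("build_training_set yields labelled, deduplicated instances per class", {
  set.seed(9)
  st <- small_domain_setup(len = 90, n_clades = 2L, n_cal = 100L)
  tr <- build_training_set(family_seed_rows(st$fam), st$dm,
                           max_decoys = 400L)
  expect_setequal(unique(tr$label), c("positive", "negative"))
  for (ty in c("SCM", "CCM")) {
    sub <- tr[tr$model_type == ty, ]
    np <- sum(sub$label == "positive"); nn <- sum(sub$label == "negative")
    expect_gt(np, 0)
    expect_gt(nn, 0)
    expect_lte(nn, np)       # negatives capped at the positive count
    key <- paste(sub$bit, sub$mean_bit, sub$label)
    expect_identical(anyDuplicated(key), 0L)
  }
})

test_that("an unlearnable domain (hopeless models) raises an error", {
  set.seed(10)
  p <- conserved_pssm(30)
  p$log_odds[] <- -50
  p$lo_rev[] <- -50
  dm <- list(domain_acc = "BAD", scm_profile = p,
             ccm_profiles = list(), ccm_thresholds = numeric())
  expect_error(build_training_set(replicate(3, rand_aa(40)), dm),
               "unlearnable")
})
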