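test_that("filter 1 removes only mutually-85%-overlapping same-domain hits", {
  p <- selection_params()
  # overlap 91 covers 91% and 100% of the two hits: keep the higher bit
  h <- make_hits("r1", "PF1", c("m1", "m2"), "SCM",
                 ali_start = c(1L, 10L), ali_end = c(100L, 100L),
                 bit_score = c(50, 40))
  out <- filter1_dedupe_same_domain(h, p)
  expect_identical(out$model_id, "m1")
  # overlap 21/100 < 0.85: two occurrences of the same domain are kept
  h2 <- make_hits("r1", "PF1", c("m1", "m2"), "SCM",
                  ali_start = c(1L, 80L), ali_end = c(100L, 180L),
                  bit_score = c(50, 40))
  expect_identical(nrow(filter1_dedupe_same_domain(h2, p)), 2L)
  # different domains never interact
  h3 <- make_hits("r1", c("PF1", "PF2"), c("m1", "m2"), "SCM",
                  ali_start = c(1L, 1L), ali_end = c(100L, 100L),
                  bit_score = c(50, 40))
  expect_identical(nrow(filter1_dedupe_same_domain(h3, p)), 2L)
  # CCM and SCM partitions are processed independently
  h4 <- make_hits("r1", "PF1", c("m1", "m2"), c("SCM", "CCM"),
                  ali_start = c(1L, 1L), ali_end = c(100L, 100L),
                  bit_score = c(50, 40))
  expect_identical(nrow(filter1_dedupe_same_domain(h4, p)), 2L)
})

test_that("filter 1 is idempotent and leaves no redundant pair", {
  set.seed(22)
  p <- selection_params()
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    s <- sample(1:60, n, replace = TRUE)
    h <- make_hits("r1", sample(c("PF1", "PF2"), n, TRUE),
                   paste0("m", 1:n),
                   sample(c("SCM", "CCM"), n, TRUE),
                   ali_start = s, ali_end = s + sample(10:50, n, TRUE),
                   bit_score = round(runif(n, 1, 60), 1))
    f1 <- filter1_dedupe_same_domain(h, p)
    expect_lte(nrow(f1), nrow(h))
    expect_equal(filter1_dedupe_same_domain(f1, p), f1)
    # no surviving same-domain same-class pair overlaps >= 85% of both
    if (nrow(f1) > 1) {
      for (i in 1:(nrow(f1) - 1)) for (j in (i + 1):nrow(f1)) {
        if (f1$domain_acc[i] != f1$domain_acc[j] ||
            f1$model_type[i] != f1$model_type[j]) next
        ov <- max(0, min(f1$ali_end[i], f1$ali_end[j]) -
                    max(f1$ali_start[i], f1$ali_start[j]) + 1)
        li <- f1$ali_end[i] - f1$ali_start[i] + 1
        lj <- f1$ali_end[j] - f1$ali_start[j] + 1
        expect_false(ov >= 0.85 * li && ov >= 0.85 * lj)
      }
    }
  }
})

test_that("filter 2 enforces strict posterior and lower-bound cuts", {
  sp <- list("PF1/SCM" = toy_space(min_neg_bit = 2))
  p <- selection_params(prob_threshold = 0.9)
  hi <- make_hits("r1", "PF1", "m1", "SCM", 1L, 20L, bit_score = 50)
  hi$mean_bit_score <- 2.5
  out <- filter2_probability(hi, sp, p)
  expect_identical(nrow(out), 1L)
  expect_gt(out$posterior, 0.9)
  # bit exactly at the lower bound is dropped (strict >)
  at <- hi; at$bit_score <- 2; at$mean_bit_score <- 2
  expect_identical(nrow(filter2_probability(at, sp, p)), 0L)
  # posterior at most the threshold is dropped
  lo <- hi; lo$bit_score <- 5; lo$mean_bit_score <- 0.5
  expect_identical(nrow(filter2_probability(lo, sp, p)), 0L)
  # missing space: dropped with a warning
  other <- hi; other$domain_acc <- "PF9"
  expect_warning(out2 <- filter2_probability(other, sp, p), "PF9")
  expect_identical(nrow(out2), 0L)
})

test_that("the 0.85 probability threshold variant is honoured", {
  sp <- list("PF1/SCM" = toy_space(p_hi = 0.88, min_neg_bit = 0))
  hi <- make_hits("r1", "PF1", "m1", "SCM", 1L, 20L, bit_score = 50)
  hi$mean_bit_score <- 2.5
  # posterior ~0.88: rejected at 0.90, accepted at 0.85
  expect_identical(nrow(filter2_probability(hi, sp, selection_params())), 0L)
  expect_identical(
    nrow(filter2_probability(hi, sp,
                             selection_params(prob_threshold = 0.85))), 1L)
})

test_that("filter 3 ranking and 10-residue rule match its worked examples", {
  p <- selection_params()
  # sharing 12 residues: only the higher-ranked hit survives
  h <- make_hits("r1", c("PF1", "PF2"), c("m1", "m2"), "SCM",
                 ali_start = c(1L, 19L), ali_end = c(30L, 48L),
                 bit_score = c(50, 40), posterior = c(0.95, 0.92))
  h$identity_pct <- c(95, 87)
  out <- filter3_rank_resolve(h, p)
  expect_identical(out$model_id, "m1")
  # sharing exactly 9 residues: both survive, sorted by start
  h2 <- make_hits("r1", c("PF1", "PF2"), c("m2", "m1"), "SCM",
                  ali_start = c(22L, 1L), ali_end = c(48L, 30L),
                  bit_score = c(40, 50), posterior = c(0.92, 0.95))
  out2 <- filter3_rank_resolve(h2, p)
  expect_identical(out2$model_id, c("m1", "m2"))
  expect_identical(out2$ali_start, c(1L, 22L))
  # single hit survives and gets its ranking score
  single <- filter3_rank_resolve(h[1, ], p)
  expect_equal(single$ranking_score, 0.95 * 0.95)
})

test_that("filter 3 agrees with a greedy oracle on exhaustive small instances", {
  set.seed(23)
  p <- selection_params()
  for (rep in 1:40) {
    n <- sample(1:5, 1)
    s <- sample(1:50, n, replace = TRUE)
    h <- make_hits("r1", paste0("PF", 1:n), paste0("m", 1:n), "SCM",
                   ali_start = s, ali_end = s + sample(8:30, n, TRUE),
                   bit_score = round(runif(n, 5, 60), 2),
                   posterior = round(runif(n, 0.9, 1), 3))
    h$identity_pct <- round(runif(n, 40, 100), 1)
    out <- filter3_rank_resolve(h, p)
    expect_identical(sort(out$model_id), oracle_filter3(h))
    # pairwise overlap among survivors is at most 9 residues
    if (nrow(out) > 1) {
      for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
        ov <- max(0, min(out$ali_end[i], out$ali_end[j]) -
                    max(out$ali_start[i], out$ali_start[j]) + 1)
        expect_lte(ov, 9L)
      }
    }
  }
})

test_that("annotating a read with one planted fragment yields one correct hit", {
  set.seed(24)
  st <- small_domain_setup(len = 90, n_clades = 1L, n_cal = 100L)
  tr <- build_training_set(family_seed_rows(st$fam), st$dm,
                           max_decoys = 400L)
  spaces <- fit_spaces(tr)
  frag <- substr(st$fam$consensus, 20, 55)
  read <- paste0(rand_aa(12), frag, rand_aa(12))
  ann <- annotate_read(read, st$lib, spaces, read_id = "readA")
  expect_identical(unique(ann$domain_acc), "SYN00001")
  expect_gte(nrow(ann), 1L)
  expect_identical(ann$read_id[1], "readA")
  # a pure-background read annotates to nothing
  empty <- annotate_read(rand_aa(60), st$lib, spaces, read_id = "bg")
  expect_identical(nrow(empty), 0L)
  # filters never increase the hit count
  raw <- scan_library(st$lib, c(readA = read))
  expect_lte(nrow(ann), nrow(raw))
})

test_that("combining annotations only rescues unannotated reads", {
  a <- make_hits("r1", "PF1", "m1", "SCM", 1L, 20L, 50)
  b <- rbind(make_hits("r1", "PF2", "m2", "SCM", 1L, 20L, 40),
             make_hits("r2", "PF3", "m3", "SCM", 5L, 25L, 30))
  comb <- combine_annotations(a, b)
  expect_identical(sort(unique(comb$read_id)), c("r1", "r2"))
  expect_identical(comb$domain_acc[comb$read_id == "r1"], "PF1")
  expect_identical(comb$domain_acc[comb$read_id == "r2"], "PF3")
  expect_gte(nrow(comb), nrow(a))
  # empty secondary leaves the primary untouched
  expect_equal(combine_annotations(a, empty_annotation()),
               cladescan:::as_annotation(a))
  # duplicated identical rows are rejected
  expect_error(combine_annotations(rbind(a, a), b), "duplicated")
})
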