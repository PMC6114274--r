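# shared fixture builders; all randomness under the caller's seed

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# a strongly conserved pssm from n identical rows of a random consensus
conserved_pssm <- function(len, n = 5L, pseudocount = 0.5) {
  cons <- rand_aa(len)
  build_pssm(rep(cons, n), pseudocount)
}

# minimal annotation-format hit table
make_hits <- function(read_id, domain_acc, model_id, model_type,
                      ali_start, ali_end, bit_score,
                      identity_pct = 100, posterior = NA_real_) {
  n <- length(ali_start)
  data.frame(read_id = rep_len(read_id, n),
             domain_acc = rep_len(domain_acc, n),
             model_id = rep_len(model_id, n),
             model_type = rep_len(model_type, n),
             ali_start = as.integer(ali_start),
             ali_end = as.integer(ali_end),
             bit_score = bit_score,
             mean_bit_score = bit_score / (ali_end - ali_start + 1),
             evalue = NA_real_,
             identity_pct = rep_len(identity_pct, n),
             posterior = rep_len(posterior, n),
             ranking_score = NA_real_,
             source_tool = "test",
             stringsAsFactors = FALSE)
}

# hand-built probability space: the bit axis is informative (posterior
# p_hi above the cut, 1 - p_hi below), the mean-bit axis uninformative
toy_space <- function(domain_acc = "PF00001", model_type = "SCM",
                      bit_cut = 10, mbit_cut = 1, min_neg_bit = 2,
                      p_hi = 0.95) {
  nm <- list(NULL, c("positive", "negative"))
  structure(list(domain_acc = domain_acc, model_type = model_type,
                 bit_cuts = bit_cut, mbit_cuts = mbit_cut,
                 priors = c(positive = 0.5, negative = 0.5),
                 cond_bit = matrix(c(1 - p_hi, p_hi, p_hi, 1 - p_hi),
                                   nrow = 2, dimnames = nm),
                 cond_mbit = matrix(0.5, nrow = 2, ncol = 2,
                                    dimnames = nm),
                 min_neg_bit = min_neg_bit, n_pos = 10L, n_neg = 10L,
                 alpha = 1),
            class = "prob_space")
}

# small synthetic family + per-domain model bundle, cheap enough for units
small_domain_setup <- function(len = 90, n_clades = 2L, n_cal = 150L) {
  fam <- make_family(len, n_seed = 6L, n_clades = n_clades,
                     domain_acc = "SYN00001")
  lib <- make_library(list(fam))
  dm <- prepare_domain_models(lib, "SYN00001", n_cal = n_cal)
  list(fam = fam, lib = lib, dm = dm)
}

family_seed_rows <- function(fam) {
  c(fam$seed_rows, unlist(lapply(fam$clades, `[[`, "subseed")))
}

# independent greedy oracle for the ranking-score overlap resolution
oracle_filter3 <- function(hits, shared = 10L) {
  rank <- hits$posterior * ifelse(is.na(hits$identity_pct), 100,
                                  hits$identity_pct) / 100
  ord <- order(-rank, -hits$bit_score, hits$model_id, hits$ali_start)
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      ov <- max(0, min(hits$ali_end[i], hits$ali_end[j]) -
                  max(hits$ali_start[i], hits$ali_start[j]) + 1)
      if (ov >= shared) ok <- FALSE
    }
    if (ok) kept <- c(kept, i)
  }
  sort(hits$model_id[kept])
}
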