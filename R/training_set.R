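#' Parameters of the positive-fragment generator
#'
#' Defaults encode the fragment construction rules: terminal prefixes and
#' suffixes up to `M = min(max_frac * len, max_len)` in steps of `L`
#' (`L` = 1 aa for domains shorter than 15 aa, 5 aa for 15-75 aa, 10 aa
#' above 75 aa), plus, for domains longer than `internal_threshold` (270 aa),
#' `internal_count` internal fragments with lengths drawn from
#' Normal(`internal_mean`, `internal_sd`).
#'
#' @param max_frac Maximum fragment size as a fraction of the domain length.
#' @param max_len Absolute maximum terminal fragment size (aa).
#' @param L_small,L_mid,L_large Ladder step (aa) for domains of length
#'   < 15, 15-75 and > 75 respectively.
#' @param internal_threshold Domain length (aa) above which internal
#'   fragments are added.
#' @param internal_count Number of internal fragments.
#' @param internal_mean,internal_sd Normal parameters of the raw internal
#'   fragment length (aa).
#' @return A list of class `fragment_params`.
#' @export
fragment_params <- function(max_frac = 0.30, max_len = 100,
                            L_small = 1L, L_mid = 5L, L_large = 10L,
                            internal_threshold = 270L, internal_count = 10L,
                            internal_mean = 50, internal_sd = 25) {
  stopifnot(max_frac > 0, max_frac <= 1, max_len > 0,
            L_small > 0, L_mid > 0, L_large > 0,
            internal_threshold > 0, internal_count >= 0,
            internal_mean > 0, internal_sd > 0)
  structure(list(max_frac = max_frac, max_len = max_len, L_small = L_small,
                 L_mid = L_mid, L_large = L_large,
                 internal_threshold = internal_threshold,
                 internal_count = internal_count,
                 internal_mean = internal_mean, internal_sd = internal_sd),
            class = "fragment_params")
}

# ladder step for a domain of the given length
ladder_step <- function(len, params) {
  if (len < 15) params$L_small
  else if (len <= 75) params$L_mid
  else params$L_large
}

#' Terminal fragment lengths for a domain length
#'
#' The ladder of prefix/suffix lengths `n * L`, n = 1..N, where N is the
#' smallest integer with `M <= N * L` and `M = min(max_frac * len, max_len)`.
#'
#' @param len Domain length (aa).
#' @param params A [fragment_params()] list.
#' @return Integer vector of fragment lengths (used at each end).
#' @export
terminal_fragment_lengths <- function(len, params = fragment_params()) {
  L <- ladder_step(len, params)
  M <- min(params$max_frac * len, params$max_len)  # kept fractional
  N <- ceiling(M / L)
  if (N < 1) N <- 1
  as.integer(pmin(seq_len(N) * L, len))
}

#' Generate positive training fragments from one domain sequence
#'
#' Produces prefixes and suffixes of the ladder lengths (see
#' [terminal_fragment_lengths()]); for domains longer than
#' `params$internal_threshold`, additionally `params$internal_count`
#' internal fragments whose start positions are drawn uniformly along the
#' middle region not covered by the terminal ladders and whose raw lengths
#' are drawn from Normal(`internal_mean`, `internal_sd`), rounded and
#' clipped to at least 1 and at most the span remaining in the middle
#' region. Uses the session RNG; call `set.seed()` for reproducibility.
#'
#' @param seq Ungapped amino-acid string of length >= 2.
#' @param params A [fragment_params()] list.
#' @return Data frame with columns `start`, `end`, `kind`
#'   (`prefix`/`suffix`/`internal`) and `fragment` (the subsequence).
#' @export
generate_positive_fragments <- function(seq, params = fragment_params()) {
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len < 2L) stop("sequence too short for fragment generation: ", len)
  lens <- terminal_fragment_lengths(len, params)
  starts <- c(rep(1L, length(lens)), len - lens + 1L)
  ends <- c(lens, rep(len, length(lens)))
  kind <- rep(c("prefix", "suffix"), each = length(lens))
  if (len > params$internal_threshold && params$internal_count > 0L) {
    covered <- max(lens)
    mid_start <- covered + 1L
    mid_end <- len - covered
    if (mid_end >= mid_start) {
      for (i in seq_len(params$internal_count)) {
        s <- sample.int(mid_end - mid_start + 1L, 1L) + mid_start - 1L
        raw <- round(stats::rnorm(1L, params$internal_mean,
                                  params$internal_sd))
        l <- max(1L, min(raw, mid_end - s + 1L))
        starts <- c(starts, s)
        ends <- c(ends, s + l - 1L)
        kind <- c(kind, "internal")
      }
    }
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             kind = kind,
             fragment = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

#' Draw a raw internal fragment length
#'
#' The Normal(mean 50, sd 25) sampler behind internal fragments, exposed so
#' its distribution can be examined: rounded to the nearest integer with a
#' minimum of 1 (clipping to the available span happens at generation time).
#'
#' @param n Number of draws.
#' @param params A [fragment_params()] list.
#' @return Integer vector of lengths.
#' @export
internal_fragment_lengths <- function(n, params = fragment_params()) {
  pmax(1L, as.integer(round(stats::rnorm(n, params$internal_mean,
                                         params$internal_sd))))
}

#' Simple decoys: 2-mer shuffle and reversal
#'
#' Decoy 1 concatenates the sequence's non-overlapping 2-mers in a random
#' permutation (an odd trailing residue stays last); decoy 2 is the reversed
#' sequence. Both preserve the residue multiset.
#'
#' @param seq Amino-acid string of length >= 2.
#' @return Character vector of length 2: `c(shuffle, reversal)`.
#' @export
generate_simple_decoys <- function(seq) {
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len < 2L) stop("sequence too short for decoy generation: ", len)
  n2 <- len %/% 2L
  mers <- substring(seq, seq(1L, by = 2L, length.out = n2),
                    seq(2L, by = 2L, length.out = n2))
  tail <- if (len %% 2L == 1L) substr(seq, len, len) else ""
  shuffle <- paste0(paste(mers[sample.int(n2)], collapse = ""), tail)
  reversal <- paste(rev(strsplit(seq, "")[[1L]]), collapse = "")
  c(shuffle, reversal)
}

# linear index of 4-tuples: i1 + 20(i2-1) + 400(i3-1) + 8000(i4-1)
TUPLE_SPACE <- 20L^4L

#' Fit an order-3 Markov decoy model from domain sequences
#'
#' Counts all overlapping amino-acid 4-tuples of the input sequences over
#' the full 20^4 = 160,000-tuple space. The emission probability of a tuple
#' with count `n` is `((n + 1) * W) / (160000 + N * W)` where `N` is the
#' total tuple count, renormalised to sum to one over the tuple space (the
#' raw form is a distribution only at `W = 1`; renormalisation preserves the
#' odds ratios). Sampling treats the model as a stationary order-3 chain:
#' the first three residues come from the marginal 3-prefix distribution of
#' the emission, subsequent residues from the conditional next-residue
#' distribution.
#'
#' @param seed_seqs Character vector of (ungapped) amino-acid sequences;
#'   sequences shorter than 4 residues contribute no counts.
#' @param W Count weight (>= 1).
#' @return An object of class `markov3` with elements `N` (total tuple
#'   occurrences), `W`, `emission` (length-160000 numeric), `prefix_prob`
#'   (length-8000 marginal) and `cond` (8000 x 20 conditional matrix).
#' @export
fit_markov3 <- function(seed_seqs, W = 1) {
  if (length(seed_seqs) == 0L) stop("seed_seqs must be non-empty")
  if (W < 1) stop("W must be >= 1")
  counts <- integer(TUPLE_SPACE)
  for (s in seed_seqs) {
    idx <- aa_index(strsplit(toupper(s), "")[[1L]])
    idx <- idx[!is.na(idx)]
    L <- length(idx)
    if (L < 4L) next
    lin <- idx[1:(L - 3L)] + 20L * (idx[2:(L - 2L)] - 1L) +
      400L * (idx[3:(L - 1L)] - 1L) + 8000L * (idx[4:L] - 1L)
    counts <- counts + tabulate(lin, nbins = TUPLE_SPACE)
  }
  N <- sum(counts)
  raw <- ((counts + 1) * W) / (TUPLE_SPACE + N * W)
  emission <- raw / sum(raw)
  m <- matrix(emission, nrow = 8000L, ncol = 20L)  # rows: 3-prefix, cols: next
  prefix_prob <- rowSums(m)
  cond <- m / prefix_prob
  structure(list(N = N, W = W, counts_total = counts, emission = emission,
                 prefix_prob = prefix_prob,
                 prefix_cum = cumsum(prefix_prob) / sum(prefix_prob),
                 cond = cond),
            class = "markov3")
}

#' @export
print.markov3 <- function(x, ...) {
  cat("Order-3 Markov decoy model: N =", x$N, "tuple occurrences, W =",
      x$W, "\n")
  invisible(x)
}

#' Sample decoy sequences from an order-3 Markov model
#'
#' @param model A `markov3` model.
#' @param lengths Integer vector of decoy lengths (one decoy per entry).
#' @return Character vector of decoy sequences.
#' @export
sample_markov_decoys <- function(model, lengths) {
  stopifnot(inherits(model, "markov3"))
  idx <- .sample_markov_cpp(model$prefix_cum, model$cond,
                            as.integer(lengths))
  vapply(idx, function(r) paste(AA20[r], collapse = ""), character(1))
}

#' Calibrate the Markov count weight W against the domain's SCM
#'
#' Starting at `W0` and incrementing by one, finds the smallest weight whose
#' batch of Markov decoys yields between `accept_min` and `accept_max`
#' decoys accepted by the SCM rule (positive best bit-score). Intended for
#' small domain families whose raw counts bias the emission too weakly.
#'
#' @param seed_seqs Domain sequences used to fit the Markov model.
#' @param scm_profile The domain's SCM as a `pssm` object.
#' @param W0 Initial weight.
#' @param batch Decoys generated per candidate weight.
#' @param max_W Largest weight tried before giving up.
#' @param accept_min,accept_max Target range of accepted decoys per batch.
#' @param min_overlap Minimum aligned columns for the scanner.
#' @return List with elements `W` and `rate` (accepted decoys in the final
#'   batch). Errors if no weight up to `max_W` lands in the target range.
#' @export
calibrate_markov_weight <- function(seed_seqs, scm_profile, W0 = 10,
                                    batch = 10000L, max_W = 200,
                                    accept_min = 1L, accept_max = 10L,
                                    min_overlap = 8L) {
  stopifnot(inherits(scm_profile, "pssm"))
  lens <- nchar(seed_seqs)
  rate <- NA_integer_
  for (W in seq(W0, max_W)) {
    model <- fit_markov3(seed_seqs, W = W)
    decoys <- sample_markov_decoys(model, sample(lens, batch, replace = TRUE))
    rate <- sum(vapply(decoys, function(d) {
      best_bit(scm_profile, d, min_overlap) > 0
    }, logical(1)))
    if (rate >= accept_min && rate <= accept_max) {
      return(list(W = W, rate = rate))
    }
  }
  stop("weight calibration failed: no W in [", W0, ", ", max_W,
       "] reached ", accept_min, "-", accept_max, " accepted decoys per ",
       batch, " (last rate: ", rate, ")")
}

#' Plan the negative-sequence generation for a domain
#'
#' The training set targets roughly one negative per two positives:
#' `required = ceiling(0.5 * n_pos)`. Negatives still missing after the
#' simple decoys (2-mer shuffles and reversals) are routed to the Markov
#' generator: `deficit = max(0, required - n_simple_negs)`. Because decoys
#' are only rarely accepted as negatives, the decoy budget is
#' `ceiling(deficit / fp_rate_per_decoy)`, with default acceptance rates of
#' 5 per 10,000 decoys for SCMs and 5 per 1,000 for CCMs (midpoints of the
#' 1-10 per 10,000 / per 1,000 operating ranges).
#'
#' @param n_pos Number of positive training sequences (>= 1).
#' @param n_simple_negs Negatives already obtained from simple decoys.
#' @param model_type `"SCM"` or `"CCM"` (sets the default acceptance rate).
#' @param fp_rate_per_decoy Expected accepted-negative rate per decoy;
#'   overrides the model-type default when given.
#' @return List with elements `required`, `deficit` and `decoy_budget`.
#' @examples
#' plan_negative_generation(100, 10)  # required 50, deficit 40
#' @export
plan_negative_generation <- function(n_pos, n_simple_negs = 0L,
                                     model_type = c("SCM", "CCM"),
                                     fp_rate_per_decoy = NULL) {
  model_type <- match.arg(model_type)
  if (n_pos < 1L) stop("n_pos must be >= 1")
  if (is.null(fp_rate_per_decoy)) {
    fp_rate_per_decoy <- if (model_type == "SCM") 5e-4 else 5e-3
  }
  required <- ceiling(0.5 * n_pos)
  deficit <- max(0L, required - n_simple_negs)
  list(required = as.integer(required), deficit = as.integer(deficit),
       decoy_budget = as.integer(ceiling(deficit / fp_rate_per_decoy)))
}

# empty training-instance table
empty_instances <- function() {
  data.frame(domain_acc = character(), model_type = character(),
             bit = numeric(), mean_bit = numeric(), label = character(),
             stringsAsFactors = FALSE)
}

#' Acceptance bit-score threshold standing in for "E-value < 1" on a CCM
#'
#' The built-in scanner produces no E-values; the CCM negative-acceptance
#' rule is made operational as a per-model bit-score cut: the 99th
#' percentile of the best bit-score over `n` uniform-random amino-acid
#' sequences of the model's consensus length.
#'
#' @param pssm A CCM `pssm`.
#' @param n Number of random calibration sequences.
#' @param len Calibration sequence length (default: consensus length).
#' @param min_overlap Scanner minimum overlap.
#' @return Numeric bit-score threshold.
#' @export
ccm_bit_threshold <- function(pssm, n = 1000L, len = NULL,
                              min_overlap = 8L) {
  stopifnot(inherits(pssm, "pssm"))
  if (is.null(len)) len <- nchar(pssm$consensus)
  bits <- vapply(seq_len(n), function(i) {
    s <- paste(AA20[sample.int(20L, len, replace = TRUE)], collapse = "")
    b <- best_bit(pssm, s, min_overlap)
    if (is.finite(b)) b else 0
  }, numeric(1))
  as.numeric(stats::quantile(bits, 0.99, names = FALSE, type = 7))
}

#' Screen one decoy against a domain's models
#'
#' A decoy becomes an SCM negative when the SCM's best hit has a positive
#' bit-score, and a CCM negative when some CCM's best hit exceeds that CCM's
#' acceptance threshold (the operational stand-in for "E-value < 1"). When
#' several CCMs accept the decoy only the best-scoring CCM instance is kept.
#'
#' @param decoy Amino-acid decoy string.
#' @param domain_models List with `domain_acc`, `scm_profile` (`pssm` or
#'   `NULL`), `ccm_profiles` (named list of `pssm`) and `ccm_thresholds`
#'   (named numeric, same names).
#' @param min_overlap Scanner minimum overlap.
#' @return Training-instance data frame (0-2 rows, label `"negative"`).
#' @export
screen_decoy <- function(decoy, domain_models, min_overlap = 8L) {
  out <- empty_instances()
  if (!nzchar(decoy)) return(out)
  acc <- domain_models$domain_acc
  if (!is.null(domain_models$scm_profile)) {
    h <- scan_pssm(domain_models$scm_profile, decoy, min_overlap)
    if (nrow(h) > 0L) {
      i <- which.max(h$bit_score)
      if (h$bit_score[i] > 0) {
        out <- rbind(out, data.frame(domain_acc = acc, model_type = "SCM",
                                     bit = h$bit_score[i],
                                     mean_bit = h$mean_bit_score[i],
                                     label = "negative"))
      }
    }
  }
  best <- NULL
  for (id in names(domain_models$ccm_profiles)) {
    h <- scan_pssm(domain_models$ccm_profiles[[id]], decoy, min_overlap)
    if (nrow(h) == 0L) next
    i <- which.max(h$bit_score)
    thr <- domain_models$ccm_thresholds[[id]]
    if (h$bit_score[i] > thr &&
        (is.null(best) || h$bit_score[i] > best$bit)) {
      best <- list(bit = h$bit_score[i], mean_bit = h$mean_bit_score[i])
    }
  }
  if (!is.null(best)) {
    out <- rbind(out, data.frame(domain_acc = acc, model_type = "CCM",
                                 bit = best$bit, mean_bit = best$mean_bit,
                                 label = "negative"))
  }
  out
}

#' Select the retained negative training instances
#'
#' Deduplicates exact (bit-score, mean-bit-score) pairs, sorts by Euclidean
#' distance from the origin of the score space (descending, i.e. most
#' significant first) and keeps at most `n_pos` instances.
#'
#' @param instances Training-instance data frame (columns `bit`,
#'   `mean_bit`).
#' @param n_pos Cap on the number of retained negatives.
#' @return The retained instances, distance-ordered.
#' @export
select_negatives <- function(instances, n_pos) {
  if (is.null(instances) || nrow(instances) == 0L) return(empty_instances())
  key <- paste(instances$bit, instances$mean_bit)
  instances <- instances[!duplicated(key), , drop = FALSE]
  d <- sqrt(instances$bit^2 + instances$mean_bit^2)
  instances <- instances[order(-d), , drop = FALSE]
  out <- utils::head(instances, n_pos)
  rownames(out) <- NULL
  out
}

dedup_instances <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- paste(df$model_type, df$bit, df$mean_bit, df$label)
  out <- df[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a SEED alignment (aligned FASTA or Stockholm)
#'
#' @param path Alignment file; format is sniffed from the first line
#'   (`# STOCKHOLM` vs FASTA).
#' @return Named character vector of aligned rows (gaps retained).
#' @export
read_seed_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^# STOCKHOLM", first)) {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    x <- as.character(aln)
  } else {
    x <- toupper(as.character(Biostrings::readBStringSet(path)))
    names(x) <- sub("\\s.*$", "", names(x))
  }
  if (length(unique(nchar(x))) != 1L) stop("ragged alignment: ", path)
  toupper(x)
}

degap <- function(x) gsub("[-.]", "", x)

#' Build the labelled training set for one domain
#'
#' Positives: every SEED sequence is fragmented with
#' [generate_positive_fragments()] and each fragment is scanned against the
#' domain's SCM and CCMs; the best hit per model class yields one positive
#' (bit, mean-bit) instance. Negatives: simple decoys (2-mer shuffle and
#' reversal of each SEED sequence) are screened with [screen_decoy()]; if a
#' model class still lacks negatives relative to
#' [plan_negative_generation()], order-3 Markov decoys are generated and
#' screened until each class reaches its requirement or the decoy budget
#' (bounded by `max_decoys`) is exhausted. Both classes' negatives then pass
#' through [select_negatives()]; positives are deduplicated on exact
#' (bit, mean-bit) the same way.
#'
#' @param seed_seqs Aligned or ungapped SEED sequences (gaps are stripped).
#' @param domain_models List as for [screen_decoy()] (per-domain profiles
#'   and CCM thresholds).
#' @param params [fragment_params()] for the positive generator.
#' @param W Markov count weight.
#' @param max_decoys Hard cap on Markov decoys generated for the domain.
#' @param min_overlap Scanner minimum overlap.
#' @param fp_rate_scm,fp_rate_ccm Planner acceptance rates per decoy.
#' @return Training-instance data frame (`domain_acc`, `model_type`, `bit`,
#'   `mean_bit`, `label`). Errors when no positive instance is recoverable.
#' @export
build_training_set <- function(seed_seqs, domain_models,
                               params = fragment_params(), W = 10,
                               max_decoys = 2000L, min_overlap = 8L,
                               fp_rate_scm = 5e-4, fp_rate_ccm = 5e-3) {
  seqs <- degap(unname(as.character(seed_seqs)))
  seqs <- seqs[nchar(seqs) >= 2L]
  if (length(seqs) == 0L) stop("no usable SEED sequences")
  acc <- domain_models$domain_acc
  has_scm <- !is.null(domain_models$scm_profile)
  has_ccm <- length(domain_models$ccm_profiles) > 0L

  pos <- list()
  for (s in seqs) {
    frags <- generate_positive_fragments(s, params)$fragment
    for (fr in frags) {
      if (has_scm) {
        h <- scan_pssm(domain_models$scm_profile, fr, min_overlap)
        if (nrow(h) > 0L) {
          i <- which.max(h$bit_score)
          pos[[length(pos) + 1L]] <-
            data.frame(domain_acc = acc, model_type = "SCM",
                       bit = h$bit_score[i], mean_bit = h$mean_bit_score[i],
                       label = "positive")
        }
      }
      if (has_ccm) {
        bb <- -Inf; bm <- NA_real_
        for (id in names(domain_models$ccm_profiles)) {
          h <- scan_pssm(domain_models$ccm_profiles[[id]], fr, min_overlap)
          if (nrow(h) > 0L) {
            i <- which.max(h$bit_score)
            if (h$bit_score[i] > bb) {
              bb <- h$bit_score[i]; bm <- h$mean_bit_score[i]
            }
          }
        }
        if (is.finite(bb)) {
          pos[[length(pos) + 1L]] <-
            data.frame(domain_acc = acc, model_type = "CCM", bit = bb,
                       mean_bit = bm, label = "positive")
        }
      }
    }
  }
  if (length(pos) == 0L) {
    stop("domain unlearnable: no positive instance recoverable for ", acc)
  }
  pos <- dedup_instances(do.call(rbind, pos))

  negs <- list()
  nn <- c(SCM = 0L, CCM = 0L)       # unique (bit, mean_bit) negatives seen
  seen <- new.env(parent = emptyenv())
  take <- function(r) {
    if (nrow(r) > 0L) {
      negs[[length(negs) + 1L]] <<- r
      for (j in seq_len(nrow(r))) {
        key <- paste(r$model_type[j], r$bit[j], r$mean_bit[j])
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nn[[r$model_type[j]]] <<- nn[[r$model_type[j]]] + 1L
        }
      }
    }
  }
  for (s in seqs) {
    for (d in generate_simple_decoys(s)) {
      take(screen_decoy(d, domain_models, min_overlap))
    }
  }

  n_pos <- c(SCM = sum(pos$model_type == "SCM"),
             CCM = sum(pos$model_type == "CCM"))
  plans <- list()
  budget <- 0L
  for (ty in c("SCM", "CCM")) {
    if (n_pos[[ty]] == 0L) next
    pl <- plan_negative_generation(n_pos[[ty]], nn[[ty]], ty,
                                   if (ty == "SCM") fp_rate_scm else fp_rate_ccm)
    plans[[ty]] <- pl
    budget <- max(budget, pl$decoy_budget)
  }
  budget <- min(budget, max_decoys)
  if (budget > 0L) {
    model <- fit_markov3(seqs, W = W)
    generated <- 0L
    lens <- nchar(seqs)
    while (generated < budget) {
      need <- any(vapply(names(plans), function(ty) {
        nn[[ty]] < plans[[ty]]$required
      }, logical(1)))
      if (!need) break
      nbatch <- min(100L, budget - generated)
      decoys <- sample_markov_decoys(model,
                                     sample(lens, nbatch, replace = TRUE))
      generated <- generated + nbatch
      for (d in decoys) {
        take(screen_decoy(d, domain_models, min_overlap))
      }
    }
  }
  neg <- bind_rows_fast(negs, template = empty_instances())

  out <- pos
  for (ty in c("SCM", "CCM")) {
    if (n_pos[[ty]] == 0L) next
    sel <- select_negatives(neg[neg$model_type == ty, , drop = FALSE],
                            n_pos[[ty]])
    out <- rbind(out, sel)
  }
  rownames(out) <- NULL
  out
}
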