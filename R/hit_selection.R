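#' Parameters of the hit-selection pipeline
#'
#' @param overlap_frac Minimum fraction of both hit lengths that the overlap
#'   must cover for two same-domain hits to be treated as redundant
#'   (filter 1).
#' @param prob_threshold Posterior probability a hit must exceed to survive
#'   filter 2 (0.90 by default; 0.85 is the permissive variant).
#' @param shared_residues Number of shared residues at which a lower-ranked
#'   hit is discarded in filter 3 (a pair sharing fewer residues coexists).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(overlap_frac = 0.85, prob_threshold = 0.90,
                             shared_residues = 10L) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1,
            prob_threshold > 0, prob_threshold < 1, shared_residues >= 1)
  structure(list(overlap_frac = overlap_frac,
                 prob_threshold = prob_threshold,
                 shared_residues = as.integer(shared_residues)),
            class = "selection_params")
}

overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Filter 1: remove redundant same-domain hits
#'
#' Within each model class (CCM and SCM are processed independently) and
#' each domain, hits are visited by decreasing bit-score and a hit is
#' dropped when its overlap with an already-retained hit of the same domain
#' covers at least `overlap_frac` of both hit lengths. Non-overlapping
#' occurrences of the same domain, and hits of different domains, are never
#' removed here. Ties on bit-score are broken by longer hit, then by
#' model_id.
#'
#' @param hits Annotation-format hit table of one read.
#' @param params A [selection_params()] list.
#' @return The retained hits.
#' @export
filter1_dedupe_same_domain <- function(hits, params = selection_params()) {
  hits <- as_annotation(hits)
  n <- nrow(hits)
  if (n == 0L) return(hits)
  s <- hits$ali_start; e <- hits$ali_end
  len <- e - s + 1L
  grp <- paste(hits$model_type, hits$domain_acc)
  keep <- logical(n)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ord <- idx[order(-hits$bit_score[idx], -len[idx], hits$model_id[idx],
                     s[idx])]
    retained <- integer()
    for (i in ord) {
      if (length(retained)) {
        ov <- pmax(0L, pmin(e[i], e[retained]) - pmax(s[i], s[retained]) + 1L)
        if (any(ov >= params$overlap_frac * len[i] &
                ov >= params$overlap_frac * len[retained])) next
      }
      retained <- c(retained, i)
    }
    keep[retained] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter 2: probability filter against the gathering thresholds
#'
#' Keeps a hit only when its bit-score is strictly greater than the
#' domain-specific lower bound (the smallest training negative's bit-score)
#' and its posterior probability of being a true positive is strictly
#' greater than `prob_threshold`. The posterior is stored on the surviving
#' hits. Hits whose (domain, model class) has no fitted space are dropped
#' with one warning giving the count.
#'
#' @param hits Annotation-format hit table.
#' @param spaces Named list of `prob_space` objects keyed
#'   `"<domain_acc>/<model_type>"` (as from [fit_spaces()]).
#' @param params A [selection_params()] list.
#' @return The retained hits with `posterior` filled.
#' @export
filter2_probability <- function(hits, spaces, params = selection_params()) {
  hits <- as_annotation(hits)
  if (nrow(hits) == 0L) return(hits)
  keys <- space_key(hits$domain_acc, hits$model_type)
  known <- keys %in% names(spaces)
  if (any(!known)) {
    warning(sum(!known), " hit(s) dropped: no fitted probability space for ",
            paste(unique(keys[!known]), collapse = ", "))
  }
  hits <- hits[known, , drop = FALSE]
  keys <- keys[known]
  n <- nrow(hits)
  if (n == 0L) return(hits)
  post <- numeric(n); minb <- numeric(n)
  for (k in unique(keys)) {
    ii <- which(keys == k)
    sp <- spaces[[k]]
    post[ii] <- posterior(sp, hits$bit_score[ii], hits$mean_bit_score[ii])
    minb[ii] <- sp$min_neg_bit
  }
  hits$posterior <- post
  keep <- hits$bit_score > minb & post > params$prob_threshold
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter 3: ranking-score resolution of the final architecture
#'
#' Each hit's ranking score is its posterior (the \\[0,1\\] statistical
#' significance of the bit-score) multiplied by its fractional identity to
#' the model consensus. Hits are visited by decreasing ranking score (ties
#' by bit-score, then model_id) and a hit is discarded when it shares at
#' least `shared_residues` read positions with an already-retained hit of
#' any domain. The result — the read's domain architecture — is returned
#' ordered by start coordinate.
#'
#' @param hits Hits that passed filter 2 (posterior filled).
#' @param params A [selection_params()] list.
#' @return The retained, coordinate-sorted hits with `ranking_score`
#'   filled.
#' @export
filter3_rank_resolve <- function(hits, params = selection_params()) {
  hits <- as_annotation(hits)
  if (nrow(hits) == 0L) return(hits)
  ident <- ifelse(is.na(hits$identity_pct), 100, hits$identity_pct)
  hits$ranking_score <- hits$posterior * (ident / 100)
  ord <- order(-hits$ranking_score, -hits$bit_score, hits$model_id,
               hits$ali_start)
  s <- hits$ali_start; e <- hits$ali_end
  retained <- integer()
  for (i in ord) {
    if (length(retained)) {
      ov <- pmax(0L, pmin(e[i], e[retained]) - pmax(s[i], s[retained]) + 1L)
      if (any(ov >= params$shared_residues)) next
    }
    retained <- c(retained, i)
  }
  out <- hits[retained[order(s[retained])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate one read
#'
#' Scans the read with every model of the library, then applies the three
#' selection filters in order (same-domain redundancy removal, probability
#' filtering against the gathering thresholds, ranking-score overlap
#' resolution).
#'
#' @param read Amino-acid string (or length-1 `AAStringSet`), named or with
#'   `read_id` supplied.
#' @param lib A [model_library] with in-memory profiles.
#' @param spaces Fitted probability spaces (see [fit_spaces()]).
#' @param params A [selection_params()] list.
#' @param min_overlap Scanner minimum aligned columns.
#' @param read_id Identifier recorded on the hits.
#' @return Annotation-format data frame: the read's non-overlapping domain
#'   architecture (possibly zero rows).
#' @export
annotate_read <- function(read, lib, spaces, params = selection_params(),
                          min_overlap = 8L, read_id = NULL) {
  if (is.null(read_id)) {
    read_id <- if (!is.null(names(read))) names(read)[1L] else "read1"
  }
  reads <- stats::setNames(as.character(read)[1L], read_id)
  raw <- scan_library(lib, reads, min_overlap)
  f1 <- filter1_dedupe_same_domain(raw, params)
  f2 <- filter2_probability(f1, spaces, params)
  filter3_rank_resolve(f2, params)
}

#' Annotate a set of reads
#'
#' Per-read application of [annotate_read()]'s filter pipeline over a
#' library scan, with per-stage hit counters.
#'
#' @param reads `AAStringSet` or named character vector of amino-acid reads.
#' @param lib A [model_library] with in-memory profiles.
#' @param spaces Fitted probability spaces.
#' @param params A [selection_params()] list.
#' @param min_overlap Scanner minimum aligned columns.
#' @param verbose Print the per-stage hit funnel.
#' @return Annotation-format data frame over all reads, with attribute
#'   `"funnel"` giving the hit counts after each stage.
#' @export
annotate_reads <- function(reads, lib, spaces, params = selection_params(),
                           min_overlap = 8L, verbose = FALSE) {
  raw <- scan_library(lib, reads, min_overlap)
  pieces <- split(raw, raw$read_id)
  out <- list()
  n1 <- 0L; n2 <- 0L; n3 <- 0L
  for (rid in names(pieces)) {
    f1 <- filter1_dedupe_same_domain(pieces[[rid]], params)
    f2 <- filter2_probability(f1, spaces, params)
    f3 <- filter3_rank_resolve(f2, params)
    n1 <- n1 + nrow(f1); n2 <- n2 + nrow(f2); n3 <- n3 + nrow(f3)
    if (nrow(f3)) out[[rid]] <- f3
  }
  res <- if (length(out)) as_annotation(bind_rows_fast(out))
         else empty_annotation()
  funnel <- c(raw = nrow(raw), after_filter1 = n1, after_filter2 = n2,
              after_filter3 = n3)
  if (verbose) {
    message("hits: raw ", funnel[1], " -> F1 ", funnel[2], " -> F2 ",
            funnel[3], " -> F3 ", funnel[4])
  }
  attr(res, "funnel") <- funnel
  res
}

#' Combine two annotation sets (primary plus secondary rescue)
#'
#' All primary annotations are kept verbatim; a secondary tool's annotations
#' are added only for reads the primary tool left unannotated. The
#' `source_tool` labels are preserved.
#'
#' @param primary,secondary Annotation-format hit tables.
#' @return The combined hit table.
#' @export
combine_annotations <- function(primary, secondary) {
  primary <- as_annotation(primary)
  secondary <- as_annotation(secondary)
  if (anyDuplicated(primary) || anyDuplicated(secondary)) {
    stop("duplicated identical hit rows within one input")
  }
  add <- secondary[!secondary$read_id %in% primary$read_id, , drop = FALSE]
  out <- rbind(primary, add)
  rownames(out) <- NULL
  out
}
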