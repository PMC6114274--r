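#' Parse a pfam2go mapping file (external2go dialect)
#'
#' Lines of the form
#' `Pfam:PF00001 7tm_1 > GO:rhodopsin-like receptor activity ; GO:0004930`
#' map a Pfam accession to a GO term; `!` lines are comments. A domain may
#' map to several terms (set semantics).
#'
#' @param path Path to the mapping file.
#' @return Named list: domain accession -> character vector of GO ids.
#' @export
load_pfam2go <- function(path) {
  if (!file.exists(path)) stop("pfam2go file not found: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "!") || !nzchar(trimws(line))) next
    m <- regmatches(line,
                    regexec("^Pfam:(\\S+)\\s.*>\\s*GO:.*;\\s*(GO:\\d+)\\s*$",
                            line))[[1L]]
    if (length(m) != 3L) {
      stop("malformed pfam2go line ", i, ": ", line)
    }
    acc <- m[2L]; go <- m[3L]
    out[[acc]] <- union(out[[acc]], go)
  }
  out
}

#' Count accepted domain hits per functional class
#'
#' Each accepted hit contributes one count to every GO class its domain
#' maps to (optionally restricted to a GO-Slim term set); hits of unmapped
#' domains are counted under the class `"unmapped"`.
#'
#' @param annotations Annotation-format hit table.
#' @param mapping Mapping as from [load_pfam2go()].
#' @param goslim_terms Optional character vector restricting the counted GO
#'   terms.
#' @return Named integer vector of per-class counts.
#' @export
class_counts <- function(annotations, mapping, goslim_terms = NULL) {
  annotations <- as_annotation(annotations)
  counts <- integer()
  bump <- function(counts, cls, by = 1L) {
    if (is.na(match(cls, names(counts)))) counts[cls] <- 0L
    counts[cls] <- counts[cls] + by
    counts
  }
  for (i in seq_len(nrow(annotations))) {
    acc <- annotations$domain_acc[i]
    terms <- mapping[[acc]]
    if (!is.null(terms) && !is.null(goslim_terms)) {
      terms <- intersect(terms, goslim_terms)
    }
    if (is.null(terms) || length(terms) == 0L) {
      counts <- bump(counts, "unmapped")
    } else {
      for (t in terms) counts <- bump(counts, t)
    }
  }
  counts
}

#' Within-sample normalised class abundance
#'
#' Divides each functional class count by the count of the most represented
#' class in the sample, yielding values in \\[0, 1\\] with the dominant
#' class at 1.
#'
#' @param counts Named numeric vector of per-class counts (some count must
#'   be positive).
#' @return Named numeric vector of normalised abundances.
#' @export
within_sample_normalise <- function(counts) {
  if (length(counts) == 0L || all(counts == 0)) {
    stop("within-sample normalisation needs at least one positive count")
  }
  counts / max(counts)
}

#' Cross-sample normalised domain abundance
#'
#' The abundance of a domain (or functional class) in a sample, normalised
#' for comparison across samples of different sizes: the count per megabase
#' multiplied by the average size of all samples — the expected count if
#' every sample had the average size.
#'
#' @param count Domain count in the sample.
#' @param sample_size_mb Size of the sample in megabases (> 0).
#' @param all_sizes_mb Sizes of all compared samples in megabases.
#' @return The normalised abundance.
#' @examples
#' cross_sample_abundance(100, 2, c(2, 6))  # (100/2) * 4 = 200
#' @export
cross_sample_abundance <- function(count, sample_size_mb, all_sizes_mb) {
  if (sample_size_mb <= 0) stop("sample_size_mb must be > 0")
  if (any(all_sizes_mb <= 0)) stop("all sample sizes must be > 0")
  (count / sample_size_mb) * mean(all_sizes_mb)
}

#' Sample size in megabases from read count and length
#'
#' @param n_reads Number of reads.
#' @param read_len_bp Read length in base pairs.
#' @return Size in megabases.
#' @export
megabases <- function(n_reads, read_len_bp) n_reads * read_len_bp / 1e6

#' Evaluate predicted annotations against a ground truth
#'
#' Read-level domain matching: a predicted hit is a true positive when the
#' same read carries a not-yet-matched truth hit of the same domain (or, in
#' clan mode, of a domain in the same clan); each truth hit is matched at
#' most once. FP are unmatched predictions, FN unmatched truths; the
#' F-score is the harmonic mean of precision and recall,
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param pred Annotation-format hit table (or any data frame with
#'   `read_id` and `domain_acc`).
#' @param truth Ground-truth table with `read_id` and `domain_acc`.
#' @param clan_map Optional named vector mapping domain accession to clan;
#'   when given, same-clan predictions count as true positives.
#' @return List with `TP`, `FP`, `FN`, `precision`, `recall`, `f_score`
#'   (the rates are `NaN` when undefined).
#' @export
evaluate_annotations <- function(pred, truth, clan_map = NULL) {
  match_key <- function(acc) {
    if (is.null(clan_map)) return(acc)
    cl <- unname(clan_map[acc])
    ifelse(is.na(cl) | !nzchar(cl), acc, cl)
  }
  pk <- paste(pred$read_id, match_key(pred$domain_acc))
  tk <- paste(truth$read_id, match_key(truth$domain_acc))
  tp <- 0L
  tt <- table(tk)
  pt <- table(pk)
  common <- intersect(names(tt), names(pt))
  for (k in common) tp <- tp + min(tt[[k]], pt[[k]])
  fp <- length(pk) - tp
  fn <- length(tk) - tp
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(TP = tp, FP = fp, FN = fn,
       precision = precision, recall = recall,
       f_score = 2 * tp / (2 * tp + fp + fn))
}

#' Clade usage of the accepted CCM annotations
#'
#' Counts accepted CCM hits per clade of origin, with proportions; the
#' operational readout of how much the clade-centered part of the library
#' contributes to an annotation run.
#'
#' @param annotations Annotation-format hit table.
#' @param lib The [model_library] the hits came from.
#' @return Data frame with columns `clade`, `count`, `proportion` (zero
#'   rows when no CCM hit is present).
#' @export
clade_usage_histogram <- function(annotations, lib) {
  annotations <- as_annotation(annotations)
  ccm <- annotations[annotations$model_type == "CCM", , drop = FALSE]
  if (nrow(ccm) == 0L) {
    return(data.frame(clade = character(), count = integer(),
                      proportion = numeric()))
  }
  clade <- lib$models$clade[match(ccm$model_id, lib$models$model_id)]
  tab <- table(clade)
  data.frame(clade = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Abundance profile of one annotated sample
#'
#' Combines [class_counts()], [within_sample_normalise()] and (when sample
#' sizes are given) [cross_sample_abundance()] into the standard per-class
#' output table.
#'
#' @param annotations Annotation-format hit table of one sample.
#' @param mapping Mapping from [load_pfam2go()].
#' @param sample_id Sample label recorded in the table.
#' @param goslim_terms Optional GO-Slim restriction.
#' @param sample_size_mb,all_sizes_mb Optional sizes (megabases) enabling
#'   the cross-sample column.
#' @return Data frame with columns `sample`, `class`, `count`,
#'   `within_norm` and (when sizes given) `cross_norm`.
#' @export
abundance_profile <- function(annotations, mapping, sample_id = "sample1",
                              goslim_terms = NULL, sample_size_mb = NULL,
                              all_sizes_mb = NULL) {
  counts <- class_counts(annotations, mapping, goslim_terms)
  if (length(counts) == 0L) {
    return(data.frame(sample = character(), class = character(),
                      count = integer(), within_norm = numeric()))
  }
  out <- data.frame(sample = sample_id, class = names(counts),
                    count = as.integer(counts),
                    within_norm = as.numeric(within_sample_normalise(counts)),
                    stringsAsFactors = FALSE)
  if (!is.null(sample_size_mb)) {
    if (is.null(all_sizes_mb)) all_sizes_mb <- sample_size_mb
    out$cross_norm <- vapply(out$count, cross_sample_abundance,
                             numeric(1), sample_size_mb, all_sizes_mb)
  }
  rownames(out) <- NULL
  out
}
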