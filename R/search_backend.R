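AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aa_index <- function(chars) match(chars, AA20)

#' Build a position-specific scoring matrix from an alignment
#'
#' Per-column residue probabilities are estimated as
#' `(count + pseudocount) / (n_residues + 20 * pseudocount)` over the 20
#' standard amino acids; gap characters (`-` or `.`) are excluded from the
#' counts and from the per-column denominator. The background is uniform
#' (1/20) and scores are log-odds in bits. The model consensus is the
#' argmax residue of each column (alphabetical tie-break).
#'
#' @param alignment Character vector of aligned sequences (equal lengths),
#'   or an `AAStringSet`.
#' @param pseudocount Non-negative pseudocount added to each residue count.
#' @return An object of class `pssm`: a list with elements `log_odds`
#'   (columns x 20 matrix, bits), `probs`, `consensus` (string) and
#'   `pseudocount`.
#' @examples
#' p <- build_pssm(c("MKV", "MKV", "MRV"), pseudocount = 0)
#' p$consensus
#' @export
build_pssm <- function(alignment, pseudocount = 0.5) {
  if (!is.character(alignment)) alignment <- as.character(alignment)
  if (length(alignment) < 1L) stop("alignment must contain at least one row")
  alignment <- toupper(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  ncol <- lens[1L]
  if (ncol == 0L) stop("alignment has zero columns")
  mat <- do.call(rbind, strsplit(alignment, ""))
  counts <- matrix(0, nrow = ncol, ncol = 20L,
                   dimnames = list(NULL, AA20))
  for (j in seq_len(ncol)) {
    tab <- table(factor(mat[, j], levels = AA20))
    counts[j, ] <- as.numeric(tab)
  }
  nres <- rowSums(counts)
  denom <- nres + 20 * pseudocount
  # all-gap columns (denom possibly 0): uniform
  probs <- (counts + pseudocount) / ifelse(denom > 0, denom, 1)
  probs[denom == 0, ] <- 1 / 20
  if (pseudocount == 0 && any(nres > 0 & apply(counts == 0, 1, any))) {
    # zero-probability cells give -Inf log-odds; legitimate for the
    # closed-form toy cases, kept as-is
  }
  log_odds <- log2(probs / (1 / 20))
  consensus <- AA20[apply(probs, 1, which.max)]
  structure(list(log_odds = log_odds, probs = probs,
                 consensus = paste(consensus, collapse = ""),
                 pseudocount = pseudocount,
                 lo_rev = log_odds[rev(seq_len(ncol)), , drop = FALSE]),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM with", nrow(x$log_odds), "columns\n")
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Serialise a PSSM to a TSV file
#'
#' One row per model column with the 20 per-column log-odds scores (bits).
#'
#' @param pssm A `pssm` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  df <- as.data.frame(pssm$log_odds)
  df <- cbind(col = seq_len(nrow(df)),
              consensus = strsplit(pssm$consensus, "")[[1L]], df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pssm\tpseudocount=%.17g", pssm$pseudocount), con)
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#'
#' @param path Path to a PSSM TSV file.
#' @return A `pssm` object.
#' @export
read_pssm <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# pssm")) stop("not a pssm file: ", path)
  pc <- as.numeric(sub(".*pseudocount=", "", header))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = c("integer", "character",
                                         rep("numeric", 20L)))
  lo <- as.matrix(df[, AA20])
  dimnames(lo) <- list(NULL, AA20)
  structure(list(log_odds = lo, probs = (1 / 20) * 2^lo,
                 consensus = paste(df$consensus, collapse = ""),
                 pseudocount = pc,
                 lo_rev = lo[rev(seq_len(nrow(lo))), , drop = FALSE]),
            class = "pssm")
}

#' Ungapped percent identity between two equal-length segments
#'
#' Columns where either side is an ambiguity (`X`) or stop (`*`) character
#' are excluded from the denominator; if no column remains the identity is
#' defined as 0.
#'
#' @param read_segment,consensus_segment Equal-length amino-acid strings.
#' @return Percent identity in \\[0, 100\\].
#' @examples
#' identity_of("MKV", "MAV")  # 66.67
#' @export
identity_of <- function(read_segment, consensus_segment) {
  a <- strsplit(toupper(read_segment), "")[[1L]]
  b <- strsplit(toupper(consensus_segment), "")[[1L]]
  if (length(a) != length(b)) {
    stop("segment length mismatch: ", length(a), " vs ", length(b))
  }
  keep <- !(a %in% c("X", "*")) & !(b %in% c("X", "*"))
  if (!any(keep)) return(0)
  100 * sum(a[keep] == b[keep]) / sum(keep)
}

# Scores of every ungapped placement of the model over the read.
# Offset d means model column j aligns to read position j + d.
# Returns list(offset, bit, ali_start, ali_end, overlap) of parallel
# vectors (NULL when no placement satisfies min_overlap).
pssm_placement_scores <- function(pssm, read_chars, min_overlap = 8L,
                                  idx = NULL) {
  C <- nrow(pssm$log_odds)
  R <- length(read_chars)
  dmin <- min_overlap - C
  dmax <- R - min_overlap
  if (dmax < dmin) return(NULL)
  if (is.null(idx)) idx <- aa_index(read_chars)  # NA for X/* -> scores 0
  lo_rev <- pssm$lo_rev
  if (is.null(lo_rev)) lo_rev <- pssm$log_odds[C:1, , drop = FALSE]
  # accumulate shifted score columns: read position p contributes
  # lo[j, aa(p)] to offset d = p - j, i.e. rev(lo[, aa(p)]) added at
  # result indices p..p+C-1 (index = d + C)
  res <- .placement_scores_cpp(lo_rev, as.integer(idx))
  i1 <- dmin + C; i2 <- dmax + C
  offs <- dmin:dmax
  bit <- res[i1:i2]
  ali_start <- pmax(1L, 1L + offs)
  ali_end <- pmin(R, C + offs)
  list(offset = offs, bit = bit, ali_start = ali_start,
       ali_end = ali_end, overlap = ali_end - ali_start + 1L)
}

#' Scan a read with a PSSM
#'
#' Evaluates every ungapped placement of the model over the read with at
#' least `min_overlap` aligned columns (terminal overhangs allowed, so
#' fragments at read edges still score). The bit-score of a placement is the
#' sum of per-column log-odds over aligned columns; read characters `X` and
#' `*` score 0 (background). Positive-scoring placements that are local
#' maxima over adjacent offsets are reported (leftmost kept on score
#' plateaus). Each reported hit is then trimmed to the placement's
#' maximal-scoring contiguous column run — the ungapped analogue of a local
#' alignment envelope, so a domain fragment embedded in unrelated sequence
#' is reported with the fragment's coordinates rather than the whole
#' placement overlap. The hit carries the trimmed bit-score, its
#' mean-bit-score (bit-score over trimmed length) and the percent identity
#' to the model consensus over the trimmed segment.
#'
#' @param pssm A `pssm` object.
#' @param read An amino-acid string, `AAString`, or length-1 `AAStringSet`.
#' @param min_overlap Minimum number of aligned model columns.
#' @return A data frame with columns `ali_start`, `ali_end`, `bit_score`,
#'   `mean_bit_score`, `identity_pct` (zero rows when no placement scores
#'   positively).
#' @export
scan_pssm <- function(pssm, read, min_overlap = 8L) {
  stopifnot(inherits(pssm, "pssm"))
  chars <- strsplit(toupper(as.character(read)[1L]), "")[[1L]]
  scan_pssm_core(pssm, chars, aa_index(chars), min_overlap)
}

EMPTY_SCAN <- data.frame(ali_start = integer(), ali_end = integer(),
                         bit_score = numeric(), mean_bit_score = numeric(),
                         identity_pct = numeric())

# fast data.frame constructor for hot paths (no checks, no name repair)
fast_df <- function(cols) {
  n <- length(cols[[1L]])
  structure(cols, class = "data.frame", row.names = seq_len(n))
}

# scanner core: takes pre-split read characters and their AA20 indices
scan_pssm_core <- function(pssm, chars, idx, min_overlap = 8L) {
  empty <- EMPTY_SCAN
  ps <- pssm_placement_scores(pssm, chars, min_overlap, idx = idx)
  if (is.null(ps)) return(empty)
  b <- ps$bit                              # already offset-ordered
  n <- length(b)
  prv <- c(-Inf, b[-n])
  nxt <- c(b[-1L], -Inf)
  # leftmost element of an all-equal positive plateau followed by a drop
  keep <- which(b > 0 & b >= prv & b > nxt)
  if (length(keep) == 0L) return(empty)
  cons <- strsplit(pssm$consensus, "")[[1L]]
  m <- length(keep)
  ts <- integer(m); te <- integer(m); bits <- numeric(m); ident <- numeric(m)
  for (k in seq_len(m)) {
    i <- keep[k]
    d <- ps$offset[i]
    rs <- ps$ali_start[i]; re <- ps$ali_end[i]
    pos <- rs:re
    contrib <- numeric(length(pos))
    ok <- !is.na(idx[pos])
    contrib[ok] <- pssm$log_odds[cbind(pos[ok] - d, idx[pos[ok]])]
    seg <- max_subarray(contrib)
    ts[k] <- rs + seg$start - 1L
    te[k] <- rs + seg$end - 1L
    bits[k] <- seg$sum
    ident[k] <- identity_of(paste(chars[ts[k]:te[k]], collapse = ""),
                            paste(cons[(ts[k] - d):(te[k] - d)],
                                  collapse = ""))
  }
  fast_df(list(ali_start = ts, ali_end = te, bit_score = bits,
               mean_bit_score = bits / (te - ts + 1L),
               identity_pct = ident))
}

# maximal-sum contiguous subarray (Kadane); leftmost, then shortest, on ties
max_subarray <- function(x) .max_subarray_cpp(x)

# best single bit-score of a read against a pssm (-Inf if no placement)
best_bit <- function(pssm, read, min_overlap = 8L) {
  chars <- strsplit(toupper(as.character(read)[1L]), "")[[1L]]
  ps <- pssm_placement_scores(pssm, chars, min_overlap)
  if (is.null(ps) || length(ps$bit) == 0L) return(-Inf)
  max(ps$bit)
}

#' Scan a set of reads against a model library
#'
#' Runs the built-in PSSM scanner for every (model, read) pair and returns
#' the raw hit table that feeds the selection filters.
#'
#' @param lib A [model_library] object with in-memory profiles.
#' @param reads `AAStringSet` or named character vector of amino-acid reads.
#' @param min_overlap Minimum aligned model columns per placement.
#' @return An annotation-format data frame of raw hits (posterior and
#'   ranking_score are `NA` until the filters run).
#' @export
scan_library <- function(lib, reads, min_overlap = 8L) {
  stopifnot(inherits(lib, "model_library"))
  if (is.character(reads)) reads <- Biostrings::AAStringSet(reads)
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named")
  models <- lib$models[order(lib$models$model_id), , drop = FALSE]
  out <- vector("list", nrow(models) * length(reads))
  k <- 0L
  seqs <- as.character(reads)
  chars_list <- strsplit(toupper(seqs), "")
  idx_list <- lapply(chars_list, aa_index)
  for (m in seq_len(nrow(models))) {
    prof <- lib$profiles[[models$model_id[m]]]
    if (is.null(prof)) next
    for (r in seq_along(seqs)) {
      h <- scan_pssm_core(prof, chars_list[[r]], idx_list[[r]], min_overlap)
      nh <- length(h$ali_start)
      if (nh == 0L) next
      k <- k + 1L
      h$read_id <- rep.int(ids[r], nh)
      h$model_id <- rep.int(models$model_id[m], nh)
      h$domain_acc <- rep.int(models$domain_acc[m], nh)
      h$model_type <- rep.int(models$model_type[m], nh)
      h$source_tool <- rep.int("cladescan", nh)
      out[[k]] <- h
    }
  }
  if (k == 0L) return(empty_annotation())
  as_annotation(bind_rows_fast(out[seq_len(k)]))
}

#' Parse a HMMER3 per-domain table (domtblout)
#'
#' One hit per domain line, using envelope coordinates and the per-domain
#' bit-score; the mean-bit-score is the bit-score divided by the envelope
#' length. Percent identity against the model consensus is computed when
#' `reads` is supplied (ungapped comparison of the envelope segment with the
#' consensus segment at the hmm coordinates, truncated to the shorter of the
#' two), otherwise `NA`.
#'
#' @param path Path to a domtblout file.
#' @param lib A [model_library]; target names are resolved as model ids
#'   first, then as domain accessions (mapped to the domain's SCM).
#' @param reads Optional `AAStringSet` of the query reads, for identity.
#' @return An annotation-format data frame of hits. Unresolvable model names
#'   are skipped with one warning giving the count.
#' @export
parse_domtblout <- function(path, lib, reads = NULL) {
  stopifnot(inherits(lib, "model_library"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_annotation())
  if (!is.null(reads) && is.character(reads)) {
    reads <- Biostrings::AAStringSet(reads)
  }
  hits <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 22L) {
      stop("malformed domtblout line ", i, ": expected >= 22 fields, got ",
           length(f))
    }
    target <- f[1L]; query <- f[4L]
    m <- resolve_model(lib, target)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    bit <- as.numeric(f[14L]); ieval <- as.numeric(f[13L])
    hmm_from <- as.integer(f[16L]); hmm_to <- as.integer(f[17L])
    env_from <- as.integer(f[20L]); env_to <- as.integer(f[21L])
    if (anyNA(c(bit, env_from, env_to)) || env_from > env_to) {
      stop("malformed domtblout line ", i, ": bad score or coordinates")
    }
    len <- env_to - env_from + 1L
    ident <- NA_real_
    if (!is.null(reads) && query %in% names(reads) &&
        !anyNA(c(hmm_from, hmm_to)) && nzchar(m$consensus)) {
      rseg <- substr(as.character(reads[[query]]), env_from, env_to)
      cseg <- substr(m$consensus, hmm_from, hmm_to)
      n <- min(nchar(rseg), nchar(cseg))
      if (n > 0L) {
        ident <- identity_of(substr(rseg, 1L, n), substr(cseg, 1L, n))
      }
    }
    hits[[i]] <- data.frame(read_id = query, domain_acc = m$domain_acc,
                            model_id = m$model_id, model_type = m$model_type,
                            ali_start = env_from, ali_end = env_to,
                            bit_score = bit, mean_bit_score = bit / len,
                            evalue = ieval, identity_pct = ident,
                            source_tool = "hmmer")
  }
  if (skipped > 0L) {
    warning(skipped, " domtblout line(s) skipped: model name not in library")
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) return(empty_annotation())
  as_annotation(do.call(rbind, hits))
}

#' Parse PSI-BLAST tabular output (outfmt 6/7 dialect)
#'
#' Expects the standard 12-column layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) with optional
#' `#` comment lines. The query is the read and the subject the model;
#' percent identity is taken from the `pident` column.
#'
#' @param path Path to the tabular file.
#' @param lib A [model_library] used to resolve subject names.
#' @return An annotation-format data frame of hits.
#' @export
parse_psiblast_tabular <- function(path, lib) {
  stopifnot(inherits(lib, "model_library"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_annotation())
  hits <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 12L) {
      stop("malformed tabular line ", i, ": expected >= 12 fields, got ",
           length(f))
    }
    m <- resolve_model(lib, f[2L])
    if (is.null(m)) { skipped <- skipped + 1L; next }
    qstart <- as.integer(f[7L]); qend <- as.integer(f[8L])
    ident <- as.numeric(f[3L]); eval <- as.numeric(f[11L])
    bit <- as.numeric(f[12L])
    if (anyNA(c(qstart, qend, bit)) || qstart <= 0L || qend <= 0L) {
      stop("malformed tabular line ", i, ": bad coordinates or score")
    }
    if (qstart > qend) { tmp <- qstart; qstart <- qend; qend <- tmp }
    len <- qend - qstart + 1L
    hits[[i]] <- data.frame(read_id = f[1L], domain_acc = m$domain_acc,
                            model_id = m$model_id, model_type = m$model_type,
                            ali_start = qstart, ali_end = qend,
                            bit_score = bit, mean_bit_score = bit / len,
                            evalue = eval, identity_pct = ident,
                            source_tool = "psiblast")
  }
  if (skipped > 0L) {
    warning(skipped, " tabular line(s) skipped: model name not in library")
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) return(empty_annotation())
  as_annotation(do.call(rbind, hits))
}
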