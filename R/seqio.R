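#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a Biostrings string set. Sequence identifiers are
#' taken as the token before the first whitespace of the header line and
#' sequences are uppercased. Empty sequences and duplicated identifiers are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"aa"` (amino acid, the default) or `"nt"`
#'   (nucleotide).
#' @return An [Biostrings::AAStringSet-class] (for `alphabet = "aa"`) or
#'   [Biostrings::DNAStringSet-class] (for `alphabet = "nt"`), in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 a read", "mkv"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  empty <- Biostrings::width(x) == 0L
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicated record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  if (alphabet == "aa") {
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", seqs)
    if (!all(ok)) {
      stop("non-amino-acid characters in record(s): ",
           paste(ids[!ok], collapse = ", "))
    }
    Biostrings::AAStringSet(seqs)
  } else {
    ok <- grepl("^[ACGTUNRYSWKMBDHV]*$", seqs)
    if (!all(ok)) {
      stop("non-IUPAC nucleotide characters in record(s): ",
           paste(ids[!ok], collapse = ", "))
    }
    Biostrings::DNAStringSet(chartr("U", "T", seqs))
  }
}

#' Write sequences to a FASTA file
#'
#' @param x A named character vector or Biostrings string set.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Six-frame translation of nucleotide reads
#'
#' Translates each nucleotide sequence in all six reading frames (+1, +2, +3
#' on the forward strand; -1, -2, -3 on the reverse complement) with the
#' standard genetic code. Stop codons are rendered as `*`, fuzzy codons
#' (containing ambiguity codes) as `X`, and trailing partial codons are
#' dropped. Frames are encoded in the output identifiers as
#' `<id>_frame<+1|..|-3>`.
#'
#' @param x A [Biostrings::DNAStringSet-class] (or named character vector of
#'   nucleotide sequences).
#' @return An [Biostrings::AAStringSet-class] with six records per input
#'   record (frames of length zero are kept as empty records only when the
#'   input is shorter than 3 nt in that frame; such records are dropped).
#' @examples
#' six_frame_translate(Biostrings::DNAStringSet(c(r1 = "ATGAAAG")))
#' @export
six_frame_translate <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  stopifnot(methods::is(x, "DNAStringSet"))
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  out <- list()
  rc <- Biostrings::reverseComplement(x)
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      src <- if (strand == "+") x else rc
      w <- Biostrings::width(src)
      starts <- pmin(f, w + 1L)
      lens <- pmax(0L, ((w - f + 1L) %/% 3L) * 3L)
      sub <- Biostrings::subseq(src, start = starts, width = lens)
      keep <- lens > 0L
      if (!any(keep)) next
      aa <- suppressWarnings(
        Biostrings::translate(sub[keep], if.fuzzy.codon = "X")
      )
      names(aa) <- paste0(ids[keep], "_frame", strand, f)
      out[[paste0(strand, f)]] <- aa
    }
  }
  res <- do.call(c, unname(out))
  # stable order: by input record, frames +1,+2,+3,-1,-2,-3
  want <- as.vector(t(outer(ids, paste0("_frame", c("+1", "+2", "+3",
                                                    "-1", "-2", "-3")),
                            paste0)))
  res[want[want %in% names(res)]]
}

# fixed column order of the annotation table
annotation_columns <- function() {
  c("read_id", "domain_acc", "model_id", "model_type", "ali_start",
    "ali_end", "bit_score", "mean_bit_score", "evalue", "identity_pct",
    "posterior", "ranking_score", "source_tool")
}

EMPTY_ANNOTATION <- data.frame(
  read_id = character(), domain_acc = character(),
  model_id = character(), model_type = character(),
  ali_start = integer(), ali_end = integer(),
  bit_score = numeric(), mean_bit_score = numeric(),
  evalue = numeric(), identity_pct = numeric(),
  posterior = numeric(), ranking_score = numeric(),
  source_tool = character(), stringsAsFactors = FALSE)

#' An empty annotation table
#'
#' @return A zero-row data frame with the standard annotation columns.
#' @export
empty_annotation <- function() EMPTY_ANNOTATION

# fast row-bind for lists of data frames sharing one column set
bind_rows_fast <- function(lst, template = NULL) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) {
    return(if (is.null(template)) NULL else template)
  }
  nms <- names(lst[[1L]])
  cols <- lapply(nms, function(nm) {
    unlist(lapply(lst, `[[`, nm), use.names = FALSE)
  })
  names(cols) <- nms
  n <- length(cols[[1L]])
  structure(cols, class = "data.frame", row.names = seq_len(n))
}

as_annotation <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(EMPTY_ANNOTATION)
  if (identical(names(df), annotation_columns())) {
    attr(df, "row.names") <- seq_len(nrow(df))
    return(df)
  }
  for (col in annotation_columns()) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("ali_start", "ali_end")) NA_integer_
                   else if (col == "source_tool") NA_character_
                   else NA_real_
    }
  }
  df <- df[, annotation_columns()]
  rownames(df) <- NULL
  df
}

#' Write an annotation table to TSV
#'
#' One row per accepted hit; numeric columns are written with enough digits
#' that [read_annotations()] reproduces them bit-exactly.
#'
#' @param annotations A hit table as produced by [annotate_reads()] (any data
#'   frame with the standard annotation columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- as_annotation(annotations)
  out <- annotations
  for (col in c("bit_score", "mean_bit_score", "evalue", "identity_pct",
                "posterior", "ranking_score")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an annotation table written by [write_annotations()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with the standard annotation columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA",
                          quote = "", comment.char = "")
  miss <- setdiff(annotation_columns(), names(df))
  if (length(miss)) {
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("ali_start", "ali_end")) df[[col]] <- as.integer(df[[col]])
  for (col in c("bit_score", "mean_bit_score", "evalue", "identity_pct",
                "posterior", "ranking_score")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  as_annotation(df)
}
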