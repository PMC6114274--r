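random_aa <- function(n) paste(AA20[sample.int(20L, n, replace = TRUE)],
                               collapse = "")

# i.i.d. substitution of each position with probability `rate`, always to a
# different residue
mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- AA20[AA20 != chars[i]]
    chars[i] <- alt[sample.int(19L, 1L)]
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic domain family
#'
#' Emulates a curated domain family: a uniform-random consensus, a SEED of
#' homologs obtained by i.i.d. substitutions at `r_seed`, and `n_clades`
#' clade variants that drift from the consensus at the (higher) rate
#' `r_clade` before spawning their own tight sub-SEED at `r_subseed`. All
#' sequences are ungapped and of equal length. Uses the session RNG.
#'
#' @param length Domain length in aa (>= 15).
#' @param n_seed Number of consensus-level SEED rows.
#' @param n_clades Number of clade variants (0 for an SCM-only family).
#' @param r_seed,r_clade,r_subseed Substitution rates in \\[0, 1).
#' @param n_subseed Sub-SEED rows per clade.
#' @param domain_acc Accession recorded on the family.
#' @return An object of class `synthetic_family`: list with `domain_acc`,
#'   `consensus`, `seed_rows`, `clades` (per clade: `variant`, `subseed`).
#' @export
make_family <- function(length, n_seed = 8L, n_clades = 3L,
                        r_seed = 0.10, r_clade = 0.35, r_subseed = 0.05,
                        n_subseed = 8L, domain_acc = "SYN00001") {
  if (length < 15L) stop("domain length must be >= 15")
  rates <- c(r_seed, r_clade, r_subseed)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must be in [0, 1)")
  consensus <- random_aa(length)
  seed_rows <- vapply(seq_len(n_seed), function(i) mutate_seq(consensus, r_seed),
                      character(1))
  names(seed_rows) <- sprintf("%s_seed%02d", domain_acc, seq_len(n_seed))
  clades <- list()
  if (n_clades > 0L) {
    for (c in seq_len(n_clades)) {
      variant <- mutate_seq(consensus, r_clade)
      sub <- vapply(seq_len(n_subseed), function(i) mutate_seq(variant, r_subseed),
                    character(1))
      names(sub) <- sprintf("%s_clade%d_m%02d", domain_acc, c,
                            seq_len(n_subseed))
      clades[[sprintf("clade%d", c)]] <- list(variant = variant,
                                              subseed = sub)
    }
  }
  structure(list(domain_acc = domain_acc, consensus = consensus,
                 seed_rows = seed_rows, clades = clades,
                 rates = c(seed = r_seed, clade = r_clade,
                           subseed = r_subseed)),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("Synthetic domain family", x$domain_acc, "- length",
      nchar(x$consensus), "aa,", length(x$seed_rows), "SEED rows,",
      length(x$clades), "clade(s)\n")
  invisible(x)
}

# the full SEED of a family: consensus-level rows plus all clade sub-SEEDs
family_seed <- function(fam) {
  c(fam$seed_rows, unlist(lapply(fam$clades, `[[`, "subseed")))
}

#' Build a model library from synthetic families
#'
#' Per family: one SCM built from the consensus-level SEED rows and one CCM
#' per clade variant built from that clade's sub-SEED. Keeping the clade
#' sub-families out of the SCM mirrors the situation the clade-centered
#' strategy targets: a global consensus model that under-represents
#' diverged niches which the CCMs then capture.
#'
#' @param families List of `synthetic_family` objects.
#' @param pseudocount Pseudocount for [build_pssm()].
#' @return A [model_library] with in-memory profiles.
#' @export
make_library <- function(families, pseudocount = 0.5) {
  if (length(families) == 0L) stop("families must be non-empty")
  rows <- list(); profiles <- list()
  for (fam in families) {
    acc <- fam$domain_acc
    scm_id <- paste0(acc, ".SCM")
    prof <- build_pssm(fam$seed_rows, pseudocount)
    profiles[[scm_id]] <- prof
    rows[[length(rows) + 1L]] <-
      data.frame(model_id = scm_id, domain_acc = acc, model_type = "SCM",
                 clade = "", consensus = prof$consensus)
    for (cl in names(fam$clades)) {
      id <- paste0(acc, ".CCM.", cl)
      p <- build_pssm(fam$clades[[cl]]$subseed, pseudocount)
      profiles[[id]] <- p
      rows[[length(rows) + 1L]] <-
        data.frame(model_id = id, domain_acc = acc, model_type = "CCM",
                   clade = cl, consensus = p$consensus)
    }
  }
  model_library(do.call(rbind, rows), profiles = profiles)
}

#' Simulate a read set with planted domain fragments
#'
#' A fraction of reads carries a contiguous fragment of a family sequence
#' (from a clade variant with probability `clade_frac`, otherwise from the
#' family consensus), with i.i.d. substitution noise, embedded at a random
#' offset in a uniform-random amino-acid background; the remaining reads
#' are pure background. The planting truth is recorded.
#'
#' @param families List of `synthetic_family` objects.
#' @param n_reads Number of reads.
#' @param read_len Read length (aa).
#' @param planted_frac Fraction of reads with a planted fragment.
#' @param frag_len Length-2 vector: range of fragment lengths (aa).
#' @param noise_rate Substitution rate applied to the planted fragment.
#' @param clade_frac Probability a planted fragment comes from a clade
#'   variant rather than the consensus.
#' @return List with `reads` (`AAStringSet`) and `truth` (data frame:
#'   `read_id`, `domain_acc`, `start`, `end`, `clade` — empty string for
#'   consensus-derived fragments).
#' @export
make_read_set <- function(families, n_reads = 2000L, read_len = 60L,
                          planted_frac = 0.5, frag_len = c(20L, 50L),
                          noise_rate = 0.02, clade_frac = 0.5) {
  if (max(frag_len) > read_len) stop("frag_len must be <= read_len")
  reads <- character(n_reads)
  truth <- list()
  n_plant <- round(planted_frac * n_reads)
  for (r in seq_len(n_reads)) {
    rid <- sprintf("read%05d", r)
    bg <- random_aa(read_len)
    if (r <= n_plant) {
      fam <- families[[sample.int(length(families), 1L)]]
      use_clade <- length(fam$clades) > 0L && stats::runif(1) < clade_frac
      if (use_clade) {
        cl <- sample(names(fam$clades), 1L)
        src <- fam$clades[[cl]]$variant
      } else {
        cl <- ""
        src <- fam$consensus
      }
      fl <- sample(seq(frag_len[1L], frag_len[2L]), 1L)
      fl <- min(fl, nchar(src))
      fs <- sample.int(nchar(src) - fl + 1L, 1L)
      frag <- mutate_seq(substr(src, fs, fs + fl - 1L), noise_rate)
      pos <- sample.int(read_len - fl + 1L, 1L)
      bg <- paste0(substr(bg, 1L, pos - 1L), frag,
                   substr(bg, pos + fl, read_len))
      truth[[length(truth) + 1L]] <-
        data.frame(read_id = rid, domain_acc = fam$domain_acc,
                   start = pos, end = pos + fl - 1L, clade = cl,
                   stringsAsFactors = FALSE)
    }
    reads[r] <- bg
    names(reads)[r] <- rid
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(read_id = character(), domain_acc = character(),
                           start = integer(), end = integer(),
                           clade = character())
  list(reads = Biostrings::AAStringSet(reads), truth = truth)
}

#' The default synthetic study fixture
#'
#' Twenty domain families of length 80-300 aa with three clades each, a
#' model library built from them, and 2,000 reads of 60 aa (about the ORF
#' length of 180-bp reads) with planted fragments in half of them. Call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param n_families,n_reads,read_len,n_clades See [make_family()] /
#'   [make_read_set()].
#' @param len_range Range of family lengths.
#' @return List with `families`, `lib`, `reads`, `truth`.
#' @export
default_fixture <- function(n_families = 20L, n_reads = 2000L,
                            read_len = 60L, n_clades = 3L,
                            len_range = c(80L, 300L)) {
  families <- lapply(seq_len(n_families), function(i) {
    make_family(length = sample(seq(len_range[1L], len_range[2L]), 1L),
                n_clades = n_clades,
                domain_acc = sprintf("SYN%05d", i))
  })
  lib <- make_library(families)
  rs <- make_read_set(families, n_reads = n_reads, read_len = read_len)
  list(families = families, lib = lib, reads = rs$reads, truth = rs$truth)
}
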