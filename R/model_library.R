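#' Construct a model library
#'
#' A model library holds, per domain, one sequence consensus model (SCM) and
#' zero or more clade-centered models (CCMs), each with a consensus sequence
#' and clade-of-origin metadata, plus an optional domain-to-clan map.
#'
#' @param models Data frame with columns `model_id`, `domain_acc`,
#'   `model_type` (`"SCM"`/`"CCM"`), `clade` (empty string for SCMs) and
#'   `consensus`.
#' @param profiles Named list (by `model_id`) of `pssm` objects; entries may
#'   be `NULL` for libraries used only to resolve external search hits.
#' @param clan_map Optional named character vector mapping `domain_acc` to a
#'   clan accession.
#' @return An object of class `model_library`.
#' @export
model_library <- function(models, profiles = list(), clan_map = NULL) {
  need <- c("model_id", "domain_acc", "model_type", "clade", "consensus")
  miss <- setdiff(need, names(models))
  if (length(miss)) stop("models missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(models$model_id)) {
    stop("duplicate model_id: ",
         paste(unique(models$model_id[duplicated(models$model_id)]),
               collapse = ", "))
  }
  bad <- !models$model_type %in% c("SCM", "CCM")
  if (any(bad)) {
    stop("unknown model_type: ", paste(unique(models$model_type[bad]),
                                       collapse = ", "))
  }
  if (any(!nzchar(models$consensus))) stop("empty consensus sequence")
  scm <- models[models$model_type == "SCM", , drop = FALSE]
  if (anyDuplicated(scm$domain_acc)) {
    stop("more than one SCM for domain: ",
         paste(unique(scm$domain_acc[duplicated(scm$domain_acc)]),
               collapse = ", "))
  }
  ccm <- models[models$model_type == "CCM", , drop = FALSE]
  orphan <- setdiff(ccm$domain_acc, models$domain_acc[models$model_type == "SCM"])
  # a CCM's domain must have a library entry; SCM-less domains are allowed
  # only if some entry for the domain exists (the CCMs themselves qualify)
  models <- models[order(models$model_id), , drop = FALSE]
  rownames(models) <- NULL
  structure(list(models = models, profiles = profiles, clan_map = clan_map),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  n_dom <- length(unique(x$models$domain_acc))
  cat("Model library:", nrow(x$models), "models over", n_dom, "domains (",
      sum(x$models$model_type == "SCM"), "SCM /",
      sum(x$models$model_type == "CCM"), "CCM )\n")
  if (!is.null(x$clan_map)) {
    cat("Clan map:", length(x$clan_map), "domain(s)\n")
  }
  invisible(x)
}

# resolve a search-output target name: model_id first, then domain_acc -> SCM
resolve_model <- function(lib, name) {
  i <- match(name, lib$models$model_id)
  if (is.na(i)) {
    cand <- which(lib$models$domain_acc == name &
                  lib$models$model_type == "SCM")
    if (length(cand) == 0L) return(NULL)
    i <- cand[1L]
  }
  as.list(lib$models[i, , drop = FALSE])
}

#' Load a model library from a manifest file
#'
#' The manifest is a TSV with header columns `model_id`, `domain_acc`,
#' `model_type`, `clade`, `consensus_or_path`. The last column is either an
#' inline consensus sequence, or the path (relative to the manifest) of a
#' profile file written by [write_pssm()], whose consensus is then used.
#'
#' @param manifest Path to the manifest TSV.
#' @param clans Optional path to a clan table in the two-column Pfam-A.clans
#'   dialect (`domain_acc TAB clan_acc`, further columns ignored).
#' @return A [model_library] object.
#' @export
load_library <- function(manifest, clans = NULL) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  df <- utils::read.table(manifest, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("model_id", "domain_acc", "model_type", "clade",
            "consensus_or_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  base <- dirname(manifest)
  profiles <- vector("list", nrow(df))
  names(profiles) <- df$model_id
  consensus <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    ref <- df$consensus_or_path[i]
    p <- if (file.exists(ref)) ref else file.path(base, ref)
    if (file.exists(p) && !dir.exists(p)) {
      prof <- read_pssm(p)
      profiles[[i]] <- prof
      consensus[i] <- prof$consensus
    } else {
      consensus[i] <- toupper(ref)
    }
  }
  models <- data.frame(model_id = df$model_id, domain_acc = df$domain_acc,
                       model_type = df$model_type, clade = df$clade,
                       consensus = consensus, stringsAsFactors = FALSE)
  clan_map <- if (!is.null(clans)) load_clan_map(clans) else NULL
  model_library(models, profiles = profiles, clan_map = clan_map)
}

#' Parse a Pfam-A.clans-style clan table
#'
#' @param path Two-or-more-column TSV: domain accession, clan accession;
#'   extra columns are ignored. Rows with an empty clan field are dropped.
#' @return Named character vector mapping domain accession to clan.
#' @export
load_clan_map <- function(path) {
  if (!file.exists(path)) stop("clan file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  acc <- vapply(parts, `[`, character(1), 1L)
  clan <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "",
                 character(1))
  keep <- nzchar(clan)
  stats::setNames(clan[keep], acc[keep])
}

#' Save a model library as manifest plus profile files
#'
#' @param lib A [model_library].
#' @param dir Output directory (created if needed). Profiles are written as
#'   `<model_id>.pssm.tsv`; models without an in-memory profile store their
#'   consensus inline.
#' @return Invisibly, the manifest path.
#' @export
save_library <- function(lib, dir) {
  stopifnot(inherits(lib, "model_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- character(nrow(lib$models))
  for (i in seq_len(nrow(lib$models))) {
    id <- lib$models$model_id[i]
    prof <- lib$profiles[[id]]
    if (!is.null(prof)) {
      fn <- paste0(id, ".pssm.tsv")
      write_pssm(prof, file.path(dir, fn))
      ref[i] <- fn
    } else {
      ref[i] <- lib$models$consensus[i]
    }
  }
  manifest <- data.frame(model_id = lib$models$model_id,
                         domain_acc = lib$models$domain_acc,
                         model_type = lib$models$model_type,
                         clade = lib$models$clade,
                         consensus_or_path = ref)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Models of one domain
#'
#' @param lib A [model_library].
#' @param domain_acc Domain accession.
#' @return List with elements `scm` (single-row data frame or `NULL`) and
#'   `ccms` (data frame of CCMs, ordered by `model_id`, possibly zero rows).
#'   Unknown accessions give an empty result, not an error.
#' @export
models_for_domain <- function(lib, domain_acc) {
  stopifnot(inherits(lib, "model_library"))
  rows <- lib$models[lib$models$domain_acc == domain_acc, , drop = FALSE]
  rows <- rows[order(rows$model_id), , drop = FALSE]
  scm <- rows[rows$model_type == "SCM", , drop = FALSE]
  list(scm = if (nrow(scm)) scm[1L, , drop = FALSE] else NULL,
       ccms = rows[rows$model_type == "CCM", , drop = FALSE])
}
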