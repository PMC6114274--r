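entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# one best binary split of (x, y01) by information gain, with the MDL
# (minimum description length) stopping criterion; returns the cut or NULL
mdl_best_cut <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NULL)
  o <- order(x)
  x <- x[o]; y <- y[o]
  # candidate cuts between adjacent distinct values
  distinct <- which(diff(x) > 0)
  if (length(distinct) == 0L) return(NULL)
  classes <- sort(unique(y))
  k <- length(classes)
  cum <- sapply(classes, function(cl) cumsum(y == cl))
  if (is.null(dim(cum))) cum <- matrix(cum, ncol = k)
  tot <- cum[n, ]
  ent_s <- entropy_bits(tot)
  best <- NULL
  best_gain <- -Inf
  for (i in distinct) {
    left <- cum[i, ]; right <- tot - left
    e1 <- entropy_bits(left); e2 <- entropy_bits(right)
    gain <- ent_s - (i / n) * e1 - ((n - i) / n) * e2
    if (gain > best_gain) {
      best_gain <- gain
      best <- list(i = i, e1 = e1, e2 = e2,
                   k1 = sum(left > 0), k2 = sum(right > 0))
    }
  }
  delta <- log2(3^k - 2) - (k * ent_s - best$k1 * best$e1 -
                            best$k2 * best$e2)
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) return(NULL)
  (x[best$i] + x[best$i + 1L]) / 2
}

mdl_cuts_recursive <- function(x, y) {
  cut <- mdl_best_cut(x, y)
  if (is.null(cut)) return(numeric())
  left <- x < cut
  c(mdl_cuts_recursive(x[left], y[left]), cut,
    mdl_cuts_recursive(x[!left], y[!left]))
}

#' Supervised discretization cut-points (Fayyad-Irani MDL)
#'
#' Recursive entropy-based binary splitting with the minimum description
#' length stopping criterion, as used by discrete naive-Bayes
#' implementations. When the criterion accepts no cut at all, falls back to
#' 20 equal-width bins over the observed range (no cuts for constant
#' input, leaving a single bin). The two boundary bins are always
#' open-ended: values outside the observed range fall into the first or
#' last bin.
#'
#' @param values Numeric vector (length >= 2).
#' @param labels Class labels, parallel to `values`.
#' @return Strictly increasing numeric vector of cut-points (possibly
#'   empty).
#' @export
discretize <- function(values, labels) {
  if (length(values) < 2L) stop("need at least 2 values to discretize")
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  cuts <- mdl_cuts_recursive(values, as.character(labels))
  if (length(cuts) == 0L) {
    rng <- range(values)
    if (diff(rng) <= 0) return(numeric())
    cuts <- seq(rng[1], rng[2], length.out = 21L)[2:20]
  }
  sort(unique(cuts))
}

#' Fit the discrete naive-Bayes probability space for one (domain, class)
#'
#' Learns the two-dimensional gathering threshold of a domain: supervised
#' discretization of the bit-score and mean-bit-score axes, Laplace-smoothed
#' per-bin conditional probabilities, empirical class priors and the
#' bit-score lower bound (smallest bit-score among the training negatives).
#' Instances of all CCMs of a domain are expected to be pooled into a single
#' space; the SCM space is fitted separately.
#'
#' @param instances Training-instance data frame with columns `bit`,
#'   `mean_bit`, `label` (`"positive"`/`"negative"`) and (optionally)
#'   `domain_acc`, `model_type` used to tag the space.
#' @param alpha Laplace smoothing count.
#' @return An object of class `prob_space` with fields `domain_acc`,
#'   `model_type`, `bit_cuts`, `mbit_cuts`, `priors`, `cond_bit`,
#'   `cond_mbit` (bins x classes matrices), `min_neg_bit`, `n_pos`, `n_neg`.
#' @export
fit_space <- function(instances, alpha = 1) {
  need <- c("bit", "mean_bit", "label")
  miss <- setdiff(need, names(instances))
  if (length(miss)) stop("instances missing column(s): ",
                         paste(miss, collapse = ", "))
  lab <- instances$label
  if (!all(lab %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative'")
  }
  n_pos <- sum(lab == "positive"); n_neg <- sum(lab == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop("unlearnable: need both positive and negative instances (",
         n_pos, " positive, ", n_neg, " negative)")
  }
  bit_cuts <- discretize(instances$bit, lab)
  mbit_cuts <- discretize(instances$mean_bit, lab)
  cond_table <- function(x, cuts) {
    nb <- length(cuts) + 1L
    bin <- findInterval(x, cuts) + 1L
    tab <- matrix(0, nrow = nb, ncol = 2L,
                  dimnames = list(NULL, c("positive", "negative")))
    for (cl in c("positive", "negative")) {
      cnt <- tabulate(bin[lab == cl], nbins = nb)
      tab[, cl] <- (cnt + alpha) / (sum(cnt) + alpha * nb)
    }
    tab
  }
  structure(list(
    domain_acc = if ("domain_acc" %in% names(instances))
      instances$domain_acc[1L] else NA_character_,
    model_type = if ("model_type" %in% names(instances))
      instances$model_type[1L] else NA_character_,
    bit_cuts = bit_cuts, mbit_cuts = mbit_cuts,
    priors = c(positive = n_pos, negative = n_neg) / (n_pos + n_neg),
    cond_bit = cond_table(instances$bit, bit_cuts),
    cond_mbit = cond_table(instances$mean_bit, mbit_cuts),
    min_neg_bit = min(instances$bit[lab == "negative"]),
    n_pos = n_pos, n_neg = n_neg, alpha = alpha
  ), class = "prob_space")
}

#' @export
print.prob_space <- function(x, ...) {
  cat("Discrete naive-Bayes probability space",
      if (!is.na(x$domain_acc)) paste0("[", x$domain_acc, "/",
                                       x$model_type, "]"), "\n")
  cat("  training: ", x$n_pos, " positive / ", x$n_neg, " negative\n",
      sep = "")
  cat("  bins: ", length(x$bit_cuts) + 1L, " (bit) x ",
      length(x$mbit_cuts) + 1L, " (mean-bit)\n", sep = "")
  cat("  bit-score lower bound (smallest training negative): ",
      format(x$min_neg_bit), "\n", sep = "")
  invisible(x)
}

#' @export
summary.prob_space <- function(object, ...) {
  print(object)
  cat("  priors: P(+) = ", format(object$priors[["positive"]]),
      ", P(-) = ", format(object$priors[["negative"]]), "\n", sep = "")
  invisible(object)
}

#' Posterior probability that a hit is a true positive
#'
#' Evaluates `P(+|bit, mean_bit)` under the discrete naive-Bayes model:
#' prior times the per-bin conditional probabilities of both axes,
#' normalised over the two classes. Values outside the training range fall
#' into the open-ended boundary bins.
#'
#' @param space A fitted `prob_space`.
#' @param bit,mbit Numeric vectors (recycled to common length).
#' @return Numeric vector of posteriors in \\[0, 1\\].
#' @export
posterior <- function(space, bit, mbit) {
  stopifnot(inherits(space, "prob_space"))
  n <- max(length(bit), length(mbit))
  bit <- rep_len(bit, n); mbit <- rep_len(mbit, n)
  bb <- findInterval(bit, space$bit_cuts) + 1L
  mb <- findInterval(mbit, space$mbit_cuts) + 1L
  num_pos <- space$priors[["positive"]] *
    space$cond_bit[bb, "positive"] * space$cond_mbit[mb, "positive"]
  num_neg <- space$priors[["negative"]] *
    space$cond_bit[bb, "negative"] * space$cond_mbit[mb, "negative"]
  unname(num_pos / (num_pos + num_neg))
}

#' @rdname posterior
#' @param object A fitted `prob_space`.
#' @param newdata Data frame with columns `bit` and `mean_bit`.
#' @param ... Unused.
#' @export
predict.prob_space <- function(object, newdata, ...) {
  posterior(object, newdata$bit, newdata$mean_bit)
}

space_key <- function(domain_acc, model_type) {
  paste(domain_acc, model_type, sep = "/")
}

#' Fit probability spaces for every (domain, model class) in a training set
#'
#' @param training Training-instance data frame covering one or more
#'   domains (columns `domain_acc`, `model_type`, `bit`, `mean_bit`,
#'   `label`).
#' @param skip_failures When `TRUE`, single-class (unlearnable) groups are
#'   skipped with a warning instead of failing.
#' @param alpha Laplace smoothing count.
#' @return Named list of `prob_space` objects, keyed
#'   `"<domain_acc>/<model_type>"`.
#' @export
fit_spaces <- function(training, skip_failures = FALSE, alpha = 1) {
  groups <- split(training,
                  list(training$domain_acc, training$model_type),
                  drop = TRUE)
  out <- list()
  for (g in groups) {
    key <- space_key(g$domain_acc[1L], g$model_type[1L])
    sp <- tryCatch(fit_space(g, alpha = alpha), error = function(e) e)
    if (inherits(sp, "error")) {
      if (skip_failures) {
        warning("skipping ", key, ": ", conditionMessage(sp))
        next
      }
      stop("fitting ", key, " failed: ", conditionMessage(sp))
    }
    out[[key]] <- sp
  }
  out[order(names(out))]
}

SPACES_FORMAT <- "cladescan_spaces_v1"

#' Persist fitted probability spaces (the gathering-threshold store)
#'
#' @param spaces Named list of `prob_space` objects.
#' @param path Output path (JSON).
#' @return Invisibly, `path`.
#' @export
save_spaces <- function(spaces, path) {
  payload <- list(format = SPACES_FORMAT,
                  spaces = lapply(spaces, function(s) {
                    s <- unclass(s)
                    s$priors <- as.list(s$priors)
                    s$cond_bit <- as.data.frame(s$cond_bit)
                    s$cond_mbit <- as.data.frame(s$cond_mbit)
                    s
                  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load probability spaces written by [save_spaces()]
#'
#' @param path Path to the JSON store.
#' @return Named list of `prob_space` objects.
#' @export
load_spaces <- function(path) {
  if (!file.exists(path)) stop("gathering-threshold store not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("corrupt store: ",
                                               conditionMessage(e)))
  if (!identical(payload$format, SPACES_FORMAT)) {
    stop("gathering-threshold store version mismatch: expected ",
         SPACES_FORMAT, ", got ", payload$format)
  }
  classes <- c("positive", "negative")
  lapply(payload$spaces, function(s) {
    s$bit_cuts <- as.numeric(unlist(s$bit_cuts))
    s$mbit_cuts <- as.numeric(unlist(s$mbit_cuts))
    pr <- unlist(s$priors)
    s$priors <- stats::setNames(as.numeric(pr[classes]), classes)
    fix_cond <- function(m) {
      m <- as.matrix(as.data.frame(m)[, classes])
      dimnames(m) <- list(NULL, classes)
      m
    }
    s$cond_bit <- fix_cond(s$cond_bit)
    s$cond_mbit <- fix_cond(s$cond_mbit)
    class(s) <- "prob_space"
    s
  })
}
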