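#' Build a directed family-pair count network from domain architectures
#'
#' For every protein, every ordered pair of domain instances (one instance
#' occurring before another along the sequence) increments the count of the
#' corresponding ordered family pair. Self-pairs (same family twice) model
#' repeating domains. Counts are never accumulated across proteins' pair
#' structure — only within a protein — but are summed over proteins.
#'
#' Counting is per instance pair by default: the architecture `A, B, A`
#' contributes `c(A,B) = 1`, `c(A,A) = 1`, `c(B,A) = 1`. With
#' `mode = "binary"` each ordered family pair is counted at most once per
#' protein (a sensitivity-analysis variant).
#'
#' @param architectures named list of character vectors: each protein's
#'   family ids in start-coordinate order (see [read_architectures()]), or a
#'   candidate data frame, which is ordered per protein with
#'   [order_candidates()] first.
#' @param mode `"instance"` (default) or `"binary"`.
#' @return A `context_counts` object. Note that, unlike the on-disk loader,
#'   no singleton pruning is applied here — pruning is a load-time rule;
#'   write the counts out and reload them (or call [prune_singletons()]) to
#'   apply it.
#' @export
build_context_counts <- function(architectures, mode = c("instance", "binary")) {
  mode <- match.arg(mode)
  if (is.data.frame(architectures)) {
    df <- architectures
    architectures <- lapply(split(df, df$protein_id),
                            function(p) order_candidates(p)$family_id)
  }
  acc <- new.env(parent = emptyenv())
  for (arch in architectures) {
    k <- length(arch)
    if (k < 2) next
    keys <- character(0)
    for (p in seq_len(k - 1)) {
      keys <- c(keys, paste0(arch[p], "\r", arch[(p + 1):k]))
    }
    if (mode == "binary") keys <- unique(keys)
    for (key in keys) {
      acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + 1L
    }
  }
  keys <- sort(ls(acc), method = "radix")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    from = vapply(parts, `[[`, "", 1),
    to = vapply(parts, function(x) if (length(x) > 1) x[[2]] else "", ""),
    count = vapply(keys, function(k) acc[[k]], integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  attr(df, "C") <- sum(df$count)
  class(df) <- c("context_counts", "data.frame")
  df
}

#' Drop singleton pairs from a count network
#'
#' Ordered pairs observed exactly once are assumed to be annotation errors
#' and are removed (the same rule [load_context_counts()] applies on disk
#' input).
#'
#' @param counts a `context_counts` object.
#' @return A pruned `context_counts` object.
#' @export
prune_singletons <- function(counts) {
  context_counts_df(counts$from, counts$to, counts$count)
}

#' Symmetrize a count network (undirected-context ablation)
#'
#' Replaces each ordered count with `c(i,j) + c(j,i)`, so that a model built
#' from the result scores both orientations of a pair identically. This is an
#' approximate stand-in for the earlier undirected-context formulation, used
#' only for ablation comparisons.
#'
#' @param counts a `context_counts` object.
#' @return A symmetric `context_counts` object (note the total `C` doubles).
#' @export
symmetrize_counts <- function(counts) {
  lookup <- stats::setNames(counts$count, paste0(counts$from, "\r", counts$to))
  ufrom <- c(counts$from, counts$to)
  uto <- c(counts$to, counts$from)
  ukey <- paste0(ufrom, "\r", uto)
  keep <- !duplicated(ukey)
  ufrom <- ufrom[keep]
  uto <- uto[keep]
  fwd <- lookup[ukey[keep]]
  bwd <- lookup[paste0(uto, "\r", ufrom)]
  cnt <- ifelse(is.na(fwd), 0L, fwd) + ifelse(is.na(bwd), 0L, bwd)
  o <- order(ufrom, uto, method = "radix")
  context_counts_df(ufrom[o], uto[o], as.integer(cnt[o]))
}

#' Estimate a directional context-score model from pair counts
#'
#' Pair probabilities are estimated with a symmetric Dirichlet prior with
#' concentration `alpha` over all `n^2` ordered family pairs:
#' `p(i,j) = (c(i,j) + alpha) / (C + alpha * n^2)`, where `C` is the total
#' count and `n` the number of families in the universe. Family priors are
#' uniform, `p(i) = 1/n`. The context score for family `i` occurring before
#' family `j` is the log-odds against independence,
#' `S(i,j) = log2( p(i,j) / (p(i) p(j)) ) = log2( p(i,j) * n^2 )`.
#'
#' Every unobserved ordered pair (`c(i,j) = 0`) shares one fixed penalty,
#' `log2( alpha * n^2 / (C + alpha * n^2) )`, which is negative whenever
#' `C > 0`. With an empty network (`C = 0`) the prior is uniform, pairs are
#' independent and every score is exactly 0.
#'
#' The universe size `n` must be supplied explicitly (normally the number of
#' rows of the family metadata): the penalty depends on `n^2` including
#' families never observed in any pair, so inferring `n` from the counts
#' would inflate scores.
#'
#' @param counts a `context_counts` object, already pruned of singletons.
#' @param families character vector: the family universe (length `n`).
#' @param alpha Dirichlet concentration; the default `1e-3` performs better
#'   than the uniform prior `alpha = 1`.
#' @return An object of class `context_model` with elements `families`, `n`,
#'   `alpha`, `C`, `penalty` (bits) and an internal score table.
#' @export
#' @examples
#' cc <- load_context_counts(c("A\tB\t8"))
#' m <- context_model(cc, families = c("A", "B"), alpha = 1)
#' pair_score(m, "A", "B")   # log2(3)
#' pair_score(m, "B", "A")   # the unobserved-pair penalty, -log2(3)
context_model <- function(counts, families, alpha = 1e-3) {
  stopifnot(length(families) >= 1, !anyDuplicated(families), alpha > 0)
  n <- length(families)
  unknown <- setdiff(unique(c(counts$from, counts$to)), families)
  if (length(unknown) > 0)
    stop("context counts mention families outside the declared universe: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  C <- total_count(counts)
  denom <- C + alpha * n^2
  scores <- new.env(parent = emptyenv(), size = max(16L, nrow(counts)))
  if (nrow(counts) > 0) {
    s <- log2((counts$count + alpha) / denom * n^2)
    keys <- paste0(counts$from, "\r", counts$to)
    for (i in seq_along(keys)) scores[[keys[i]]] <- s[i]
  }
  structure(list(
    families = as.character(families), n = n, alpha = alpha, C = C,
    penalty = log2(alpha * n^2 / denom),
    scores = scores
  ), class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat("context_model: n =", x$n, "families, C =", x$C,
      ", alpha =", x$alpha, ", penalty =", round(x$penalty, 4), "bits,",
      length(ls(x$scores)), "observed pairs\n")
  invisible(x)
}

#' Directional context score of an ordered family pair
#'
#' Returns the log-odds score (bits) for a domain of family `from` occurring
#' before a domain of family `to`. Directional: `pair_score(m, A, B)` and
#' `pair_score(m, B, A)` generally differ. Unobserved pairs return the
#' model's shared penalty.
#'
#' @param model a `context_model`.
#' @param from,to family ids (vectorized, recycled to a common length).
#' @return numeric vector of scores in bits.
#' @export
pair_score <- function(model, from, to) {
  stopifnot(inherits(model, "context_model"))
  nn <- max(length(from), length(to))
  from <- rep_len(as.character(from), nn)
  to <- rep_len(as.character(to), nn)
  unknown <- setdiff(unique(c(from, to)), model$families)
  if (length(unknown) > 0)
    stop("unknown family: ", paste(utils::head(unknown, 3), collapse = ", "))
  keys <- paste0(from, "\r", to)
  vapply(keys, function(k) {
    v <- model$scores[[k]]
    if (is.null(v)) model$penalty else v
  }, numeric(1), USE.NAMES = FALSE)
}

#' Smoothed probability of an ordered family pair
#'
#' Mostly useful for checking normalization: summed over all `n^2` ordered
#' pairs these probabilities add to 1.
#'
#' @inheritParams pair_score
#' @return numeric vector of probabilities.
#' @export
pair_probability <- function(model, from, to) {
  2^pair_score(model, from, to) / model$n^2
}
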