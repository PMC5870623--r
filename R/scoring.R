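#' The directional context objective of a candidate subset
#'
#' For a subset of (pairwise non-conflicting) candidate domains on one
#' protein, ordered by start coordinate, the objective in bits is
#'
#' \deqn{\sum_i (H_i - T^d_{F_i}) + \sum_{i<j} S_{F_i,F_j} - \sum_F \tilde T_F,}
#'
#' where `H_i` is the per-domain bit score, `T^d` the family's domain
#' threshold, `S` the directional context score of every ordered pair (all
#' pairs, not just adjacent ones — this is what distinguishes the model from
#' both the undirected and the first-order Markov formulations), and the last
#' sum charges each distinct selected family its sequence-threshold surcharge
#' once. The empty subset scores 0, the null model: no domains should be
#' predicted when no subset scores above 0.
#'
#' @param subset candidate data frame (one protein); any row order — rows are
#'   ordered internally with [order_candidates()].
#' @param meta family metadata.
#' @param model a `context_model`.
#' @param breakdown if `TRUE`, attach the per-term breakdown as attribute
#'   `"breakdown"` (a list with `domain`, `pair` and `family` data frames).
#' @param check_conflicts if `TRUE` (default) error when the subset contains
#'   a conflicting pair; callers that have already filtered may disable it.
#' @param ... overlap parameters passed to [conflict_edges()].
#' @return Objective value in bits.
#' @export
context_objective <- function(subset, meta, model, breakdown = FALSE,
                              check_conflicts = TRUE, ...) {
  if (nrow(subset) == 0) return(0)
  subset <- order_candidates(subset)
  if (check_conflicts && nrow(conflict_edges(subset, meta, ...)) > 0)
    stop("subset contains a conflicting pair; pre-filter before scoring")
  terms <- objective_terms(subset, meta, model)
  val <- sum(terms$domain$term) + sum(terms$pair$term) - sum(terms$family$t_tilde)
  if (breakdown) attr(val, "breakdown") <- terms
  val
}

# shared term computation; subset must already be in start order
objective_terms <- function(subset, meta, model) {
  k <- nrow(subset)
  t_dom <- meta$t_dom[match(subset$family_id, meta$family_id)]
  if (anyNA(t_dom))
    stop("family missing from metadata: ",
         subset$family_id[is.na(t_dom)][1])
  domain <- data.frame(family_id = subset$family_id,
                       term = subset$bitscore - t_dom)
  if (k >= 2) {
    idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    pair <- data.frame(i = i, j = j,
                       from = subset$family_id[i], to = subset$family_id[j],
                       term = pair_score(model, subset$family_id[i],
                                         subset$family_id[j]))
  } else {
    pair <- data.frame(i = integer(0), j = integer(0), from = character(0),
                       to = character(0), term = numeric(0))
  }
  fams <- unique(subset$family_id)
  family <- data.frame(family_id = fams,
                       t_tilde = meta$t_tilde[match(fams, meta$family_id)])
  list(domain = domain, pair = pair, family = family)
}

#' First-order Markov context score
#'
#' The earlier Markov-model formulation scores only consecutive pairs:
#' `sum_i (H_i - T^d) + sum_i S(F_{i-1}, F_i)` with the leading term of the
#' first domain set to 0, plus the same family surcharges as
#' [context_objective()]. The two scores agree for subsets of at most two
#' domains, and in general
#' `context_objective - markov_score = sum over non-adjacent ordered pairs of S`.
#'
#' @inheritParams context_objective
#' @return Score in bits.
#' @export
markov_score <- function(subset, meta, model, check_conflicts = TRUE, ...) {
  if (nrow(subset) == 0) return(0)
  subset <- order_candidates(subset)
  if (check_conflicts && nrow(conflict_edges(subset, meta, ...)) > 0)
    stop("subset contains a conflicting pair; pre-filter before scoring")
  terms <- objective_terms(subset, meta, model)
  adjacent <- terms$pair$term[terms$pair$j == terms$pair$i + 1]
  sum(terms$domain$term) + sum(adjacent) - sum(terms$family$t_tilde)
}

#' Standard Pfam baseline selection
#'
#' The curated-threshold baseline, context-free: (1) keep candidates whose
#' bit score meets the family's domain threshold `H >= T^d`; (2) drop every
#' family whose kept candidates sum to less than its sequence threshold
#' `sum H < T^s`; (3) resolve strict overlaps (one or more shared residues,
#' alignment coordinates) between candidates of the same clan by iterating in
#' ascending P-value order and removing the less significant of each
#' conflicting pair. Candidates without a clan are never removed in step (3).
#'
#' @param candidates candidate data frame (one protein). If `clan_id` is
#'   empty it is filled from `meta`.
#' @param meta family metadata.
#' @return The selected subset of `candidates` rows.
#' @export
standard_pfam_filter <- function(candidates, meta) {
  if (nrow(candidates) == 0) return(candidates)
  if (length(unique(candidates$protein_id)) > 1) {
    parts <- split(candidates, candidates$protein_id)
    return(do.call(rbind, c(lapply(parts, standard_pfam_filter, meta = meta),
                            list(make.row.names = FALSE))))
  }
  clan <- meta$clan_id[match(candidates$family_id, meta$family_id)]
  fill <- !nzchar(candidates$clan_id) & !is.na(clan)
  candidates$clan_id[fill] <- clan[fill]
  t_dom <- meta$t_dom[match(candidates$family_id, meta$family_id)]
  t_seq <- meta$t_seq[match(candidates$family_id, meta$family_id)]
  if (anyNA(t_dom))
    stop("family missing from metadata: ",
         candidates$family_id[is.na(t_dom)][1])
  kept <- candidates[candidates$bitscore >= t_dom, , drop = FALSE]
  if (nrow(kept) == 0) return(kept)
  sums <- tapply(kept$bitscore, kept$family_id, sum)
  t_seq_by_fam <- meta$t_seq[match(names(sums), meta$family_id)]
  ok_fams <- names(sums)[sums >= t_seq_by_fam]
  kept <- kept[kept$family_id %in% ok_fams, , drop = FALSE]
  if (nrow(kept) <= 1) return(kept)
  # same-clan strict-overlap resolution, greedy by significance
  kept <- kept[order(kept$pvalue, kept$ali_start, kept$family_id, method = "radix"), ,
               drop = FALSE]
  alive <- rep(TRUE, nrow(kept))
  for (a in seq_len(nrow(kept) - 1)) {
    if (!alive[a]) next
    for (b in seq((a + 1), nrow(kept))) {
      if (!alive[b]) next
      if (kept$protein_id[a] != kept$protein_id[b]) next
      if (!nzchar(kept$clan_id[a]) || kept$clan_id[a] != kept$clan_id[b]) next
      if (overlap_length(kept$ali_start[a], kept$ali_end[a],
                         kept$ali_start[b], kept$ali_end[b]) >= 1L)
        alive[b] <- FALSE
    }
  }
  order_candidates(kept[alive, , drop = FALSE])
}
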