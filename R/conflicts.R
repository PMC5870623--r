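#' Overlap length of two 1-based inclusive ranges
#'
#' @param s1,e1,s2,e2 integer vectors of range endpoints.
#' @return integer overlap lengths (0 when disjoint).
#' @export
overlap_length <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

range_cols <- function(coords = c("env", "ali")) {
  coords <- match.arg(coords)
  if (coords == "env") c("env_start", "env_end") else c("ali_start", "ali_end")
}

#' Permissive overlap test
#'
#' Two candidate domains on the same protein overlap "permissively" when they
#' share more than `max_aa` residues or more than `max_frac` of the shorter
#' of the two ranges. This is the spatial-incompatibility rule: candidates on
#' different proteins never overlap. By default the envelope coordinates are
#' compared (the envelope is HMMER's estimate of the full homologous region);
#' `coords = "ali"` switches to the alignment span.
#'
#' @param d1,d2 single-row candidate data frames (or rows of one).
#' @param max_aa residue-count threshold (default 40).
#' @param max_frac fraction-of-shorter-range threshold (default 0.5).
#' @param coords `"env"` (default) or `"ali"`.
#' @return logical.
#' @export
permissive_overlap <- function(d1, d2, max_aa = 40L, max_frac = 0.5,
                               coords = c("env", "ali")) {
  if (d1$protein_id != d2$protein_id) return(FALSE)
  rc <- range_cols(coords)
  ov <- overlap_length(d1[[rc[1]]], d1[[rc[2]]], d2[[rc[1]]], d2[[rc[2]]])
  shorter <- min(d1[[rc[2]]] - d1[[rc[1]]] + 1L, d2[[rc[2]]] - d2[[rc[1]]] + 1L)
  ov > max_aa || ov > max_frac * shorter
}

nesting_key_set <- function(meta) {
  if (nrow(meta) == 0) return(character(0))
  partners <- strsplit(meta$nesting, ";", fixed = TRUE)
  from <- rep(meta$family_id, lengths(partners))
  to <- unlist(partners, use.names = FALSE)
  keep <- nzchar(to)
  # symmetric closure: A nests B implies B nests A
  unique(c(paste0(from[keep], "\r", to[keep]), paste0(to[keep], "\r", from[keep])))
}

#' Do two candidates conflict?
#'
#' Candidates conflict when they overlap permissively and their family pair
#' is not on the curated nesting whitelist (families allowed to overlap
#' because one commonly inserts into the other; the whitelist is treated as
#' symmetric). Same-family and same-clan pairs get no special exemption
#' here — under the context model only spatial overlap creates conflict
#' (clan-based exclusion belongs to the Standard Pfam baseline,
#' [standard_pfam_filter()]).
#'
#' @inheritParams permissive_overlap
#' @param meta family metadata (see [load_family_meta()]).
#' @return logical.
#' @export
in_conflict <- function(d1, d2, meta, max_aa = 40L, max_frac = 0.5,
                        coords = c("env", "ali")) {
  if (!permissive_overlap(d1, d2, max_aa = max_aa, max_frac = max_frac,
                          coords = coords))
    return(FALSE)
  !(paste0(d1$family_id, "\r", d2$family_id) %in% nesting_key_set(meta))
}

#' Conflict edges among a protein's candidates
#'
#' Applies [in_conflict()] to all pairs, vectorized. Row indices refer to the
#' row order of `df` as given.
#'
#' @param df candidate data frame (one protein).
#' @inheritParams in_conflict
#' @return Integer matrix with two columns `i`, `j` (`i < j`), one row per
#'   conflicting pair.
#' @export
conflict_edges <- function(df, meta, max_aa = 40L, max_frac = 0.5,
                           coords = c("env", "ali")) {
  k <- nrow(df)
  if (k < 2) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  rc <- range_cols(coords)
  s <- df[[rc[1]]]; e <- df[[rc[2]]]
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- df$protein_id[i] == df$protein_id[j]
  ov <- overlap_length(s[i], e[i], s[j], e[j])
  shorter <- pmin(e[i] - s[i] + 1L, e[j] - s[j] + 1L)
  hit <- same & (ov > max_aa | ov > max_frac * shorter)
  if (any(hit)) {
    nest <- nesting_key_set(meta)
    hit[hit] <- !(paste0(df$family_id[i[hit]], "\r", df$family_id[j[hit]]) %in% nest)
  }
  cbind(i = i[hit], j = j[hit])
}

#' Cover all conflict edges with cliques (greedy heuristic)
#'
#' The ILP expresses "at most one of a mutually conflicting set" with one
#' constraint per clique; any family of cliques that (a) are cliques of the
#' conflict graph and (b) jointly contain every edge yields a correct ILP —
#' covers affect only speed. This greedy heuristic iterates edges in
#' lexicographic node order; for each not-yet-covered edge it seeds a clique
#' with the edge's endpoints and repeatedly adds the lowest-index node
#' adjacent to all current members. Cliques that end up nested inside another
#' are dropped. Deterministic, so rebuilt ILPs are identical.
#'
#' @param n_nodes number of candidates (nodes are `1:n_nodes`).
#' @param edges integer matrix of conflict edges (from [conflict_edges()]).
#' @return List of integer vectors (each sorted ascending, length >= 2);
#'   empty list for an edgeless graph.
#' @export
greedy_clique_cover <- function(n_nodes, edges) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  o <- order(edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  covered <- matrix(FALSE, n_nodes, n_nodes)
  cliques <- list()
  for (r in seq_len(nrow(edges))) {
    a <- as.integer(edges[r, 1]); b <- as.integer(edges[r, 2])
    if (covered[a, b]) next
    clique <- c(a, b)
    repeat {
      cand <- which(colSums(adj[clique, , drop = FALSE]) == length(clique))
      cand <- setdiff(cand, clique)
      if (length(cand) == 0) break
      clique <- c(clique, cand[1])
    }
    clique <- sort(clique)
    pairs <- which(upper.tri(matrix(0, length(clique), length(clique))), arr.ind = TRUE)
    covered[cbind(clique[pairs[, 1]], clique[pairs[, 2]])] <- TRUE
    cliques[[length(cliques) + 1]] <- clique
  }
  drop_nested_cliques(cliques)
}

drop_nested_cliques <- function(cliques) {
  if (length(cliques) <= 1) return(cliques)
  keep <- rep(TRUE, length(cliques))
  for (i in seq_along(cliques)) {
    for (j in seq_along(cliques)) {
      if (i == j || !keep[j]) next
      if (all(cliques[[i]] %in% cliques[[j]]) &&
          (length(cliques[[i]]) < length(cliques[[j]]) || i > j)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cliques[keep]
}
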