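#' Macro-averaged false discovery rate estimate
#'
#' Given per-prediction TP/FP labels, the estimated FDR is the average over
#' proteins of the per-protein false-positive fraction
#' `FP_i / (TP_i + FP_i)`; proteins without any prediction are excluded from
#' the average (and it is an error if no protein has one, since the estimate
#' is then undefined). The estimator is invariant to protein order and to
#' how a protein's labels are split across rows.
#'
#' @param labeled data frame with columns `protein_id` and `label`
#'   (`"TP"` or `"FP"`).
#' @return Estimate in `[0, 1]`, with attribute `"m"` (number of proteins
#'   contributing).
#' @export
fdr_estimate <- function(labeled) {
  stopifnot(is.data.frame(labeled),
            all(c("protein_id", "label") %in% names(labeled)))
  if (!all(labeled$label %in% c("TP", "FP")))
    stop("labels must be \"TP\" or \"FP\"")
  if (nrow(labeled) == 0)
    stop("FDR undefined: no protein has predictions")
  fp <- tapply(labeled$label == "FP", labeled$protein_id, mean)
  structure(mean(fp), m = length(fp))
}

#' Label pooled real/decoy predictions for the reversed-sequence FDR test
#'
#' In the RevSeq test, candidate domains are predicted on both the real
#' protein and its reversed-sequence decoy, pooled, and selected together;
#' selections on the real sequence count as TP and selections on the decoy
#' as FP. Because some families have near-palindromic signatures, a decoy
#' prediction that overlaps (by at least `min_overlap` residues, alignment
#' coordinates mapped back to the forward frame by the caller) a real
#' prediction of the same family on the same protein is removed rather than
#' counted as FP. The resulting estimate undercounts false discoveries by
#' about half (decoys model only one of two error directions), so the
#' reported FDR is `2 x` the raw estimate; both are returned and the
#' correction is never applied silently.
#'
#' @param real_preds,reversed_preds candidate data frames of selected
#'   predictions on the real and reversed sequences (forward-frame
#'   coordinates).
#' @param min_overlap residue overlap at or above which a same-family decoy
#'   prediction is removed (default 1, i.e. any shared residue).
#' @return A list: `labeled` (data frame with candidate columns plus `label`
#'   and `source`), `n_removed`, `doubling_factor = 2`, `fdr_raw` and
#'   `fdr_reported = 2 * fdr_raw` (both `NA` if no protein has predictions).
#' @export
revseq_label <- function(real_preds, reversed_preds, min_overlap = 1L) {
  removed <- rep(FALSE, nrow(reversed_preds))
  for (r in seq_len(nrow(reversed_preds))) {
    same <- real_preds$protein_id == reversed_preds$protein_id[r] &
      real_preds$family_id == reversed_preds$family_id[r]
    if (!any(same)) next
    ov <- overlap_length(real_preds$ali_start[same], real_preds$ali_end[same],
                         reversed_preds$ali_start[r], reversed_preds$ali_end[r])
    removed[r] <- any(ov >= min_overlap)
  }
  kept_rev <- reversed_preds[!removed, , drop = FALSE]
  labeled <- rbind(
    cbind(real_preds, label = rep("TP", nrow(real_preds)),
          source = rep("real", nrow(real_preds))),
    cbind(kept_rev, label = rep("FP", nrow(kept_rev)),
          source = rep("reversed", nrow(kept_rev)))
  )
  fdr_raw <- if (nrow(labeled) > 0) as.numeric(fdr_estimate(labeled)) else NA_real_
  list(labeled = labeled, n_removed = sum(removed), doubling_factor = 2,
       fdr_raw = fdr_raw, fdr_reported = 2 * fdr_raw)
}

#' Generate a synthetic selection instance
#'
#' Builds one protein's worth of candidate domains plus matching family
#' metadata and a random directed context network, for testing the full
#' scoring/pruning/ILP stack. The generated world is chosen so every
#' objective term is exercised:
#' \itemize{
#'   \item bit scores are drawn around the family domain thresholds
#'     (`bitscore = t_dom + rnorm(score_mean, score_sd)`), so with the
#'     defaults roughly half the candidates fail their threshold — the
#'     regime where context decides and where the PE/trivial/ILP branches
#'     all get exercised;
#'   \item intervals are placed left to right with small random gaps; with
#'     probability `conflict_rate` a candidate is instead placed to fully
#'     overlap a random earlier candidate, guaranteeing a permissive-overlap
#'     conflict;
#'   \item a fraction `frac_Ttilde_positive` of families get a sequence
#'     threshold strictly above `t_dom / 0.9`, so their surcharge survives
#'     the near-equal forcing rule;
#'   \item each ordered family pair is observed in the count network with
#'     probability `1 - frac_negative_context` (count `>= 2`); unobserved
#'     pairs score the negative penalty.
#' }
#'
#' @param k number of candidate domains.
#' @param n_families size of the family universe.
#' @param protein_length protein length in residues; an error is raised if
#'   `k` intervals cannot fit.
#' @param conflict_rate probability a candidate is placed in conflict.
#' @param score_mean,score_sd offset distribution of `bitscore - t_dom` in
#'   bits.
#' @param frac_negative_context fraction of ordered family pairs left
#'   unobserved in the count network.
#' @param frac_Ttilde_positive fraction of families with a positive
#'   sequence-threshold surcharge.
#' @param alpha Dirichlet concentration for the context model.
#' @param protein_id identifier given to the protein.
#' @param world optionally, a list with elements `meta`, `counts` and
#'   `model` from a previous instance: the family universe and context
#'   network are reused instead of redrawn, so several proteins can share
#'   one world (see [generate_dataset()]).
#' @param seed integer RNG seed; the instance is a pure function of the seed
#'   and parameters (the caller's RNG state is restored on exit).
#' @return An object of class `synthetic_instance`: `candidates`, `meta`,
#'   `counts`, `model`, `protein_length`, `seed`, `params`.
#' @export
generate_instance <- function(k = 8, n_families = 6, protein_length = 2000,
                              conflict_rate = 0.25, score_mean = 0,
                              score_sd = 6, frac_negative_context = 0.5,
                              frac_Ttilde_positive = 0.2, alpha = 1e-3,
                              protein_id = "SYNTH_P1", world = NULL, seed) {
  stopifnot(k >= 0, n_families >= 1, protein_length >= 1,
            conflict_rate >= 0, conflict_rate <= 1, score_sd >= 0,
            frac_negative_context >= 0, frac_negative_context <= 1,
            frac_Ttilde_positive >= 0, frac_Ttilde_positive <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  if (!is.null(world)) {
    meta <- world$meta
    counts <- world$counts
    model <- world$model
    families <- meta$family_id
    n_families <- length(families)
    t_dom <- meta$t_dom
    clan_id <- meta$clan_id
  } else {
  families <- sprintf("FAM%03d", seq_len(n_families))
  t_dom <- round(stats::runif(n_families, 18, 30), 1)
  t_seq <- t_dom
  n_tt <- round(frac_Ttilde_positive * n_families)
  if (n_tt > 0) {
    which_tt <- sample.int(n_families, n_tt)
    t_seq[which_tt] <- round(t_dom[which_tt] / 0.9 +
                               stats::runif(n_tt, 0.5, 4), 1)
  }
  clan_id <- rep("", n_families)
  n_clan_pairs <- floor(n_families / 3)
  if (n_clan_pairs >= 1) {
    for (q in seq_len(n_clan_pairs))
      clan_id[c(2 * q - 1, 2 * q)] <- sprintf("CL%03d", q)
  }
  meta <- data.frame(family_id = families, t_dom = t_dom, t_seq = t_seq,
                     t_tilde = compute_t_tilde(t_seq, t_dom),
                     clan_id = clan_id, nesting = "",
                     stringsAsFactors = FALSE)

  # directed count network over all ordered pairs (self-pairs included)
  pairs <- expand.grid(from = families, to = families,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  observed <- stats::runif(nrow(pairs)) >= frac_negative_context
  counts <- context_counts_df(pairs$from[observed], pairs$to[observed],
                              2L + stats::rpois(sum(observed), 5))
  model <- context_model(counts, families, alpha = alpha)
  }

  # interval placement
  ali_start <- integer(k); ali_end <- integer(k)
  cursor <- 1L
  for (i in seq_len(k)) {
    len <- sample(40:120, 1)
    if (i > 1 && stats::runif(1) < conflict_rate) {
      prev <- sample.int(i - 1, 1)
      # same start as an earlier interval: the shorter range is fully
      # contained, always a permissive overlap
      ali_start[i] <- ali_start[prev]
    } else {
      ali_start[i] <- cursor + sample(1:20, 1)
    }
    ali_end[i] <- ali_start[i] + len - 1L
    if (ali_end[i] > protein_length - 2L)
      stop("infeasible parameters: ", k, " intervals do not fit in ",
           protein_length, " residues")
    cursor <- max(cursor, ali_end[i])
  }
  fam_of <- sample(families, k, replace = TRUE)
  bit <- t_dom[match(fam_of, families)] + stats::rnorm(k, score_mean, score_sd)
  candidates <- candidate_domains(
    protein_id = rep(protein_id, length.out = k), family_id = fam_of,
    ali_start = ali_start, ali_end = ali_end,
    env_start = pmax(1L, ali_start - sample(0:3, k, replace = TRUE)),
    env_end = pmin(protein_length, ali_end + sample(0:3, k, replace = TRUE)),
    bitscore = round(bit, 1),
    pvalue = pmin(1, 2^(-pmax(bit, 0) / 1.5)),
    clan_id = clan_id[match(fam_of, families)]
  )
  structure(list(candidates = order_candidates(candidates), meta = meta,
                 counts = counts, model = model,
                 protein_length = protein_length, seed = seed,
                 params = list(k = k, n_families = n_families,
                               conflict_rate = conflict_rate,
                               score_mean = score_mean, score_sd = score_sd,
                               frac_negative_context = frac_negative_context,
                               frac_Ttilde_positive = frac_Ttilde_positive,
                               alpha = alpha)),
            class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat("synthetic_instance: seed", x$seed, "-", nrow(x$candidates),
      "candidates,", nrow(x$meta), "families, C =", x$model$C, "\n")
  invisible(x)
}

#' Generate a multi-protein synthetic dataset
#'
#' Draws one shared family universe / context network (from `seed`) and one
#' candidate set per protein (from `seed + i`), reusing
#' [generate_instance()].
#'
#' @inheritParams generate_instance
#' @param n_proteins number of proteins.
#' @return A list with `candidates` (all proteins stacked), `meta`, `counts`,
#'   `model`, `instances` (per-protein `synthetic_instance`s).
#' @export
generate_dataset <- function(n_proteins = 5, seed, ...) {
  stopifnot(n_proteins >= 1)
  dots <- list(...)
  shared_args <- dots
  shared_args$k <- 0
  shared <- do.call(generate_instance, c(shared_args, list(seed = seed)))
  world <- list(meta = shared$meta, counts = shared$counts,
                model = shared$model)
  insts <- lapply(seq_len(n_proteins), function(i) {
    do.call(generate_instance,
            c(dots, list(protein_id = sprintf("SYNTH_P%03d", i),
                         world = world, seed = seed + i)))
  })
  cands <- do.call(rbind, c(lapply(insts, `[[`, "candidates"),
                            list(make.row.names = FALSE)))
  list(candidates = cands, meta = shared$meta, counts = shared$counts,
       model = shared$model, instances = insts)
}
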