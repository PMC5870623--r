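# Internal: per-protein scoring arrays for candidates in start order.
# S[i, j] (i < j) is the directional context score of the pair at positions
# (i, j); the lower triangle and diagonal are 0. conflict is a symmetric
# logical matrix of pairwise conflicts.
scoring_arrays <- function(cands, meta, model, max_aa = 40L, max_frac = 0.5,
                           coords = c("env", "ali")) {
  k <- nrow(cands)
  t_dom <- meta$t_dom[match(cands$family_id, meta$family_id)]
  if (anyNA(t_dom))
    stop("family missing from metadata: ", cands$family_id[is.na(t_dom)][1])
  w <- cands$bitscore - t_dom
  S <- matrix(0, k, k)
  if (k >= 2) {
    idx <- which(upper.tri(S), arr.ind = TRUE)
    S[idx] <- pair_score(model, cands$family_id[idx[, 1]],
                         cands$family_id[idx[, 2]])
  }
  conflict <- matrix(FALSE, k, k)
  edges <- conflict_edges(cands, meta, max_aa = max_aa, max_frac = max_frac,
                          coords = coords)
  if (nrow(edges) > 0) {
    conflict[edges] <- TRUE
    conflict[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  fam <- cands$family_id
  t_tilde <- meta$t_tilde[match(fam, meta$family_id)]
  list(k = k, w = w, S = S, conflict = conflict, family = fam,
       t_tilde_by_cand = t_tilde)
}

#' Positive elimination
#'
#' Iterative sound pruning of candidates that cannot be in any optimal
#' subset. At each iteration every remaining candidate is scored
#' optimistically as
#' `S+_i = H_i - T^d + sum over remaining partners of max(0, S)`,
#' where the directional context score between two candidates is taken in
#' their start-coordinate order and forced to 0 for conflicting pairs (they
#' can never co-occur). A candidate with `S+_i < 0` would lower the objective
#' of any subset containing it even if every positive context materialized,
#' so it is removed. When no individual candidate is removable, every family
#' whose remaining candidates satisfy `sum S+_i < t_tilde` is removed whole
#' (its best-case contribution cannot pay the sequence-threshold surcharge).
#' Iteration stops at a fixpoint. The optimum over the survivors equals the
#' optimum over the input (tested against the brute-force oracle).
#'
#' Individual eliminations are applied before the family test within an
#' iteration: applying the family test while negative-`S+` candidates drag
#' the family sum down could unsoundly remove a family whose good candidates
#' alone meet the surcharge.
#'
#' @param candidates candidate data frame (one protein).
#' @param meta family metadata.
#' @param model a `context_model`.
#' @param ... overlap parameters (`max_aa`, `max_frac`, `coords`).
#' @return The surviving rows, in start order, with attribute
#'   `"pe_iterations"` (candidate count at the start of each iteration).
#' @export
positive_elimination <- function(candidates, meta, model, ...) {
  cands <- order_candidates(candidates)
  sizes <- integer(0)
  repeat {
    k <- nrow(cands)
    sizes <- c(sizes, k)
    if (k == 0) break
    arr <- scoring_arrays(cands, meta, model, ...)
    Spos <- pmax(arr$S, 0)
    Spos[arr$conflict] <- 0
    splus <- arr$w + rowSums(Spos) + colSums(Spos)
    if (any(splus < 0)) {
      cands <- cands[splus >= 0, , drop = FALSE]
      next
    }
    fam_sum <- tapply(splus, arr$family, sum)
    tt <- meta$t_tilde[match(names(fam_sum), meta$family_id)]
    bad_fams <- names(fam_sum)[fam_sum < tt]
    if (length(bad_fams) == 0) break
    cands <- cands[!(arr$family %in% bad_fams), , drop = FALSE]
  }
  attr(cands, "pe_iterations") <- sizes
  cands
}

#' Trivial-solution test
#'
#' After positive elimination, a survivor set can sometimes be returned as
#' the optimum directly, skipping the ILP. This implementation requires, for
#' the shortcut to fire, that the survivors have (a) no conflicting pair,
#' (b) no negative context score among ordered survivor pairs, (c) no
#' candidate with `H_i < T^d`, and (d) for every family,
#' `sum of (H_i - T^d) >= t_tilde`. Under (a)-(d) every term lost by
#' dropping any subset of survivors is non-negative, so the full survivor
#' set is optimal (see the methods vignette for the argument, and for a
#' counterexample showing that (a) and (b) alone — a commonly stated
#' shortcut condition — do not guarantee optimality).
#'
#' @inheritParams positive_elimination
#' @param survivors candidate data frame, normally the output of
#'   [positive_elimination()].
#' @return logical: `TRUE` when returning all survivors is provably optimal.
#' @export
is_trivial <- function(survivors, meta, model, ...) {
  k <- nrow(survivors)
  if (k <= 1) {
    if (k == 0) return(TRUE)
    arr <- scoring_arrays(order_candidates(survivors), meta, model, ...)
    return(arr$w[1] >= 0 && arr$w[1] >= arr$t_tilde_by_cand[1])
  }
  arr <- scoring_arrays(order_candidates(survivors), meta, model, ...)
  if (any(arr$conflict)) return(FALSE)
  if (any(arr$S[upper.tri(arr$S)] < 0)) return(FALSE)
  if (any(arr$w < 0)) return(FALSE)
  fam_w <- tapply(arr$w, arr$family, sum)
  tt <- meta$t_tilde[match(names(fam_w), meta$family_id)]
  all(fam_w >= tt)
}

#' Build the integer linear program for a survivor set
#'
#' Binary variables: `x_i` per candidate (in start order), `y_i_j` per
#' ordered pair with a nonzero context score, and `f_<family>` per family
#' with a positive sequence-threshold surcharge. The objective is
#' `sum x_i (H_i - T^d) + sum y_i_j S_ij - sum f_F t_tilde_F`. Constraints:
#' the tight AND linearization `y <= x_i`, `y <= x_j`, `y >= x_i + x_j - 1`
#' (its LP polytope has only integral vertices); the OR linearization
#' `f_F >= x_i` and `f_F <= sum x_i`; and one `sum_{i in C} x_i <= 1` row
#' per clique of the conflict cover.
#'
#' @inheritParams positive_elimination
#' @param survivors non-empty candidate data frame (one protein).
#' @param cliques conflict-clique cover from [greedy_clique_cover()];
#'   computed from the survivors when `NULL`.
#' @return An object of class `ilp_instance`: variables, objective
#'   coefficients, constraint rows, and the structured arrays the solver
#'   uses.
#' @export
build_ilp <- function(survivors, meta, model, cliques = NULL, ...) {
  stopifnot(nrow(survivors) > 0)
  cands <- order_candidates(survivors)
  arr <- scoring_arrays(cands, meta, model, ...)
  k <- arr$k
  if (is.null(cliques))
    cliques <- greedy_clique_cover(k, conflict_edges(cands, meta, ...))
  x_vars <- paste0("x", seq_len(k))
  pair_idx <- which(upper.tri(arr$S) & arr$S != 0, arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  y_vars <- if (nrow(pair_idx) > 0)
    paste0("y", pair_idx[, 1], "_", pair_idx[, 2]) else character(0)
  fams <- unique(arr$family)
  tt <- meta$t_tilde[match(fams, meta$family_id)]
  f_fams <- fams[tt > 0]
  f_tt <- tt[tt > 0]
  f_vars <- if (length(f_fams) > 0) paste0("f_", f_fams) else character(0)
  obj <- c(stats::setNames(arr$w, x_vars),
           stats::setNames(arr$S[pair_idx], y_vars),
           stats::setNames(-f_tt, f_vars))
  cons <- list()
  add <- function(type, vars, coef, dir, rhs) {
    cons[[length(cons) + 1]] <<- list(type = type, vars = vars, coef = coef,
                                      dir = dir, rhs = rhs)
  }
  for (p in seq_len(nrow(pair_idx))) {
    i <- pair_idx[p, 1]; j <- pair_idx[p, 2]; y <- y_vars[p]
    add("and_le_i", c(y, x_vars[i]), c(1, -1), "<=", 0)
    add("and_le_j", c(y, x_vars[j]), c(1, -1), "<=", 0)
    add("and_ge", c(y, x_vars[i], x_vars[j]), c(1, -1, -1), ">=", -1)
  }
  for (q in seq_along(f_fams)) {
    members <- x_vars[arr$family == f_fams[q]]
    for (mv in members) add("or_ge", c(f_vars[q], mv), c(1, -1), ">=", 0)
    add("or_le", c(f_vars[q], members), c(1, rep(-1, length(members))), "<=", 0)
  }
  for (cl in cliques)
    add("clique", x_vars[cl], rep(1, length(cl)), "<=", 1)
  structure(list(
    candidates = cands, k = k, variables = c(x_vars, y_vars, f_vars),
    objective = obj, constraints = cons, cliques = cliques,
    pair_idx = pair_idx, w = arr$w, S = arr$S, conflict = arr$conflict,
    family = arr$family, f_fams = f_fams, f_tt = f_tt
  ), class = "ilp_instance")
}

#' @export
print.ilp_instance <- function(x, ...) {
  cat("ilp_instance:", x$k, "candidate vars,", nrow(x$pair_idx), "pair vars,",
      length(x$f_fams), "family vars,", length(x$constraints), "constraints\n")
  invisible(x)
}

# Internal: check a 0/1 assignment (named vector) against all stored
# constraint rows; returns TRUE/FALSE.
ilp_feasible <- function(instance, x, tol = 1e-9) {
  for (cn in instance$constraints) {
    lhs <- sum(cn$coef * x[cn$vars])
    ok <- if (cn$dir == "<=") lhs <= cn$rhs + tol else lhs >= cn$rhs - tol
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Solve an ILP instance exactly
#'
#' An exact depth-first branch-and-bound over the candidate indicator
#' variables. The AND constraints force each pair variable to
#' `x_i AND x_j` and the OR constraints force each family variable to the
#' disjunction of its instances, so for any candidate assignment the
#' remaining variables (and hence the objective) are determined; branching is
#' therefore only over `x_i`, with clique constraints pruning conflicting
#' selections and an optimistic bound (each free candidate contributes at
#' most `max(0, w_i + sum of positive context)`) pruning the search. The
#' empty assignment is always feasible, so the optimum is never below 0.
#'
#' @param instance an `ilp_instance` from [build_ilp()].
#' @param timeout wall-clock limit in seconds; exceeding it raises an error
#'   of class `domctx_timeout` carrying the best bound found so far.
#' @return A list with `selected` (candidate indices in start order),
#'   `objective` (bits), `status = "optimal"`, `x` (the full named 0/1
#'   assignment) and `nodes` (search-tree nodes visited).
#' @export
solve_ilp <- function(instance, timeout = 60) {
  stopifnot(inherits(instance, "ilp_instance"))
  k <- instance$k
  w <- instance$w
  S <- instance$S
  conflict <- instance$conflict
  f_fams <- instance$f_fams
  tt <- stats::setNames(instance$f_tt, f_fams)
  fam <- instance$family
  Spos <- pmax(S, 0)
  Spos[conflict] <- 0
  gain <- pmax(0, w + rowSums(Spos) + colSums(Spos))
  suffix <- rev(cumsum(rev(gain)))
  suffix <- c(suffix, 0)
  st <- new.env(parent = emptyenv())
  st$best <- 0
  st$best_sel <- integer(0)
  st$nodes <- 0L
  t0 <- proc.time()[["elapsed"]]
  recurse <- function(i, sel, cur, famcnt) {
    st$nodes <- st$nodes + 1L
    if (st$nodes %% 8192L == 0L &&
        proc.time()[["elapsed"]] - t0 > timeout) {
      cnd <- simpleError(sprintf("ILP solve timed out after %gs (best bound %g)",
                                 timeout, st$best))
      class(cnd) <- c("domctx_timeout", class(cnd))
      attr(cnd, "best_bound") <- st$best
      stop(cnd)
    }
    if (cur + suffix[i] <= st$best + 1e-12 && i <= k) return(invisible())
    if (i > k) {
      if (cur > st$best + 1e-12) {
        st$best <- cur
        st$best_sel <- sel
      }
      return(invisible())
    }
    # branch: select i when no selected candidate conflicts with it
    if (!any(conflict[sel, i])) {
      delta <- w[i] + sum(S[sel, i])
      fi <- fam[i]
      newfam <- famcnt
      if (fi %in% f_fams) {
        if (famcnt[fi] == 0L) delta <- delta - tt[fi]
        newfam[fi] <- famcnt[fi] + 1L
      }
      recurse(i + 1L, c(sel, i), cur + delta, newfam)
    }
    recurse(i + 1L, sel, cur, famcnt)
  }
  famcnt0 <- stats::setNames(integer(length(f_fams)), f_fams)
  recurse(1L, integer(0), 0, famcnt0)
  sel <- st$best_sel
  x <- stats::setNames(numeric(length(instance$variables)), instance$variables)
  x[paste0("x", sel)] <- 1
  if (nrow(instance$pair_idx) > 0) {
    on <- instance$pair_idx[, 1] %in% sel & instance$pair_idx[, 2] %in% sel
    x[paste0("y", instance$pair_idx[on, 1], "_", instance$pair_idx[on, 2])] <- 1
  }
  if (length(f_fams) > 0)
    x[paste0("f_", f_fams[f_fams %in% fam[sel]])] <- 1
  stopifnot(ilp_feasible(instance, x))
  list(selected = sel, objective = st$best, status = "optimal", x = x,
       nodes = st$nodes)
}

# deterministic tie-break helper: is index set a "better" than b at equal
# objective? fewer members first, then lexicographically smaller index vector
tie_better <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  d <- which(a != b)
  if (length(d) == 0) return(FALSE)
  a[d[1]] < b[d[1]]
}

#' Brute-force oracle
#'
#' Enumerates every conflict-free subset of at most `limit` candidates and
#' returns the maximizer of [context_objective()]. Independent of the
#' PE/ILP path; exists to test it. Ties are broken toward fewer domains,
#' then the lexicographically smallest index set (in start order).
#'
#' @inheritParams positive_elimination
#' @param limit maximum candidate count (default 20; `2^k` subsets are
#'   enumerated).
#' @return A `domain_solution` (see [predict_domains()]) with
#'   `status = "optimal"` (or `"empty"` when nothing is selected).
#' @export
brute_force <- function(candidates, meta, model, limit = 20L, ...) {
  cands <- order_candidates(candidates)
  k <- nrow(cands)
  if (k > limit) stop("brute_force limited to ", limit, " candidates, got ", k)
  if (k == 0) return(new_solution(cands, 0, "empty", list(oracle = TRUE)))
  arr <- scoring_arrays(cands, meta, model, ...)
  Cnum <- arr$conflict * 1
  fams <- unique(arr$family)
  tt <- meta$t_tilde[match(fams, meta$family_id)]
  fam_cols <- lapply(fams[tt > 0], function(f) arr$family == f)
  tt <- tt[tt > 0]
  best <- 0
  best_sel <- integer(0)
  chunk <- 2^min(k, 14L)
  total <- 2^k
  for (base in seq(0, total - 1, by = chunk)) {
    ids <- base + seq_len(min(chunk, total - base)) - 1
    M <- matrix(0, length(ids), k)
    for (j in seq_len(k)) M[, j] <- (ids %/% 2^(j - 1)) %% 2
    feas <- rowSums((M %*% Cnum) * M) == 0
    if (!any(feas)) next
    M <- M[feas, , drop = FALSE]
    val <- as.numeric(M %*% arr$w) + rowSums((M %*% arr$S) * M)
    for (q in seq_along(tt))
      val <- val - tt[q] * (rowSums(M[, fam_cols[[q]], drop = FALSE]) > 0)
    for (r in seq_along(val)) {
      sel <- which(M[r, ] == 1)
      if (val[r] > best + 1e-12 ||
          (abs(val[r] - best) <= 1e-12 && tie_better(sel, best_sel))) {
        best <- val[r]
        best_sel <- sel
      }
    }
  }
  status <- if (length(best_sel) == 0) "empty" else "optimal"
  new_solution(cands[best_sel, , drop = FALSE], best, status,
               list(oracle = TRUE, enumerated = total))
}

new_solution <- function(candidates, objective, status, diagnostics = list()) {
  structure(list(candidates = candidates, objective = objective,
                 status = status, diagnostics = diagnostics),
            class = "domain_solution")
}

#' @export
print.domain_solution <- function(x, ...) {
  cat("domain_solution:", nrow(x$candidates), "domain(s), objective =",
      format(x$objective, digits = 8), "bits, status =", x$status, "\n")
  if (nrow(x$candidates) > 0)
    print(x$candidates[, c("family_id", "ali_start", "ali_end", "bitscore")])
  invisible(x)
}

#' Predict the optimal domain subset for one protein
#'
#' The full per-protein pipeline: positive elimination prunes hopeless
#' candidates; if the survivors pass the trivial-solution test they are
#' returned directly; otherwise the conflict graph is covered with cliques,
#' the ILP is built and solved exactly. The returned objective is always
#' `>= 0` (the empty set is a feasible solution scoring 0). Proteins are
#' independent under the model, so callers map this over proteins in any
#' order.
#'
#' @inheritParams positive_elimination
#' @param timeout ILP time limit in seconds.
#' @param use_pe disable positive elimination (for testing) with `FALSE`.
#' @return A `domain_solution`: `candidates` (selected rows, start order),
#'   `objective` in bits, `status` (`"optimal"`, `"trivial"` or `"empty"`),
#'   and `diagnostics` (input size, survivor count, whether the ILP ran,
#'   nodes visited).
#' @export
predict_domains <- function(candidates, meta, model, timeout = 60,
                            use_pe = TRUE, ...) {
  cands <- order_candidates(candidates)
  k_in <- nrow(cands)
  if (k_in == 0)
    return(new_solution(cands, 0, "empty",
                        list(k_in = 0L, k_survivors = 0L, used_ilp = FALSE)))
  surv <- if (use_pe) positive_elimination(cands, meta, model, ...) else cands
  diag <- list(k_in = k_in, k_survivors = nrow(surv), used_ilp = FALSE,
               pe_iterations = attr(surv, "pe_iterations"))
  if (nrow(surv) == 0)
    return(new_solution(surv, 0, "empty", diag))
  if (is_trivial(surv, meta, model, ...)) {
    obj <- context_objective(surv, meta, model, check_conflicts = FALSE)
    status <- if (nrow(surv) == 0) "empty" else "trivial"
    return(new_solution(surv, obj, status, diag))
  }
  cliques <- greedy_clique_cover(nrow(surv),
                                 conflict_edges(surv, meta, ...))
  inst <- build_ilp(surv, meta, model, cliques = cliques, ...)
  sol <- solve_ilp(inst, timeout = timeout)
  sel <- inst$candidates[sol$selected, , drop = FALSE]
  obj <- context_objective(sel, meta, model, check_conflicts = FALSE)
  stopifnot(abs(obj - sol$objective) <= 1e-6)
  diag$used_ilp <- TRUE
  diag$nodes <- sol$nodes
  status <- if (nrow(sel) == 0) "empty" else "optimal"
  new_solution(sel, obj, status, diag)
}
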