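# In-code fixtures shared across the suite; everything is built
# programmatically so tests carry no data files.

# quick candidate table: non-overlapping by default (laid left to right)
cand <- function(fam, s, e, H, protein = "P1", p = 1e-6, clan = "",
                 env_s = s, env_e = e) {
  candidate_domains(protein_id = protein, family_id = fam,
                    ali_start = s, ali_end = e, bitscore = H, pvalue = p,
                    env_start = env_s, env_end = env_e, clan_id = clan)
}

# family metadata with t_dom = 0 by default so bitscores read directly as
# H - T^d in hand-computed examples
mk_meta <- function(family_id, t_dom = 0, t_seq = t_dom, clan_id = "",
                    nesting = "") {
  data.frame(family_id = family_id, t_dom = t_dom, t_seq = t_seq,
             t_tilde = compute_t_tilde(t_seq, t_dom), clan_id = clan_id,
             nesting = nesting, stringsAsFactors = FALSE)
}

# context model from explicit pair counts; `pairs` is a data frame
# from/to/count or NULL for an empty network (all scores zero)
mk_model <- function(families, pairs = NULL, alpha = 1e-3) {
  counts <- if (is.null(pairs)) load_context_counts(character(0))
  else load_context_counts(sprintf("%s\t%s\t%d", pairs$from, pairs$to,
                                   as.integer(pairs$count)))
  context_model(counts, families, alpha = alpha)
}

# a model whose every score is a fixed value for observed pairs is awkward to
# construct from counts; for hand-built objective examples we instead forge
# the score table directly (tests of scoring arithmetic, not of estimation)
forge_model <- function(families, scores = list(), penalty = 0) {
  env <- new.env(parent = emptyenv())
  for (key in names(scores)) {
    ft <- strsplit(key, ">", fixed = TRUE)[[1]]
    env[[paste0(ft[1], "\r", ft[2])]] <- scores[[key]]
  }
  structure(list(families = families, n = length(families), alpha = 1e-3,
                 C = 1L, penalty = penalty, scores = env),
            class = "context_model")
}

# one hand-assembled well-formed domtblout line (hmmscan dialect)
domtbl_line <- function(fam = "FAM1", prot = "PROT1", score = 31.4,
                        ieval = "2e-09", ali = c(5, 60), env = c(2, 63)) {
  paste(fam, "PF00001.1", 80, prot, "-", 500, "1e-09", 33.0, 0.1, 1, 1,
        "3e-09", ieval, score, 0.1, 1, 56, ali[1], ali[2], env[1], env[2],
        0.92, "some description text")
}
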