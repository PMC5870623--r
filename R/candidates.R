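#' Construct a table of candidate domains
#'
#' A candidate domain is one scored match of a profile-HMM family to a region
#' of a protein: the unit that domain selection operates on. Candidates are
#' kept in an ordinary data frame with one row per match; all coordinates are
#' 1-based inclusive residue positions, exactly as HMMER reports them. The
#' alignment span (`ali_start`..`ali_end`) is the aligned match; the envelope
#' (`env_start`..`env_end`) is HMMER's wider estimate of the homologous
#' region and must contain the alignment span.
#'
#' @param protein_id character, protein (query) identifier.
#' @param family_id character, domain family (HMM) identifier.
#' @param ali_start,ali_end integer, alignment coordinates.
#' @param bitscore numeric, per-domain bit score (the log2-odds score H of the
#'   match versus the background residue model).
#' @param pvalue numeric in (0, 1], per-domain P-value.
#' @param env_start,env_end integer, envelope coordinates; default to the
#'   alignment coordinates.
#' @param clan_id character, Pfam clan of the family ("" when unassigned).
#'
#' @return A data frame with columns `protein_id`, `family_id`, `clan_id`,
#'   `ali_start`, `ali_end`, `env_start`, `env_end`, `bitscore`, `pvalue`.
#' @export
#' @examples
#' candidate_domains("P1", c("A", "B"), c(10, 90), c(60, 140),
#'                   bitscore = c(31.4, 12.0), pvalue = c(2e-9, 1e-3))
candidate_domains <- function(protein_id, family_id, ali_start, ali_end,
                              bitscore, pvalue,
                              env_start = ali_start, env_end = ali_end,
                              clan_id = "") {
  n <- length(ali_start)
  df <- data.frame(
    protein_id = rep(as.character(protein_id), length.out = n),
    family_id  = as.character(family_id),
    clan_id    = rep(as.character(clan_id), length.out = n),
    ali_start  = as.integer(ali_start),
    ali_end    = as.integer(ali_end),
    env_start  = as.integer(env_start),
    env_end    = as.integer(env_end),
    bitscore   = as.numeric(bitscore),
    pvalue     = as.numeric(pvalue),
    stringsAsFactors = FALSE
  )
  validate_candidates(df)
  df
}

candidate_columns <- c("protein_id", "family_id", "clan_id",
                       "ali_start", "ali_end", "env_start", "env_end",
                       "bitscore", "pvalue")

#' Validate candidate-domain invariants
#'
#' Checks coordinate ordering (`ali_start <= ali_end`, envelope contains the
#' alignment), finite bit scores and P-values in (0, 1]. Called by all
#' constructors and loaders; exported so user-assembled data frames can be
#' checked too.
#'
#' @param df candidate data frame (see [candidate_domains()]).
#' @param where character used to label error messages (e.g. a file name).
#' @return `df`, invisibly, on success.
#' @export
validate_candidates <- function(df, where = "candidates") {
  stopifnot(is.data.frame(df))
  miss <- setdiff(candidate_columns, names(df))
  if (length(miss) > 0)
    stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  bad <- function(i, msg) {
    if (any(i)) stop(where, ", row ", which(i)[1], ": ", msg)
  }
  bad(df$ali_start > df$ali_end, "coordinates out of order (ali_start > ali_end)")
  bad(df$env_start > df$ali_start, "envelope does not contain alignment (env_start > ali_start)")
  bad(df$ali_end > df$env_end, "envelope does not contain alignment (ali_end > env_end)")
  bad(df$ali_start < 1L, "coordinates must be positive (1-based)")
  bad(df$env_start < 1L, "coordinates must be positive (1-based)")
  bad(!is.finite(df$bitscore), "non-finite bit score")
  bad(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
      "P-value outside (0, 1]")
  invisible(df)
}

#' Order candidates by position along the protein
#'
#' The selection objective sums a directional context term over candidate
#' pairs in start-coordinate order, so the ordering convention matters.
#' Candidates are sorted by `ali_start`, ties broken by `ali_end`, then by
#' `family_id` lexicographically (in the C locale), making builds
#' deterministic.
#'
#' @param df candidate data frame.
#' @return `df` with rows reordered.
#' @export
order_candidates <- function(df) {
  if (nrow(df) <= 1) return(df)
  o <- order(df$ali_start, df$ali_end, df$family_id, method = "radix")
  df[o, , drop = FALSE]
}
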