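#' Parse an HMMER3 per-domain hit table (domtblout)
#'
#' Reads the whitespace-delimited per-domain table written by
#' `hmmscan --domtblout`. Each non-comment line has 22 positional fields plus
#' a free-text description; for `hmmscan` the target (columns 1-3) is the HMM
#' family and the query (columns 4-6) is the protein. The per-domain bit
#' score is taken from the "this domain" score column (14) and the P-value
#' from the independent E-value column (13).
#'
#' The documented upstream contract is that `hmmscan` was run with
#' `-Z 1 --domZ 1`, which makes the E-value columns hold P-values. If the
#' search was run against a database of size Z instead, pass `z` and the
#' loader rescales `pvalue = evalue / z` (capped at 1).
#'
#' @param input path to a domtblout file, or a character vector of lines.
#' @param z optional search-space size used to convert E-values back to
#'   P-values; `NULL` (default) means the values are already P-values.
#' @return A candidate data frame (see [candidate_domains()]); `clan_id` is
#'   empty — clans live in the family metadata, not in domtblout.
#' @export
parse_domtblout <- function(input, z = NULL) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    readLines(input) else as.character(input)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(empty_candidates())
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23)) {
    i <- which(nf < 23)[1]
    stop("domtblout line ", idx[i], ": expected >= 23 fields, got ", nf[i])
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("domtblout line ", idx[i], ": non-numeric ", what)
    }
    v
  }
  pvalue <- num(13, "i-Evalue")
  if (!is.null(z)) {
    stopifnot(is.numeric(z), z > 0)
    pvalue <- pmin(pvalue / z, 1)
  }
  df <- data.frame(
    protein_id = vapply(fields, `[[`, "", 4),
    family_id  = vapply(fields, `[[`, "", 1),
    clan_id    = "",
    ali_start  = as.integer(num(18, "ali coordinate")),
    ali_end    = as.integer(num(19, "ali coordinate")),
    env_start  = as.integer(num(20, "env coordinate")),
    env_end    = as.integer(num(21, "env coordinate")),
    bitscore   = num(14, "domain score"),
    pvalue     = pvalue,
    stringsAsFactors = FALSE
  )
  validate_candidates(df, where = "domtblout")
  df
}

empty_candidates <- function() {
  candidate_domains(character(0), character(0), integer(0), integer(0),
                    numeric(0), numeric(0))
}

#' Write candidates as a domtblout-dialect table
#'
#' Emits a file in the HMMER3 `--domtblout` column layout so that synthetic
#' instances can be fed back through [parse_domtblout()] and the CLI.
#' Full-sequence and unavailable columns are filled with placeholders.
#'
#' @param df candidate data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(df, path) {
  validate_candidates(df)
  header <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  lines <- header
  if (nrow(df) > 0) {
    hlen <- df$ali_end - df$ali_start + 1L
    lines <- c(lines, sprintf(
      "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.90 -",
      df$family_id, hlen, df$protein_id, df$env_end + 10L,
      df$pvalue, df$bitscore, df$pvalue, df$pvalue, df$bitscore,
      hlen, df$ali_start, df$ali_end, df$env_start, df$env_end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load per-family metadata (thresholds, clan, nesting partners)
#'
#' Reads a tab-separated table with header columns `family_id`, `t_seq`,
#' `t_dom`, `clan_id`, `nesting` (semicolon-joined family ids; both `clan_id`
#' and `nesting` may be empty). `t_dom` is the curated per-domain gathering
#' threshold in bits and `t_seq` the per-family sequence threshold: the sum
#' of bit scores over a family's accepted domains in one protein must reach
#' `t_seq`.
#'
#' The derived column `t_tilde = t_seq - t_dom` is the extra sequence-level
#' cost a family pays in the selection objective. It is forced to 0 when the
#' thresholds coincide, when `t_dom >= (9/10) * t_seq` (families whose
#' sequence threshold is nearly implied by the domain threshold are treated
#' as if it were), and whenever the difference would be negative.
#'
#' @param input path to the TSV, or a character vector of lines.
#' @return A data frame with columns `family_id`, `t_dom`, `t_seq`,
#'   `t_tilde`, `clan_id`, `nesting`.
#' @export
load_family_meta <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    readLines(input) else as.character(input)
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          blank.lines.skip = TRUE)
  need <- c("family_id", "t_seq", "t_dom")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("family metadata: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$family_id))
    stop("family metadata: duplicate family_id: ",
         df$family_id[duplicated(df$family_id)][1])
  t_seq <- as.numeric(df$t_seq)
  t_dom <- as.numeric(df$t_dom)
  if (anyNA(t_seq) || anyNA(t_dom))
    stop("family metadata: non-numeric threshold")
  out <- data.frame(
    family_id = df$family_id,
    t_dom = t_dom,
    t_seq = t_seq,
    t_tilde = compute_t_tilde(t_seq, t_dom),
    clan_id = if ("clan_id" %in% names(df)) df$clan_id else "",
    nesting = if ("nesting" %in% names(df)) df$nesting else "",
    stringsAsFactors = FALSE
  )
  out$clan_id[is.na(out$clan_id)] <- ""
  out$nesting[is.na(out$nesting)] <- ""
  out
}

#' Sequence-threshold surcharge for a family
#'
#' `t_tilde = t_seq - t_dom`, forced to 0 when negative or when
#' `t_dom >= (9/10) * t_seq` (the near-equal case where the sequence
#' threshold is ignored).
#'
#' @param t_seq,t_dom numeric vectors of thresholds in bits.
#' @return numeric vector of surcharges, all `>= 0`.
#' @export
compute_t_tilde <- function(t_seq, t_dom) {
  tt <- t_seq - t_dom
  tt[tt < 0 | t_dom >= 0.9 * t_seq] <- 0
  tt
}

#' Write family metadata
#'
#' @param meta metadata data frame from [load_family_meta()] (the derived
#'   `t_tilde` column is not written; it is recomputed on load).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_family_meta <- function(meta, path) {
  out <- meta[, c("family_id", "t_seq", "t_dom", "clan_id", "nesting")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load / write a directed family-pair count network
#'
#' The context network is a directed multigraph summary: `count(i, j)` is the
#' number of times a domain instance of family `i` occurred before an
#' instance of family `j` within one protein, accumulated over a large
#' database. The file is header-less TSV with rows `family_i family_j count`.
#' Rows with `count == 1` are dropped at load time (singleton pairs are
#' assumed to be annotation errors); zero or negative counts and duplicate
#' ordered pairs are errors.
#'
#' @param input path to the TSV, or a character vector of lines.
#' @return An object of class `context_counts`: a data frame with columns
#'   `from`, `to`, `count` plus attribute `C`, the total count (after
#'   dropping singletons).
#' @export
load_context_counts <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    readLines(input) else as.character(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(context_counts_df(character(0), character(0), integer(0)))
  df <- utils::read.delim(text = lines, header = FALSE, sep = "\t",
                          colClasses = c("character", "character", "numeric"),
                          quote = "")
  if (ncol(df) != 3) stop("context counts: expected 3 tab-separated columns")
  names(df) <- c("from", "to", "count")
  if (anyNA(df$count) || any(df$count != round(df$count)))
    stop("context counts: non-integer count")
  if (any(df$count <= 0)) stop("context counts: count must be positive")
  if (anyDuplicated(paste0(df$from, "\r", df$to)))
    stop("context counts: duplicate ordered pair")
  context_counts_df(df$from, df$to, as.integer(df$count))
}

context_counts_df <- function(from, to, count) {
  keep <- count >= 2L
  df <- data.frame(from = as.character(from)[keep], to = as.character(to)[keep],
                   count = as.integer(count)[keep], stringsAsFactors = FALSE)
  attr(df, "C") <- sum(df$count)
  class(df) <- c("context_counts", "data.frame")
  df
}

#' @rdname load_context_counts
#' @param counts a `context_counts` object.
#' @param path output file path.
#' @export
write_context_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts)[, c("from", "to", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Total count of a context network
#'
#' @param counts a `context_counts` object.
#' @return The total `C` over all retained ordered pairs.
#' @export
total_count <- function(counts) {
  c0 <- attr(counts, "C")
  if (is.null(c0)) sum(counts$count) else c0
}

#' Read ordered domain architectures
#'
#' One line per protein: `protein_id<TAB>fam1,fam2,...` with families listed
#' in start-coordinate order.
#'
#' @param input path or character vector of lines.
#' @return Named list of character vectors (one per protein).
#' @export
read_architectures <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    readLines(input) else as.character(input)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("architectures: expected 2 tab-separated fields")
  ids <- vapply(parts, `[[`, "", 1)
  archs <- strsplit(vapply(parts, `[[`, "", 2), ",", fixed = TRUE)
  names(archs) <- ids
  archs
}

#' Write prediction records
#'
#' One row per predicted domain, sorted by protein then `ali_start`, with the
#' within-protein rank, the protein's solution objective (bits) and the
#' solver status. A constant `#` comment line leads the file so repeated runs
#' on identical inputs are byte-identical.
#'
#' @param pred prediction data frame (candidate columns plus `rank`,
#'   `objective`, `status`).
#' @param path output file path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(all(is.finite(pred$objective)))
  o <- order(pred$protein_id, pred$ali_start, pred$ali_end, pred$family_id,
             method = "radix")
  pred <- pred[o, , drop = FALSE]
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines("# domctx predictions", con)
  cols <- c(candidate_columns, "rank", "objective", "status")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(pred) > 0) {
    body <- do.call(paste, c(lapply(cols, function(cl) {
      v <- pred[[cl]]
      if (is.numeric(v) && !is.integer(v)) format(v, digits = 10, trim = TRUE) else as.character(v)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Export predictions as GFF3
#'
#' Writes standard 1-based GFF3 using the family as the feature type and the
#' alignment span as the feature coordinates; the bit score goes in the score
#' column.
#'
#' @param pred prediction data frame (as in [write_predictions()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(pred, path) {
  o <- order(pred$protein_id, pred$ali_start, pred$ali_end, pred$family_id,
             method = "radix")
  pred <- pred[o, , drop = FALSE]
  lines <- "##gff-version 3"
  if (nrow(pred) > 0) {
    attrs <- sprintf("ID=%s.%d;family=%s;pvalue=%g", pred$protein_id,
                     seq_len(nrow(pred)), pred$family_id, pred$pvalue)
    lines <- c(lines, sprintf("%s\tdomctx\t%s\t%d\t%d\t%.1f\t.\t.\t%s",
                              pred$protein_id, pred$family_id,
                              pred$ali_start, pred$ali_end, pred$bitscore, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
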