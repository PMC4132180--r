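## File formats: line / cross TSV tables, the pattern-notation dialect, YAML
## run configuration and provenance records.

.check_counts <- function(df, zzcol = "zz", totcol = "total", what = "row") {
  bad <- which(!is.finite(df[[zzcol]]) | !is.finite(df[[totcol]]) |
               df[[zzcol]] < 0 | df[[zzcol]] > df[[totcol]] | df[[totcol]] < 0)
  if (length(bad))
    stop("invalid counts (zz > total or negative) in ", what, " ",
         bad[1L], call. = FALSE)
  invisible(df)
}

#' Read a line table
#'
#' Tab-separated with header `family line zz total [balancer]`.
#'
#' @param path file path.
#' @return Data frame of line records; malformed counts raise an error naming
#'   the offending row.
#' @export
read_lines_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "line", "zz", "total")
  if (!all(need %in% names(df)))
    stop("line table must have columns ", paste(need, collapse = ", "))
  if (!"balancer" %in% names(df)) df$balancer <- rep(FALSE, nrow(df))
  df$balancer <- as.logical(df$balancer)
  .check_counts(df, what = "line-table row")
}

#' Read a cross table
#'
#' Tab-separated with header `family line_a line_b zz total`.
#'
#' @param path file path.
#' @return Data frame of cross records.
#' @export
read_crosses_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "line_a", "line_b", "zz", "total")
  if (!all(need %in% names(df)))
    stop("cross table must have columns ", paste(need, collapse = ", "))
  .check_counts(df, what = "cross-table row")
}

#' Write line / cross tables
#'
#' @param df data frame as returned by [read_lines_tsv()] /
#'   [read_crosses_tsv()] or produced by [generate_experiment()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_lines_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lines_tsv
#' @export
write_crosses_tsv <- write_lines_tsv

#' Format a pattern tally in screen notation
#'
#' One block per family size: a `families: N` header (total families of that
#' size, mutant or not) followed by the pattern line, e.g.
#' `20: <1>^11 <2> <3> <17> <1,1>^2`.
#'
#' @param tally a [pattern_tally()].
#' @return Character vector of text lines.
#' @export
format_pattern_notation <- function(tally) {
  stopifnot(inherits(tally, "pattern_tally"))
  out <- character(0)
  for (fs in names(tally$families)) {
    rows <- tally$entries[tally$entries$f == as.integer(fs), , drop = FALSE]
    toks <- vapply(seq_len(nrow(rows)), function(i) {
      t <- paste0("<", rows$key[i], ">")
      if (rows$n[i] > 1L) paste0(t, "^", rows$n[i]) else t
    }, character(1))
    out <- c(out, paste0("families: ", tally$families[[fs]]),
             paste0(fs, ": ", paste(toks, collapse = " ")))
  }
  out
}

#' Parse pattern-tally notation
#'
#' Inverse of [format_pattern_notation()]; `parse` after `format` is the
#' identity.  A missing `families:` header takes the listed patterns as the
#' complete family set.
#'
#' @param text character vector of lines, or one string with embedded
#'   newlines.
#' @return A [pattern_tally()].
#' @examples
#' t <- parse_pattern_notation(c("families: 111",
#'                               "20: <1>^11 <2> <3> <17> <1,1>^2"))
#' tally_summary(t)$mutant_families  # 16
#' @export
parse_pattern_notation <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- data.frame(f = integer(0), key = character(0), n = integer(0))
  families <- integer(0)
  pending <- NA_integer_
  for (li in seq_along(lines)) {
    ln <- lines[li]
    if (grepl("^families:", ln)) {
      pending <- as.integer(sub("^families:\\s*", "", ln))
      if (is.na(pending)) stop("malformed families header at line ", li)
      next
    }
    m <- regmatches(ln, regexec("^([0-9]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed pattern line at line ", li, ": ", ln)
    f <- as.integer(m[2L])
    body <- m[3L]
    nmut <- 0L
    nempty <- 0L
    if (nzchar(body)) {
      toks <- strsplit(body, "\\s+")[[1L]]
      for (tk in toks) {
        tm <- regmatches(tk, regexec("^<([0-9,\\s]*)>(\\^([0-9]+))?$", tk))[[1L]]
        if (!length(tm))
          stop("malformed pattern token '", tk, "' at line ", li)
        sizes <- .key_sizes(gsub("\\s", "", tm[2L]))
        n <- if (nzchar(tm[4L])) as.integer(tm[4L]) else 1L
        if (length(sizes)) {
          entries <- rbind(entries,
                           data.frame(f = f, key = .sizes_key(sizes), n = n))
          nmut <- nmut + n
        } else {
          nempty <- nempty + n
        }
      }
    }
    tot <- if (!is.na(pending)) pending else nmut + nempty
    families[as.character(f)] <-
      if (is.na(families[as.character(f)])) tot
      else families[[as.character(f)]] + tot
    pending <- NA_integer_
  }
  families <- families[!is.na(families)]
  if (nrow(entries)) {
    agg <- stats::aggregate(n ~ f + key, data = entries, FUN = sum)
  } else {
    agg <- entries
  }
  new_pattern_tally(agg, families)
}

#' Read a run configuration
#'
#' YAML (or JSON) block describing the germline model, e.g.
#' `{"D": 38, "n5": 6, "n8": 8, "stem_cap": 128, "partition": [1, 2, 14, -5]}`.
#'
#' @param path path to a YAML/JSON file.
#' @return List with `partition` (an [interval_partition()]), `dyn`
#'   (a [germline_dynamics()]) and the raw fields.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  D <- cfg$D %||% 38
  partition <- interval_partition(unlist(cfg$partition), D)
  dyn <- germline_dynamics(D, cfg$n5 %||% 6, cfg$n8 %||% 8,
                           stem_cap = cfg$stem_cap %||% 128)
  c(list(partition = partition, dyn = dyn), cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a provenance record
#'
#' JSON sidecar recording the seed, configuration fields and package version
#' of a run, sufficient to reproduce its outputs.
#'
#' @param path output path.
#' @param seed integer seed used.
#' @param config list of configuration fields (serializable values only).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, seed, config = list()) {
  rec <- list(package = "mutscreen",
              version = as.character(utils::packageVersion("mutscreen")),
              seed = seed, config = config,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
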