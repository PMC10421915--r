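# Rule-based parser for free-text coronary procedure reports.
#
# Reports are segmented into clauses at commas and periods. Each clause is
# matched against a segment dictionary (artery names plus positional
# modifiers); a stenosis percentage is read from the 1-3 digit number
# nearest a "%" glyph, and occlusion keywords ("thrombus", "obstruction",
# "occlusion") assign 100%. Ostial segments merge into proximal, all
# left-main subdivisions merge into the left-main class, and the most
# severe stenosis per canonical segment is retained (the REPORT-stenosis
# label). Qualitative-only clauses and excluded territories (diagonals,
# marginals, septals, ramus, grafts) yield no record.

#' Load the coronary segment dictionary
#'
#' The dictionary is a three-column table (`kind`, `key`, `synonym`):
#' `artery` rows name the five artery roots (left main, LAD, LCX, RCA,
#' PDA), `position` rows the ostial/proximal/mid/distal modifiers, and
#' `excluded` rows territories whose stenoses are dropped. Matching is
#' case-insensitive on word boundaries, longest synonym first. The shipped
#' table is a seed; users may extend it with their own file.
#'
#' @param path optional path to a custom TSV; default is the packaged
#'   dictionary.
#' @return data.frame with columns `kind`, `key`, `synonym`.
#' @export
default_segment_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "segment_dictionary.tsv",
                        package = "angiopipe", mustWork = TRUE)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "key", "synonym") %in% names(d)))
  if (anyDuplicated(d[c("kind", "synonym")]))
    stop("duplicate synonyms within a dictionary kind")
  d
}

#' Split report text into clauses
#'
#' Splits on commas and periods, trims whitespace and drops empty clauses.
#'
#' @param text a character scalar (plain UTF-8 report text).
#' @return character vector of clauses (possibly empty).
#' @export
segment_sentences <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character())
  parts <- strsplit(text, "[.,]")[[1L]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Find the longest dictionary synonym of a given kind present in `clause`
# (case-insensitive, word boundaries). Returns list(key, synonym) or NULL.
match_synonym <- function(clause, dictionary, kind) {
  rows <- dictionary[dictionary$kind == kind, , drop = FALSE]
  rows <- rows[order(-nchar(rows$synonym)), , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              rows$synonym[i]), "\\b")
    if (grepl(pat, clause, ignore.case = TRUE, perl = TRUE)) {
      return(list(key = rows$key[i], synonym = rows$synonym[i]))
    }
  }
  NULL
}

#' Extract the stenosis percentage from a clause
#'
#' Finds `%` glyphs and returns the 1-3 digit number whose end is nearest
#' (in characters) to a `%`; ties favour the number preceding the glyph.
#' Numbers above 100 are ignored. For ranges such as "90-95%" the digit
#' run adjacent to the glyph (the upper bound) wins by distance.
#'
#' @param clause one sentence fragment.
#' @return integer percent in `[0, 100]`, or `NA` if the clause carries no
#'   `%` token.
#' @export
extract_percent <- function(clause) {
  pct <- gregexpr("%", clause, fixed = TRUE)[[1L]]
  if (pct[1L] == -1L) return(NA_integer_)
  runs <- gregexpr("(?<!\\d)\\d{1,3}(?!\\d)", clause, perl = TRUE)[[1L]]
  if (runs[1L] == -1L) return(NA_integer_)
  starts <- as.integer(runs)
  ends <- starts + attr(runs, "match.length") - 1L
  vals <- as.integer(substring(clause, starts, ends))
  keep <- vals <= 100L
  if (!any(keep)) return(NA_integer_)
  starts <- starts[keep]; ends <- ends[keep]; vals <- vals[keep]
  best <- NULL; best_d <- Inf
  for (p in pct) {
    # distance between the digit run's end and the % glyph; a run after
    # the glyph is measured from its start
    d <- ifelse(ends < p, p - ends, starts - p)
    # ties -> preceding number
    ord <- order(d, ifelse(ends < p, 0L, 1L), -ends)
    if (d[ord[1L]] < best_d) {
      best_d <- d[ord[1L]]
      best <- vals[ord[1L]]
    }
  }
  as.integer(best)
}

occlusion_keywords <- function() c("occlu", "thromb", "obstruct")

has_occlusion_keyword <- function(clause) {
  any(vapply(occlusion_keywords(), grepl, logical(1), x = clause,
             ignore.case = TRUE))
}

#' Apply the occlusion-keyword rule to a clause
#'
#' If the clause contains "thrombus", "obstruction" or "occlusion" (any
#' inflection), a 100% stenosis is assigned to the matched segment.
#'
#' @param clause sentence fragment already matched to a segment.
#' @param matched_segment canonical (or pre-merge) segment label.
#' @return a one-row stenosis record data.frame, or `NULL` if no keyword
#'   is present.
#' @export
apply_occlusion_rule <- function(clause, matched_segment) {
  if (!has_occlusion_keyword(clause)) return(NULL)
  data.frame(segment = matched_segment, percent = 100L,
             source = "occlusion_keyword", clause = clause,
             stringsAsFactors = FALSE)
}

#' Merge pre-merge segment labels onto the 11-segment scheme
#'
#' Ostial labels merge into the proximal class of the same artery; all
#' left-main subdivisions merge into `lm`. Canonical labels pass through.
#'
#' @param labels character vector of pre-merge labels such as
#'   `"rca_ostial"` or `"lm_mid"`.
#' @return character vector of canonical labels.
#' @export
merge_segments <- function(labels) {
  out <- labels
  out[grepl("^lm(_|$)", out)] <- "lm"
  out[grepl("^pda(_|$)", out)] <- "pda"
  out <- sub("^(lad|lcx|rca)_ostial$", "\\1_prox", out)
  bad <- setdiff(out, coronary_segments())
  if (length(bad) > 0L) stop("unknown segment label: ",
                             paste(bad, collapse = ", "))
  out
}

# Classify one clause. Returns a record row, or NULL, with a log entry
# recorded through `note`.
parse_clause <- function(clause, dictionary, note) {
  if (!is.null(match_synonym(clause, dictionary, "excluded"))) {
    note("excluded_territory", clause); return(NULL)
  }
  art <- match_synonym(clause, dictionary, "artery")
  if (is.null(art)) {
    if (grepl("%", clause, fixed = TRUE)) note("non_matched_percent", clause)
    return(NULL)
  }
  pos <- match_synonym(clause, dictionary, "position")
  pre <- if (art$key %in% c("lm", "pda")) art$key
         else paste0(art$key, "_", if (is.null(pos)) "prox" else pos$key)
  occ <- apply_occlusion_rule(clause, pre)
  if (!is.null(occ)) return(occ)
  pct <- extract_percent(clause)
  if (is.na(pct)) { note("qualitative_only", clause); return(NULL) }
  data.frame(segment = pre, percent = pct, source = "percent_token",
             clause = clause, stringsAsFactors = FALSE)
}

#' Parse a free-text procedure report into stenosis records
#'
#' Runs the full rule set: clause segmentation, dictionary matching,
#' percent extraction, occlusion keywords, segment merging and
#' max-severity retention per canonical segment.
#'
#' @param text report text (character scalar).
#' @param dictionary a segment dictionary, see
#'   [default_segment_dictionary()].
#' @return data.frame with columns `segment`, `percent`, `source`,
#'   `clause` — one row per canonical segment carrying the maximal percent
#'   found. Unparseable clauses are recorded in the `"log"` attribute, not
#'   fatal.
#' @export
parse_report <- function(text, dictionary = default_segment_dictionary()) {
  log_entries <- list()
  note <- function(rule, clause) {
    log_entries[[length(log_entries) + 1L]] <<-
      data.frame(rule = rule, clause = clause, stringsAsFactors = FALSE)
  }
  clauses <- segment_sentences(text)
  recs <- list()
  for (cl in clauses) {
    r <- parse_clause(cl, dictionary, note)
    if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  }
  empty <- data.frame(segment = character(), percent = integer(),
                      source = character(), clause = character(),
                      stringsAsFactors = FALSE)
  out <- if (length(recs) == 0L) empty else do.call(rbind, recs)
  if (nrow(out) > 0L) {
    out$segment <- merge_segments(out$segment)
    # most severe stenosis per canonical segment
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$segment), function(i) {
      i[which.max(out$percent[i])]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "log") <- if (length(log_entries) > 0L)
    do.call(rbind, log_entries) else
    data.frame(rule = character(), clause = character())
  out
}

#' Parse a directory of report text files
#'
#' @param dir directory containing `<exam_id>.txt` files.
#' @param dictionary segment dictionary.
#' @return data.frame with columns `exam_id`, `segment`, `percent`,
#'   `source`, `clause`.
#' @export
parse_report_dir <- function(dir, dictionary = default_segment_dictionary()) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    r <- parse_report(paste(readLines(f, warn = FALSE), collapse = " "),
                      dictionary)
    if (nrow(r) == 0L) return(NULL)
    cbind(exam_id = sub("\\.txt$", "", basename(f)), r)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(exam_id = character(), segment = character(),
                      percent = integer(), source = character(),
                      clause = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
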