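# Column aliases accepted on read. Field exports vary (Praat table exports
# differ across versions), so headers are resolved case-insensitively after
# stripping non-alphanumeric characters.
.column_aliases <- list(
  speaker    = c("speaker", "speakerid", "participant", "subject", "id"),
  session    = c("session", "timepoint", "time", "visit"),
  vowel      = c("vowel", "vowellabel", "phoneme", "target"),
  repetition = c("repetition", "rep", "token", "trial"),
  f1_hz      = c("f1hz", "f1", "formant1"),
  f2_hz      = c("f2hz", "f2", "formant2")
)

.canon_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.resolve_columns <- function(header) {
  canon <- .canon_header(header)
  out <- vapply(.column_aliases, function(aliases) {
    hit <- which(canon %in% aliases)
    if (length(hit) == 0) NA_integer_ else hit[[1]]
  }, integer(1))
  out
}

# plausible formant range for child speech in Hz; outside it a token is
# flagged for review, never dropped
.hz_range <- c(50, 5000)

#' Read a long-format formant token table
#'
#' Reads a CSV (or TSV) table with one row per vowel token: speaker, session,
#' vowel, repetition, F1 and F2 in Hz. Column names are matched
#' case-insensitively against common aliases (e.g. `F1(Hz)`, `f1_hz`, `F1`).
#' Structural problems (missing columns, duplicate token keys, non-numeric
#' formants, unknown vowel or session labels, non-positive frequencies) are
#' hard errors naming the offending row; phonetically suspicious but parseable
#' values (F2 <= F1, frequencies outside a plausible child-speech range) are
#' recorded as warning rows in the attached validation report so the analyst
#' sees, rather than silently loses, likely formant-tracking failures.
#'
#' @param path Path to the table.
#' @param delim Field delimiter; defaults to `","`, or `"\t"` when the file
#'   extension is `.tsv`/`.tab`.
#' @return A tibble of tokens with columns `speaker`, `session`, `vowel`,
#'   `repetition`, `f1_hz`, `f2_hz`, in file row order, carrying the
#'   validation report as attribute `"validation"` (also retrievable with
#'   [validation_report()]).
#' @seealso [validate_formant_tokens()], [write_formant_table()]
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("speaker,session,vowel,repetition,f1_hz,f2_hz",
#'              "DS01,baseline,IY,1,460,1800",
#'              "DS01,baseline,IY,2,465,1815"), path)
#' read_formant_table(path)
#' @export
read_formant_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    vs_abort(paste0("Formant table not found: ", path), "vowelspace_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  idx <- .resolve_columns(names(raw))
  if (anyNA(idx)) {
    vs_abort(
      paste0("Missing required column(s): ",
             paste(names(idx)[is.na(idx)], collapse = ", "),
             " (header was: ", paste(names(raw), collapse = ", "), ")"),
      "vowelspace_schema_error"
    )
  }
  tokens <- tibble::tibble(
    speaker    = raw[[idx[["speaker"]]]],
    session    = tolower(raw[[idx[["session"]]]]),
    vowel      = raw[[idx[["vowel"]]]],
    repetition = raw[[idx[["repetition"]]]],
    f1_hz      = raw[[idx[["f1_hz"]]]],
    f2_hz      = raw[[idx[["f2_hz"]]]]
  )

  for (col in c("repetition", "f1_hz", "f2_hz")) {
    num <- suppressWarnings(as.numeric(tokens[[col]]))
    bad <- which(is.na(num) & !is.na(tokens[[col]]))
    if (length(bad) > 0) {
      vs_abort(
        paste0("Non-numeric value in column '", col, "' at data row ",
               bad[[1]], ": '", tokens[[col]][bad[[1]]], "'"),
        "vowelspace_parse_error"
      )
    }
    tokens[[col]] <- num
  }
  tokens$repetition <- as.integer(tokens$repetition)

  bad_session <- which(!tokens$session %in% session_levels())
  if (length(bad_session) > 0) {
    vs_abort(
      paste0("Session label must be one of ",
             paste(session_levels(), collapse = "/"), "; data row ",
             bad_session[[1]], " has '", tokens$session[bad_session[[1]]], "'"),
      "vowelspace_schema_error"
    )
  }
  tokens$vowel <- normalize_vowel(tokens$vowel)

  key <- paste(tokens$speaker, tokens$session, tokens$vowel, tokens$repetition,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    vs_abort(
      paste0("Duplicate token key (speaker, session, vowel, repetition) at ",
             "data row ", dup[[1]], ": ",
             gsub("\r", "/", key[dup[[1]]], fixed = TRUE)),
      "vowelspace_duplicate_error"
    )
  }
  if (any(tokens$f1_hz <= 0 | tokens$f2_hz <= 0, na.rm = TRUE)) {
    bad <- which(tokens$f1_hz <= 0 | tokens$f2_hz <= 0)[[1]]
    vs_abort(
      paste0("Non-positive formant frequency at data row ", bad),
      "vowelspace_parse_error"
    )
  }

  issues <- validate_formant_tokens(tokens)
  attr(tokens, "validation") <- issues
  tokens
}

#' Validation report for a token table
#'
#' Screens tokens for phonetically suspicious values. These are surfaced as
#' warnings, not errors: mis-tracked formants are common in child speech and
#' must remain visible to the analyst rather than being dropped or imputed.
#'
#' @param tokens A token tibble as returned by [read_formant_table()].
#' @return A tibble with columns `row`, `speaker`, `session`, `vowel`,
#'   `repetition`, `check`, `message`; zero rows when the table is clean.
#'   Checks: `f2_le_f1` (second formant at or below the first) and
#'   `hz_out_of_range` (frequency outside 50-5000 Hz).
#' @export
validate_formant_tokens <- function(tokens) {
  flag <- function(rows, check, message) {
    tibble::tibble(
      row = rows,
      speaker = tokens$speaker[rows],
      session = tokens$session[rows],
      vowel = tokens$vowel[rows],
      repetition = tokens$repetition[rows],
      check = check,
      message = message
    )
  }
  swapped <- which(tokens$f2_hz <= tokens$f1_hz)
  outside <- which(
    tokens$f1_hz < .hz_range[[1]] | tokens$f1_hz > .hz_range[[2]] |
    tokens$f2_hz < .hz_range[[1]] | tokens$f2_hz > .hz_range[[2]]
  )
  dplyr::bind_rows(
    flag(swapped, "f2_le_f1", "F2 <= F1: possible formant-tracking error"),
    flag(outside, "hz_out_of_range",
         paste0("formant outside ", .hz_range[[1]], "-", .hz_range[[2]], " Hz"))
  )
}

#' @rdname validate_formant_tokens
#' @param x An object carrying a validation report.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation", exact = TRUE)
  if (is.null(rep)) validate_formant_tokens(x) else rep
}

#' Write a formant token table
#'
#' Writes tokens in the same CSV layout [read_formant_table()] reads, so a
#' write/read round trip reproduces the table field-for-field.
#'
#' @param tokens Token tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formant_table <- function(tokens, path) {
  readr::write_csv(
    tokens[, c("speaker", "session", "vowel", "repetition", "f1_hz", "f2_hz")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Per-vowel mean formants
#'
#' Averages F1 and F2 over repetitions within each (speaker, session, vowel)
#' cell — the per-vowel, per-participant, per-session averaging step the
#' quadrilateral metric and the shift-vector display are built on. No pooling
#' occurs across speakers or sessions.
#'
#' @param tokens Token tibble (columns `speaker`, `session`, `vowel`,
#'   `f1_hz`, `f2_hz`).
#' @return A tibble with one row per observed (speaker, session, vowel):
#'   `f1_mean`, `f2_mean` (arithmetic means, Hz) and `n_tokens`.
#' @export
compute_vowel_means <- function(tokens) {
  if (is.null(tokens) || nrow(tokens) == 0) {
    vs_abort("No tokens supplied to compute_vowel_means().",
             "vowelspace_empty_error")
  }
  tokens |>
    dplyr::group_by(.data$speaker, .data$session, .data$vowel) |>
    dplyr::summarise(
      f1_mean = mean(.data$f1_hz),
      f2_mean = mean(.data$f2_hz),
      n_tokens = dplyr::n(),
      .groups = "drop"
    )
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "vowelspace")
  if (!nzchar(path) || !file.exists(path)) {
    vs_abort(paste0("Packaged data file missing: ", file,
                    " (broken installation?)"), "vowelspace_packaging_error")
  }
  path
}

#' Published per-speaker change scores and intelligibility gains
#'
#' Loads the packaged transcription of the study cohort's individual-level
#' results: for each of the 13 children with Down syndrome, the baseline to
#' post-enrichment change in the three vowel space metrics (Hz^2) and the
#' intelligibility gain, i.e. the difference in Growth Scale Values on the
#' articulation battery's age-equivalent subtest. These printed values are
#' the inputs to the intelligibility-gain regression; the underlying audio
#' and formant tables are not publicly available.
#'
#' @return A 13-row tibble: `speaker`, `d_aavs`, `d_qvsa`, `d_vsahull`
#'   (Hz^2 change scores), `wcab_ae_gain` (integer gain score).
#' @seealso [fit_intelligibility_model()], [compute_vif()]
#' @examples
#' load_change_records()
#' @export
load_change_records <- function() {
  out <- readr::read_csv(
    .extdata("ds_change_scores.csv"),
    col_types = readr::cols(
      speaker = readr::col_character(),
      d_aavs = readr::col_double(),
      d_qvsa = readr::col_double(),
      d_vsahull = readr::col_double(),
      wcab_ae_gain = readr::col_integer()
    ),
    progress = FALSE
  )
  if (nrow(out) != 13 || anyNA(out) || anyDuplicated(out$speaker) > 0) {
    vs_abort("Packaged change-score data is corrupt.",
             "vowelspace_packaging_error")
  }
  out
}

#' Published group-level mean formants
#'
#' Loads the packaged group-average F1/F2 coordinates for the ten target
#' vowels: the Down syndrome cohort at baseline (`"DS"`) or the published
#' reference values for typically developing 10-12-year-olds (`"TD"`). These
#' support group overlay plots and the corner-vowel quadrilateral example;
#' they are group summaries, so `n_tokens` is not applicable and is `NA`.
#'
#' @param group `"DS"` or `"TD"`.
#' @return A 10-row tibble in the layout of [compute_vowel_means()]:
#'   `speaker` (the group label), `session` (`"baseline"` for DS,
#'   `"reference"` for TD), `vowel`, `f1_mean`, `f2_mean`, `n_tokens` (`NA`).
#' @examples
#' load_group_formants("DS")
#' @export
load_group_formants <- function(group = c("DS", "TD")) {
  group <- match.arg(group)
  all <- readr::read_csv(
    .extdata("group_formant_means.csv"),
    col_types = readr::cols(
      group = readr::col_character(),
      vowel = readr::col_character(),
      f1_hz = readr::col_double(),
      f2_hz = readr::col_double()
    ),
    progress = FALSE
  )
  sub <- all[all$group == group, ]
  if (nrow(sub) != 10) {
    vs_abort("Packaged group formant data is corrupt.",
             "vowelspace_packaging_error")
  }
  tibble::tibble(
    speaker = group,
    session = if (group == "DS") "baseline" else "reference",
    vowel = normalize_vowel(sub$vowel),
    f1_mean = sub$f1_hz,
    f2_mean = sub$f2_hz,
    n_tokens = NA_integer_
  )
}
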