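#' Write a symptom panel to CSV
#'
#' Canonical on-disk format: one row per observed subject-wave with columns
#' `subject_id`, `wave`, then one column per node.
#'
#' @param panel A `symptom_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  nodes <- panel_nodes(panel)
  readr::write_csv(panel[, c("subject_id", "wave", nodes)], path)
  invisible(path)
}

#' Read and validate a symptom panel from CSV
#'
#' Expects the [write_panel()] layout: header `subject_id`, `wave`, node
#' columns; waves labelled `T0`/`T1`. Malformed rows are collected into a
#' reject report rather than silently dropped: unknown wave labels,
#' duplicated (subject, wave) pairs, non-numeric or missing scores, and T1
#' rows without a corresponding T0 row. If more than half of all rows are
#' rejected, reading fails.
#'
#' @param path CSV file.
#' @param nodes Node columns to expect; default: every column after
#'   `subject_id` and `wave`.
#' @param wide Set `TRUE` if the file is one-row-per-subject wide format
#'   with node columns suffixed `_T0` / `_T1` instead.
#' @return A `symptom_panel`; the reject report (tibble `subject_id`,
#'   `wave`, `reason`) is in `attr(, "rejects")`.
#' @export
read_panel <- function(path, nodes = NULL, wide = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (wide) {
    stopifnot("subject_id" %in% names(raw))
    long <- tidyr::pivot_longer(raw, -"subject_id",
                                names_to = c(".value", "wave"),
                                names_pattern = "(.*)_(T[01])$")
    # a wholly empty follow-up row means "not observed", not malformed
    vals <- long[setdiff(names(long), c("subject_id", "wave"))]
    all_empty <- Reduce(`&`, lapply(vals, function(v) is.na(v) | v == ""))
    long <- long[long$wave == "T0" | !all_empty, , drop = FALSE]
    raw <- dplyr::relocate(long, "subject_id", "wave")
  }
  if (!all(c("subject_id", "wave") %in% names(raw))) {
    stop("panel file must have `subject_id` and `wave` columns", call. = FALSE)
  }
  nodes <- nodes %||% setdiff(names(raw), c("subject_id", "wave"))
  missing_nodes <- setdiff(nodes, names(raw))
  if (length(missing_nodes)) {
    stop("missing node column(s): ", paste(missing_nodes, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(raw)
  rejects <- tibble::tibble(subject_id = character(), wave = character(),
                            reason = character())
  add_reject <- function(id, wv, why) {
    rejects <<- dplyr::bind_rows(rejects,
                                 tibble::tibble(subject_id = id, wave = wv,
                                                reason = why))
  }

  bad_wave <- !raw$wave %in% c("T0", "T1")
  if (any(bad_wave)) {
    add_reject(raw$subject_id[bad_wave], raw$wave[bad_wave],
               "unknown wave label")
    raw <- raw[!bad_wave, , drop = FALSE]
  }
  dup <- duplicated(raw[c("subject_id", "wave")]) |
    duplicated(raw[c("subject_id", "wave")], fromLast = TRUE)
  if (any(dup)) {
    bad_ids <- unique(raw$subject_id[dup])
    add_reject(bad_ids, NA_character_, "duplicated (subject, wave) row")
    raw <- raw[!raw$subject_id %in% bad_ids, , drop = FALSE]
  }
  scores <- suppressWarnings(
    purrr::map(raw[nodes], ~ as.numeric(.x))
  )
  bad_score <- Reduce(`|`, purrr::map(scores, is.na))
  if (any(bad_score)) {
    is_t0 <- raw$wave == "T0" & bad_score
    # a broken T0 row invalidates the subject; a broken T1 row only itself
    if (any(is_t0)) {
      add_reject(raw$subject_id[is_t0], "T0", "non-numeric or missing score")
      raw_bad_subj <- unique(raw$subject_id[is_t0])
    } else raw_bad_subj <- character()
    is_t1 <- raw$wave == "T1" & bad_score
    if (any(is_t1)) {
      add_reject(raw$subject_id[is_t1], "T1", "non-numeric or missing score")
    }
    keep <- !(raw$subject_id %in% raw_bad_subj) & !bad_score
    raw <- raw[keep, , drop = FALSE]
    scores <- purrr::map(scores, ~ .x[keep])
  }
  t0_ids <- raw$subject_id[raw$wave == "T0"]
  orphan <- raw$wave == "T1" & !raw$subject_id %in% t0_ids
  if (any(orphan)) {
    add_reject(raw$subject_id[orphan], "T1", "no T0 row for subject")
    scores <- purrr::map(scores, ~ .x[!orphan])
    raw <- raw[!orphan, , drop = FALSE]
  }
  n_rejected_rows <- n_input - nrow(raw)
  if (n_input > 0 && n_rejected_rows > 0.5 * n_input) {
    stop("more than 50% of rows rejected (", n_rejected_rows, " of ",
         n_input, "); see the reject report", call. = FALSE)
  }
  out <- tibble::as_tibble(c(list(subject_id = raw$subject_id,
                                  wave = raw$wave), scores))
  panel <- new_symptom_panel(out, nodes)
  attr(panel, "rejects") <- rejects
  panel
}
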