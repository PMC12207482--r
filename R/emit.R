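# Result emitters. CSV is the canonical output; episode logs can also be
# written as JSON-lines. Every file starts with `#`-prefixed metadata lines
# (tool version, seed, config hash) so a run can be reproduced from its
# outputs alone; data go to files, log messages to standard error.

result_meta_lines <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("partnerbias"))
  lines <- sprintf("# partnerbias %s", ver)
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config_hash: %s", config_hash(config)))
  }
  lines
}

#' Write a result table as CSV with a metadata header
#'
#' Numeric columns are fixed to 12 significant digits. The file starts with
#' comment lines (`# partnerbias <version>`, `# seed: ...`,
#' `# config_hash: ...`) that [read_result_csv()] skips.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, seed = NULL, config = NULL) {
  tryCatch({
    writeLines(result_meta_lines(seed, config), path)
    out <- dplyr::mutate(tibble::as_tibble(x),
                         dplyr::across(dplyr::where(is.numeric),
                                       \(v) signif(v, 12)))
    readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  }, error = function(e) {
    stop(sprintf("failed to write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a result CSV written by [write_result_csv()]
#'
#' @param path Path to a result CSV.
#' @return A tibble (metadata comment lines are skipped).
#' @export
read_result_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write episode records as JSON-lines
#'
#' One line per episode: `{"episode": <id>, "races": [<per-race records>]}`.
#' Each line parses independently.
#'
#' @param records An episode-record tibble from [run_episodes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episodes_jsonl <- function(records, path) {
  check_records(records)
  split_recs <- split(records[setdiff(names(records), "episode")],
                      records$episode)
  lines <- vapply(names(split_recs), function(ep) {
    jsonlite::toJSON(list(episode = as.integer(ep),
                          races = split_recs[[ep]]),
                     auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  tryCatch(writeLines(lines, path), error = function(e) {
    stop(sprintf("failed to write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a JSON-lines episode log
#'
#' @param path Path written by [write_episodes_jsonl()].
#' @return An episode-record tibble.
#' @export
read_episodes_jsonl <- function(path) {
  lines <- readLines(path)
  purrr::map(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    dplyr::mutate(tibble::as_tibble(obj$races),
                  episode = as.integer(obj$episode), .before = 1)
  }) |>
    dplyr::bind_rows()
}
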