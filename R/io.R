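#' Read a trial table
#'
#' Tab-separated trial table with columns participant_id, block,
#' condition_id, trial_index, response (hyphen-joined button indices 1..5,
#' empty = no presses), is_catch. Header comment lines (`#`) are kept as
#' provenance. Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param design Optional `rabbit_design` to validate condition ids against.
#' @return data.frame (trial table), attribute `"header"` with the comment
#'   lines.
#' @export
read_trials <- function(path, design = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  body <- if (length(hdr)) lines[-hdr] else lines
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(response = "character"))
  tab$response[is.na(tab$response)] <- ""
  tab$is_catch <- as.logical(tab$is_catch)
  offset <- length(hdr) + 1L  # header line
  bad <- character(0)
  for (i in seq_len(nrow(tab))) {
    p <- tryCatch(parse_response(tab$response[i]), warning = function(w) NA)
    if (anyNA(p) || any(p < 1 | p > 5)) {
      bad <- c(bad, paste0("line ", i + offset, ": bad response '",
                           tab$response[i], "'"))
    }
  }
  if (!is.null(design)) {
    known <- c(condition_ids(design), "CATCH")
    for (i in which(!tab$condition_id %in% known)) {
      bad <- c(bad, paste0("line ", i + offset, ": unknown condition '",
                           tab$condition_id[i], "'"))
    }
  }
  if (length(bad)) stop("trial table schema violations:\n",
                        paste(bad, collapse = "\n"))
  attr(tab, "header") <- lines[hdr]
  tab
}

#' Write a trial table
#'
#' @param trials Trial table.
#' @param path Output path.
#' @param header Character vector of provenance comment lines (prefixed
#'   with `#` if not already).
#' @export
write_trials <- function(trials, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) {
    writeLines(ifelse(grepl("^#", header), header, paste0("# ", header)),
               con)
  }
  utils::write.table(trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth table
#'
#' @param ground_truth Ground-truth table from [generate_cohort()].
#' @param path Output path.
#' @param seed Master seed recorded in the header.
#' @export
write_ground_truth <- function(ground_truth, path, seed = NA) {
  write_trials(ground_truth, path,
               header = paste0("# ground truth; master_seed=", seed))
}
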