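# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_config <- function(...) {
  stop(structure(
    class = c("pdinet_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
stop_domain <- function(...) {
  stop(structure(
    class = c("pdinet_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Trim surrounding whitespace; identifiers are matched exactly otherwise.
#' @noRd
trim_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

#' @noRd
is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}
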