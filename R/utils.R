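# Shared small helpers. Kept internal.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a tab-delimited table
#'
#' Thin wrapper over [utils::read.delim()] enforcing the conventions used
#' throughout the package: header row, tab delimiter, no factor coercion,
#' UTF-8.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a tab-delimited table
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

# Split a peptide string into a character vector of residues.
pep_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Assert a peptide uses only the 20 amino acids plus X.
check_peptide <- function(x, what = "sequence") {
  bad <- setdiff(unique(pep_chars(x)), c(AA20, "X"))
  if (length(bad) > 0) {
    stop(what, " contains invalid residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# stopifnot with a readable message
fail_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
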