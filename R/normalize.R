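#' Normalize a microbe name
#'
#' Canonicalizes taxon names as they appear in Greengenes-style lineages and
#' profiling output: surrounding whitespace is trimmed, a leading rank prefix
#' of the form `"g__"` (any single letter) is removed, trailing `"_noname"`
#' and `"_unclassified"` suffixes are stripped (repeatedly, in any order), and
#' internal underscores separating words become single spaces.
#'
#' The function is idempotent: applying it twice gives the same result as
#' applying it once.
#'
#' @param raw Character vector of raw taxon names.
#' @return Character vector of normalized names, same length as `raw`.
#' @examples
#' normalize_taxon_name("Lactobacillus_noname")   # "Lactobacillus"
#' normalize_taxon_name("g__Bacteroides")         # "Bacteroides"
#' normalize_taxon_name("Escherichia_coli")       # "Escherichia coli"
#' @export
normalize_taxon_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw) || anyNA(raw) || any(!nzchar(raw))) {
    msea_error("msea_invalid_name_error", "taxon names must be non-empty strings")
  }
  x <- trimws(raw)
  x <- sub("^[A-Za-z]__", "", x)
  # strip stacked suffixes such as "_noname_noname" or "_unclassified_noname"
  repeat {
    y <- sub("(_noname|_unclassified)$", "", x)
    if (identical(y, x)) break
    x <- y
  }
  x <- gsub("_+", " ", x)
  x <- gsub("[ \t]+", " ", x)
  x <- trimws(x)
  if (any(!nzchar(x))) {
    bad <- raw[!nzchar(x)]
    msea_error(
      "msea_invalid_name_error",
      sprintf("name(s) empty after normalization: %s",
              paste(sQuote(bad), collapse = ", "))
    )
  }
  x
}
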