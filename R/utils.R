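`%||%` <- function(x, y) if (is.null(x)) y else x

# Signal a classed error so callers can dispatch on condition class.
msea_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "msea_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

msea_warning <- function(class, message) {
  warning(structure(
    class = c(class, "msea_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Case-insensitive canonical key for microbe-name matching. Stored names keep
# their original capitalization; all set operations go through this key.
taxon_key <- function(x) tolower(x)

# Unique by case-insensitive key, keeping the first-seen capitalization.
unique_taxa <- function(x) x[!duplicated(taxon_key(x))]
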