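#' Construct a microbe-set
#'
#' A named set of normalized microbe names. Members are deduplicated
#' case-insensitively (first-seen capitalization wins) and must be non-empty.
#'
#' @param term_id Term identifier (unique within a library).
#' @param members Character vector of microbe names (normalized).
#' @param term_label Human-readable name; defaults to `term_id`.
#' @export
microbe_set <- function(term_id, members, term_label = term_id) {
  stopifnot(is.character(term_id), length(term_id) == 1L, nzchar(term_id))
  members <- unique_taxa(as.character(members))
  if (length(members) == 0L) {
    msea_error("msea_empty_set_error",
               sprintf("microbe-set %s has no members", sQuote(term_id)))
  }
  structure(list(term_id = term_id, term_label = term_label,
                 members = members),
            class = "microbe_set")
}

#' Construct a microbe-set library
#'
#' A themed collection of microbe-sets with provenance; the canonical
#' container consumed by [msea()] and produced by the library builders.
#'
#' @param sets List of [microbe_set()] objects (term_ids must be unique).
#' @param name Library name.
#' @param provenance One of `"taxonomy"`, `"literature"`, `"disbiome"`,
#'   `"user"`.
#' @param allow_empty Permit a library with zero sets (used by builders whose
#'   input legitimately selects nothing, e.g. a rank absent from a tree).
#' @return A `microbe_set_library` with fields `name`, `provenance`, `sets`
#'   (named by term_id) and `member_union`.
#' @export
microbe_set_library <- function(sets, name = "library", provenance = "user",
                                allow_empty = FALSE) {
  provenance <- match.arg(provenance,
                          c("taxonomy", "literature", "disbiome", "user"))
  stopifnot(is.list(sets))
  if (length(sets) == 0L && !allow_empty) {
    msea_error("msea_empty_library_error", "library has no sets")
  }
  ids <- vapply(sets, function(s) s$term_id, character(1))
  if (anyDuplicated(ids)) {
    msea_error("msea_duplicate_term_error",
               sprintf("duplicate term_id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(sets) <- ids
  member_union <- unique_taxa(unlist(lapply(sets, `[[`, "members"),
                                     use.names = FALSE) %||% character(0))
  structure(list(name = name, provenance = provenance, sets = sets,
                 member_union = member_union),
            class = "microbe_set_library")
}

#' @export
print.microbe_set_library <- function(x, ...) {
  cat(sprintf("Microbe-set library '%s' (%s): %d sets, %d distinct members\n",
              x$name, x$provenance, length(x$sets), length(x$member_union)))
  invisible(x)
}

#' @export
length.microbe_set_library <- function(x) length(x$sets)

set_sizes <- function(library) {
  vapply(library$sets, function(s) length(s$members), integer(1))
}

#' Read a set library from a GMT file
#'
#' GMT dialect: one set per line, tab-delimited fields
#' `term_id`, `description`, then one member per field. Duplicate members on
#' a line collapse to one (set semantics).
#'
#' @param path File path.
#' @param name,provenance Passed to [microbe_set_library()].
#' @export
read_gmt <- function(path, name = basename(path), provenance = "user") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      msea_error("msea_format_error",
                 sprintf("GMT line %d has %d field(s); need term, description and at least one member",
                         i, length(fields)))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[i]] <- microbe_set(fields[1L], members, term_label = fields[2L])
  }
  microbe_set_library(sets, name = name, provenance = provenance,
                      allow_empty = TRUE)
}

#' Write a set library to a GMT file
#'
#' Inverse of [read_gmt()]: writing then reading reproduces the library up to
#' member order.
#'
#' @param library A `microbe_set_library`.
#' @param path Output path.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "microbe_set_library"))
  lines <- vapply(library$sets, function(s) {
    paste(c(s$term_id, s$term_label, s$members), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Build a disease-centric library from Disbiome-style records
#'
#' Groups organisms by disease regardless of the reported direction of
#' change (elevated or reduced), so a disease's set is the distinct organisms
#' ever linked to it. Records with a blank organism are skipped with a
#' warning.
#'
#' @param records Data frame with columns `disease`, `organism`, `direction`
#'   (direction values `"elevated"`/`"reduced"`; retained only for input
#'   validation, the grouping ignores it).
#' @return A `microbe_set_library` with provenance `"disbiome"`.
#' @export
parse_disbiome <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("disease", "organism", "direction") %in% names(records)))
  organism <- trimws(as.character(records$organism))
  blank <- !nzchar(organism) | is.na(organism)
  if (any(blank)) {
    msea_warning("msea_skipped_records_warning",
                 sprintf("skipped %d record(s) with blank organism", sum(blank)))
  }
  keep <- records[!blank, , drop = FALSE]
  if (nrow(keep) == 0L) {
    msea_error("msea_empty_library_error",
               "no usable disease-organism records after skipping blanks")
  }
  bad_dir <- !tolower(trimws(keep$direction)) %in% c("elevated", "reduced")
  if (any(bad_dir)) {
    msea_error("msea_format_error",
               sprintf("unknown direction value(s): %s",
                       paste(unique(keep$direction[bad_dir]), collapse = ", ")))
  }
  org <- normalize_taxon_name(trimws(keep$organism))
  sets <- lapply(split(org, as.character(keep$disease)), unique_taxa)
  sets <- Map(function(id, members) microbe_set(id, members),
              names(sets), sets)
  microbe_set_library(unname(sets), name = "disbiome",
                      provenance = "disbiome")
}

#' Read Disbiome export records from JSON or TSV
#'
#' The JSON form is an array of objects using the public export field names
#' (`disease_name`, `organism_name`, `qualitative_outcome`); the TSV form
#' uses headers `disease`, `organism`, `direction`. Both are mapped onto the
#' record layout [parse_disbiome()] consumes.
#'
#' @param path File path ending in `.json` or a tab-delimited file.
#' @return Data frame with columns `disease`, `organism`, `direction`.
#' @export
read_disbiome <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    stopifnot(is.data.frame(rec))
    cols <- c(disease = "disease_name", organism = "organism_name",
              direction = "qualitative_outcome")
    missing <- setdiff(unname(cols), names(rec))
    if (length(missing)) {
      msea_error("msea_format_error",
                 sprintf("Disbiome JSON lacks field(s): %s",
                         paste(missing, collapse = ", ")))
    }
    out <- data.frame(disease = rec[[cols["disease"]]],
                      organism = rec[[cols["organism"]]],
                      direction = tolower(rec[[cols["direction"]]]),
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(c("disease", "organism", "direction"), names(out))
    if (length(missing)) {
      msea_error("msea_format_error",
                 sprintf("Disbiome TSV lacks column(s): %s",
                         paste(missing, collapse = ", ")))
    }
    out <- out[c("disease", "organism", "direction")]
  }
  # the public export says "Elevated"/"Reduced"; normalize case
  out$direction <- tolower(out$direction)
  out
}
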